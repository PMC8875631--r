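test_that("1D topological winner matches the literal double loop", {
  w <- topological_winner_1d(c(0, 1, 10))
  expect_identical(w$index, 2L)       # totals 101, 82, 181
  expect_identical(w$value, 1)
  expect_identical(topological_winner_1d(5)$value, 5)
  set.seed(610)
  # n >= 3: with continuous draws the totals are distinct almost surely
  # (an n = 2 pair always ties in real arithmetic)
  for (i in 1:200) {
    s <- switch(1 + i %% 2, rnorm(sample(3:20, 1)), runif(sample(3:20, 1)))
    expect_identical(topological_winner_1d(s)$index, brute_winner_1d(s))
  }
  expect_error(topological_winner_1d(numeric(0)), "non-empty")
})

test_that("the winner is always the sample nearest the sample mean", {
  expect_identical(prop1_oracle(c(0, 1, 10)), 2L)   # mean 11/3
  expect_identical(prop1_oracle(c(-1, 1)), 1L)      # symmetric tie -> first
  expect_identical(topological_winner_1d(c(-1, 1))$index, 1L)
  set.seed(611)
  for (i in 1:500) {
    s <- if (i %% 2) rnorm(sample(3:30, 1)) else runif(sample(3:30, 1))
    expect_identical(topological_winner_1d(s)$index, prop1_oracle(s))
  }
})

test_that("2D topological winner is a sample and matches brute force", {
  pts <- rbind(c(0, 0), c(1, 1), c(10, 100))
  w <- topological_winner_2d(pts)
  expect_identical(w$index, 2L)
  expect_equal(w$point, c(1, 1))
  same <- rbind(c(2, 3), c(2, 3), c(2, 3))
  expect_equal(topological_winner_2d(same)$point, c(2, 3))
  set.seed(612)
  for (i in 1:100) {
    pts <- matrix(rnorm(2 * sample(3:15, 1)), ncol = 2)
    w <- topological_winner_2d(pts)
    expect_identical(w$index, brute_winner_2d(pts))
    expect_equal(w$point, pts[w$index, ])   # winner containment
  }
})

test_that("convergence runs are deterministic and shrink with n", {
  cfg <- sim_config(dimension = 1, distribution = "normal",
                    n_grid = c(10, 1000), replicates = 100, seed = 42)
  r1 <- run_convergence_experiment(cfg)
  r2 <- run_convergence_experiment(cfg)
  expect_identical(r1$draws, r2$draws)
  expect_lt(r1$summary$mean_err_topo[2], r1$summary$mean_err_topo[1])
  expect_lt(r1$summary$mean_err_avg[2], r1$summary$mean_err_avg[1])
  # a near-degenerate distribution pins every estimate to theta
  tight <- sim_config(dimension = 1, distribution = "uniform",
                      a = 0.5 - 1e-6, b = 0.5 + 1e-6,
                      n_grid = c(10, 50), replicates = 20, seed = 7)
  rt <- run_convergence_experiment(tight)
  expect_true(all(rt$draws$err_topo <= 1e-6))
  expect_true(all(rt$draws$err_avg <= 1e-6))
})

test_that("structured 2D samples keep the topological output on the curve", {
  cfg <- sim_config(dimension = 2, distribution = "uniform", a = 0, b = 1,
                    n = 50, replicates = 50, f = "square", seed = 9)
  r <- run_structured_2d_experiment(cfg)
  expect_identical(r$draws$topo_y, r$draws$topo_x^2)
  expect_true(all(r$draws$avg_y > r$draws$avg_x^2))   # Jensen, strict a.s.
  cfg3 <- sim_config(dimension = 2, distribution = "uniform", a = -1, b = 1,
                     n = 50, replicates = 50, f = "cube", seed = 9)
  r3 <- run_structured_2d_experiment(cfg3)
  expect_identical(r3$draws$topo_y, r3$draws$topo_x^3)
  inv <- sim_config(dimension = 2, distribution = "uniform", a = 0, b = 1,
                    n = 50, replicates = 10, f = "inv1p", seed = 9)
  ri <- run_structured_2d_experiment(inv)
  expect_identical(ri$draws$topo_y, 1 / (1 + ri$draws$topo_x))
  expect_error(sim_config(dimension = 2, f = "pole"), "arg")
})

test_that("simulation configs validate their fields", {
  expect_error(sim_config(dimension = 3), "1 or 2")
  expect_error(sim_config(replicates = 0), ">= 1")
  expect_error(run_convergence_experiment(sim_config(dimension = 2)), "1D")
  expect_error(run_structured_2d_experiment(sim_config(dimension = 1)), "2D")
})
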