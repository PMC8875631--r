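test_that("total distances and scores match hand-worked ensembles", {
  d <- disjoint_pair()
  e <- mask_ensemble(list(d$a, d$a, d$b))
  expect_equal(total_distances(e), c(1, 1, 2))
  expect_equal(total_scores(e), c(2, 2, 1))
  same <- mask_ensemble(list(d$a, d$a, d$a))
  expect_equal(total_distances(same), c(0, 0, 0))
  expect_equal(total_scores(same), c(3, 3, 3))
})

test_that("J_k + d_k = n and argmin d = argmax J on random ensembles", {
  set.seed(310)
  for (i in 1:20) {
    e <- random_hard_ensemble(sample(3:7, 1), 8, 8)
    d <- total_distances(e); J <- total_scores(e)
    expect_equal(J + d, rep(e$n, e$n))
    expect_identical(which.min(d), which.max(J))
  }
})

test_that("topological vote returns an input mask and permutes equivariantly", {
  d <- disjoint_pair()
  e <- mask_ensemble(list(d$a, d$a, d$b))
  r <- topological_vote(e)
  expect_identical(r$winner_index, 1L)
  expect_identical(fused_of(r), unclass(e$masks[[1]]))
  # move the B mask to the front: the A-copies still win
  r2 <- topological_vote(mask_ensemble(list(d$b, d$a, d$a)))
  expect_identical(r2$winner_index, 2L)
  expect_identical(fused_of(r2), d$a)
  set.seed(311)
  e3 <- random_hard_ensemble(5, 8, 8)
  r3 <- topological_vote(e3)
  expect_true(any(vapply(e3$masks,
                         function(m) identical(unclass(m), fused_of(r3)),
                         logical(1))))
})

test_that("hard arithmetical voting is per-pixel majority with ties to 1", {
  m1 <- matrix(c(1, 1, 0, 0), 2, 2)
  m2 <- matrix(c(1, 0, 1, 0), 2, 2)
  m3 <- matrix(c(1, 0, 0, 0), 2, 2)
  r <- arithmetical_vote_hard(mask_ensemble(list(m1, m2, m3)))
  expect_identical(fused_of(r), matrix(c(1, 0, 0, 0), 2, 2))
  # n = 2 tie goes to 1 (>= branch of the threshold)
  tie <- arithmetical_vote_hard(mask_ensemble(list(m1, 1 - m1)))
  expect_identical(fused_of(tie), matrix(1, 2, 2))
  expect_error(arithmetical_vote_hard(mask_ensemble(list(matrix(0.4, 2, 2), m1))),
               "hard")
})

test_that("soft arithmetical voting averages then thresholds", {
  s <- lapply(c(0.2, 0.4, 0.9), function(v) matrix(v, 2, 2))
  r <- arithmetical_vote_soft(mask_ensemble(s, kind = "soft"))
  expect_equal(unclass(r$fused_soft), matrix(0.5, 2, 2))
  expect_identical(fused_of(r), matrix(1, 2, 2))
  z <- mask_ensemble(list(matrix(0, 2, 2), matrix(0, 2, 2)), kind = "soft")
  expect_identical(fused_of(arithmetical_vote_soft(z)), matrix(0, 2, 2))
})

test_that("weighted voting recovers its degenerate cases", {
  d <- disjoint_pair()
  e <- mask_ensemble(list(d$a, d$a, d$b))
  # one-hot weights select that mask
  r <- weighted_arithmetical_vote(e, c(0, 0, 1))
  expect_identical(fused_of(r), d$b)
  # equal weights equal the soft average
  s <- random_soft_ensemble(3, 4, 4)
  expect_equal(unclass(weighted_arithmetical_vote(s, c(1, 1, 1))$fused_soft),
               unclass(arithmetical_vote_soft(s)$fused_soft))
  # default J_k weights on {A, A, B} give A-pixels 4/5 and B-pixels 1/5
  rj <- weighted_arithmetical_vote(e)
  expect_identical(fused_of(rj), d$a)
  expect_error(weighted_arithmetical_vote(e, c(0, 0, 0)), "zero")
  expect_error(weighted_arithmetical_vote(e, c(-1, 1, 1)), "non-negative")
})

test_that("soft topological voting scores on regularized masks but returns originals", {
  # u and v threshold identically but their regularized scores differ
  set.seed(317)
  u <- random_soft(6, 6)
  e <- mask_ensemble(list(u, u, random_soft(6, 6)), kind = "soft")
  r <- topological_vote(e)
  expect_identical(r$winner_index, 1L)
  expect_identical(unclass(r$fused_soft), u)   # original, not regularized
  reg <- lapply(e$masks, regularize_soft)
  expect_equal(r$scores[1],
               sum(vapply(reg, jaccard_soft, numeric(1), v = reg[[1]])))
})

test_that("every voting method on n copies of one mask returns that mask", {
  set.seed(318)
  m <- random_hard(6, 6)
  e <- mask_ensemble(list(m, m, m))
  expect_identical(fused_of(topological_vote(e)), m)
  expect_identical(fused_of(arithmetical_vote_hard(e)), m)
  expect_identical(fused_of(weighted_arithmetical_vote(e, c(1, 2, 3))), m)
  expect_identical(fused_of(local_topological_vote(e, 1)), m)
})
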