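test_that("truth masks are deterministic, connected, and shaped as advertised", {
  for (kind in c("blob", "rectangle", "vessel")) {
    t1 <- make_truth_mask(c(64, 64), kind, seed = 13)
    t2 <- make_truth_mask(c(64, 64), kind, seed = 13)
    expect_identical(t1, t2)
    expect_gt(sum(t1), 0)
    expect_true(max(EBImage::bwlabel(unclass(t1))) == 1)  # one component
  }
  expect_error(make_truth_mask(c(8, 64), "blob"), "16 x 16")
})

test_that("a rectangle truth is exactly one filled axis-aligned rectangle", {
  t <- make_truth_mask(c(48, 32), "rectangle", seed = 4)
  rows <- range(which(rowSums(t) > 0)); cols <- range(which(colSums(t) > 0))
  expect_equal(sum(t), (diff(rows) + 1) * (diff(cols) + 1))
})

test_that("vessel truths are thin and stay connected across seeds", {
  for (seed in 1:10) {
    v <- make_truth_mask(c(64, 64), "vessel", seed = seed)
    expect_lt(mean(v), 0.25)
    expect_true(max(EBImage::bwlabel(unclass(v))) == 1)
  }
})

test_that("annotator perturbation is identity at zero noise and empty at full dropout", {
  t <- make_truth_mask(c(64, 64), "blob", seed = 2)
  expect_identical(perturb_mask(t, list(jitter = 0, dropout = 0, translate = 0), 5),
                   t)
  expect_identical(sum(perturb_mask(t, list(jitter = 0, dropout = 1, translate = 0), 5)),
                   0)
  expect_identical(perturb_mask(t, default_good_noise(), 5),
                   perturb_mask(t, default_good_noise(), 5))
  expect_error(perturb_mask(t, list(jitter = -1, dropout = 0, translate = 0), 1),
               ">= 0")
})

test_that("default noise keeps good annotators close to the truth", {
  hits <- 0L
  for (seed in 1:40) {
    t <- make_truth_mask(c(64, 64), "blob", seed = seed)
    p <- perturb_mask(t, default_good_noise(), seed = seed + 1000)
    hits <- hits + (jaccard_hard(p, t) > 0.5)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("ensembles are reproducible and their outliers land where reported", {
  spec <- ensemble_spec(n = 7, n_outliers = 2, seed = 21)
  r1 <- make_ensemble(spec)
  r2 <- make_ensemble(spec)
  expect_identical(lapply(r1$ensemble$masks, unclass),
                   lapply(r2$ensemble$masks, unclass))
  expect_identical(r1$outlier_indices, r2$outlier_indices)
  expect_identical(r1$ensemble$n, 7L)
  expect_identical(sort(unique(r1$manifest$role)), c("good", "shift"))
  expect_identical(which(r1$manifest$role != "good"), r1$outlier_indices)
  expect_error(ensemble_spec(n = 6, n_outliers = 3), "good")
})

test_that("zero-noise, zero-outlier ensembles are n copies of the truth", {
  spec <- ensemble_spec(n = 5, n_outliers = 0,
                        good_noise = list(jitter = 0, dropout = 0, translate = 0),
                        seed = 3)
  r <- make_ensemble(spec)
  for (m in r$ensemble$masks) expect_identical(unclass(m), unclass(r$truth))
})

test_that("planted outliers score below every good annotator", {
  ok <- 0L
  for (seed in 1:40) {
    r <- make_ensemble(ensemble_spec(n = 8, n_outliers = 2, seed = seed))
    J <- vapply(r$ensemble$masks, jaccard_hard, numeric(1), b = r$truth)
    out <- r$outlier_indices
    ok <- ok + (max(J[out]) < min(J[-out]))
  }
  expect_gte(ok / 40, 0.95)
})

test_that("spurious and empty outlier modes behave as declared", {
  re <- make_ensemble(ensemble_spec(n = 5, n_outliers = 1,
                                    outlier_mode = "empty", seed = 8))
  expect_identical(sum(re$ensemble$masks[[re$outlier_indices]]), 0)
  rs <- make_ensemble(ensemble_spec(n = 5, n_outliers = 1,
                                    outlier_mode = "spurious", seed = 8))
  sp <- rs$ensemble$masks[[rs$outlier_indices]]
  expect_gt(sum(sp), 0)
  expect_false(identical(unclass(sp), unclass(rs$truth)))
})

test_that("softened masks stay in [0, 1] and track their hard source", {
  t <- make_truth_mask(c(64, 64), "blob", seed = 6)
  s <- soften_mask(t, sigma = 1)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(jaccard_hard(threshold_mask(s), t), 0.9)
  e <- make_ensemble(ensemble_spec(n = 4, n_outliers = 1, seed = 9))
  se <- soften_ensemble(e$ensemble, sigma = 1)
  expect_identical(se$kind, "soft")
  expect_identical(se$n, 4L)
})
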