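#' Topological winner of a 1D sample
#'
#' The topological estimator of a location parameter picks the *sample*
#' `Y_n = argmin_{S_i} sum_j (S_i - S_j)^2` — the medoid under squared
#' distance — instead of the sample average `mean(samples)`. The totals are
#' evaluated through the algebraic expansion
#' `sum_j (S_i - S_j)^2 = n S_i^2 - 2 S_i sum_j S_j + sum_j S_j^2`, which is
#' O(n) per candidate; tests check it against the literal O(n^2) double loop.
#' Ties go to the lowest index. The winner is always the sample closest to the
#' sample mean (see [prop1_oracle()]).
#'
#' @param samples numeric vector, length >= 1.
#' @return a list with `value` (the winning sample) and `index` (1-based).
#' @examples
#' topological_winner_1d(c(0, 1, 10))  # totals 101, 82, 181 -> winner 1
#' @export
topological_winner_1d <- function(samples) {
  n <- length(samples)
  if (n == 0L) stop("samples must be non-empty", call. = FALSE)
  tot <- n * samples^2 - 2 * samples * sum(samples) + sum(samples^2)
  i <- which.min(tot)
  list(value = samples[i], index = i)
}

#' Closed-form oracle for the 1D topological winner
#'
#' The total squared distance `h(x) = sum_j (x - S_j)^2` is a parabola with
#' vertex at the sample mean and is symmetric about it, so the sample
#' minimizing the total is exactly the sample closest to the mean. This
#' function computes `argmin_i |S_i - mean(samples)|` directly (ties to the
#' lowest index) and serves as the exact cross-check for
#' [topological_winner_1d()].
#'
#' @inheritParams topological_winner_1d
#' @return the 1-based index of the sample nearest the mean.
#' @export
prop1_oracle <- function(samples) {
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  which.min(abs(samples - mean(samples)))
}

#' Topological winner of a 2D sample
#'
#' The planar medoid under squared Euclidean distance:
#' `argmin_i sum_j ||S_i - S_j||^2`, ties to the lowest index. Because the
#' winner is one of the samples, it inherits any structure the samples share —
#' e.g. points of the form `[x, f(x)]` stay exactly on the curve `y = f(x)`,
#' which the coordinate-wise average does not.
#'
#' @param points an n x 2 numeric matrix of sample points.
#' @return a list with `point` (length-2 vector) and `index` (1-based).
#' @export
topological_winner_2d <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stop("points must be non-empty", call. = FALSE)
  tot <- n * rowSums(points^2) -
    2 * as.vector(points %*% colSums(points)) + sum(points^2)
  i <- which.min(tot)
  list(point = points[i, ], index = i)
}

#' Simulation configuration
#'
#' @param dimension 1 or 2.
#' @param distribution `"normal"` (mean `theta`, sd `sigma`) or `"uniform"`
#'   (on `[a, b]`, so theta = (a+b)/2).
#' @param theta,sigma location and spread of the normal draws.
#' @param a,b bounds of the uniform draws.
#' @param n_grid sample sizes to simulate at.
#' @param n sample size for single-n experiments (2D).
#' @param replicates independent datasets per sample size.
#' @param f structure function label for 2D draws: `"square"` (x^2), `"cube"`
#'   (x^3) or `"inv1p"` (1/(1+x)).
#' @param seed integer seed; all draws are reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(dimension = 1, distribution = c("normal", "uniform"),
                       theta = 0, sigma = 1, a = 0, b = 1,
                       n_grid = c(10L, 100L, 1000L, 10000L), n = 200L,
                       replicates = 500L, f = c("square", "cube", "inv1p"),
                       seed = 1L) {
  distribution <- match.arg(distribution)
  f <- match.arg(f)
  if (!dimension %in% c(1, 2)) stop("dimension must be 1 or 2", call. = FALSE)
  if (any(n_grid < 1) || replicates < 1 || n < 1) {
    stop("n_grid, n and replicates must be >= 1", call. = FALSE)
  }
  structure(list(dimension = dimension, distribution = distribution,
                 theta = theta, sigma = sigma, a = a, b = b,
                 n_grid = as.integer(n_grid), n = as.integer(n),
                 replicates = as.integer(replicates), f = f,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_theta <- function(cfg) {
  switch(cfg$distribution, normal = cfg$theta, uniform = (cfg$a + cfg$b) / 2)
}

sim_draw <- function(cfg, n) {
  switch(cfg$distribution,
         normal = stats::rnorm(n, cfg$theta, cfg$sigma),
         uniform = stats::runif(n, cfg$a, cfg$b))
}

struct_fun <- function(label) {
  switch(label,
         square = function(x) x^2,
         cube = function(x) x^3,
         inv1p = function(x) 1 / (1 + x),
         stop(sprintf("unknown structure function '%s'", label), call. = FALSE))
}

#' Convergence experiment: sample average vs topological estimator (1D)
#'
#' For each sample size on `cfg$n_grid`, draws `cfg$replicates` i.i.d.
#' datasets and records the absolute error to theta of the sample average
#' `Sigma_n` and of the topological winner `Y_n`. Both estimators converge to
#' theta at the sqrt(n) rate; the per-n summary carries
#' `mean_err * sqrt(n)` so the rate is directly inspectable. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [sim_config()] with `dimension = 1`.
#' @return a `sim_result`: list with `draws` (per-replicate data.frame:
#'   n, replicate, err_avg, err_topo) and `summary` (per-n means/sds and
#'   sqrt(n)-scaled means).
#' @export
run_convergence_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$dimension != 1) stop("run_convergence_experiment is 1D", call. = FALSE)
  theta <- sim_theta(cfg)
  rows <- with_seed(cfg$seed, {
    lapply(cfg$n_grid, function(n) {
      err_avg <- numeric(cfg$replicates)
      err_topo <- numeric(cfg$replicates)
      for (r in seq_len(cfg$replicates)) {
        s <- sim_draw(cfg, n)
        err_avg[r] <- abs(mean(s) - theta)
        err_topo[r] <- abs(topological_winner_1d(s)$value - theta)
      }
      data.frame(n = n, replicate = seq_len(cfg$replicates),
                 err_avg = err_avg, err_topo = err_topo)
    })
  })
  draws <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(draws, draws$n), function(d) {
    data.frame(n = d$n[1],
               mean_err_avg = mean(d$err_avg), sd_err_avg = stats::sd(d$err_avg),
               mean_err_topo = mean(d$err_topo), sd_err_topo = stats::sd(d$err_topo),
               scaled_err_avg = mean(d$err_avg) * sqrt(d$n[1]),
               scaled_err_topo = mean(d$err_topo) * sqrt(d$n[1]))
  }))
  summ <- summ[order(summ$n), ]
  rownames(summ) <- NULL
  structure(list(config = cfg, draws = draws, summary = summ),
            class = "sim_result")
}

#' Structured 2D experiment: estimators on a curve
#'
#' Draws `x_i` i.i.d. with mean theta, forms structured samples
#' `S_i = [x_i, f(x_i)]`, and compares the coordinate-wise average
#' `[mean(x), mean(f(x))]` with the topological winner against the truth
#' `[theta, f(theta)]` in Euclidean distance. The topological output is always
#' a sample, hence exactly on the curve `y = f(x)`; for convex f (e.g. x^2 on
#' U(0,1)) the average's second component overshoots `f` of its first
#' component (Jensen), dragging the average off the curve.
#'
#' @param cfg a [sim_config()] with `dimension = 2`; uses `cfg$n` samples per
#'   replicate.
#' @return a `sim_result` with per-replicate errors (`err_avg`, `err_topo`),
#'   the average's components (`avg_x`, `avg_y`), the winner's components
#'   (`topo_x`, `topo_y`), and a summary row.
#' @export
run_structured_2d_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$dimension != 2) stop("run_structured_2d_experiment is 2D", call. = FALSE)
  f <- struct_fun(cfg$f)
  theta <- sim_theta(cfg)
  truth <- c(theta, f(theta))
  draws <- with_seed(cfg$seed, {
    out <- vector("list", cfg$replicates)
    for (r in seq_len(cfg$replicates)) {
      x <- sim_draw(cfg, cfg$n)
      S <- cbind(x, f(x))
      avg <- c(mean(S[, 1]), mean(S[, 2]))
      topo <- topological_winner_2d(S)$point
      out[[r]] <- data.frame(
        replicate = r,
        avg_x = avg[1], avg_y = avg[2], topo_x = topo[1], topo_y = topo[2],
        err_avg = sqrt(sum((avg - truth)^2)),
        err_topo = sqrt(sum((topo - truth)^2)))
    }
    do.call(rbind, out)
  })
  summ <- data.frame(n = cfg$n, f = cfg$f,
                     mean_err_avg = mean(draws$err_avg),
                     mean_err_topo = mean(draws$err_topo))
  structure(list(config = cfg, draws = draws, summary = summ, truth = truth),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %dD %s, seed %d\n", x$config$dimension,
              x$config$distribution, x$config$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
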