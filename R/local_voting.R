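#' Clipped square neighborhood of a pixel
#'
#' The s-neighborhood of pixel (i, j) is the inclusive square
#' `[i-s, i+s] x [j-s, j+s]` intersected with the image grid, so interior
#' windows have shape (2s+1) x (2s+1) and windows near the border are clipped
#' (never padded). With s = 0 the neighborhood is the pixel itself.
#'
#' @param m a mask or numeric matrix.
#' @param center integer pair `c(i, j)` (1-based row, column), inside `m`.
#' @param s non-negative integer radius.
#' @return the sub-matrix of `m` over the clipped window.
#' @export
extract_window <- function(m, center, s) {
  m <- unclass(as.matrix(m))
  i <- as.integer(center[1]); j <- as.integer(center[2])
  s <- as.integer(s)
  if (s < 0) stop("radius s must be >= 0", call. = FALSE)
  if (i < 1 || i > nrow(m) || j < 1 || j > ncol(m)) {
    stop(sprintf("center (%d, %d) outside %dx%d image", i, j, nrow(m), ncol(m)),
         call. = FALSE)
  }
  m[max(1L, i - s):min(nrow(m), i + s),
    max(1L, j - s):min(ncol(m), j + s), drop = FALSE]
}

# sliding sums of the (2s+1) row-neighbors of every entry, clipped at the
# image border: out-of-image positions contribute nothing (exact zeros)
axis_sums_rows <- function(x, s) {
  h <- nrow(x)
  acc <- x
  for (d in seq_len(min(s, h - 1L))) {
    lo <- seq_len(h - d); hi <- (1L + d):h
    acc[hi, ] <- acc[hi, , drop = FALSE] + x[lo, , drop = FALSE]
    acc[lo, ] <- acc[lo, , drop = FALSE] + x[hi, , drop = FALSE]
  }
  acc
}

# clipped-window sums for every pixel of x at radius s, as two separable
# shifted-addition passes. Unlike a summed-area table this only ever *adds*
# the window's own elements, so sums that are exact in real arithmetic (e.g.
# an all-zero window) stay exact in floating point — no prefix-sum
# cancellation noise, which is what bit-exact agreement with the per-pixel
# reference requires.
window_sums <- function(x, s) {
  t(axis_sums_rows(t(axis_sums_rows(x, s)), s))
}

# per-pixel pairwise min-over-max score matrix for masks a, b at radius s;
# a window whose union sum is 0 (truly empty: the sums are exact for
# nonnegative entries) scores 1 by the empty/empty convention
pair_score_windows <- function(a, b, s) {
  mn <- window_sums(pmin(a, b), s)
  mx <- window_sums(pmax(a, b), s)
  sc <- mn / mx
  sc[mx == 0] <- 1
  sc
}

# per-pixel total distances for all candidates: list of n h x w matrices,
# accumulated in i = 1..n order (matches the reference path's sum order)
local_total_distances <- function(masks, s) {
  n <- length(masks)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  pair <- vector("list", n * n)  # [i + n*(k-1)] for i <= k
  for (i in seq_len(n)) {
    for (k in i:n) {
      pair[[i + n * (k - 1L)]] <-
        if (i == k) matrix(1, h, w) else pair_score_windows(masks[[i]], masks[[k]], s)
    }
  }
  lapply(seq_len(n), function(k) {
    d <- matrix(0, h, w)
    for (i in seq_len(n)) {
      sc <- if (i <= k) pair[[i + n * (k - 1L)]] else pair[[k + n * (i - 1L)]]
      d <- d + (1 - sc)
    }
    d
  })
}

#' Local topological voting on sliding neighborhoods
#'
#' Runs topological voting independently at every pixel: the n candidate
#' windows `extract_window(S_k, p, s)` compete by total windowed Jaccard
#' distance, and the fused value at p is the local winner's value at p. The
#' radius interpolates between the global methods: s = 0 reproduces per-pixel
#' majority voting (for odd n), and s >= max(h, w) reproduces global
#' [topological_vote()]. Soft ensembles are scored on
#' [regularize_soft()]-transformed values; fused values come from the
#' original masks. Ties go to the lowest candidate index. The implementation
#' accumulates clipped-window pairwise min/max sums with separable sliding
#' box sums (O(n^2 s N) total) and is checked bit-exactly against the literal
#' per-pixel loop [local_vote_reference()].
#'
#' @param e a [mask_ensemble()] or list of same-shape masks.
#' @param s non-negative integer radius of the square neighborhood.
#' @return a `vote_report` whose `winner_map` is the h x w matrix of winning
#'   candidate indices (1-based).
#' @export
local_topological_vote <- function(e, s) {
  e <- as_ensemble(e)
  s <- as.integer(s)
  if (s < 0) stop("radius s must be >= 0", call. = FALSE)
  D <- local_total_distances(scoring_masks(e), s)
  h <- e$dim[1]; w <- e$dim[2]
  Dmat <- vapply(D, c, numeric(h * w))
  if (h * w == 1L) Dmat <- matrix(Dmat, nrow = 1L)
  win <- max.col(-Dmat, ties.method = "first")
  M <- vapply(e$masks, c, numeric(h * w))
  if (h * w == 1L) M <- matrix(M, nrow = 1L)
  fused <- matrix(M[cbind(seq_len(h * w), win)], h, w)
  wm <- matrix(win, h, w)
  if (e$kind == "soft") {
    new_vote_report("local-topological-soft", threshold_mask(fused),
                    soft_mask(fused), winner_map = wm, params = list(s = s))
  } else {
    new_vote_report("local-topological-hard", hard_mask(fused),
                    winner_map = wm, params = list(s = s))
  }
}

#' Brute-force reference for local topological voting
#'
#' The definitional per-pixel loop: extract every candidate's clipped window,
#' score all pairs with the (hard or soft) Jaccard score, pick the argmin of
#' the total distance. No optimization whatsoever; exists as the equivalence
#' oracle for [local_topological_vote()], which must match it bit-exactly.
#'
#' @inheritParams local_topological_vote
#' @return a `vote_report` with the same contract as
#'   [local_topological_vote()].
#' @export
local_vote_reference <- function(e, s) {
  e <- as_ensemble(e)
  s <- as.integer(s)
  if (s < 0) stop("radius s must be >= 0", call. = FALSE)
  masks <- scoring_masks(e)
  n <- e$n; h <- e$dim[1]; w <- e$dim[2]
  fused <- matrix(0, h, w)
  wm <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      wins <- lapply(masks, extract_window, center = c(i, j), s = s)
      d <- numeric(n)
      for (k in seq_len(n)) {
        for (l in seq_len(n)) {
          d[k] <- d[k] + (1 - mom_score(wins[[l]], wins[[k]]))
        }
      }
      best <- which.min(d)
      wm[i, j] <- best
      fused[i, j] <- e$masks[[best]][i, j]
    }
  }
  if (e$kind == "soft") {
    new_vote_report("local-topological-soft-reference", threshold_mask(fused),
                    soft_mask(fused), winner_map = wm, params = list(s = s))
  } else {
    new_vote_report("local-topological-hard-reference", hard_mask(fused),
                    winner_map = wm, params = list(s = s))
  }
}
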