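#' Hard and soft segmentation masks
#'
#' A *hard mask* is a 2D grid of values in \{0, 1\} marking the region of
#' interest in an image; a *soft mask* carries continuous per-pixel values in
#' \[0, 1\] (e.g. sigmoid outputs of a segmentation model). Both are stored as
#' plain numeric matrices with a class attribute. Coordinates are row-major and
#' 1-based: entry `[i, j]` is row `i` from the top, column `j` from the left.
#'
#' @param values a numeric matrix (or object coercible to one); entries must be
#'   exactly 0/1 for `hard_mask()` and within \[0, 1\] for `soft_mask()`.
#' @return a matrix of class `hard_mask` or `soft_mask`.
#' @examples
#' m <- hard_mask(matrix(c(1, 1, 0, 0), 2, 2))
#' s <- soft_mask(matrix(runif(9), 3, 3))
#' @export
hard_mask <- function(values) {
  m <- as_mask_matrix(values)
  if (!all(m == 0 | m == 1)) {
    stop("hard mask entries must be exactly 0 or 1", call. = FALSE)
  }
  structure(m, class = c("hard_mask", "mask"))
}

#' @rdname hard_mask
#' @export
soft_mask <- function(values) {
  m <- as_mask_matrix(values)
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("soft mask entries must lie in [0, 1]", call. = FALSE)
  }
  structure(m, class = c("soft_mask", "mask"))
}

as_mask_matrix <- function(values) {
  m <- unclass(as.matrix(values))
  if (!is.numeric(m)) stop("mask values must be numeric", call. = FALSE)
  if (nrow(m) < 1L || ncol(m) < 1L) stop("mask must be at least 1x1", call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @rdname hard_mask
#' @param x an object.
#' @export
is_hard_mask <- function(x) inherits(x, "hard_mask")

#' @rdname hard_mask
#' @export
is_soft_mask <- function(x) inherits(x, "soft_mask")

#' Infer whether a mask is hard (binary) or soft
#'
#' Classed masks report their class; a bare matrix is "hard" when every entry
#' is exactly 0 or 1, "soft" otherwise.
#'
#' @param m a mask or numeric matrix.
#' @return `"hard"` or `"soft"`.
#' @export
mask_kind <- function(m) {
  if (is_hard_mask(m)) return("hard")
  if (is_soft_mask(m)) return("soft")
  if (all(m == 0 | m == 1)) "hard" else "soft"
}

#' @export
print.mask <- function(x, ...) {
  cat(sprintf("<%s> %d x %d, foreground weight %.4g\n",
              class(x)[1], nrow(x), ncol(x), sum(x)))
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Jaccard (IoU) score of two hard masks
#'
#' The intersection-over-union score |a AND b| / |a OR b|. When both masks are
#' entirely empty the score is defined as 1: two empty masks coincide, and this
#' convention makes radius-0 local topological voting coincide with per-pixel
#' majority voting.
#'
#' @param a,b hard masks (or binary matrices) of the same shape.
#' @return a number in \[0, 1\].
#' @examples
#' jaccard_hard(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 0, 0, 1), 2))
#' @export
jaccard_hard <- function(a, b) {
  check_same_shape(a, b)
  if (!all(a == 0 | a == 1) || !all(b == 0 | b == 1)) {
    stop("jaccard_hard requires binary masks", call. = FALSE)
  }
  mom_score(a, b)
}

#' Soft Jaccard (min-over-max) score of two soft masks
#'
#' The MOM generalization of IoU: sum of per-pixel minima over sum of per-pixel
#' maxima. On binary-valued inputs it reduces exactly to [jaccard_hard()]; the
#' empty/empty case is 1 by the same convention.
#'
#' @param u,v soft masks (or matrices with entries in \[0, 1\]) of one shape.
#' @return a number in \[0, 1\].
#' @export
jaccard_soft <- function(u, v) {
  check_same_shape(u, v)
  if (any(u < 0) || any(u > 1) || any(v < 0) || any(v > 1)) {
    stop("soft mask entries must lie in [0, 1]", call. = FALSE)
  }
  mom_score(u, v)
}

# min-over-max on validated same-shape matrices; 0/0 -> 1
mom_score <- function(a, b) {
  mx <- sum(pmax(a, b))
  if (mx == 0) return(1)
  sum(pmin(a, b)) / mx
}

#' Jaccard distance between two masks
#'
#' One minus the (hard or soft) Jaccard score; a metric on masks, 0 exactly
#' when two hard masks coincide.
#'
#' @param a,b masks of the same shape.
#' @param kind `"hard"`, `"soft"`, or `NULL` to infer from the inputs (binary
#'   values mean hard).
#' @return a number in \[0, 1\].
#' @export
jaccard_distance <- function(a, b, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (mask_kind(a) == "hard" && mask_kind(b) == "hard") "hard" else "soft"
  }
  kind <- match.arg(kind, c("hard", "soft"))
  1 - switch(kind, hard = jaccard_hard(a, b), soft = jaccard_soft(a, b))
}

#' Naive binary accuracy of a mask against a reference
#'
#' Fraction of pixels at which `a` equals `truth`. For small objects this
#' score is misleading: a prediction with zero overlap against a tiny target
#' can still score near 1, which is why evaluation here leans on the Jaccard
#' score instead.
#'
#' @param a,truth hard masks of the same shape.
#' @return a number in \[0, 1\].
#' @export
binary_accuracy <- function(a, truth) {
  check_same_shape(a, truth)
  mean(a == truth)
}

#' Threshold a soft mask into a hard mask
#'
#' A pixel becomes 1 when its value is greater than *or equal to* the
#' threshold (the >= branch carries the boundary), else 0.
#'
#' @param s a soft mask or numeric matrix with entries in \[0, 1\].
#' @param t threshold, strictly between 0 and 1; default 0.5.
#' @return a [hard_mask()].
#' @export
threshold_mask <- function(s, t = 0.5) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1) {
    stop("threshold t must lie strictly in (0, 1)", call. = FALSE)
  }
  hard_mask((unclass(as.matrix(s)) >= t) * 1)
}

#' Regularize sigmoid-valued soft masks before scoring
#'
#' Piecewise-linear truncation of soft values: \[0, 0.2\] maps to 0,
#' \[0.8, 1\] maps to 1, and the middle band maps linearly,
#' `10 * (v - 0.2) / 6`. Sigmoid outputs hug 0 and 1; truncating the
#' near-saturated tails before computing soft Jaccard scores stops tiny
#' background noise from diluting the min/max sums. The map is continuous,
#' non-decreasing, and fixes 0.5, so thresholding at 0.5 before or after
#' regularization agrees away from the exact 0.5 level.
#'
#' @param s a soft mask or matrix with entries in \[0, 1\].
#' @return a [soft_mask()] of the same shape.
#' @export
regularize_soft <- function(s) {
  m <- unclass(as.matrix(s))
  if (any(m < 0) || any(m > 1)) {
    stop("soft mask entries must lie in [0, 1]", call. = FALSE)
  }
  soft_mask(pmin(pmax(10 * (m - 0.2) / 6, 0), 1))
}
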