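#' Total Jaccard distances and scores within an ensemble
#'
#' For each candidate mask S_k the total distance is
#' `d_k = sum_i jaccard_distance(S_i, S_k)` and the total score is
#' `J_k = sum_i J(S_i, S_k)`, both including the self term (which contributes
#' 0 to d_k and 1 to J_k), so `J_k + d_k = n` for every k. These totals drive
#' every topological and hybrid voting rule: the mask closest to all the
#' others (the ensemble medoid under the Jaccard distance) is the
#' topologically best candidate. Scoring of soft ensembles happens on
#' [regularize_soft()]-transformed values.
#'
#' @param e a [mask_ensemble()] or list of same-shape masks.
#' @return a numeric vector of length n.
#' @export
total_distances <- function(e) {
  e <- as_ensemble(e)
  totals_from_masks(scoring_masks(e), e$kind)$d
}

#' @rdname total_distances
#' @export
total_scores <- function(e) {
  e <- as_ensemble(e)
  totals_from_masks(scoring_masks(e), e$kind)$J
}

# pairwise min-over-max scores, accumulated sequentially in i order so the
# summation order matches the per-pixel reference path bit for bit
totals_from_masks <- function(masks, kind) {
  n <- length(masks)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    S[i, i] <- 1
    for (k in seq_len(n)[-seq_len(i)]) {
      S[i, k] <- S[k, i] <- mom_score(masks[[i]], masks[[k]])
    }
  }
  J <- numeric(n)
  d <- numeric(n)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      J[k] <- J[k] + S[i, k]
      d[k] <- d[k] + (1 - S[i, k])
    }
  }
  list(J = J, d = d)
}

new_vote_report <- function(method, fused_hard, fused_soft = NULL,
                            winner_index = NA_integer_, distances = NULL,
                            scores = NULL, winner_map = NULL,
                            survivors = NULL, params = list()) {
  structure(list(method = method, winner_index = winner_index,
                 distances = distances, scores = scores,
                 fused = fused_hard, fused_soft = fused_soft,
                 winner_map = winner_map, survivors = survivors,
                 params = params),
            class = "vote_report")
}

#' @export
print.vote_report <- function(x, ...) {
  cat(sprintf("<vote_report> method: %s\n", x$method))
  if (!is.na(x$winner_index)) cat("  winner index:", x$winner_index, "\n")
  if (!is.null(x$scores)) {
    cat("  total scores J_k:", paste(sprintf("%.4f", x$scores), collapse = " "), "\n")
  }
  if (!is.null(x$survivors)) {
    cat("  survivors:", paste(x$survivors, collapse = " "), "\n")
  }
  cat(sprintf("  fused mask: %d x %d, foreground %d px\n",
              nrow(x$fused), ncol(x$fused), sum(x$fused)))
  invisible(x)
}

#' Global topological ("winner takes all") voting
#'
#' Selects the input mask with the smallest total Jaccard distance to the
#' other masks — equivalently the highest total Jaccard score — and returns it
#' verbatim as the fused output. Soft ensembles are scored after
#' [regularize_soft()]; the fused output is the winner's *original* soft mask
#' (regularization is a scoring aid only), with its 0.5-threshold binarization
#' alongside. Ties in the argmin go to the lowest index.
#'
#' @param e a [mask_ensemble()] or list of same-shape masks.
#' @return a `vote_report` with `winner_index`, per-candidate `distances` and
#'   `scores`, and the fused mask.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2); b <- matrix(c(0, 0, 1, 1), 2, 2)
#' topological_vote(list(a, a, b))$winner_index  # 1
#' @export
topological_vote <- function(e) {
  e <- as_ensemble(e)
  tot <- totals_from_masks(scoring_masks(e), e$kind)
  win <- which.min(tot$d)
  winner <- e$masks[[win]]
  if (e$kind == "soft") {
    new_vote_report("topological-soft", threshold_mask(winner), winner,
                    winner_index = win, distances = tot$d, scores = tot$J)
  } else {
    new_vote_report("topological-hard", winner,
                    winner_index = win, distances = tot$d, scores = tot$J)
  }
}

#' Arithmetical (per-pixel) voting
#'
#' `arithmetical_vote_hard()` is per-pixel majority voting on hard masks,
#' implemented as the per-pixel mean followed by thresholding at 0.5 with >=,
#' so an even split goes to 1. `arithmetical_vote_soft()` averages soft masks
#' per pixel and reports both the soft mean and its 0.5-threshold
#' binarization.
#'
#' @param e a [mask_ensemble()] (hard for the hard variant, soft for the soft
#'   variant) or list of same-shape masks.
#' @return a `vote_report`; `winner_index` is absent (per-pixel fusion has no
#'   single winning annotator).
#' @export
arithmetical_vote_hard <- function(e) {
  e <- as_ensemble(e)
  if (e$kind != "hard") stop("arithmetical_vote_hard needs a hard ensemble", call. = FALSE)
  new_vote_report("arithmetical-hard", threshold_mask(mean_mask(e$masks)))
}

#' @rdname arithmetical_vote_hard
#' @export
arithmetical_vote_soft <- function(e) {
  e <- as_ensemble(e, kind = "soft")
  if (e$kind != "soft") stop("arithmetical_vote_soft needs a soft ensemble", call. = FALSE)
  avg <- soft_mask(mean_mask(e$masks))
  new_vote_report("arithmetical-soft", threshold_mask(avg), avg)
}

mean_mask <- function(masks) {
  acc <- unclass(masks[[1]])
  for (k in seq_along(masks)[-1]) acc <- acc + unclass(masks[[k]])
  acc / length(masks)
}

#' Weighted arithmetical voting
#'
#' Per-pixel weighted average `sum_k w_k S_k / sum_k w_k`, then thresholding
#' at 0.5. With equal weights this is plain soft averaging; with a one-hot
#' weight vector it reproduces topological selection of that one mask. When
#' `weights = NULL` the weights default to the total Jaccard scores J_k, so
#' annotators that agree more with the ensemble weigh more.
#'
#' @param e a [mask_ensemble()] or list of same-shape masks (hard or soft).
#' @param weights n non-negative reals with positive sum, or `NULL` for
#'   J_k-proportional weights.
#' @return a `vote_report` with the weighted soft mean and its binarization.
#' @export
weighted_arithmetical_vote <- function(e, weights = NULL) {
  e <- as_ensemble(e)
  if (is.null(weights)) weights <- total_scores(e)
  if (length(weights) != e$n) {
    stop(sprintf("need %d weights, got %d", e$n, length(weights)), call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  acc <- matrix(0, e$dim[1], e$dim[2])
  for (k in seq_len(e$n)) acc <- acc + weights[k] * unclass(e$masks[[k]])
  avg <- soft_mask(acc / sum(weights))
  new_vote_report("weighted-arithmetical", threshold_mask(avg), avg,
                  params = list(weights = weights))
}
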