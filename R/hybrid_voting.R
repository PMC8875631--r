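#' Outlier-exclusion rules for hybrid voting
#'
#' Round one of hybrid voting does not pick a winner — it picks losers. Two
#' rules are supported, both driven by the total Jaccard scores J_k:
#' the *threshold* rule keeps candidate k iff `J_k >= n / H` for a chosen
#' `H > 1` (the survivor count varies per input), and the *rank* rule keeps
#' the `n_select` candidates with the highest J_k (the survivor count is
#' always `n_select`).
#'
#' @param method `"threshold"` or `"rank"`.
#' @param H threshold parameter, must be > 1 (threshold rule).
#' @param n_select number of survivors, in `[1, n]` (rank rule).
#' @return an `exclusion_rule` object.
#' @export
exclusion_rule <- function(method = c("threshold", "rank"), H = NULL, n_select = NULL) {
  method <- match.arg(method)
  if (method == "threshold") {
    if (is.null(H) || !is.numeric(H) || length(H) != 1L || H <= 1) {
      stop("threshold rule needs a single H > 1", call. = FALSE)
    }
    n_select <- NULL
  } else {
    if (is.null(n_select) || length(n_select) != 1L || n_select < 1 ||
        n_select != round(n_select)) {
      stop("rank rule needs a single integer n_select >= 1", call. = FALSE)
    }
    H <- NULL
    n_select <- as.integer(n_select)
  }
  structure(list(method = method, H = H, n_select = n_select),
            class = "exclusion_rule")
}

#' @rdname exclusion_rule
#' @param J numeric vector of total Jaccard scores, one per candidate.
#' @param n ensemble size (the cutoff is `n / H`).
#' @return `exclude_by_threshold()` / `exclude_by_rank()`: the sorted integer
#'   indices of the surviving candidates.
#' @export
exclude_by_threshold <- function(J, n, H) {
  if (H <= 1) stop("H must be > 1", call. = FALSE)
  keep <- which(J >= n / H)
  # a vote must produce an output: if everything falls below the cutoff,
  # keep the single top-scoring candidate (lowest index on ties)
  if (length(keep) == 0L) keep <- which.max(J)
  keep
}

#' @rdname exclusion_rule
#' @export
exclude_by_rank <- function(J, n_select) {
  n <- length(J)
  if (n_select < 1 || n_select > n) {
    stop(sprintf("n_select must lie in [1, %d]", n), call. = FALSE)
  }
  # order() is stable, so ties at the cut go to the lowest index
  sort(order(-J)[seq_len(n_select)])
}

apply_rule <- function(rule, J, n) {
  switch(rule$method,
         threshold = exclude_by_threshold(J, n, rule$H),
         rank = exclude_by_rank(J, rule$n_select))
}

#' Hybrid topological-arithmetical (two-round) voting
#'
#' Round 1 scores candidates topologically (total Jaccard score J_k, global or
#' on the s-neighborhood of each pixel) and excludes outliers by the given
#' [exclusion_rule()]; round 2 takes the ordinary arithmetical vote — majority
#' for hard ensembles, mean-then-threshold for soft — among the survivors.
#' With a keep-all rule this reduces exactly to arithmetical voting; with the
#' rank rule at `n_select = 1` it reduces exactly to [topological_vote()].
#'
#' With `radius = NULL` exclusion is global: one survivor set for the whole
#' image. With an integer `radius`, J_k is computed per pixel on clipped
#' square windows (as in [local_topological_vote()]) and both the exclusion
#' and the arithmetical vote happen independently at each pixel
#' (`scope = "window"`, the default). `scope = "global"` keeps a radius set
#' for reporting but excludes on the global J_k.
#'
#' @param e a [mask_ensemble()] or list of same-shape masks.
#' @param rule an [exclusion_rule()].
#' @param radius `NULL` for global scoring, or a non-negative integer window
#'   radius for per-pixel scoring.
#' @param scope `"window"` (per-pixel exclusion, default) or `"global"`.
#' @return a `vote_report`; for global exclusion `survivors` holds the
#'   surviving indices, for per-pixel exclusion `winner_map` holds the
#'   per-pixel survivor count and `survivors` is `NULL`.
#' @export
hybrid_vote <- function(e, rule, radius = NULL, scope = c("window", "global")) {
  e <- as_ensemble(e)
  if (!inherits(rule, "exclusion_rule")) stop("rule must be an exclusion_rule", call. = FALSE)
  scope <- match.arg(scope)
  if (!is.null(rule$n_select) && rule$n_select > e$n) {
    stop(sprintf("n_select must lie in [1, %d]", e$n), call. = FALSE)
  }
  if (is.null(radius) || scope == "global") {
    J <- total_scores(e)
    keep <- apply_rule(rule, J, e$n)
    fuse_survivors(e, keep, J, radius)
  } else {
    hybrid_vote_windowed(e, rule, as.integer(radius))
  }
}

fuse_survivors <- function(e, keep, J, radius) {
  masks <- e$masks[keep]
  label <- sprintf("hybrid-%s", e$kind)
  if (e$kind == "hard") {
    fused <- if (length(masks) == 1L) masks[[1]] else
      threshold_mask(mean_mask(masks))
    new_vote_report(label, fused, scores = J, survivors = keep,
                    params = list(radius = radius))
  } else {
    avg <- if (length(masks) == 1L) masks[[1]] else soft_mask(mean_mask(masks))
    new_vote_report(label, threshold_mask(avg), avg, scores = J,
                    survivors = keep, params = list(radius = radius))
  }
}

hybrid_vote_windowed <- function(e, rule, s) {
  if (s < 0) stop("radius must be >= 0", call. = FALSE)
  n <- e$n; h <- e$dim[1]; w <- e$dim[2]; P <- h * w
  D <- local_total_distances(scoring_masks(e), s)
  Jmat <- n - vapply(D, c, numeric(P))      # per-pixel total scores, P x n
  if (P == 1L) Jmat <- matrix(Jmat, nrow = 1L)
  K <- matrix(FALSE, P, n)
  if (rule$method == "threshold") {
    K <- Jmat >= n / rule$H
    none <- rowSums(K) == 0L
    if (any(none)) {
      K[cbind(which(none), max.col(Jmat[none, , drop = FALSE], ties.method = "first"))] <- TRUE
    }
  } else {
    picks <- apply(Jmat, 1L, function(j) order(-j)[seq_len(rule$n_select)])
    picks <- matrix(picks, nrow = rule$n_select)
    K[cbind(rep(seq_len(P), each = rule$n_select), c(picks))] <- TRUE
  }
  M <- vapply(e$masks, c, numeric(P))
  if (P == 1L) M <- matrix(M, nrow = 1L)
  avg <- matrix(rowSums(M * K) / rowSums(K), h, w)
  counts <- matrix(rowSums(K), h, w)
  label <- sprintf("hybrid-local-%s", e$kind)
  if (e$kind == "hard") {
    new_vote_report(label, threshold_mask(avg), winner_map = counts,
                    params = list(radius = s, rule = rule))
  } else {
    new_vote_report(label, threshold_mask(avg), soft_mask(avg),
                    winner_map = counts, params = list(radius = s, rule = rule))
  }
}
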