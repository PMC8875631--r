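#' Generate a synthetic ground-truth mask
#'
#' Three truth regimes cover the shapes the voting methods are meant for:
#' `"blob"` — one smooth connected region (a thresholded Gaussian-smoothed
#' noise field, largest connected component kept), like a salt body in a
#' seismic slice; `"rectangle"` — one filled axis-aligned rectangle, like a
#' face bounding box; `"vessel"` — a connected tree of thin (1–2 px) random
#' walks, like a retinal vessel tree. Deterministic given `seed`.
#'
#' @param shape integer pair `c(h, w)`, both >= 16.
#' @param truth_kind `"blob"`, `"rectangle"` or `"vessel"`.
#' @param seed integer seed.
#' @return a [hard_mask()].
#' @export
make_truth_mask <- function(shape, truth_kind = c("blob", "rectangle", "vessel"),
                            seed = 1L) {
  truth_kind <- match.arg(truth_kind)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (h < 16L || w < 16L) stop("shape must be at least 16 x 16", call. = FALSE)
  with_seed(seed, switch(truth_kind,
    blob = truth_blob(h, w),
    rectangle = truth_rectangle(h, w),
    vessel = truth_vessel(h, w)))
}

truth_blob <- function(h, w) {
  field <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w),
                          sigma = min(h, w) / 8)
  m <- (field >= stats::quantile(field, 0.8)) * 1
  hard_mask(largest_component(m))
}

truth_rectangle <- function(h, w) {
  rh <- sample(round(0.25 * h):round(0.6 * h), 1L)
  rw <- sample(round(0.25 * w):round(0.6 * w), 1L)
  r1 <- sample(seq_len(h - rh + 1L), 1L)
  c1 <- sample(seq_len(w - rw + 1L), 1L)
  m <- matrix(0, h, w)
  m[r1:(r1 + rh - 1L), c1:(c1 + rw - 1L)] <- 1
  hard_mask(m)
}

# connected tree of correlated 4-connected random walks; every branch starts
# on an existing pixel, so the whole mask stays 4-connected (hence also
# 8-connected)
truth_vessel <- function(h, w) {
  m <- matrix(0, h, w)
  budget <- floor(0.15 * h * w)
  pos <- c(sample(round(0.35 * h):round(0.65 * h), 1L),
           sample(round(0.35 * w):round(0.65 * w), 1L))
  m[pos[1], pos[2]] <- 1
  trail <- matrix(pos, 1L, 2L)
  n_branches <- sample(4:7, 1L)
  for (b in seq_len(n_branches)) {
    cur <- trail[sample(nrow(trail), 1L), ]
    theta <- stats::runif(1, 0, 2 * pi)
    len <- sample(round(0.4 * min(h, w)):round(0.9 * min(h, w)), 1L)
    wide <- stats::runif(1) < 0.4
    for (step in seq_len(len)) {
      if (sum(m) >= budget) break
      theta <- theta + stats::rnorm(1, 0, 0.25)
      dc <- cos(theta); dr <- sin(theta)
      if (stats::runif(1) < abs(dc) / (abs(dc) + abs(dr))) {
        cur[2] <- min(max(cur[2] + sign(dc), 1L), w)
      } else {
        cur[1] <- min(max(cur[1] + sign(dr), 1L), h)
      }
      m[cur[1], cur[2]] <- 1
      if (wide && cur[2] < w) m[cur[1], cur[2] + 1L] <- 1
      trail <- rbind(trail, cur)
    }
  }
  hard_mask(m)
}

largest_component <- function(m) {
  lab <- EBImage::bwlabel(m)
  if (max(lab) <= 1) return((m > 0) * 1)
  counts <- tabulate(lab[lab > 0])
  (lab == which.max(counts)) * 1
}

#' Default annotator noise for synthetic ensembles
#'
#' Jitter radius 1 px (one morphological dilation or erosion step), 5% random
#' foreground dropout, and up to 1 px of translation — a "mostly good"
#' annotator whose Jaccard to the truth stays high.
#'
#' @return a named list with `jitter`, `dropout`, `translate`.
#' @export
default_good_noise <- function() list(jitter = 1L, dropout = 0.05, translate = 1L)

#' Perturb a truth mask like an imperfect annotator
#'
#' Applies, in order: a uniform random translation of up to `translate` px per
#' axis, boundary jitter (one morphological dilation or erosion with a random
#' disc of radius up to `jitter`; skipped if it would erase the mask), and
#' random dropout of foreground pixels. All-zero noise returns the truth
#' bit-exactly. Deterministic given `seed`.
#'
#' @param truth a [hard_mask()].
#' @param noise list with `jitter` (px >= 0), `dropout` (rate in \[0, 1\]),
#'   `translate` (px >= 0); see [default_good_noise()].
#' @param seed integer seed.
#' @return a [hard_mask()] of the same shape.
#' @export
perturb_mask <- function(truth, noise = default_good_noise(), seed = 1L) {
  m <- unclass(hard_mask(truth))
  jitter <- noise$jitter %||% 0L
  dropout <- noise$dropout %||% 0
  translate <- noise$translate %||% 0L
  if (jitter < 0 || translate < 0 || dropout < 0 || dropout > 1) {
    stop("noise rates must be >= 0 and dropout in [0, 1]", call. = FALSE)
  }
  if (jitter == 0 && dropout == 0 && translate == 0) return(hard_mask(m))
  with_seed(seed, {
    if (translate > 0) {
      m <- shift_mask(m, sample(-translate:translate, 1L),
                      sample(-translate:translate, 1L))
    }
    if (jitter > 0) {
      r <- sample(0:jitter, 1L)
      if (r > 0) {
        brush <- EBImage::makeBrush(2L * r + 1L, "disc")
        m2 <- if (stats::runif(1) < 0.5) EBImage::dilate(m, brush)
              else EBImage::erode(m, brush)
        if (sum(m2) > 0) m <- (m2 > 0) * 1
      }
    }
    if (dropout > 0) {
      fg <- which(m == 1)
      drop <- fg[stats::runif(length(fg)) < dropout]
      m[drop] <- 0
    }
    hard_mask(m)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# translate with zero fill; dr > 0 moves content down, dc > 0 moves it right
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  r1 <- max(1L, 1L + dr); r2 <- min(h, h + dr)
  c1 <- max(1L, 1L + dc); c2 <- min(w, w + dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc)]
  }
  out
}

#' Specification of a synthetic annotator ensemble
#'
#' @param shape integer pair `c(h, w)`.
#' @param truth_kind truth regime, see [make_truth_mask()].
#' @param n number of annotators (>= 2).
#' @param n_outliers number of planted outliers; must satisfy
#'   `2 * n_outliers < n` — voting is only sensible while most annotators are
#'   good, and the generator refuses hopeless ensembles.
#' @param good_noise noise for the good annotators, see [perturb_mask()].
#' @param outlier_mode `"shift"` (truth translated by 35% of the shorter image
#'   side in a random direction), `"spurious"` (an unrelated truth draw), or
#'   `"empty"` (all-zero mask).
#' @param seed integer seed.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(shape = c(64L, 64L), truth_kind = "blob", n = 10L,
                          n_outliers = 0L, good_noise = default_good_noise(),
                          outlier_mode = c("shift", "spurious", "empty"),
                          seed = 1L) {
  outlier_mode <- match.arg(outlier_mode)
  n <- as.integer(n); n_outliers <- as.integer(n_outliers)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (n_outliers < 0L || 2L * n_outliers >= n) {
    stop("need 2 * n_outliers < n (most annotators must be good)", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), truth_kind = truth_kind, n = n,
                 n_outliers = n_outliers, good_noise = good_noise,
                 outlier_mode = outlier_mode, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Build a synthetic annotator ensemble with planted outliers
#'
#' Draws a truth mask, `n - n_outliers` good annotators (perturbed truths) and
#' `n_outliers` structured outliers, shuffles their order, and reports where
#' the outliers landed. Deterministic given `spec$seed`.
#'
#' @param spec an [ensemble_spec()].
#' @return a list: `ensemble` (a hard [mask_ensemble()]), `truth` (the
#'   [hard_mask()]), `outlier_indices` (sorted, 1-based), and `manifest`
#'   (data.frame of index and role).
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  out <- with_seed(spec$seed, {
    sub <- sample.int(.Machine$integer.max - 1L, spec$n + 2L)
    truth <- make_truth_mask(spec$shape, spec$truth_kind, seed = sub[1])
    n_good <- spec$n - spec$n_outliers
    masks <- vector("list", spec$n)
    roles <- character(spec$n)
    for (i in seq_len(n_good)) {
      masks[[i]] <- perturb_mask(truth, spec$good_noise, seed = sub[i + 1L])
      roles[i] <- "good"
    }
    for (k in seq_len(spec$n_outliers)) {
      i <- n_good + k
      masks[[i]] <- switch(spec$outlier_mode,
        shift = {
          theta <- stats::runif(1, 0, 2 * pi)
          d <- 0.35 * min(h, w)
          hard_mask(shift_mask(unclass(truth), round(d * sin(theta)),
                               round(d * cos(theta))))
        },
        spurious = make_truth_mask(spec$shape, spec$truth_kind,
                                   seed = (sub[spec$n + 2L] + k) %% (.Machine$integer.max - 1L)),
        empty = hard_mask(matrix(0, h, w)))
      roles[i] <- spec$outlier_mode
    }
    perm <- sample.int(spec$n)
    list(masks = masks[perm], roles = roles[perm], truth = truth)
  })
  list(ensemble = mask_ensemble(out$masks, kind = "hard"),
       truth = out$truth,
       outlier_indices = which(out$roles != "good"),
       manifest = data.frame(index = seq_len(spec$n), role = out$roles))
}

#' Blur a hard mask into a calibrated soft mask
#'
#' Gaussian-smooths a binary mask into a \[0, 1\]-valued soft mask (values
#' clamped after smoothing), emulating the graded confidence of a continuous
#' segmentor around object boundaries.
#'
#' @param m a [hard_mask()].
#' @param sigma Gaussian kernel standard deviation in px (default 1).
#' @return a [soft_mask()].
#' @export
soften_mask <- function(m, sigma = 1) {
  g <- EBImage::gblur(unclass(hard_mask(m)), sigma = sigma)
  soft_mask(pmin(pmax(g, 0), 1))
}

#' @rdname soften_mask
#' @param e a hard [mask_ensemble()].
#' @return `soften_ensemble()`: a soft [mask_ensemble()].
#' @export
soften_ensemble <- function(e, sigma = 1) {
  e <- as_ensemble(e)
  mask_ensemble(lapply(e$masks, soften_mask, sigma = sigma), kind = "soft")
}
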