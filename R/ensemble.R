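#' Ensemble of co-registered masks
#'
#' An ordered collection of n >= 2 masks of one image, all the same shape and
#' all the same kind (hard or soft) — one mask per annotator/segmentor.
#'
#' @param masks a list of masks (matrices); bare matrices are classified as
#'   hard when binary, soft otherwise.
#' @param kind `"hard"`, `"soft"`, or `NULL` to infer; mixing kinds is an
#'   error.
#' @return an object of class `mask_ensemble`: a list with elements `masks`
#'   (the list of classed masks), `n`, `kind`, and `dim` (c(h, w)).
#' @examples
#' a <- hard_mask(matrix(c(1, 1, 0, 0), 2, 2))
#' b <- hard_mask(matrix(c(1, 0, 0, 1), 2, 2))
#' e <- mask_ensemble(list(a, a, b))
#' @export
mask_ensemble <- function(masks, kind = NULL) {
  if (!is.list(masks) || length(masks) < 2L) {
    stop("an ensemble needs a list of at least 2 masks", call. = FALSE)
  }
  kinds <- vapply(masks, mask_kind, character(1))
  if (is.null(kind)) {
    # one soft member makes the whole ensemble soft (a binary-valued soft
    # annotator is still a valid soft mask)
    kind <- if (any(kinds == "soft")) "soft" else "hard"
  }
  kind <- match.arg(kind, c("hard", "soft"))
  if (kind == "hard" && any(kinds == "soft")) {
    stop("hard ensemble contains non-binary masks", call. = FALSE)
  }
  ctor <- if (kind == "hard") hard_mask else soft_mask
  masks <- lapply(masks, ctor)
  d1 <- dim(masks[[1]])
  for (k in seq_along(masks)) check_same_shape(masks[[1]], masks[[k]])
  structure(list(masks = masks, n = length(masks), kind = kind, dim = d1),
            class = "mask_ensemble")
}

#' @export
print.mask_ensemble <- function(x, ...) {
  cat(sprintf("<mask_ensemble> %d %s masks of %d x %d\n",
              x$n, x$kind, x$dim[1], x$dim[2]))
  invisible(x)
}

as_ensemble <- function(e, kind = NULL) {
  if (inherits(e, "mask_ensemble")) e else mask_ensemble(e, kind = kind)
}

# regularized copies of the mask matrices used for *scoring* soft ensembles;
# hard ensembles score on the masks as-is
scoring_masks <- function(e) {
  if (e$kind == "soft") lapply(e$masks, function(m) unclass(regularize_soft(m)))
  else lapply(e$masks, unclass)
}
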