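#' Read a mask from disk
#'
#' Two dialects are supported. 8-bit grayscale PNG: for hard masks any nonzero
#' pixel reads as 1 (0 = background, 255 = foreground on write); for soft
#' masks the pixel value is divided by 255. Plain text grid: whitespace-
#' delimited rows of reals in \[0, 1\], one image row per line; for hard masks
#' any nonzero value reads as 1. Grids are row-major: the first line is the
#' top image row, values left to right.
#'
#' @param path file path; `.png` selects the PNG dialect, anything else the
#'   text grid.
#' @param kind `"hard"` or `"soft"`.
#' @return a [hard_mask()] or [soft_mask()].
#' @export
read_mask <- function(path, kind = c("hard", "soft")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      stop(sprintf("%s: multi-channel PNG; masks must be single-channel grayscale",
                   path), call. = FALSE)
    }
    img
  } else {
    read_text_grid(path)
  }
  if (any(m < 0) || any(m > 1)) {
    stop(sprintf("%s: values outside [0, 1]", path), call. = FALSE)
  }
  if (kind == "hard") hard_mask((m != 0) * 1) else soft_mask(m)
}

read_text_grid <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("%s: empty grid", path), call. = FALSE)
  rows <- lapply(strsplit(lines, "[ \t]+"), as.numeric)
  wdt <- lengths(rows)
  if (any(wdt != wdt[1]) || anyNA(unlist(rows))) {
    stop(sprintf("%s: malformed text grid", path), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a mask to disk
#'
#' PNG files (extension `.png`) store 8-bit grayscale: hard masks as 0/255,
#' soft masks quantized to value*255. Any other extension writes the text-grid
#' dialect, lossless to 6 decimals. Both round-trip through [read_mask()]
#' (hard masks bit-exactly; soft PNG up to the 1/255 quantization).
#'
#' @param m a mask (or numeric matrix with values in \[0, 1\]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  v <- unclass(as.matrix(m))
  if (any(v < 0) || any(v > 1)) stop("mask values outside [0, 1]", call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(v, target = path)
  } else {
    writeLines(apply(v, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               path)
  }
  invisible(path)
}

#' Evaluate a predicted mask against a ground truth
#'
#' Reports the Jaccard score, the Jaccard distance, and the naive binary
#' accuracy (fraction of agreeing pixels). The Jaccard score is the headline
#' metric; binary accuracy can sit near 1 even with zero overlap when the
#' object is small.
#'
#' @param pred,truth hard masks of the same shape.
#' @return a one-row data.frame with columns `jaccard`, `jaccard_distance`,
#'   `binary_accuracy`.
#' @export
evaluate_mask <- function(pred, truth) {
  j <- jaccard_hard(pred, truth)
  data.frame(jaccard = j, jaccard_distance = 1 - j,
             binary_accuracy = binary_accuracy(pred, truth))
}
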