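#' Fluorescence co-localization percentage within an ROI
#'
#' Pearson coefficient R between two fluorescence channels over the pixels
#' selected by a region-of-interest mask (typically a single-cell boundary),
#' reported as the co-localization percentage (R + 1) / 2 * 100. No
#' intensity thresholding or randomization is applied: the statistic is the
#' plain ROI-masked Pearson coefficient mapped onto the 0-100 scale, so it is
#' invariant to positive affine rescaling of either channel and symmetric
#' in the two channels.
#'
#' @param channel_a,channel_b Numeric matrices (or vectors) of pixel
#'   intensities with identical dimensions.
#' @param mask Logical (or 0/1) array of the same shape selecting ROI
#'   pixels; default all pixels. At least 3 pixels must be selected and
#'   both channels must be nonconstant within the mask.
#' @return Object of class `coloc_result`: `r`, `percent`, `n_pixels`.
#' @export
coloc_percentage <- function(channel_a, channel_b, mask = NULL) {
  a <- as.numeric(channel_a)
  b <- as.numeric(channel_b)
  if (length(a) != length(b)) {
    stop("channels must have identical shape", call. = FALSE)
  }
  if (is.null(mask)) {
    sel <- rep(TRUE, length(a))
  } else {
    if (length(mask) != length(a)) {
      stop("mask must have the same shape as the channels", call. = FALSE)
    }
    sel <- as.logical(mask)
  }
  if (anyNA(sel)) stop("mask contains NA", call. = FALSE)
  n <- sum(sel)
  if (n < 3L) stop("mask selects < 3 pixels", call. = FALSE)
  av <- a[sel]; bv <- b[sel]
  if (any(!is.finite(av)) || any(!is.finite(bv))) {
    stop("non-finite pixel intensity within mask", call. = FALSE)
  }
  if (stats::var(av) == 0 || stats::var(bv) == 0) {
    stop("constant channel within mask; Pearson undefined", call. = FALSE)
  }
  r <- stats::cor(av, bv)
  structure(list(r = r, percent = (r + 1) / 2 * 100, n_pixels = n),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> R = %.4f -> %.1f%% co-localization (%d pixels)\n",
              x$r, x$percent, x$n_pixels))
  invisible(x)
}

#' Aggregate per-cell co-localization percentages
#'
#' Cells are the unit of analysis: each cell contributes one percentage and
#' the summary reports their mean with the standard error of the mean.
#'
#' @param cells List of `coloc_result` objects (or a numeric vector of
#'   percentages), one entry per cell.
#' @return List with `mean`, `sem` (0 with `single_cell = TRUE` when only
#'   one cell is supplied), `n`, `percentages`.
#' @export
per_cell_summary <- function(cells) {
  if (is.list(cells)) {
    pct <- vapply(cells, function(cl) {
      if (inherits(cl, "coloc_result")) cl$percent else as.numeric(cl)
    }, numeric(1L))
  } else {
    pct <- as.numeric(cells)
  }
  if (!length(pct)) stop("no cells supplied", call. = FALSE)
  n <- length(pct)
  single <- n == 1L
  list(mean = mean(pct),
       sem = if (single) 0 else stats::sd(pct) / sqrt(n),
       n = n, single_cell = single, percentages = pct)
}
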