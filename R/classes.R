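#' Fixed-width partition of the CT number scale
#'
#' The HU scale is divided into \code{count} half-open classes
#' \code{[lower + (k-1) w, lower + k w)} of width \code{w}.  The default —
#' 128 classes of 32 HU anchored at -1024 HU — spans [-1024, 3072), which
#' covers the clinical 140 kVp scale; values outside the range clamp to the
#' first/last class.  With 32 HU classes the reconstruction is quantised:
#' no in-range HU value is farther than 16 HU from its class midpoint, so
#' per-class mean errors cannot be expected below +/- 16 HU.
#'
#' @param lower Lower edge of class 1, HU.
#' @param width Class width, HU.
#' @param count Number of classes.
#' @return An object of class \code{"class_binning"}.
#' @export
class_binning <- function(lower = -1024, width = 32, count = 128L) {
  count <- as.integer(count)
  if (width <= 0 || count < 1L) stopf("invalid binning")
  structure(list(lower = lower, width = width, count = count),
            class = "class_binning")
}

#' @export
print.class_binning <- function(x, ...) {
  cat(sprintf("HU class binning: %d classes of %g HU over [%g, %g)\n",
              x$count, x$width, x$lower, x$lower + x$count * x$width))
  invisible(x)
}

#' Map HU values to class indices
#'
#' Half-open intervals: an HU value exactly on a class's lower edge belongs
#' to that class.  Out-of-range values clamp to the first or last class
#' rather than erroring, so metal-like outliers in noisy data do not abort
#' training.
#'
#' @param hu Numeric vector of HU values.
#' @param binning A \code{\link{class_binning}}.
#' @return Integer class indices in \code{1..count}.
#' @export
bin_hu <- function(hu, binning) {
  idx <- floor((hu - binning$lower) / binning$width) + 1
  as.integer(pmin(pmax(idx, 1), binning$count))
}

#' Midpoints of the HU classes
#' @param binning A \code{\link{class_binning}}.
#' @param k Class indices (default all).
#' @return Midpoint HU values.
#' @export
class_midpoints <- function(binning, k = seq_len(binning$count)) {
  binning$lower + (k - 0.5) * binning$width
}

#' Per-class counts and mean HU on the learning set
#'
#' Classes with no members are flagged empty and carry no mean; such
#' classes are excluded from the classifier.
#'
#' @param hu HU values of the learning voxels (inside the mask).
#' @param binning A \code{\link{class_binning}}.
#' @return Data frame with \code{class}, \code{midpoint}, \code{n},
#'   \code{mean_hu} (NA for empty classes).
#' @export
class_stats <- function(hu, binning) {
  if (!length(hu)) stopf("class_stats: no learning voxels")
  k <- bin_hu(hu, binning)
  n <- tabulate(k, nbins = binning$count)
  mean_hu <- rep(NA_real_, binning$count)
  agg <- tapply(hu, k, mean)
  mean_hu[as.integer(names(agg))] <- agg
  data.frame(class = seq_len(binning$count),
             midpoint = class_midpoints(binning),
             n = n, mean_hu = mean_hu)
}
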