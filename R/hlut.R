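#' Hounsfield lookup table (HU to relative WEPL)
#'
#' An ordered set of control points defining the piecewise-linear empirical
#' conversion from CT number to relative water-equivalent path length
#' (relative stopping-power proxy), with linear extrapolation beyond the
#' end points, floored at 0.
#'
#' @param hu Strictly increasing HU control points (>= 2 values).
#' @param wepl Non-negative relative WEPL at the control points.
#' @return An object of class \code{"hlut"}.
#' @export
hlut <- function(hu, wepl) {
  hu <- as.numeric(hu); wepl <- as.numeric(wepl)
  if (length(hu) < 2 || length(hu) != length(wepl))
    stopf("hlut needs >= 2 (hu, wepl) control points of equal length")
  if (any(diff(hu) <= 0)) stopf("hlut HU control points must be strictly increasing")
  if (any(wepl < 0)) stopf("hlut WEPL values must be non-negative")
  structure(list(hu = hu, wepl = wepl), class = "hlut")
}

#' @export
print.hlut <- function(x, ...) {
  cat(sprintf("HLUT: %d control points, HU [%g, %g], WEPL [%g, %g]\n",
              length(x$hu), min(x$hu), max(x$hu), min(x$wepl), max(x$wepl)))
  invisible(x)
}

#' Default 140 kVp-style HLUT
#'
#' A compact plausible conversion table for a 140 kVp CT scale (air 0, water
#' 1, cortical-bone-range HU above 1).  The table is configuration, not a
#' calibration: any WET numbers the package reports are relative to the
#' HLUT in use, and site-specific tables should be supplied via
#' \code{\link{read_hlut}}.
#'
#' @return An \code{\link{hlut}}.
#' @export
default_hlut <- function() {
  hlut(hu   = c(-1000, -100, 0, 100, 1200, 3000),
       wepl = c(0.00, 0.95, 1.00, 1.07, 1.65, 2.40))
}

#' Read / write an HLUT as a two-column CSV
#'
#' Columns \code{hu}, \code{wepl}.
#'
#' @param path CSV path.
#' @return \code{read_hlut}: an \code{\link{hlut}}.
#' @export
read_hlut <- function(path) {
  df <- utils::read.csv(path)
  hlut(df$hu, df$wepl)
}

#' @rdname read_hlut
#' @param h An \code{\link{hlut}}.
#' @export
write_hlut <- function(h, path) {
  utils::write.csv(data.frame(hu = h$hu, wepl = h$wepl), path,
                   row.names = FALSE)
  invisible(path)
}

#' Convert HU values to relative WEPL through an HLUT
#'
#' Piecewise-linear interpolation between control points; linear
#' extrapolation with the end-segment slopes beyond the table, floored at 0
#' (a path length cannot be negative).
#'
#' @param hu Numeric vector/array of HU values.
#' @param h An \code{\link{hlut}}.
#' @return Relative WEPL values, same shape as \code{hu}.
#' @export
hu_to_wepl <- function(hu, h) {
  x <- h$hu; y <- h$wepl
  n <- length(x)
  hu_num <- as.numeric(hu)
  out <- stats::approx(x, y, xout = hu_num, rule = 2)$y
  s_lo <- (y[2] - y[1]) / (x[2] - x[1])
  s_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  lo <- which(hu_num < x[1]); hi <- which(hu_num > x[n])
  out[lo] <- y[1] + s_lo * (hu_num[lo] - x[1])
  out[hi] <- y[n] + s_hi * (hu_num[hi] - x[n])
  out <- pmax(out, 0)
  if (is.array(hu)) array(out, dim = dim(hu)) else out
}

#' Convert a CT volume to a WEPL volume
#'
#' @param ct CT or pseudo-CT \code{volume}.
#' @param h An \code{\link{hlut}}.
#' @return A \code{volume} with role \code{"wepl"}.
#' @export
ct_to_wepl <- function(ct, h) {
  volume(hu_to_wepl(ct$values, h), spacing = ct$spacing, origin = ct$origin,
         role = "wepl")
}

#' Default HU tissue grouping for WET error reporting
#'
#' Named half-open HU intervals covering the scale: air, "partial volume"
#' (the air/soft-tissue mixture band), soft tissue, soft bone, bone.  The
#' group names are standard; the boundaries are configuration.
#'
#' @param breaks Numeric breaks between the five groups (4 values).
#' @param range HU range covered (used for the outer interval edges).
#' @return Data frame \code{tissue}, \code{lo}, \code{hi} (half-open
#'   \code{[lo, hi)}).
#' @export
tissue_grouping <- function(breaks = c(-800, -150, 150, 700),
                            range = c(-1024, 3072)) {
  if (length(breaks) != 4 || any(diff(breaks) <= 0))
    stopf("breaks must be 4 increasing values")
  edges <- c(range[1], breaks, range[2])
  data.frame(tissue = c("air", "partial_volume", "soft_tissue", "soft_bone",
                        "bone"),
             lo = edges[1:5], hi = edges[2:6], stringsAsFactors = FALSE)
}

#' Assign HU values to tissue groups
#' @param hu Numeric vector.
#' @param grouping A \code{\link{tissue_grouping}} data frame.
#' @return Character vector of tissue group names (clamped at the ends).
#' @export
group_hu <- function(hu, grouping = tissue_grouping()) {
  idx <- findInterval(hu, c(grouping$lo, grouping$hi[nrow(grouping)]),
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(grouping))
  grouping$tissue[idx]
}
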