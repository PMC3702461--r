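#' Mean absolute error between pseudo CT and reference CT
#'
#' \eqn{MAE = \frac{1}{n} \sum_{i=1}^n |pCT_i - rCT_i|} over the masked
#' voxels, together with the standard deviation of the absolute errors.
#'
#' @param pct Pseudo-CT \code{volume}.
#' @param rct Reference-CT \code{volume} (same grid).
#' @param mask Mask \code{volume}; must contain at least one voxel.
#' @return List with \code{mae}, \code{sd_abs} (both HU) and \code{n}.
#' @export
mae <- function(pct, rct, mask) {
  stopifnot_same_grid(pct, rct, "pct and rct")
  stopifnot_same_grid(pct, mask, "pct and mask")
  sel <- mask$values > 0
  if (!any(sel)) stopf("mae: empty mask")
  ae <- abs(pct$values[sel] - rct$values[sel])
  list(mae = mean(ae), sd_abs = stats::sd(ae), n = sum(sel))
}

#' Signed mean error of pseudo CT per HU class
#'
#' \eqn{ME_{cl} = \frac{1}{n_{cl}} \sum_{i=1}^{n_{cl}} (pCT_{i,cl} -
#' rCT_{i,cl})}.  Class membership is determined from the reference CT, so
#' errors are attributed to the true tissue class.  Empty classes are
#' omitted.
#'
#' @param pct,rct Pseudo and reference CT \code{volume}s (shared grid).
#' @param mask Mask \code{volume}.
#' @param binning A \code{\link{class_binning}}.
#' @return Data frame: \code{class}, \code{midpoint} (HU), \code{n},
#'   \code{me} (HU).
#' @export
me_per_class <- function(pct, rct, mask, binning = class_binning()) {
  stopifnot_same_grid(pct, rct, "pct and rct")
  stopifnot_same_grid(pct, mask, "pct and mask")
  sel <- mask$values > 0
  if (!any(sel)) stopf("me_per_class: empty mask")
  rv <- rct$values[sel]; pv <- pct$values[sel]
  k <- bin_hu(rv, binning)
  err <- pv - rv
  me <- tapply(err, k, mean)
  n <- tapply(err, k, length)
  cls <- as.integer(names(me))
  data.frame(class = cls, midpoint = class_midpoints(binning, cls),
             n = as.integer(n), me = as.numeric(me))
}

#' Voxelwise signed difference map
#'
#' \code{pct - rct}; intended for visualisation on a symmetric (signed)
#' log-like colour scale since boundary errors span orders of magnitude.
#'
#' @param pct,rct \code{volume}s on a shared grid.
#' @return A \code{volume} of signed differences (role \code{"pct"}).
#' @export
difference_map <- function(pct, rct) {
  stopifnot_same_grid(pct, rct, "pct and rct")
  volume(pct$values - rct$values, spacing = pct$spacing,
         origin = pct$origin, role = "pct")
}
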