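#' Propagate per-tissue pseudo-CT errors to water-equivalent thickness
#'
#' For each tissue group, the signed pseudo-CT mean error (HU) is converted
#' to a WEPL deviation through the HLUT at the group's representative HU:
#' \eqn{\Delta WEPL = wepl(HU_{rep} + ME) - wepl(HU_{rep})}, and then to a
#' water-equivalent thickness deviation for a beam crossing a thickness d
#' of that tissue: \eqn{\Delta WET = \Delta WEPL \times d} (exactly linear
#' in d).
#'
#' The standard error of \eqn{\Delta WET} treats the per-voxel pCT error
#' spread as either independent voxel-to-voxel noise accumulating as a
#' random walk along the path (\code{se_mode = "sqrt"}:
#' \eqn{SE = \sigma_{wepl} \, s \sqrt{d / s}} with s the voxel size along
#' the beam) or as fully correlated (\code{se_mode = "linear"}:
#' \eqn{SE = \sigma_{wepl} \, d}), where \eqn{\sigma_{wepl}} is the
#' per-voxel WEPL error sd obtained by pushing the per-voxel HU error sd
#' through the local HLUT slope.
#'
#' @param me_per_tissue Named numeric vector: signed mean pCT error (HU)
#'   per tissue group (names matching \code{grouping$tissue}).
#' @param h An \code{\link{hlut}}.
#' @param thicknesses Tissue thicknesses d in cm; default \code{c(1, 5, 10)}.
#' @param error_sd_per_voxel Named numeric vector: per-voxel sd of the pCT
#'   error (HU) per tissue group; NA/absent tissues get NA standard errors.
#' @param voxel_size Voxel size along the beam, mm; default 0.5.
#' @param se_mode \code{"sqrt"} (independent voxel errors) or
#'   \code{"linear"} (fully correlated).
#' @param grouping A \code{\link{tissue_grouping}}.
#' @param representative_hu Named numeric vector of the HU at which each
#'   group's HLUT slope is evaluated; default the interval midpoints.
#' @return Data frame: one row per tissue with \code{me_hu},
#'   \code{dwepl}, and per thickness \code{dwet_<d>cm_mm} and
#'   \code{se_<d>cm_mm}.
#' @export
delta_wet <- function(me_per_tissue, h, thicknesses = c(1, 5, 10),
                      error_sd_per_voxel = NULL, voxel_size = 0.5,
                      se_mode = c("sqrt", "linear"),
                      grouping = tissue_grouping(),
                      representative_hu = NULL) {
  se_mode <- match.arg(se_mode)
  if (any(thicknesses <= 0)) stopf("thicknesses must be > 0")
  tn <- grouping$tissue
  if (is.null(representative_hu))
    representative_hu <- stats::setNames((grouping$lo + grouping$hi) / 2, tn)
  out <- data.frame(tissue = tn, stringsAsFactors = FALSE)
  out$me_hu <- as.numeric(me_per_tissue[tn])
  rep_hu <- representative_hu[tn]
  out$dwepl <- hu_to_wepl(rep_hu + out$me_hu, h) - hu_to_wepl(rep_hu, h)
  sd_hu <- if (is.null(error_sd_per_voxel)) rep(NA_real_, length(tn))
           else as.numeric(error_sd_per_voxel[tn])
  # local HLUT slope (WEPL per HU) at the representative HU
  eps <- 0.5
  slope <- (hu_to_wepl(rep_hu + eps, h) - hu_to_wepl(rep_hu - eps, h)) / (2 * eps)
  sd_wepl <- sd_hu * slope
  for (d in thicknesses) {
    d_mm <- d * 10
    out[[sprintf("dwet_%gcm_mm", d)]] <- out$dwepl * d_mm
    se <- switch(se_mode,
                 sqrt = sd_wepl * voxel_size * sqrt(d_mm / voxel_size),
                 linear = sd_wepl * d_mm)
    out[[sprintf("se_%gcm_mm", d)]] <- se
  }
  out
}

#' Per-tissue pCT error summary feeding \code{\link{delta_wet}}
#'
#' Groups masked voxels by the reference-CT tissue group and returns the
#' signed mean error and per-voxel error sd per group.
#'
#' @param pct,rct Pseudo/reference CT \code{volume}s.
#' @param mask Mask \code{volume}.
#' @param grouping A \code{\link{tissue_grouping}}.
#' @return Data frame \code{tissue}, \code{n}, \code{me_hu}, \code{sd_hu}.
#' @export
me_per_tissue <- function(pct, rct, mask, grouping = tissue_grouping()) {
  stopifnot_same_grid(pct, rct, "pct and rct")
  sel <- mask$values > 0
  if (!any(sel)) stopf("me_per_tissue: empty mask")
  g <- factor(group_hu(rct$values[sel], grouping), levels = grouping$tissue)
  err <- pct$values[sel] - rct$values[sel]
  data.frame(tissue = grouping$tissue,
             n = as.integer(tapply(err, g, length)),
             me_hu = as.numeric(tapply(err, g, mean)),
             sd_hu = as.numeric(tapply(err, g, stats::sd)),
             stringsAsFactors = FALSE)
}

#' Trace cumulative water-equivalent thickness along an axis-aligned ray
#'
#' Sums \code{wepl * step} voxel by voxel from an entry voxel along a grid
#' axis.  Rays are axis-aligned only: the simplified range proxy mirrors a
#' lateral irradiation geometry and makes no claim to be a dose engine.
#'
#' @param wepl_vol WEPL \code{volume}.
#' @param entry Integer length-3 voxel index where the ray enters.
#' @param axis Axis 1, 2 or 3; \code{direction} +1 or -1.
#' @param direction Travel direction along the axis.
#' @param wet_target Optional WET target (mm): the crossing depth is the
#'   geometric depth (mm) at which the cumulative WET first reaches it,
#'   with linear sub-voxel interpolation; \code{NA} if the ray exits first.
#' @return List: \code{depth} (mm, at voxel exit faces), \code{wet}
#'   (cumulative mm), \code{crossing_depth} (mm or NA), \code{crossed}.
#' @export
trace_wet <- function(wepl_vol, entry, axis = 1, direction = 1,
                      wet_target = NULL) {
  d <- dim(wepl_vol$values)
  entry <- as.integer(entry)
  if (any(entry < 1L) || any(entry > d)) stopf("entry voxel outside grid")
  step <- wepl_vol$spacing[axis]
  idx <- if (direction > 0) entry[axis]:d[axis] else entry[axis]:1
  coords <- list(entry[1], entry[2], entry[3])
  vals <- vapply(idx, function(i) {
    coords[[axis]] <- i
    wepl_vol$values[coords[[1]], coords[[2]], coords[[3]]]
  }, 0.0)
  wet <- cumsum(vals * step)
  depth <- seq_along(idx) * step
  crossing <- NA_real_; crossed <- FALSE
  if (!is.null(wet_target)) {
    j <- which(wet >= wet_target)
    if (length(j)) {
      j <- j[1]
      w_prev <- if (j == 1) 0 else wet[j - 1]
      frac <- if (wet[j] > w_prev) (wet_target - w_prev) / (wet[j] - w_prev) else 0
      crossing <- (j - 1 + frac) * step
      crossed <- TRUE
    }
  }
  list(depth = depth, wet = wet, crossing_depth = crossing,
       crossed = crossed)
}

# cumulative WET (mm) to the exit face of voxel index `upto` along `axis`,
# for all rays at once; returns a matrix over the two perpendicular axes
wet_to_depth_matrix <- function(wepl_vol, axis, upto_matrix) {
  d <- dim(wepl_vol$values)
  step <- wepl_vol$spacing[axis]
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(wepl_vol$values, perm)            # axis first
  cw <- apply(a, c(2, 3), cumsum) * step       # n_axis x n2 x n3
  out <- matrix(NA_real_, dim(a)[2], dim(a)[3])
  ok <- which(!is.na(upto_matrix), arr.ind = TRUE)
  for (r in seq_len(nrow(ok))) {
    i2 <- ok[r, 1]; i3 <- ok[r, 2]
    out[i2, i3] <- cw[upto_matrix[i2, i3], i2, i3]
  }
  out
}

# index (along `axis`) of the distal PTV surface for every perpendicular
# ray; NA where the ray misses the PTV
distal_surface <- function(ptv, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(ptv$values > 0, perm)
  apply(a, c(2, 3), function(v) if (any(v)) max(which(v)) else NA_integer_)
}

#' Per-ray distal WET discrepancy over a target volume
#'
#' For every axis-aligned ray that intersects the PTV, computes the
#' water-equivalent thickness from the volume entry face to the distal PTV
#' surface under the pseudo CT and under the reference CT, and reports the
#' per-ray difference (mm).  A positive value means the pseudo CT
#' overestimates the stopping material upstream of and inside the target
#' (beam stops short: distal underdosage); the sign convention is
#' \code{pct - rct}.
#'
#' @param pct,rct CT \code{volume}s on a shared grid.
#' @param h An \code{\link{hlut}}.
#' @param axis Beam axis (rays travel toward increasing index).
#' @param ptv Mask \code{volume} of the planning target volume.
#' @return List: \code{diff} (matrix of per-ray differences, mm, NA off the
#'   PTV shadow), \code{mean}, \code{mean_abs}, \code{sd}, \code{n_rays}.
#' @export
range_error_map <- function(pct, rct, h, axis = 1, ptv) {
  stopifnot_same_grid(pct, rct, "pct and rct")
  stopifnot_same_grid(pct, ptv, "pct and ptv")
  if (!any(ptv$values > 0)) stopf("range_error_map: empty PTV")
  upto <- distal_surface(ptv, axis)
  wp <- wet_to_depth_matrix(ct_to_wepl(pct, h), axis, upto)
  wr <- wet_to_depth_matrix(ct_to_wepl(rct, h), axis, upto)
  diff <- wp - wr
  v <- diff[!is.na(diff)]
  list(diff = diff, mean = mean(v), mean_abs = mean(abs(v)),
       sd = stats::sd(v), n_rays = length(v))
}

#' Shift a binary mask by a millimetre vector
#'
#' Integer-voxel shifts are applied exactly; fractional shifts use
#' trilinear interpolation of the indicator followed by a 0.5 threshold.
#'
#' @param mask Mask \code{volume}.
#' @param shift_mm Length-3 shift in mm.
#' @return The shifted mask \code{volume}.
#' @export
shift_mask <- function(mask, shift_mm) {
  vox <- shift_mm / mask$spacing
  if (max(abs(vox - round(vox))) < 1e-9) {
    out <- mask
    out$values <- shift_pad_num(mask$values, round(vox[1]), round(vox[2]),
                                round(vox[3]), 0)
    if (sum(out$values) < sum(mask$values))
      stopf("shifted mask leaves the grid")
    return(out)
  }
  target <- mask
  target$origin <- mask$origin - shift_mm   # sample source at x - shift
  sm <- resample_to(volume(mask$values, mask$spacing, mask$origin, "mr"),
                    target, pad = 0)
  out <- mask
  out$values <- array(as.numeric(sm$values >= 0.5), dim = dim(mask$values))
  if (!any(out$values > 0)) stopf("shifted mask leaves the grid")
  out$origin <- mask$origin
  out
}

#' Target-shift adaptation experiment (range proxy)
#'
#' Simulates an interfractional target movement by shifting the PTV and
#' compares two strategies through the distal-WET range proxy:
#' \describe{
#'   \item{A (adapted, pseudo-CT based)}{re-plan on the pseudo CT against
#'     the shifted PTV; error = per-ray distal WET under pCT minus under
#'     the reference CT, both to the shifted PTV's distal surface.  This
#'     isolates the classifier's range error at the new target position.}
#'   \item{B (non-adapted, reference-CT based)}{keep the original plan
#'     (reference CT, unshifted PTV) and evaluate it against the shifted
#'     PTV; error = per-ray WET to the shifted distal surface minus WET to
#'     the original distal surface, on the reference CT.  This isolates
#'     the geometric-miss error of not adapting.}
#' }
#' With zero shift and pct == rct both are 0; with zero shift, B is 0 and A
#' equals the plain pseudo-CT range error.
#'
#' @param pct,rct CT \code{volume}s (shared grid).
#' @param h An \code{\link{hlut}}.
#' @param ptv PTV mask \code{volume}.
#' @param shift_mm Length-3 target shift in mm.
#' @param axis Beam axis.
#' @return List: \code{adapted} / \code{non_adapted} with per-strategy mean
#'   absolute distal WET error (mm) and per-ray detail; \code{ptv_shifted}.
#' @export
shift_experiment <- function(pct, rct, h, ptv, shift_mm = c(2, 2, 0),
                             axis = 1) {
  ptv_s <- shift_mask(ptv, shift_mm)
  # A: adapted plan on pCT, judged on rCT, shifted PTV
  A <- range_error_map(pct, rct, h, axis = axis, ptv = ptv_s)
  # B: non-adapted plan (rCT ranges to the old distal surface) evaluated
  # against the shifted PTV on rCT
  up_new <- distal_surface(ptv_s, axis)
  up_old <- distal_surface(ptv, axis)
  wr <- ct_to_wepl(rct, h)
  w_new <- wet_to_depth_matrix(wr, axis, up_new)
  # rays through the shifted PTV that never crossed the old PTV carry no
  # planned range; they are excluded and counted
  up_old_masked <- up_old
  up_old_masked[is.na(up_new)] <- NA_integer_
  w_old <- wet_to_depth_matrix(wr, axis, up_old_masked)
  diffB <- w_new - w_old
  vB <- diffB[!is.na(diffB)]
  n_unplanned <- sum(!is.na(up_new) & is.na(up_old))
  list(
    adapted = list(mean_abs = A$mean_abs, mean = A$mean, sd = A$sd,
                   n_rays = A$n_rays, diff = A$diff),
    non_adapted = list(mean_abs = mean(abs(vB)), mean = mean(vB),
                       sd = stats::sd(vB), n_rays = length(vB),
                       n_unplanned_rays = n_unplanned, diff = diffB),
    ptv_shifted = ptv_s, shift_mm = shift_mm, axis = axis
  )
}
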