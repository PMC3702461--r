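#' Feature specification for the per-voxel observation vector
#'
#' Describes how the observation vector is assembled from contrast images:
#' which contrasts enter as raw intensities, which neighbourhood features
#' (box mean, box standard deviation) are added per contrast, and which
#' coordinate features (per-axis absolute distances to the sample centroid,
#' in-slice radial distance) are appended globally.
#'
#' The dimensionality is
#' \code{p = n_contrasts * (1 + box_mean + box_sd) + 3 * dist_xyz + dist_center}.
#'
#' @param contrasts Ordered character vector of contrast image names.
#' @param box_mean,box_sd Add the neighbourhood-box mean / sd feature for
#'   every contrast?
#' @param dist_xyz Add the three per-axis absolute distances to the mask
#'   centroid (mm)?
#' @param dist_center Add the in-slice (axial-plane) radial distance to the
#'   mask centroid (mm)?
#' @param box_halfwidth Half-width of the neighbourhood box in voxels;
#'   1 gives the 3x3x3 box (26 neighbours plus the centre).
#' @return An object of class \code{"feature_spec"}.
#' @export
feature_spec <- function(contrasts, box_mean = FALSE, box_sd = FALSE,
                         dist_xyz = FALSE, dist_center = FALSE,
                         box_halfwidth = 1L) {
  contrasts <- as.character(contrasts)
  if (!length(contrasts)) stopf("at least one contrast must be selected")
  structure(list(contrasts = contrasts, box_mean = box_mean, box_sd = box_sd,
                 dist_xyz = dist_xyz, dist_center = dist_center,
                 box_halfwidth = as.integer(box_halfwidth)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  feats <- c(if (x$box_mean) "box.mean", if (x$box_sd) "box.sd",
             if (x$dist_xyz) "dist.xyz", if (x$dist_center) "dist.center")
  cat(sprintf("feature spec: contrasts {%s}%s; p = %d\n",
              paste(x$contrasts, collapse = ", "),
              if (length(feats)) paste0(" + ", paste(feats, collapse = ", "))
              else "",
              n_features(x)))
  invisible(x)
}

#' Dimensionality of a feature spec
#' @param spec A \code{\link{feature_spec}}.
#' @return Integer p.
#' @export
n_features <- function(spec) {
  length(spec$contrasts) * (1L + spec$box_mean + spec$box_sd) +
    3L * spec$dist_xyz + 1L * spec$dist_center
}

#' Number of neighbours in the feature box
#' @param halfwidth Box half-width in voxels.
#' @return Number of surrounding voxels (box size minus the centre).
#' @export
n_box_neighbors <- function(halfwidth = 1L) {
  (2L * halfwidth + 1L)^3 - 1L
}

#' Sliding-box sums over a 3D array with border truncation
#'
#' Returns per-voxel sum, sum of squares and count over the
#' \code{(2h+1)^3} box centred at each voxel, using only voxels inside the
#' grid (boxes at borders are truncated, not padded).
#'
#' @keywords internal
box_sums <- function(a, h = 1L) {
  d <- dim(a)
  s <- array(0, d); s2 <- array(0, d); cnt <- array(0, d)
  one <- array(1, d)
  offs <- seq(-h, h)
  for (dx in offs) for (dy in offs) for (dz in offs) {
    s <- s + shift_pad_num(a, dx, dy, dz, 0)
    s2 <- s2 + shift_pad_num(a^2, dx, dy, dz, 0)
    cnt <- cnt + shift_pad_num(one, dx, dy, dz, 0)
  }
  list(sum = s, sumsq = s2, count = cnt)
}

#' Neighbourhood-box mean of every voxel
#'
#' Mean intensity of the box surrounding each voxel, including the central
#' voxel; boxes clipped at the volume border use the available voxels only.
#'
#' @param vol A \code{volume}.
#' @param halfwidth Box half-width in voxels (1 = 3x3x3).
#' @return A \code{volume} of box means.
#' @export
box_mean_volume <- function(vol, halfwidth = 1L) {
  bs <- box_sums(vol$values, halfwidth)
  out <- vol
  out$values <- bs$sum / bs$count
  out
}

#' Neighbourhood-box standard deviation times central intensity
#'
#' The population standard deviation (n denominator) of the box surrounding
#' each voxel, including the central voxel, multiplied by the central
#' voxel's intensity.  The intensity weighting is deliberate: it amplifies
#' the feature at bright boundary voxels, which is where partial-volume
#' misclassification happens.  Set \code{weight_by_intensity = FALSE} for
#' the plain box standard deviation.
#'
#' @param vol A \code{volume}.
#' @param halfwidth Box half-width in voxels.
#' @param weight_by_intensity Multiply by the central intensity (default)?
#' @return A \code{volume} of box-sd features.
#' @export
box_sd_volume <- function(vol, halfwidth = 1L, weight_by_intensity = TRUE) {
  bs <- box_sums(vol$values, halfwidth)
  m <- bs$sum / bs$count
  v <- pmax(bs$sumsq / bs$count - m^2, 0)
  out <- vol
  out$values <- sqrt(v) * (if (weight_by_intensity) vol$values else 1)
  out
}

#' Coordinate features relative to the mask centroid
#'
#' World coordinates (mm, voxel centres) are translated so the centroid of
#' the mask voxels sits at the origin, emulating samples centred in the
#' imaging volume.  Returns per-voxel absolute distances along each axis
#' and the in-plane (axial, x-y) radial distance.
#'
#' @param mask A mask \code{volume} with at least one voxel set.
#' @return List of four \code{volume}s: \code{dist_x}, \code{dist_y},
#'   \code{dist_z}, \code{dist_center}, all in mm.
#' @export
dist_features <- function(mask) {
  m <- mask$values > 0
  if (!any(m)) stopf("dist_features: empty mask")
  d <- dim(mask$values)
  xs <- axis_centers(mask, 1); ys <- axis_centers(mask, 2)
  zs <- axis_centers(mask, 3)
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  cx <- mean(X[m]); cy <- mean(Y[m]); cz <- mean(Z[m])
  mk <- function(vals) volume(vals, mask$spacing, mask$origin, role = "mr")
  list(dist_x = mk(abs(X - cx)), dist_y = mk(abs(Y - cy)),
       dist_z = mk(abs(Z - cz)),
       dist_center = mk(sqrt((X - cx)^2 + (Y - cy)^2)))
}

#' Assemble the per-voxel observation matrix
#'
#' One row per mask voxel; columns ordered as: contrast intensities (in
#' spec order), then the toggled box features per contrast (box.mean then
#' box.sd, contrasts in spec order), then dist.x/dist.y/dist.z, then
#' dist.center.
#'
#' @param volumes Named list of contrast \code{volume}s covering
#'   \code{spec$contrasts}, all on the mask grid.
#' @param spec A \code{\link{feature_spec}}.
#' @param mask Mask \code{volume}.
#' @return An object of class \code{"obs_matrix"}: list with \code{x}
#'   (n x p matrix with named columns), \code{voxels} (linear indices into
#'   the grid), \code{grid} (dim/spacing/origin), optional \code{labels},
#'   optional \code{scaling}.
#' @export
assemble_observations <- function(volumes, spec, mask) {
  missing <- setdiff(spec$contrasts, names(volumes))
  if (length(missing))
    stopf("missing contrast volume(s): %s", paste(missing, collapse = ", "))
  for (nm in spec$contrasts)
    stopifnot_same_grid(volumes[[nm]], mask, paste0("contrast '", nm, "' and mask"))
  sel <- which(mask$values > 0)
  cols <- list()
  for (nm in spec$contrasts) cols[[nm]] <- volumes[[nm]]$values[sel]
  if (spec$box_mean)
    for (nm in spec$contrasts)
      cols[[paste0(nm, ".box.mean")]] <-
        box_mean_volume(volumes[[nm]], spec$box_halfwidth)$values[sel]
  if (spec$box_sd)
    for (nm in spec$contrasts)
      cols[[paste0(nm, ".box.sd")]] <-
        box_sd_volume(volumes[[nm]], spec$box_halfwidth)$values[sel]
  if (spec$dist_xyz || spec$dist_center) {
    df <- dist_features(mask)
    if (spec$dist_xyz) {
      cols[["dist.x"]] <- df$dist_x$values[sel]
      cols[["dist.y"]] <- df$dist_y$values[sel]
      cols[["dist.z"]] <- df$dist_z$values[sel]
    }
    if (spec$dist_center) cols[["dist.center"]] <- df$dist_center$values[sel]
  }
  x <- do.call(cbind, cols)
  stopifnot(ncol(x) == n_features(spec))
  structure(list(x = x, voxels = sel,
                 grid = list(dim = dim(mask$values), spacing = mask$spacing,
                             origin = mask$origin),
                 labels = NULL, scaling = NULL, spec = spec),
            class = "obs_matrix")
}

#' @export
print.obs_matrix <- function(x, ...) {
  cat(sprintf("observation matrix: %d voxels x %d features%s%s\n",
              nrow(x$x), ncol(x$x),
              if (!is.null(x$labels)) ", labelled" else "",
              if (!is.null(x$scaling)) ", scaled" else ""))
  invisible(x)
}

#' Standardise observation columns to mean 0, sd 1
#'
#' Computes per-column mean and standard deviation on the learning set and
#' standardises.  Prediction data must be transformed with the learning
#' set's parameters via \code{\link{apply_scaling}}, never rescaled on its
#' own.
#'
#' @param obs An \code{obs_matrix}.
#' @return The scaled \code{obs_matrix}; scaling parameters in
#'   \code{$scaling} (\code{center}, \code{scale} named vectors).
#' @export
scale_observations <- function(obs) {
  if (nrow(obs$x) < 2) stopf("scaling needs at least 2 observations")
  ctr <- colMeans(obs$x)
  sdv <- apply(obs$x, 2, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero))
    stopf("zero-variance feature column(s): %s",
          paste(colnames(obs$x)[zero], collapse = ", "))
  obs$x <- sweep(sweep(obs$x, 2, ctr), 2, sdv, "/")
  obs$scaling <- list(center = ctr, scale = sdv)
  obs
}

#' Apply existing scaling parameters to an observation matrix
#'
#' @param obs An \code{obs_matrix} (unscaled).
#' @param scaling Scaling parameters from \code{\link{scale_observations}}.
#' @return The transformed \code{obs_matrix}.
#' @export
apply_scaling <- function(obs, scaling) {
  if (ncol(obs$x) != length(scaling$center))
    stopf("scaling parameters do not match feature dimensionality")
  obs$x <- sweep(sweep(obs$x, 2, scaling$center), 2, scaling$scale, "/")
  obs$scaling <- scaling
  obs
}
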