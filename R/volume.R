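#' 3D scalar volume with grid metadata
#'
#' A minimal container for a 3D scalar grid: the voxel array plus spacing
#' (mm per axis), world origin (mm) and a role tag saying what the values
#' mean (CT numbers, MR intensities, tissue labels, a binary mask, a
#' predicted pseudo CT or a WEPL map).
#'
#' Coordinate convention: voxel indices are 1-based in R; the world
#' coordinate of the centre of voxel \code{(i,j,k)} is
#' \code{origin + (c(i,j,k) - 0.5) * spacing}.  This voxel-centre convention
#' is used consistently by resampling, distance features and ray tracing.
#'
#' @param values Numeric 3D array.
#' @param spacing Numeric length-3, mm per axis, all > 0.
#' @param origin Numeric length-3, mm; world position of the first voxel's
#'   corner.
#' @param role One of \code{"ct"}, \code{"mr"}, \code{"label"}, \code{"mask"},
#'   \code{"pct"}, \code{"wepl"}.
#' @return An object of class \code{"volume"}.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   role = c("ct", "mr", "label", "mask", "pct", "wepl")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("'values' must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("'spacing' must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("'origin' must be 3 finite numbers (mm)")
  if (role == "mask" && !all(values %in% c(0, 1)))
    stopf("mask volumes may only contain 0 and 1")
  structure(list(values = values, spacing = spacing, origin = origin,
                 role = role),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$values)

#' @export
as.array.volume <- function(x, ...) x$values

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume [%s]: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$role, d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  rng <- range(x$values)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param vol A \code{volume}.
#' @param axis Axis 1, 2 or 3.
#' @return Numeric vector of centre coordinates (mm) along that axis.
#' @keywords internal
axis_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

#' Check that two volumes share a grid
#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stopf("%s must share the same grid", what)
}
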