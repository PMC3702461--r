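#' Geometric region primitives for phantom scenes
#'
#' Regions are evaluated at fine-grid voxel centres in world mm; later
#' regions overwrite earlier ones, and the background is air.
#'
#' @param tissue Tissue name (must exist in the scene's tissue table).
#' @param center Length-3 centre, mm.
#' @param semiaxes Length-3 semi-axes (ellipsoid), mm.
#' @param radius,inner_radius Outer/inner radius (cylinder/shell), mm.
#' @param half_length Half-length along the cylinder axis, mm.
#' @param axis Cylinder axis: 1, 2 or 3.
#' @return A region description list.
#' @name regions
NULL

#' @rdname regions
#' @export
region_ellipsoid <- function(tissue, center, semiaxes) {
  list(type = "ellipsoid", tissue = tissue, center = as.numeric(center),
       semiaxes = as.numeric(semiaxes))
}

#' @rdname regions
#' @export
region_cylinder <- function(tissue, center, radius, half_length, axis = 3,
                            inner_radius = 0) {
  list(type = "cylinder", tissue = tissue, center = as.numeric(center),
       radius = radius, inner_radius = inner_radius,
       half_length = half_length, axis = as.integer(axis))
}

region_contains <- function(region, x, y, z) {
  c0 <- region$center
  switch(region$type,
    ellipsoid = {
      a <- region$semiaxes
      ((x - c0[1]) / a[1])^2 + ((y - c0[2]) / a[2])^2 +
        ((z - c0[3]) / a[3])^2 <= 1
    },
    cylinder = {
      co <- list(x, y, z)
      ax <- region$axis
      pl <- setdiff(1:3, ax)
      r2 <- (co[[pl[1]]] - c0[pl[1]])^2 + (co[[pl[2]]] - c0[pl[2]])^2
      inside <- r2 <= region$radius^2 &
        abs(co[[ax]] - c0[ax]) <= region$half_length
      if (region$inner_radius > 0)
        inside <- inside & r2 >= region$inner_radius^2
      inside
    },
    stopf("unknown region type '%s'", region$type)
  )
}

#' Define a phantom scene
#'
#' A scene fixes everything the generator needs: the target grid, the list
#' of geometric tissue regions (rendered in order, later overwrites earlier,
#' air background), the supersampling factor used to create partial-volume
#' voxels at tissue boundaries, the multiplicative bias-field amplitude, the
#' noise levels, and the root seed from which all noise streams are derived.
#'
#' @param shape Integer length-3 target grid shape.
#' @param spacing Numeric length-3 voxel spacing, mm.
#' @param regions List of regions (see \code{\link{region_ellipsoid}}).
#' @param tissues Tissue table; default \code{\link{tissue_table}()}.
#' @param supersampling Integer >= 1; fine grid is \code{shape * supersampling}.
#' @param bias_amplitude Relative amplitude of the multiplicative bias field
#'   applied to MR volumes, in [0, 1); 0 disables it.
#' @param mr_sigma Rician noise sigma for MR magnitudes (single value or one
#'   per contrast), in signal units.
#' @param ct_sigma Additive Gaussian noise sigma for CT, HU.
#' @param origin World origin, mm.
#' @param seed Root seed for all noise streams.
#' @return An object of class \code{"phantom_scene"}.
#' @export
phantom_scene <- function(shape, spacing = c(2, 2, 2), regions = list(),
                          tissues = tissue_table(), supersampling = 2L,
                          bias_amplitude = 0.05, mr_sigma = 0.02,
                          ct_sigma = 10, origin = c(0, 0, 0), seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) stopf("supersampling must be >= 1")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stopf("bias_amplitude must be in [0, 1) to keep the field positive")
  known <- tissues$name
  for (r in regions)
    if (!r$tissue %in% known)
      stopf("region references unknown tissue '%s'", r$tissue)
  validate_tissues(tissues)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 regions = regions, tissues = tissues,
                 supersampling = supersampling,
                 bias_amplitude = bias_amplitude,
                 mr_sigma = mr_sigma, ct_sigma = ct_sigma,
                 origin = as.numeric(origin), seed = as.integer(seed)),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom scene: %s voxels at %s mm, %d regions, supersampling %d, seed %d\n",
              paste(x$shape, collapse = "x"),
              paste(x$spacing, collapse = "x"),
              length(x$regions), x$supersampling, x$seed))
  invisible(x)
}

#' Rasterise scene regions into a fine-grid tissue label volume
#'
#' Labels are tissue indices into the scene's tissue table (air = index of
#' "air").  Every fine voxel carries exactly one label: regions are painted
#' in list order, later regions overwriting earlier ones, over an air
#' background.  Deterministic for a fixed scene.
#'
#' @param scene A \code{\link{phantom_scene}}.
#' @return A label \code{volume} at the supersampled resolution.
#' @export
build_labels <- function(scene) {
  s <- scene$supersampling
  fd <- scene$shape * s
  fs <- scene$spacing / s
  air_idx <- match("air", scene$tissues$name)
  lab <- array(air_idx, dim = fd)
  xs <- scene$origin[1] + (seq_len(fd[1]) - 0.5) * fs[1]
  ys <- scene$origin[2] + (seq_len(fd[2]) - 0.5) * fs[2]
  zs <- scene$origin[3] + (seq_len(fd[3]) - 0.5) * fs[3]
  X <- rep(xs, times = fd[2] * fd[3])
  Y <- rep(rep(ys, each = fd[1]), times = fd[3])
  Z <- rep(zs, each = fd[1] * fd[2])
  for (r in scene$regions) {
    idx <- match(r$tissue, scene$tissues$name)
    inside <- region_contains(r, X, Y, Z)
    lab[inside] <- idx
  }
  volume(lab, spacing = fs, origin = scene$origin, role = "label")
}

block_average <- function(a, s) {
  if (s == 1L) return(a)
  d <- dim(a); td <- d %/% s
  dim(a) <- c(s, td[1], s, td[2], s, td[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(s^3, prod(td))
  array(colMeans(a), dim = td)
}

block_mode <- function(a, s) {
  if (s == 1L) return(a)
  d <- dim(a); td <- d %/% s
  dim(a) <- c(s, td[1], s, td[2], s, td[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(s^3, prod(td))
  out <- vapply(seq_len(ncol(a)), function(j) which.max(tabulate(a[, j])),
                0L)
  array(out, dim = td)
}

#' Smooth multiplicative bias field
#'
#' \code{1 + amplitude * P(x, y, z)} where P is a quadratic polynomial in
#' coordinates normalised to [-1, 1], with coefficients drawn once from the
#' scene's seed and P rescaled to max |P| = 1, so the field lies in
#' \code{[1 - amplitude, 1 + amplitude]} and is strictly positive for
#' amplitude < 1.
#'
#' @keywords internal
bias_field <- function(shape, amplitude, seed) {
  if (amplitude == 0) return(array(1, dim = shape))
  cf <- with_seed(seed, stats::rnorm(10))
  u <- lapply(1:3, function(ax) {
    n <- shape[ax]
    if (n == 1) rep(0, 1) else seq(-1, 1, length.out = n)
  })
  X <- rep(u[[1]], times = shape[2] * shape[3])
  Y <- rep(rep(u[[2]], each = shape[1]), times = shape[3])
  Z <- rep(u[[3]], each = shape[1] * shape[2])
  P <- cf[1] * X + cf[2] * Y + cf[3] * Z + cf[4] * X * Y + cf[5] * X * Z +
    cf[6] * Y * Z + cf[7] * X^2 + cf[8] * Y^2 + cf[9] * Z^2 +
    cf[10] * X * Y * Z
  m <- max(abs(P))
  if (m > 0) P <- P / m
  array(1 + amplitude * P, dim = shape)
}

rician <- function(signal, sigma, seed) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  with_seed(seed, {
    re <- signal + stats::rnorm(n, sd = sigma)
    im <- stats::rnorm(n, sd = sigma)
    sqrt(re^2 + im^2)
  })
}

#' Render co-registered MR and CT volumes plus ground-truth labels
#'
#' The full forward model: (1) rasterise tissue labels on the supersampled
#' grid; (2) paint each contrast's noiseless signal and the nominal-HU CT on
#' that grid; (3) block-average down to the target grid, which creates
#' partial-volume voxels at boundaries; (4) multiply each MR volume by the
#' smooth bias field; (5) add Rician noise to MR magnitudes and Gaussian
#' noise to the CT.  Labels are reduced by per-block majority vote.  All
#' noise streams are derived from the scene seed, so a fixed scene renders
#' bit-identically.
#'
#' @param scene A \code{\link{phantom_scene}}.
#' @param sequences Named list of \code{\link{sequence_params}}; default
#'   \code{\link{default_protocol}()}.
#' @return List with elements \code{mr} (named list of MR volumes),
#'   \code{ct} (CT volume), \code{labels} (majority-vote label volume at
#'   target resolution), and \code{scene}.
#' @export
render_volumes <- function(scene, sequences = default_protocol()) {
  s <- scene$supersampling
  lab_fine <- build_labels(scene)
  lf <- lab_fine$values
  tt <- scene$tissues
  nt <- nrow(tt)
  # CT on fine grid
  hu_by_tissue <- tt$nominal_hu
  ct_fine <- array(hu_by_tissue[lf], dim = dim(lf))
  ct_vals <- block_average(ct_fine, s)
  if (scene$ct_sigma > 0) {
    ct_vals <- ct_vals + with_seed(derive_seed(scene$seed, "ct-noise"),
      array(stats::rnorm(length(ct_vals), sd = scene$ct_sigma),
            dim = dim(ct_vals)))
  }
  ct <- volume(ct_vals, spacing = scene$spacing, origin = scene$origin,
               role = "ct")
  # MR per contrast
  bias <- bias_field(scene$shape, scene$bias_amplitude,
                     derive_seed(scene$seed, "bias"))
  sig <- scene$mr_sigma
  if (length(sig) == 1L) sig <- rep(sig, length(sequences))
  if (length(sig) != length(sequences))
    stopf("mr_sigma must have length 1 or one per contrast")
  mr <- vector("list", length(sequences))
  names(mr) <- names(sequences)
  for (ci in seq_along(sequences)) {
    sq <- sequences[[ci]]
    sig_by_tissue <- vapply(seq_len(nt),
                            function(ti) mr_signal(tt[ti, ], sq), 0.0)
    fine <- array(sig_by_tissue[lf], dim = dim(lf))
    vals <- block_average(fine, s) * bias
    vals <- array(
      rician(as.numeric(vals), sig[ci],
             derive_seed(scene$seed, paste0("mr-", names(sequences)[ci]))),
      dim = scene$shape)
    mr[[ci]] <- volume(vals, spacing = scene$spacing, origin = scene$origin,
                       role = "mr")
  }
  labels <- volume(block_mode(lf, s), spacing = scene$spacing,
                   origin = scene$origin, role = "label")
  list(mr = mr, ct = ct, labels = labels, scene = scene)
}

#' Default meat-sample scene
#'
#' Mimics a piece of pork used as a multimodal phantom: a subcutaneous fat
#' shell around a muscle bulk, one cortical-bone cylinder shell with a
#' yellow-marrow core, a cartilage band next to the bone, and an internal
#' air cavity.  \code{variant} jitters region centres (up to 3 mm) and sizes
#' (up to 5 percent) deterministically so that several distinct but
#' anatomically similar samples can be generated for cross-validation.
#'
#' @param seed Root seed for the scene's noise streams.
#' @param variant Integer; 0 gives the nominal geometry, other values give
#'   jittered geometry (deterministic in \code{variant}).
#' @param shape,spacing Grid shape and spacing (mm).
#' @param noise If \code{FALSE}, all noise and the bias field are disabled.
#' @param air_cavity Include the internal air cavity?
#' @param ... Passed on to \code{\link{phantom_scene}} (e.g. \code{mr_sigma},
#'   \code{ct_sigma}, \code{bias_amplitude}, \code{supersampling}).
#' @return A \code{\link{phantom_scene}}.
#' @export
default_scene <- function(seed = 1L, variant = 0L, shape = c(48, 48, 24),
                          spacing = c(2, 2, 2), noise = TRUE,
                          air_cavity = TRUE, ...) {
  ext <- shape * spacing
  c0 <- ext / 2
  j <- if (variant == 0L) list(dc = matrix(0, 6, 3), ds = rep(1, 6))
       else with_seed(derive_seed(1000L + as.integer(variant), "scene-jitter"),
                      list(dc = matrix(stats::runif(18, -3, 3), 6, 3),
                           ds = stats::runif(6, 0.95, 1.05)))
  regions <- list(
    region_ellipsoid("fat", c0 + j$dc[1, ],
                     c(0.42, 0.38, 0.42) * ext * j$ds[1]),
    region_ellipsoid("muscle", c0 + j$dc[2, ],
                     c(0.355, 0.315, 0.355) * ext * j$ds[2]),
    region_cylinder("bone", c0 + c(-10, 0, 0) + j$dc[3, ],
                    radius = 8 * j$ds[3], half_length = 0.33 * ext[3],
                    axis = 3),
    region_cylinder("marrow", c0 + c(-10, 0, 0) + j$dc[3, ],
                    radius = 4.5 * j$ds[3], half_length = 0.33 * ext[3],
                    axis = 3),
    region_ellipsoid("cartilage", c0 + c(10, 5, 0) + j$dc[5, ],
                     c(6, 6, 10) * j$ds[5])
  )
  if (air_cavity)
    regions <- c(regions, list(
      region_ellipsoid("air", c0 + c(4, 14, 0) + j$dc[6, ],
                       c(5, 4, 6) * j$ds[6])))
  extra <- list(...)
  args <- c(list(shape = shape, spacing = spacing, regions = regions,
                 seed = seed), extra)
  if (!noise) {
    args$bias_amplitude <- 0
    args$mr_sigma <- 0
    args$ct_sigma <- 0
  }
  do.call(phantom_scene, args)
}

#' Read a phantom scene from a YAML or JSON config file
#'
#' @param path Config file path (.yaml/.yml or .json).
#' @return A \code{\link{phantom_scene}}.
#' @export
read_scene <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  tissues <- if (!is.null(cfg$tissues))
    as.data.frame(cfg$tissues, stringsAsFactors = FALSE)
  else tissue_table()
  regions <- lapply(cfg$regions %||% list(), function(r) {
    switch(r$type,
      ellipsoid = region_ellipsoid(r$tissue, unlist(r$center),
                                   unlist(r$semiaxes)),
      cylinder = region_cylinder(r$tissue, unlist(r$center), r$radius,
                                 r$half_length, axis = r$axis %||% 3,
                                 inner_radius = r$inner_radius %||% 0),
      stopf("unknown region type '%s'", r$type))
  })
  phantom_scene(shape = unlist(cfg$shape),
                spacing = unlist(cfg$spacing %||% c(2, 2, 2)),
                regions = regions, tissues = tissues,
                supersampling = cfg$supersampling %||% 2L,
                bias_amplitude = cfg$bias_amplitude %||% 0.05,
                mr_sigma = unlist(cfg$mr_sigma %||% 0.02),
                ct_sigma = cfg$ct_sigma %||% 10,
                origin = unlist(cfg$origin %||% c(0, 0, 0)),
                seed = cfg$seed %||% 1L)
}
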