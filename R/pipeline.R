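#' Pipeline configuration
#'
#' @param binning HU \code{\link{class_binning}}; default 128 classes of
#'   32 HU.
#' @param threshold Scree-gap threshold for subspace dimension selection.
#' @param floor_b Variance regularisation floor (scaled units).
#' @param class_floor_mult Minimum class size as a multiple of the feature
#'   dimensionality p; classes with fewer learning voxels are dropped and
#'   their voxels relabelled to the nearest retained class.
#' @param max_learning_voxels Cap on learning voxels; above it, a
#'   class-stratified seeded subsample is used for covariance fitting
#'   (class mean HU values always use all learning voxels).
#' @param chunk_size Prediction chunk size in voxels; results are
#'   independent of it.
#' @param seed Seed for the learning-voxel subsample.
#' @return A config list.
#' @export
pct_config <- function(binning = class_binning(), threshold = 0.2,
                       floor_b = 1e-6, class_floor_mult = 5,
                       max_learning_voxels = 200000L,
                       chunk_size = 100000L, seed = 1L) {
  list(binning = binning, threshold = threshold, floor_b = floor_b,
       class_floor_mult = class_floor_mult,
       max_learning_voxels = max_learning_voxels,
       chunk_size = chunk_size, seed = as.integer(seed))
}

# relabel voxels of dropped classes to the nearest retained class (by HU
# class midpoint)
relabel_to_retained <- function(k, retained, binning) {
  if (all(k %in% retained)) return(k)
  mid_ret <- class_midpoints(binning, retained)
  drop_idx <- which(!(k %in% retained))
  mid_drop <- class_midpoints(binning, k[drop_idx])
  nearest <- vapply(mid_drop, function(m) retained[which.min(abs(mid_ret - m))],
                    0L)
  k[drop_idx] <- nearest
  k
}

#' Train the pseudo-CT predictor
#'
#' Learns the MR-to-CT decision rule from one or more co-registered
#' learning samples.  Per sample, the observation matrix is assembled from
#' the selected contrasts and features over the mask; samples are pooled;
#' each voxel is labelled with its HU class from the reference CT; features
#' are standardised; and the subspace Gaussian discriminant model
#' (\code{\link{hdda}}) is fitted on the retained classes.  Per-class mean
#' CT numbers from the pooled learning voxels are stored for
#' reconstruction.
#'
#' @param samples List of learning samples; each a list with \code{mr}
#'   (named list of MR \code{volume}s), \code{ct} (reference CT
#'   \code{volume}) and \code{mask} (mask \code{volume}).
#' @param spec A \code{\link{feature_spec}}.
#' @param config A \code{\link{pct_config}}.
#' @return An object of class \code{"pct_model"}.
#' @export
pct_train <- function(samples, spec, config = pct_config()) {
  if (!length(samples)) stopf("at least one learning sample is required")
  p <- n_features(spec)
  xs <- vector("list", length(samples))
  hus <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot_same_grid(s$ct, s$mask, "ct and mask")
    obs <- assemble_observations(s$mr, spec, s$mask)
    xs[[i]] <- obs$x
    hus[[i]] <- s$ct$values[obs$voxels]
  }
  x <- do.call(rbind, xs)
  hu <- unlist(hus)
  binning <- config$binning
  stats <- class_stats(hu, binning)
  k <- bin_hu(hu, binning)
  floor_n <- config$class_floor_mult * p
  retained <- stats$class[stats$n >= max(floor_n, 2)]
  if (length(retained) < 2)
    stopf("fewer than 2 retained HU classes (have %d); the learning set is degenerate",
          length(retained))
  k <- relabel_to_retained(k, retained, binning)
  # recompute mean HU on the relabelled memberships so every retained class
  # has a mean over exactly its learning voxels
  mean_hu <- vapply(retained, function(cl) mean(hu[k == cl]), 0.0)
  # stratified subsample for covariance fitting
  idx <- seq_along(k)
  if (length(idx) > config$max_learning_voxels) {
    frac <- config$max_learning_voxels / length(idx)
    idx <- with_seed(derive_seed(config$seed, "subsample"), {
      unlist(lapply(split(idx, k), function(ii) {
        take <- max(2L, floor(length(ii) * frac))
        if (take >= length(ii)) ii else sort(sample(ii, take))
      }), use.names = FALSE)
    })
    idx <- sort(idx)
  }
  obs_fit <- structure(list(x = x[idx, , drop = FALSE], voxels = NULL,
                            grid = NULL, labels = k[idx], scaling = NULL,
                            spec = spec), class = "obs_matrix")
  obs_fit <- scale_observations(obs_fit)
  # fix the class order: hdda labels, the classes table and the posterior
  # columns all follow `retained` (ascending HU class index)
  model <- hdda(obs_fit$x, factor(obs_fit$labels, levels = retained),
                threshold = config$threshold, floor_b = config$floor_b)
  structure(list(spec = spec, scaling = obs_fit$scaling, binning = binning,
                 classes = data.frame(class = retained,
                                      midpoint = class_midpoints(binning, retained),
                                      mean_hu = mean_hu),
                 class_n = as.integer(table(factor(k, levels = retained))),
                 hdda = model, config = config,
                 n_learning = length(k), p = p),
            class = "pct_model")
}

#' @export
print.pct_model <- function(x, ...) {
  cat(sprintf("pseudo-CT predictor: p = %d features (%s), %d retained HU classes, %d learning voxels\n",
              x$p, paste(x$spec$contrasts, collapse = "+"),
              nrow(x$classes), x$n_learning))
  invisible(x)
}

#' @export
summary.pct_model <- function(object, ...) {
  cat(sprintf("pseudo-CT predictor\n  features (p = %d): %s\n", object$p,
              paste(colnames(object$scaling$center) %||%
                      names(object$scaling$center), collapse = ", ")))
  print(object$binning)
  df <- object$classes
  df$n <- object$class_n
  cat(sprintf("  %d retained classes; mean HU range [%g, %g]\n",
              nrow(df), min(df$mean_hu), max(df$mean_hu)))
  invisible(df)
}

#' Predict a pseudo-CT volume from MR volumes
#'
#' Assembles the observation vector for every mask voxel, applies the
#' learning-set scaling, computes class posteriors under the fitted
#' subspace Gaussian model, and reconstructs the pseudo CT number as the
#' posterior-weighted average of the retained classes' mean CT numbers:
#' \eqn{pCT_j = \sum_k P(C_k | X_j) \overline{HU}_k}.  Voxels outside the
#' mask are set to air (-1000 HU).  Prediction runs in chunks; the result
#' is independent of the chunk size.
#'
#' @param object A \code{pct_model}.
#' @param mr Named list of MR \code{volume}s covering the model's
#'   contrasts, on the mask grid.
#' @param mask Mask \code{volume}.
#' @param ... Unused.
#' @return A pseudo-CT \code{volume} (role \code{"pct"}).
#' @export
predict.pct_model <- function(object, mr, mask, ...) {
  obs <- assemble_observations(mr, object$spec, mask)
  obs <- apply_scaling(obs, object$scaling)
  n <- nrow(obs$x)
  mean_hu <- object$classes$mean_hu
  pct_vals <- numeric(n)
  cs <- object$config$chunk_size %||% 100000L
  starts <- seq(1L, n, by = cs)
  for (s0 in starts) {
    s1 <- min(s0 + cs - 1L, n)
    post <- predict(object$hdda, obs$x[s0:s1, , drop = FALSE])
    pct_vals[s0:s1] <- as.numeric(post %*% mean_hu)
  }
  out <- array(-1000, dim = obs$grid$dim)
  out[obs$voxels] <- pct_vals
  volume(out, spacing = obs$grid$spacing, origin = obs$grid$origin,
         role = "pct")
}

#' Leave-one-sample-out cross-validation and combination search
#'
#' For each feature spec, trains on all samples but one and predicts the
#' held-out sample, reporting per-fold MAE and per-class mean error.  With
#' several specs this is the combination search: the summary table is
#' sorted by mean MAE across folds (ascending).
#'
#' @param samples List of samples (\code{mr}, \code{ct}, \code{mask}); at
#'   least 2.
#' @param specs A single \code{\link{feature_spec}} or a list of them.
#' @param config A \code{\link{pct_config}}.
#' @return An object of class \code{"pct_crossval"}: \code{table} (one row
#'   per spec: contrasts, features, p, mean/per-fold MAE) and
#'   \code{folds} (per spec, per fold: \code{mae}, \code{me} data frame,
#'   \code{pct} volume).
#' @export
pct_crossval <- function(samples, specs, config = pct_config()) {
  if (length(samples) < 2) stopf("cross-validation needs >= 2 samples")
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  nS <- length(samples)
  res <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    folds <- vector("list", nS)
    maes <- numeric(nS)
    for (f in seq_len(nS)) {
      train_samples <- samples[-f]
      model <- pct_train(train_samples, spec, config)
      held <- samples[[f]]
      pct <- predict(model, held$mr, held$mask)
      m <- mae(pct, held$ct, held$mask)
      me <- me_per_class(pct, held$ct, held$mask, config$binning)
      folds[[f]] <- list(mae = m, me = me, pct = pct, model = model)
      maes[f] <- m$mae
    }
    res[[si]] <- folds
    feats <- c(if (spec$box_mean) "box.mean", if (spec$box_sd) "box.sd",
               if (spec$dist_xyz) "dist.xyz",
               if (spec$dist_center) "dist.center")
    rows[[si]] <- data.frame(
      spec = si,
      contrasts = paste(spec$contrasts, collapse = "+"),
      features = if (length(feats)) paste(feats, collapse = "+") else "none",
      p = n_features(spec),
      mean_mae = mean(maes),
      t(stats::setNames(maes, paste0("mae_fold", seq_len(nS)))),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$mean_mae)
  structure(list(table = tab[ord, , drop = FALSE], folds = res,
                 specs = specs), class = "pct_crossval")
}

#' @export
print.pct_crossval <- function(x, ...) {
  cat("leave-one-sample-out cross-validation\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialise / restore a trained predictor as JSON
#'
#' All numeric arrays are stored inline at full precision; the artifact is
#' version-stamped.
#'
#' @param model A \code{pct_model}.
#' @param path Output path (.json).
#' @return \code{path} / the restored \code{pct_model}.
#' @export
save_pct_model <- function(model, path) {
  art <- list(
    format = "pction-pct-model", version = 1L,
    spec = unclass(model$spec),
    scaling = lapply(model$scaling, as.list),
    binning = unclass(model$binning),
    classes = model$classes,
    class_n = model$class_n,
    n_learning = model$n_learning, p = model$p,
    config = list(threshold = model$config$threshold,
                  floor_b = model$config$floor_b,
                  class_floor_mult = model$config$class_floor_mult,
                  max_learning_voxels = model$config$max_learning_voxels,
                  chunk_size = model$config$chunk_size,
                  seed = model$config$seed),
    hdda = list(labels = model$hdda$labels, p = model$hdda$p,
                threshold = model$hdda$threshold,
                floor_b = model$hdda$floor_b,
                classes = lapply(model$hdda$classes, function(cl)
                  list(prior = cl$prior, mu = cl$mu,
                       Q = as.numeric(cl$Q), d = cl$d,
                       a = cl$a, b = cl$b, n = cl$n)))
  )
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_pct_model
#' @export
load_pct_model <- function(path) {
  art <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(art$format, "pction-pct-model"))
    stopf("%s is not a serialized pct_model", path)
  p <- art$p
  cls <- lapply(seq_along(art$hdda$classes$prior %||% art$hdda$classes),
                function(i) NULL)
  hcl <- art$hdda$classes
  classes <- if (is.data.frame(hcl)) {
    lapply(seq_len(nrow(hcl)), function(i)
      new_hdda_class(hcl$prior[i], unlist(hcl$mu[i]),
                     matrix(unlist(hcl$Q[i]), nrow = p),
                     unlist(hcl$a[i]), hcl$b[i], hcl$d[i], hcl$n[i]))
  } else {
    lapply(hcl, function(cl)
      new_hdda_class(cl$prior, unlist(cl$mu),
                     matrix(unlist(cl$Q), nrow = p),
                     unlist(cl$a), cl$b, cl$d, cl$n))
  }
  hd <- structure(list(classes = classes, p = p,
                       labels = as.character(art$hdda$labels),
                       threshold = art$hdda$threshold,
                       floor_b = art$hdda$floor_b), class = "hdda")
  spec <- do.call(feature_spec, art$spec[c("contrasts", "box_mean", "box_sd",
                                           "dist_xyz", "dist_center",
                                           "box_halfwidth")])
  binning <- class_binning(art$binning$lower, art$binning$width,
                           art$binning$count)
  cfg <- pct_config(binning = binning, threshold = art$config$threshold,
                    floor_b = art$config$floor_b,
                    class_floor_mult = art$config$class_floor_mult,
                    max_learning_voxels = art$config$max_learning_voxels,
                    chunk_size = art$config$chunk_size,
                    seed = art$config$seed)
  structure(list(spec = spec,
                 scaling = list(center = unlist(art$scaling$center),
                                scale = unlist(art$scaling$scale)),
                 binning = binning, classes = as.data.frame(art$classes),
                 class_n = as.integer(art$class_n), hdda = hd, config = cfg,
                 n_learning = art$n_learning, p = p),
            class = "pct_model")
}
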