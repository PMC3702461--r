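# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, suppressWarnings(build()), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_signs_test <- function(Q) {
  for (j in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, j]) > 1e-12)
    if (length(nz) && Q[nz[1], j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

axis_ctr <- function(vol, ax) {
  vol$origin[ax] + (seq_len(dim(vol$values)[ax]) - 0.5) * vol$spacing[ax]
}

# three noiseless, geometry-jittered meat-sample scenes for cross-validation
noiseless_samples <- function() {
  fixture("noiseless_samples", function() {
    lapply(1:3, function(v) {
      r <- render_volumes(default_scene(seed = v, variant = v, noise = FALSE))
      list(mr = r$mr, ct = r$ct, mask = air_mask(r$ct), labels = r$labels,
           scene = r$scene)
    })
  })
}

best_spec <- function() {
  feature_spec(c("TSE1", "UTE2e1", "UTE2e2"), box_sd = TRUE,
               dist_center = TRUE)
}

# a small random hdda model with valid parameters (orthonormal Q, a >= b)
random_hdda_model <- function(p, K, d = NULL) {
  priors <- stats::runif(K); priors <- priors / sum(priors)
  mu <- lapply(seq_len(K), function(k) stats::rnorm(p, sd = 2))
  Q <- list(); a <- list(); b <- numeric(K)
  for (k in seq_len(K)) {
    dk <- if (is.null(d)) sample(seq_len(p - 1), 1) else d
    M <- matrix(stats::rnorm(p * dk), p, dk)
    Q[[k]] <- qr.Q(qr(M))
    b[k] <- stats::runif(1, 0.1, 0.5)
    a[[k]] <- sort(stats::runif(dk, b[k], b[k] + 5), decreasing = TRUE)
  }
  hdda_model(priors, mu, Q, a, b)
}

# dense multivariate-normal log-density oracle (chol-based, no package)
dmvnorm_log <- function(x, mu, Sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- ncol(x)
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(sweep(x, 2, mu)))
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# posterior oracle via dense densities on the reconstructed covariances
posterior_oracle <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  K <- length(model$classes)
  lp <- sapply(seq_len(K), function(k) {
    cl <- model$classes[[k]]
    log(cl$prior) + dmvnorm_log(x, cl$mu, hdda_covariance(model, k))
  })
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
  m <- apply(lp, 1, max)
  w <- exp(lp - m)
  w / rowSums(w)
}
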