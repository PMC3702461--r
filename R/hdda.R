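#' Scree-gap selection of the intrinsic subspace dimension
#'
#' Cattell's scree rule on the eigenvalue gaps: with
#' \eqn{\delta_j = \lambda_j - \lambda_{j+1}}, the retained dimension is the
#' largest \eqn{j} with \eqn{\delta_j \ge t \cdot \max_j \delta_j}, bounded
#' to \code{[1, p-1]}.  If two gaps tie at the maximum the larger \eqn{j}
#' wins (keeps more structure).  If all eigenvalues are equal there is no
#' scree and the dimension falls back to 1.
#'
#' @param eigenvalues Eigenvalues in descending order (length >= 2, all >= 0).
#' @param threshold Fraction of the largest gap, default 0.2.
#' @return Integer dimension in \code{[1, length(eigenvalues) - 1]}.
#' @export
select_dimension <- function(eigenvalues, threshold = 0.2) {
  p <- length(eigenvalues)
  if (p < 2) stopf("select_dimension needs at least 2 eigenvalues")
  if (any(eigenvalues < -1e-12)) stopf("eigenvalues must be >= 0")
  if (is.unsorted(rev(eigenvalues), strictly = FALSE) &&
      any(diff(eigenvalues) > 1e-8 * max(abs(eigenvalues), 1)))
    stopf("eigenvalues must be in descending order")
  delta <- eigenvalues[-p] - eigenvalues[-1]
  mx <- max(delta)
  if (mx <= 0) return(1L)
  d <- max(which(delta >= threshold * mx))
  as.integer(min(max(d, 1L), p - 1L))
}

fix_eigen_signs <- function(Q, tol = 1e-12) {
  for (j in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, j]) > tol)
    if (length(nz) && Q[nz[1], j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

new_hdda_class <- function(prior, mu, Q, a, b, d, n = NA_integer_) {
  list(prior = prior, mu = mu, Q = Q, a = a, b = b, d = d, n = n)
}

#' Construct a subspace Gaussian discriminant model from explicit parameters
#'
#' Builds an \code{hdda} object directly from per-class parameters (priors,
#' means, orthonormal subspace bases, subspace variances and noise
#' variances) without fitting.  Each class k models the data as Gaussian
#' with covariance
#' \deqn{\Sigma_k = Q_k \, diag(a_{k1} \ldots a_{kd_k}) \, Q_k^T +
#'   b_k (I - Q_k Q_k^T),}
#' i.e. a \eqn{d_k}-dimensional signal subspace with variances \eqn{a_{kj}}
#' and isotropic noise \eqn{b_k} in the orthogonal complement.
#'
#' @param priors Numeric vector of class priors (must sum to 1).
#' @param mu List of p-vectors (class means).
#' @param Q List of p x d_k matrices with orthonormal columns.
#' @param a List of subspace variance vectors (length d_k, all >= b_k).
#' @param b Numeric vector of noise variances (> 0).
#' @param labels Optional class labels (default 1..K).
#' @return An object of class \code{"hdda"}.
#' @export
hdda_model <- function(priors, mu, Q, a, b, labels = NULL) {
  K <- length(priors)
  stopifnot(length(mu) == K, length(Q) == K, length(a) == K, length(b) == K)
  if (abs(sum(priors) - 1) > 1e-8) stopf("priors must sum to 1")
  p <- length(mu[[1]])
  classes <- vector("list", K)
  for (k in seq_len(K)) {
    Qk <- as.matrix(Q[[k]])
    if (max(abs(crossprod(Qk) - diag(ncol(Qk)))) > 1e-8)
      stopf("Q[[%d]] columns are not orthonormal", k)
    if (b[k] <= 0) stopf("b must be > 0")
    if (any(a[[k]] < b[k] - 1e-12))
      stopf("subspace variances a must be >= noise variance b (class %d)", k)
    classes[[k]] <- new_hdda_class(priors[k], mu[[k]], Qk, a[[k]], b[k],
                                   ncol(Qk))
  }
  structure(list(classes = classes, p = p,
                 labels = labels %||% seq_len(K),
                 threshold = NA_real_, floor_b = NA_real_),
            class = "hdda")
}

#' Fit the subspace Gaussian discriminant model
#'
#' High-dimensional discriminant analysis in its most general form: each
#' class gets its own Gaussian with a class-specific low-dimensional signal
#' subspace.  Per class, the empirical (maximum-likelihood) covariance is
#' eigendecomposed; the intrinsic dimension \eqn{d_k} is chosen by the
#' scree-gap rule (\code{\link{select_dimension}}); the top \eqn{d_k}
#' eigenvalues become the subspace variances \eqn{a_{kj}}; the remaining
#' variance is pooled into one isotropic noise variance
#' \eqn{b_k = (tr(\Sigma_k) - \sum_{j \le d_k} \lambda_{kj}) / (p - d_k)},
#' floored at \code{floor_b} to survive singular classes.  Eigenvector
#' signs are fixed (first non-zero component positive) so the fit is
#' deterministic.
#'
#' Observations are expected already standardised (mean 0, sd 1 per
#' column); see \code{\link{scale_observations}}.
#'
#' @param x Numeric matrix, n x p, p >= 2 (scaled features).
#' @param grouping Class labels, one per row (factor or vector).
#' @param threshold Scree-gap threshold for dimension selection, default 0.2.
#' @param floor_b Lower floor for variances (regularisation), default 1e-6.
#' @return An object of class \code{"hdda"}: per-class priors, means,
#'   orthonormal bases \code{Q}, subspace variances \code{a}, noise
#'   variance \code{b}, dimension \code{d}.
#' @seealso \code{\link{predict.hdda}}, \code{\link{hdda_cost}}
#' @export
hdda <- function(x, grouping, threshold = 0.2, floor_b = 1e-6) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stopf("hdda requires p >= 2 features")
  if (nrow(x) != length(grouping)) stopf("grouping length must match rows")
  g <- factor(grouping)
  labels <- levels(g)
  K <- length(labels)
  if (K < 2) stopf("hdda requires at least 2 classes")
  n <- nrow(x)
  classes <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- which(g == labels[k])
    nk <- length(rows)
    if (nk < 2) stopf("class '%s' has fewer than 2 observations", labels[k])
    xk <- x[rows, , drop = FALSE]
    muk <- colMeans(xk)
    xc <- sweep(xk, 2, muk)
    S <- crossprod(xc) / nk          # ML covariance
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    d <- select_dimension(lam, threshold)
    b <- (sum(lam) - sum(lam[seq_len(d)])) / (p - d)
    if (b < floor_b) {
      b <- floor_b
      warning(sprintf("class '%s': near-singular covariance, noise variance floored",
                      labels[k]), call. = FALSE)
    }
    a <- pmax(lam[seq_len(d)], b)
    Q <- fix_eigen_signs(ev$vectors[, seq_len(d), drop = FALSE])
    classes[[k]] <- new_hdda_class(nk / n, muk, Q, a, b, d, nk)
  }
  structure(list(classes = classes, p = p, labels = labels,
                 threshold = threshold, floor_b = floor_b),
            class = "hdda")
}

#' @export
print.hdda <- function(x, ...) {
  K <- length(x$classes)
  d <- vapply(x$classes, `[[`, 0L, "d")
  cat(sprintf("subspace Gaussian discriminant model: %d classes, p = %d\n",
              K, x$p))
  cat(sprintf("  intrinsic dimensions d_k: %s\n",
              paste(range(d), collapse = "..")))
  invisible(x)
}

#' @export
summary.hdda <- function(object, ...) {
  tab <- data.frame(
    class = object$labels,
    n = vapply(object$classes, `[[`, 0L, "n"),
    prior = vapply(object$classes, `[[`, 0.0, "prior"),
    d = vapply(object$classes, `[[`, 0L, "d"),
    b = vapply(object$classes, `[[`, 0.0, "b"),
    a_max = vapply(object$classes, function(cl) max(cl$a), 0.0)
  )
  structure(list(p = object$p, table = tab), class = "summary.hdda")
}

#' @export
print.summary.hdda <- function(x, ...) {
  cat(sprintf("subspace Gaussian discriminant model (p = %d)\n", x$p))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hdda <- function(object, ...) {
  list(priors = vapply(object$classes, `[[`, 0.0, "prior"),
       means = do.call(rbind, lapply(object$classes, `[[`, "mu")),
       d = vapply(object$classes, `[[`, 0L, "d"),
       b = vapply(object$classes, `[[`, 0.0, "b"),
       a = lapply(object$classes, `[[`, "a"),
       Q = lapply(object$classes, `[[`, "Q"))
}

#' Per-class classification cost
#'
#' The cost of assigning observation x to class k,
#' \deqn{K_k(x) = \sum_{j \le d_k} \frac{(q_{kj}^T (x-\mu_k))^2}{a_{kj}}
#'   + \frac{\| (x-\mu_k) - Q_k Q_k^T (x-\mu_k) \|^2}{b_k}
#'   + \sum_{j \le d_k} \log a_{kj} + (p-d_k) \log b_k - 2 \log \pi_k,}
#' which equals \eqn{-2 \log(\pi_k \phi(x; \mu_k, \Sigma_k))} minus the
#' class-independent constant \eqn{p \log 2\pi}, with \eqn{\Sigma_k} the
#' reconstructed subspace-plus-noise covariance.  Lower is better.
#'
#' @param model An \code{hdda} object.
#' @param x Numeric matrix (n x p) or p-vector.
#' @return n x K matrix of costs (columns named by class label).
#' @export
hdda_cost <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$p) stopf("x must have p = %d columns", model$p)
  K <- length(model$classes)
  out <- matrix(NA_real_, nrow(x), K)
  for (k in seq_len(K)) {
    cl <- model$classes[[k]]
    xc <- sweep(x, 2, cl$mu)
    proj <- xc %*% cl$Q                       # n x d
    quad_sub <- proj^2 %*% (1 / cl$a)         # n x 1
    resid2 <- rowSums(xc^2) - rowSums(proj^2) # squared distance off-subspace
    resid2 <- pmax(resid2, 0)
    out[, k] <- quad_sub + resid2 / cl$b + sum(log(cl$a)) +
      (model$p - cl$d) * log(cl$b) - 2 * log(cl$prior)
  }
  colnames(out) <- model$labels
  out
}

#' Reconstruct the full covariance of one class
#'
#' \eqn{\Sigma_k = Q_k diag(a_k) Q_k^T + b_k (I - Q_k Q_k^T)}.  Used by the
#' dense-Gaussian oracle tests; not needed for prediction.
#'
#' @param model An \code{hdda} object.
#' @param k Class index.
#' @return p x p covariance matrix.
#' @export
hdda_covariance <- function(model, k) {
  cl <- model$classes[[k]]
  P <- tcrossprod(cl$Q)
  cl$Q %*% diag(cl$a, nrow = cl$d) %*% t(cl$Q) + cl$b * (diag(model$p) - P)
}

#' Posterior class probabilities / class predictions
#'
#' Posteriors are computed from the class costs with max-subtraction for
#' numerical stability:
#' \eqn{P(C_k | x) = \exp(-K_k(x)/2) / \sum_l \exp(-K_l(x)/2)}.
#'
#' @param object An \code{hdda} object.
#' @param newdata Matrix of observations (same scaling as the fit).
#' @param type \code{"posterior"} (n x K probability matrix, rows sum to 1)
#'   or \code{"class"} (maximum-posterior label).
#' @param ... Unused.
#' @return Posterior matrix or label vector.
#' @export
predict.hdda <- function(object, newdata, type = c("posterior", "class"),
                         ...) {
  type <- match.arg(type)
  cost <- hdda_cost(object, newdata)
  cmin <- apply(cost, 1, min)
  w <- exp(-(cost - cmin) / 2)
  post <- w / rowSums(w)
  if (type == "posterior") return(post)
  object$labels[max.col(post, ties.method = "first")]
}
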