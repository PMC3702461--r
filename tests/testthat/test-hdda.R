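test_that("scree-gap dimension selection follows the gap rule", {
  # gaps (1, 8, 0.1, 0.1); max 8; largest j with gap >= 1.6 is 2
  expect_equal(select_dimension(c(10, 9, 1, 0.9, 0.8), 0.2), 2L)
  # only the first gap passes
  expect_equal(select_dimension(c(5, 1, 1, 1), 0.2), 1L)
  # threshold 0: every gap passes, upper bound p - 1 applies
  expect_equal(select_dimension(c(5, 4, 3, 2, 1), 0), 4L)
  # flat spectrum: no scree, documented fallback d = 1
  expect_equal(select_dimension(c(2, 2, 2, 2), 0.2), 1L)
  # ties at the max gap resolve to the larger j
  expect_equal(select_dimension(c(10, 6, 2, 1.9), 0.2), 2L)
  expect_error(select_dimension(c(3), 0.2), "at least 2")
})

test_that("classification cost matches the dense-Gaussian oracle up to a constant", {
  set.seed(31)
  model <- random_hdda_model(p = 6, K = 3)
  x <- matrix(rnorm(40 * 6, sd = 3), 40, 6)
  cost <- hdda_cost(model, x)
  for (k in 1:3) {
    cl <- model$classes[[k]]
    oracle <- -2 * (log(cl$prior) +
                      dmvnorm_log(x, cl$mu, hdda_covariance(model, k)))
    diff <- cost[, k] - oracle
    # equal up to the class-independent p*log(2*pi)
    expect_lt(max(diff) - min(diff), 1e-8)
    expect_equal(diff[1], -6 * log(2 * pi), tolerance = 1e-8)
  }
  # at the class mean only the log-determinant and prior terms remain
  cl <- model$classes[[1]]
  k_mu <- unname(hdda_cost(model, cl$mu)[1, 1])
  expect_equal(k_mu, sum(log(cl$a)) + (6 - cl$d) * log(cl$b) -
                 2 * log(cl$prior), tolerance = 1e-10)
})

test_that("posteriors equal the dense-Gaussian posterior oracle", {
  set.seed(32)
  for (rep in 1:5) {
    p <- sample(3:10, 1); K <- sample(2:8, 1)
    model <- random_hdda_model(p, K)
    x <- matrix(rnorm(30 * p, sd = 3), 30, p)
    post <- predict(model, x)
    expect_lt(max(abs(post - posterior_oracle(model, x))), 1e-8)
    expect_equal(rowSums(post), rep(1, 30), tolerance = 1e-9)
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("posterior limiting behaviour: symmetry and separation", {
  # two identical isotropic classes, equal priors: uniform posterior at any x
  Q <- list(diag(3)[, 1, drop = FALSE], diag(3)[, 1, drop = FALSE])
  m <- hdda_model(c(0.5, 0.5), list(rep(0, 3), rep(0, 3)), Q,
                  list(1, 1), c(1, 1))
  post <- predict(m, matrix(rnorm(15), 5, 3))
  expect_equal(post, matrix(0.5, 5, 2, dimnames = list(NULL, 1:2)),
               tolerance = 1e-12)
  # two isotropic classes 100 units apart: the near class wins outright
  m2 <- hdda_model(c(0.5, 0.5), list(rep(0, 3), c(100, 0, 0)), Q,
                   list(1, 1), c(1, 1))
  post2 <- predict(m2, matrix(c(1, 0, 0), 1, 3))
  expect_gt(post2[1, 1], 1 - 1e-10)
})

test_that("fit recovers isotropic and low-rank-plus-noise structure", {
  set.seed(33)
  # isotropic unit-variance classes: a ~ b ~ 1, priors ~ 1/2
  n <- 4000
  x <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4, mean = 8), n, 4))
  g <- rep(1:2, each = n)
  fit <- suppressWarnings(hdda(x, g))
  for (k in 1:2) {
    cl <- fit$classes[[k]]
    expect_equal(cl$prior, 0.5)
    expect_lt(abs(cl$b - 1), 3 * sqrt(2 / n))
    expect_lt(abs(cl$a[1] - 1), 0.15)
  }

  # known rank-2-plus-noise covariance: d, a, b recovered
  p <- 6; n2 <- 10000
  lam <- c(8, 4, rep(0.5, p - 2))
  V <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  z <- matrix(rnorm(n2 * p), n2, p) %*% diag(sqrt(lam)) %*% t(V)
  x2 <- rbind(z, matrix(rnorm(n2 * p, mean = 20), n2, p))
  fit2 <- hdda(x2, rep(1:2, each = n2))
  cl <- fit2$classes[[1]]
  expect_equal(cl$d, 2L)
  expect_lt(abs(cl$a[1] - 8) / 8, 0.05)
  expect_lt(abs(cl$a[2] - 4) / 4, 0.05)
  expect_lt(abs(cl$b - 0.5) / 0.5, 0.05)
})

test_that("degenerate classes hit the variance floor instead of crashing", {
  x <- rbind(matrix(rep(c(1, 2, 3), each = 50), 50, 3),
             matrix(rnorm(150, mean = 10), 50, 3))
  expect_warning(fit <- hdda(x, rep(1:2, each = 50)), "floored")
  expect_equal(fit$classes[[1]]$b, 1e-6)
  expect_true(all(fit$classes[[1]]$a >= fit$classes[[1]]$b))
  # p < 2 rejected
  expect_error(hdda(matrix(1:10, ncol = 1), rep(1:2, 5)), "p >= 2")
})

test_that("fit is deterministic and matches unconstrained QDA in the full-dimension limit", {
  set.seed(34)
  x <- matrix(rnorm(600), 200, 3)
  x[101:200, ] <- x[101:200, ] %*% diag(c(2, 1, 0.5)) + 5
  g <- rep(1:2, each = 100)
  f1 <- hdda(x, g); f2 <- hdda(x, g)
  for (k in 1:2) {
    expect_identical(f1$classes[[k]]$Q, f2$classes[[k]]$Q)
    expect_identical(f1$classes[[k]]$a, f2$classes[[k]]$a)
  }

  # d = p - 1 with b equal to the smallest eigenvalue reconstructs the full
  # empirical covariance, i.e. the model collapses to QDA
  for (k in 1:2) {
    rows <- which(g == k)
    S <- stats::cov(x[rows, ]) * (length(rows) - 1) / length(rows)
    ev <- eigen(S, symmetric = TRUE)
    m <- hdda_model(1, list(colMeans(x[rows, ])),
                    list(fix_signs_test(ev$vectors[, 1:2])),
                    list(ev$values[1:2]), ev$values[3], labels = "k")
    expect_equal(hdda_covariance(m, 1), S, tolerance = 1e-10)
  }
})

test_that("posteriors are invariant to adding a constant to every cost", {
  set.seed(35)
  model <- random_hdda_model(p = 4, K = 3)
  x <- matrix(rnorm(20), 5, 4)
  cost <- hdda_cost(model, x)
  soft <- function(cm) {
    w <- exp(-(cm - apply(cm, 1, min)) / 2); w / rowSums(w)
  }
  expect_equal(soft(cost), soft(cost + 123.4), tolerance = 1e-12)
})
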