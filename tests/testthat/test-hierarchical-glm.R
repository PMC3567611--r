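make_design <- function(L, nt, seed = 1, theta2 = 3.5, vartheta2 = 1,
                        l1 = 2, l2 = 0.5) {
  set.seed(seed)
  x <- abs(rnorm(nt)) + 0.1
  amp <- purrr::map_dfr(seq_len(L), function(l) {
    th <- theta2 + rnorm(1, 0, sqrt(l2))
    vt <- vartheta2 + rnorm(1, 0, sqrt(l2))
    tibble::tibble(participant = l, trial = seq_len(nt),
                   Y = th + vt * x + rnorm(nt, 0, sqrt(l1)))
  })
  list(design = build_design(amp, x), x = x, amp = amp)
}

test_that("design assembly has the stated shapes and block structure", {
  d <- make_design(1, 6)$design     # one participant, N = 3 trials per category
  expect_equal(dim(d$X1), c(6, 2))
  expect_equal(dim(d$X2), c(2, 2))
  expect_equal(d$X2, diag(2))

  d16 <- make_design(16, 384)$design
  expect_equal(dim(d16$X1), c(6144, 32))
  expect_equal(dim(d16$X2), c(32, 2))
  # off-block entries are zero
  X1 <- d16$X1
  for (l in c(1, 7, 16)) {
    rows <- ((l - 1) * 384 + 1):(l * 384)
    expect_true(all(X1[rows, -c(2 * l - 1, 2 * l)] == 0))
    expect_equal(X1[rows, 2 * l - 1], rep(1, 384))
  }
  # ragged inputs are rejected
  amp_bad <- dplyr::filter(make_design(2, 10)$amp, !(participant == 2 & trial == 10))
  expect_error(build_design(amp_bad, rnorm(10)), "ragged|same trial count")
})

test_that("PEB evidence matches dense evaluation of the collapsed Gaussian", {
  # instances of at most 32 observations, both at EM optimum and fixed lambdas
  for (seed in 1:4) {
    d <- make_design(2, 8, seed = seed)$design
    fit <- peb_fit(d)
    expect_lt(abs(fit$F - collapsed_log_density(d, fit$lambda)), 1e-6)

    lam <- c(1.3, 0.4, 50)
    fit_fixed <- peb_fit(d, peb_control(fixed_lambda = lam))
    expect_lt(abs(fit_fixed$F - collapsed_log_density(d, lam)), 1e-6)
  }
  # single-participant toy with known lambdas
  d1 <- make_design(1, 8, seed = 9)$design
  lam <- c(2, 1, 10)
  f1 <- peb_fit(d1, peb_control(fixed_lambda = lam))
  expect_lt(abs(f1$F - collapsed_log_density(d1, lam)), 1e-6)
})

test_that("EM increases the marginal likelihood monotonically and converges", {
  d <- make_design(6, 40, seed = 3)$design
  fit <- peb_fit(d)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
  # flagged, not silent, when the budget is too small
  fit2 <- peb_fit(d, peb_control(max_iter = 2))
  expect_false(fit2$converged)
})

test_that("noise-free data is interpolated in the small-lambda1 limit", {
  set.seed(7)
  L <- 4; nt <- 32
  x <- abs(rnorm(nt)) + 0.1
  theta <- cbind(3.5 + rnorm(L, 0, 0.7), 1 + rnorm(L, 0, 0.7))
  amp <- purrr::map_dfr(seq_len(L), function(l) {
    tibble::tibble(participant = l, trial = seq_len(nt),
                   Y = theta[l, 1] + theta[l, 2] * x)
  })
  d <- build_design(amp, x)
  fit <- peb_fit(d, peb_control(fixed_lambda = c(1e-7, 0.1, 0.1)))
  est <- matrix(fit$theta1, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(est - theta) / abs(theta)), 1e-6)
  expect_lt(fit$mse, 1e-12)
})

test_that("posterior participant means are matrix-shrunk from OLS toward the group", {
  for (seed in 1:5) {
    md <- make_design(6, 30, seed = seed)
    fit <- peb_fit(md$design)
    Xb <- cbind(1, md$x)
    A <- crossprod(Xb) / fit$lambda[1]
    S <- solve(A + diag(2) / fit$lambda[2], A)
    ev <- eigen(S, only.values = TRUE)$values
    expect_true(all(Re(ev) >= -1e-10 & Re(ev) <= 1 + 1e-10))
    for (l in 1:6) {
      Yl <- md$amp$Y[md$amp$participant == l]
      ols <- drop(solve(crossprod(Xb), crossprod(Xb, Yl)))
      post <- fit$theta1[(2 * l - 1):(2 * l)]
      pred <- drop(S %*% ols + (diag(2) - S) %*% fit$theta2)
      expect_equal(post, pred, tolerance = 1e-6)
      # contraction: the posterior is no farther from the group than OLS
      expect_lte(sqrt(sum((post - fit$theta2)^2)),
                 sqrt(sum((ols - fit$theta2)^2)) + 1e-8)
    }
  }
})

test_that("log-Bayes factors difference evidences with guard rails", {
  expect_equal(log_bayes_factor(10, 10)$log_bf, 0)
  expect_equal(log_bayes_factor(3, 10)$log_bf, -log_bayes_factor(10, 3)$log_bf)
  expect_equal(log_bayes_factor(45, 10)$evidence, "very strong")
  expect_equal(log_bayes_factor(10, 10)$evidence, "inconclusive")

  d1 <- make_design(2, 10, seed = 1)$design
  d2 <- make_design(2, 10, seed = 2)$design
  f1 <- peb_fit(d1); f2 <- peb_fit(d2)
  expect_error(log_bayes_factor(f1, f2), "same data")
})

test_that("goodness of fit matches the hand-computed two-point case", {
  g <- goodness_of_fit(c(0, 2), c(1, 1))
  expect_equal(g$mse, 1)
  expect_equal(g$fve, 0)
  y <- rnorm(50)
  expect_equal(goodness_of_fit(y, y)$mse, 0)
  expect_equal(goodness_of_fit(y, y)$fve, 1)
  expect_equal(goodness_of_fit(y, rep(mean(y), 50))$fve, 0)
  expect_error(goodness_of_fit(c(1, 1), c(1, 1)), "zero-variance")
})

test_that("tidy and glance expose the fit in broom style", {
  md <- make_design(3, 12, seed = 4)
  fit <- peb_fit(md$design)
  tt <- tidy(fit)
  expect_equal(nrow(tt), 2 + 2 * 3)
  expect_true(all(c("level", "term", "estimate", "std.error") %in% names(tt)))
  expect_true(all(tt$std.error > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$logF, fit$F)
})
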