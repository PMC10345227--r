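sim_ri <- function(n_subj, k, beta = c(10, 2), sigma_b = 2, sigma = 1,
                   p_extra_cols = 1) {
  subj <- rep(seq_len(n_subj), each = k)
  n <- length(subj)
  X <- cbind(1, matrix(rnorm(n * p_extra_cols), n))
  y <- drop(X %*% beta) + rnorm(n_subj, sd = sigma_b)[subj] +
    rnorm(n, sd = sigma)
  list(X = X, y = y, subj = subj)
}

test_that("restricted likelihood reduces to OLS at theta = 0 and is
           invariant to within-subject row order", {
  set.seed(31)
  d <- sim_ri(12, 3)
  ll0 <- reml_loglik(0, d$X, d$y, d$subj)
  # OLS restricted likelihood computed directly
  qrX <- qr(d$X)
  rss <- sum(qr.resid(qrX, d$y)^2)
  df <- length(d$y) - ncol(d$X)
  s2 <- rss / df
  R <- qr.R(qrX)
  ll_direct <- -0.5 * (df * log(2 * pi * s2) + df +
                         2 * sum(log(abs(diag(R)))))
  expect_equal(ll0, ll_direct)
  # permute rows within subjects
  perm <- unlist(lapply(split(seq_along(d$subj), d$subj), sample))
  expect_equal(reml_loglik(0.7, d$X, d$y, d$subj),
               reml_loglik(0.7, d$X[perm, ], d$y[perm], d$subj[perm]))
  expect_error(reml_loglik(-0.1, d$X, d$y, d$subj), "theta")
})

test_that("balanced intercept-only REML matches the ANOVA closed form", {
  set.seed(32)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    m <- sample(c(8, 15, 30), 1)
    b <- rnorm(m, sd = runif(1, 1, 3))
    y <- rep(b, each = k) + rnorm(m * k, sd = 1) + 5
    subj <- rep(seq_len(m), each = k)
    fit <- fit_lmm_reml(matrix(1, m * k, 1), y, subj)
    msb <- k * var(tapply(y, subj, mean))
    msw <- mean(tapply(y, subj, var))
    theta_anova <- (msb - msw) / (k * msw)
    if (theta_anova > 0.01) {
      expect_equal(fit$theta, theta_anova, tolerance = 1e-6)
    } else {
      expect_lt(fit$theta, max(theta_anova, 0) + 1e-4)
    }
  }
})

test_that("singleton-only subjects reduce exactly to OLS with a warning", {
  set.seed(33)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
  expect_warning(fit <- fit_lmm_reml(X, y, seq_len(n)), "unidentifiable")
  ols <- lm(y ~ X - 1)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-10)
})

test_that("near-zero noise recovers the coefficients almost exactly", {
  set.seed(34)
  subj <- rep(1:20, each = 2)
  n <- length(subj)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(3, -1.5)) + rnorm(n, sd = 1e-7)
  fit <- fit_lmm_reml(X, y, subj)
  expect_lt(max(abs(coef(fit) - c(3, -1.5))), 1e-6)
})

test_that("GLS on a tiny 2-subject dataset matches the closed form", {
  # 4 rows, 2 subjects; compare against direct matrix GLS at the
  # REML-optimal theta
  X <- cbind(1, c(0, 1, 0, 1))
  y <- c(1, 2, 4, 3.5)
  subj <- c("a", "a", "b", "b")
  fit <- fit_lmm_reml(X, y, subj)
  V <- diag(4)
  V[1:2, 1:2] <- V[1:2, 1:2] + fit$theta
  V[3:4, 3:4] <- V[3:4, 3:4] + fit$theta
  diag(V) <- 1 + fit$theta
  W <- solve(V)
  beta_gls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(coef(fit)), drop(beta_gls), tolerance = 1e-8)
  se_gls <- sqrt(diag(solve(t(X) %*% W %*% X)) * fit$sigma2)
  expect_equal(unname(fit$se), se_gls, tolerance = 1e-8)
})

test_that("estimates agree with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  set.seed(35)
  n <- 160
  subj <- sample(1:45, n, replace = TRUE)
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(45, sd = 3)[subj] +
    rnorm(n, sd = 2)
  fit <- fit_lmm_reml(X, y, subj)
  lf <- lme4::lmer(y ~ X[, 2] + X[, 3] + (1 | subj), REML = TRUE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(coef(summary(lf))[, "Std. Error"]), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma_b2, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
})

test_that("profile optimum is a local minimum of the negative likelihood", {
  set.seed(36)
  d <- sim_ri(25, 3, sigma_b = 2, sigma = 1)
  fit <- fit_lmm_reml(d$X, d$y, d$subj)
  if (fit$theta > 1e-4) {
    eps <- max(1e-5, fit$theta * 1e-4)
    ll <- function(th) reml_loglik(th, d$X, d$y, d$subj)
    expect_gte(ll(fit$theta) + 1e-9, ll(fit$theta - eps))
    expect_gte(ll(fit$theta) + 1e-9, ll(fit$theta + eps))
  }
})

test_that("Wald table has the documented shape and symmetries", {
  set.seed(37)
  d <- sim_ri(20, 2)
  fit <- fit_lmm_reml(d$X, d$y, d$subj)
  tab <- wald_tests(fit)
  expect_identical(names(tab), c("term", "effect_size", "se", "t", "p"))
  expect_equal(nrow(tab), ncol(d$X))
  # p symmetric in the sign of the estimate
  expect_equal(2 * pt(-abs(tab$t), fit$df), tab$p)
  # flipped response flips effect sizes, keeps p
  fit2 <- fit_lmm_reml(d$X, -d$y, d$subj)
  expect_equal(coef(fit2), -coef(fit), tolerance = 1e-8)
  expect_equal(fit2$p, fit$p, tolerance = 1e-8)
})

test_that("relmm formula interface and methods work end to end", {
  coh <- tiny_cohort(50, seed = 43)
  fit <- relmm(msel_composite ~ sex + batch_year, coh,
               subject = "subject_id")
  expect_s3_class(fit, "relmm")
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  pr <- predict(fit, include_ranef = TRUE)
  expect_equal(length(pr), fit$n_obs)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_obs, 3L))
  expect_output(print(summary(fit)), "Wald tests")
  cond <- residuals(fit, type = "conditional")
  expect_lt(sd(cond), sd(residuals(fit)) + 1e-8)
})

test_that("Wald 95% intervals hold nominal coverage on simulated cohorts", {
  set.seed(38)
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    subj <- rep(1:40, times = sample(1:3, 40, replace = TRUE))
    n <- length(subj)
    X <- cbind(1, rnorm(n))
    y <- 1 + 0.8 * X[, 2] + rnorm(40, sd = 2)[subj] + rnorm(n, sd = 1.5)
    fit <- fit_lmm_reml(X, y, subj)
    ci <- coef(fit)[2] + c(-1, 1) * qt(0.975, fit$df) * fit$se[2]
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) hits <- hits + 1L
  }
  coverage <- hits / reps
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("a singular fixed-effects design is reported, not silently fit", {
  set.seed(39)
  subj <- rep(1:10, each = 2)
  x <- rnorm(20)
  X <- cbind(1, x, 2 * x)  # exactly collinear
  expect_error(fit_lmm_reml(X, rnorm(20), subj), "singular")
})
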