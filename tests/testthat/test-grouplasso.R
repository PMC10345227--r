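test_that("penalty at or above lambda_max yields the null penalized model", {
  set.seed(21)
  pb <- random_gl_problem(n = 60, n_groups = 6)
  lmax <- lambda_max(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen)
  fit <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                         lambda = lmax * 1.0001)
  pen_cols <- setdiff(seq_len(ncol(pb$X)), seq_len(pb$n_unpen))
  expect_true(all(fit$latent_coef[pen_cols] == 0))
  expect_false(any(fit$selected))
  expect_true(all(kkt_residuals(fit, pb$X, pb$y) <= 1e-6))
})

test_that("lambda = 0 reproduces least squares on a full-rank design", {
  set.seed(22)
  pb <- random_gl_problem(n = 80, n_groups = 4)
  fit <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                         lambda = 0, kkt_tol = 1e-9)
  ols <- qr.coef(qr(pb$X), pb$y)
  expect_lt(max(abs(fit$latent_coef - ols)), 1e-6)
})

test_that("objective matches a projected-subgradient oracle", {
  set.seed(23)
  # small 30 x 10 problem, 3 groups, lambda at half lambda_max
  sizes <- c(3, 3, 3)
  X <- cbind(1, matrix(rnorm(30 * 9), 30))
  groups <- split(1 + seq_len(9), rep(1:3, sizes))
  names(groups) <- NULL
  w <- sqrt(sizes)
  beta <- c(0.5, rnorm(3, sd = 2), numeric(6))
  y <- drop(X %*% beta) + rnorm(30, sd = 0.5)
  lmax <- lambda_max(X, y, groups, w, 1L)
  lam <- 0.5 * lmax
  fit <- fit_group_lasso(X, y, groups, w, 1L, lambda = lam)
  oracle <- subgrad_group_lasso(X, y, groups, w, 1L, lam, iters = 4e4)
  expect_lt(abs(fit$objective - oracle$objective) /
              max(1, abs(oracle$objective)), 1e-5)
  expect_lte(fit$objective, oracle$objective + 1e-10)
})

test_that("KKT gaps are tight on random problems and detect perturbation", {
  set.seed(24)
  for (i in 1:25) {
    pb <- random_gl_problem(n = sample(30:120, 1),
                            n_groups = sample(2:12, 1))
    lmax <- lambda_max(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen)
    fit <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                           lambda = runif(1, 0.05, 0.9) * lmax)
    expect_true(fit$converged)
    expect_lte(max(kkt_residuals(fit, pb$X, pb$y)), 1e-6)
  }
  # perturbing an active coefficient opens its group's gap
  pb <- random_gl_problem(n = 60, n_groups = 5)
  lmax <- lambda_max(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen)
  fit <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                         lambda = 0.2 * lmax)
  act <- which(fit$selected)[1]
  expect_false(is.na(act))
  fit2 <- fit
  fit2$latent_coef[fit$expanded_groups[[act]][1]] <-
    fit2$latent_coef[fit$expanded_groups[[act]][1]] + 0.1
  expect_gt(kkt_residuals(fit2, pb$X, pb$y)[act], 1e-4)
})

test_that("lambda path is decreasing and starts at the null model", {
  set.seed(25)
  pb <- random_gl_problem(n = 50, n_groups = 5)
  lam <- lambda_path(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                     n_lambdas = 20, lambda_min_ratio = 0.01)
  expect_length(lam, 20)
  expect_true(all(diff(lam) < 0))
  fit <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                         lambda = lam[1])
  expect_false(any(fit$selected))
  # orthonormal 4 x 2 design: lambda_max = max correlation / n
  Xo <- cbind(c(1, 1, -1, -1) / 2, c(1, -1, 1, -1) / 2)
  yo <- c(2, 1, 0.5, -1)
  expect_equal(lambda_max(Xo, yo, list(1L, 2L), c(1, 1), 0L),
               max(abs(crossprod(Xo, yo))) / 4)
})

test_that("warm-started path matches cold starts to 1e-6 in objective", {
  set.seed(26)
  pb <- random_gl_problem(n = 60, n_groups = 8)
  lam <- lambda_path(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                     n_lambdas = 12, lambda_min_ratio = 0.05)
  warm <- hmotriad:::solve_path(pb$X, pb$y, pb$groups, pb$weights,
                                pb$n_unpen, lam, 1e-10, 1e-6, 50000)
  for (j in c(3, 7, 12)) {
    cold <- fit_group_lasso(pb$X, pb$y, pb$groups, pb$weights, pb$n_unpen,
                            lambda = lam[j])
    expect_lt(abs(warm$objective[j] - cold$objective) /
                max(1, abs(cold$objective)), 1e-6)
  }
})

test_that("subject-level CV keeps subjects together and selects signal", {
  set.seed(27)
  # 40 subjects x 2 visits, one strong group, little noise
  n_subj <- 40
  subj <- rep(seq_len(n_subj), each = 2)
  n <- length(subj)
  X <- cbind(1, matrix(rnorm(n * 6), n))
  groups <- list(2:3, 4:5, 6:7)
  y <- drop(X[, 2:3] %*% c(3, -2)) + rnorm(n, sd = 0.1)
  sel <- cv_select(X, y, groups, sqrt(c(2, 2, 2)), 1L, subj, k = 10,
                   n_lambdas = 30, lambda_min_ratio = 0.01)
  expect_true(sel$selected[1])
  # leave-one-subject-out boundary runs
  sel2 <- cv_select(X, y, groups, sqrt(c(2, 2, 2)), 1L, subj, k = n_subj,
                    n_lambdas = 10, lambda_min_ratio = 0.05)
  expect_true(sel2$selected[1])
  expect_error(cv_select(X, y, groups, sqrt(c(2, 2, 2)), 1L, subj,
                         k = n_subj + 1), "fewer subjects")
  # folds partition subjects: all rows of a subject share a fold
  folds <- hmotriad:::subject_folds(subj, 10)
  expect_true(all(tapply(folds, subj, function(f) length(unique(f))) == 1))
})

test_that("stability selection frequencies and fallback rule behave", {
  set.seed(28)
  n_subj <- 30
  subj <- rep(seq_len(n_subj), each = 2)
  n <- length(subj)
  X <- cbind(1, matrix(rnorm(n * 6), n))
  groups <- list(2:3, 4:5, 6:7)
  roles <- c("hmo_main", "mb_main", "interaction")

  # reps = 1: frequencies are 0/1 and the final set is that repetition's
  y1 <- drop(X[, 6:7] %*% c(3, 3)) + rnorm(n, sd = 0.1)
  st1 <- stability_select(X, y1, groups, sqrt(c(2, 2, 2)), 1L, subj,
                          group_roles = roles, reps = 1, k = 5,
                          n_lambdas = 20, lambda_min_ratio = 0.01)
  expect_true(all(st1$frequency %in% c(0, 1)))
  expect_true(st1$selected[3])
  expect_false(st1$fallback_used)

  # pure noise: fallback to all mains
  ynoise <- rnorm(n)
  stn <- stability_select(X, ynoise, groups, sqrt(c(2, 2, 2)), 1L, subj,
                          group_roles = roles, reps = 5, k = 5,
                          n_lambdas = 20, lambda_min_ratio = 0.05)
  if (stn$fallback_used) {
    expect_identical(stn$selected, roles %in% c("hmo_main", "mb_main"))
  }
  expect_true(all(stn$frequency >= 0 & stn$frequency <= 1))
})
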