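# Sufficient statistics for the profiled random-intercept REML criterion:
# everything needed to evaluate the restricted likelihood at any theta in
# O(n_subjects * p^2).
lmm_suffstats <- function(X, y, subject_ids) {
  subj <- factor(subject_ids, levels = unique(subject_ids))
  idx <- split(seq_along(y), subj)
  S <- vapply(idx, function(ix) colSums(X[ix, , drop = FALSE]), # block colsums
              numeric(ncol(X)))
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       S = S, t = vapply(idx, function(ix) sum(y[ix]), numeric(1)),
       ni = lengths(idx), n = length(y), p = ncol(X), idx = idx)
}

# Profiled REML pieces at variance ratio theta = sigma_b^2 / sigma^2.
# V_i = I + theta * J has inverse I - (theta / (1 + n_i theta)) * J and
# log-determinant log(1 + n_i theta), so all quantities reduce to rank-one
# downdates of the OLS cross-products.
lmm_profile <- function(ss, theta) {
  ci <- theta / (1 + ss$ni * theta)
  XtWX <- ss$XtX
  XtWy <- ss$Xty
  yWy <- ss$yty
  for (i in seq_along(ss$ni)) {
    if (ci[i] == 0) next
    XtWX <- XtWX - ci[i] * tcrossprod(ss$S[, i])
    XtWy <- XtWy - ci[i] * ss$S[, i] * ss$t[i]
    yWy <- yWy - ci[i] * ss$t[i]^2
  }
  ch <- tryCatch(chol(XtWX), error = function(e) {
    stop("singular weighted cross-product X'V^{-1}X; ",
         "drop collinear columns", call. = FALSE)
  })
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  rss <- max(yWy - sum(beta * XtWy), 0)
  df <- ss$n - ss$p
  sigma2 <- rss / df
  logdet_V <- sum(log1p(ss$ni * theta))
  logdet_XtWX <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (df * log(2 * pi * sigma2) + df + logdet_V + logdet_XtWX)
  list(beta = beta, sigma2 = sigma2, loglik = ll, chol = ch,
       XtWy = XtWy, rss = rss)
}

#' Restricted log-likelihood of the random-intercept model
#'
#' Evaluates the REML criterion, profiled over the residual variance and
#' the fixed effects, at a given variance ratio `theta = sigma_b^2 /
#' sigma^2`. Computation is blockwise per subject using the closed-form
#' inverse of `I + theta * 11'`.
#'
#' @param theta non-negative variance ratio.
#' @param X fixed-effects design matrix (including the intercept).
#' @param y response vector.
#' @param subject_ids per-row subject identifiers.
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(theta, X, y, subject_ids) {
  if (theta < 0) stop("theta must be >= 0")
  lmm_profile(lmm_suffstats(as.matrix(X), y, subject_ids), theta)$loglik
}

#' Fit the random-intercept linear mixed model by REML
#'
#' Estimates the variance ratio `theta = sigma_b^2 / sigma^2` by scalar
#' maximisation of the profiled restricted likelihood on `[0, 1000]`
#' (tolerance 1e-10; the boundary `theta = 0` is permitted), then computes
#' the generalised-least-squares fixed effects, their standard errors, and
#' two-sided Wald t-tests with `df = n_obs - p_fixed` degrees of freedom.
#' If every subject contributes a single row the ratio is unidentifiable:
#' a warning is issued and the fit reduces exactly to ordinary least
#' squares (`theta = 0`).
#'
#' @inheritParams reml_loglik
#' @return object of class `relmm`; see [relmm()] for the methods.
#' @export
fit_lmm_reml <- function(X, y, subject_ids) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (length(unique(subject_ids)) < 2L) {
    stop("need at least 2 subjects")
  }
  ss <- lmm_suffstats(X, y, subject_ids)
  if (all(ss$ni == 1L)) {
    warning("all subjects have a single observation; ",
            "random-intercept variance is unidentifiable, fitting theta = 0")
    theta <- 0
  } else {
    negll <- function(th) -lmm_profile(ss, th)$loglik
    opt <- optimize(negll, interval = c(0, 1000), tol = 1e-8)
    # polish on a narrow bracket; the wide interval limits Brent's accuracy
    lo <- max(0, opt$minimum * (1 - 1e-3))
    hi <- opt$minimum * (1 + 1e-3) + 1e-8
    opt2 <- optimize(negll, interval = c(lo, hi), tol = 1e-12)
    best <- if (opt2$objective < opt$objective) opt2 else opt
    theta <- if (negll(0) <= best$objective) 0 else best$minimum
  }
  prof <- lmm_profile(ss, theta)
  cov_unscaled <- chol2inv(prof$chol)
  se <- sqrt(pmax(diag(cov_unscaled) * prof$sigma2, 0))
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  tstat <- ifelse(se > 0, beta / se, NA_real_)
  df <- ss$n - ss$p
  pval <- 2 * pt(-abs(tstat), df = df)

  fitted_fixed <- drop(X %*% beta)
  resid_marg <- y - fitted_fixed
  # Empirical BLUPs of the subject intercepts.
  t_r <- vapply(ss$idx, function(ix) sum(resid_marg[ix]), numeric(1))
  blup <- theta * t_r / (1 + ss$ni * theta)

  structure(list(
    coefficients = beta, se = setNames(se, colnames(X)),
    t = setNames(tstat, colnames(X)), p = setNames(pval, colnames(X)),
    theta = theta, sigma2 = prof$sigma2, sigma_b2 = theta * prof$sigma2,
    reml_loglik = prof$loglik, df = df, n_obs = ss$n,
    n_subjects = length(ss$ni),
    vcov = cov_unscaled * prof$sigma2,
    fitted = fitted_fixed, residuals = resid_marg,
    ranef = setNames(blup, names(ss$idx)),
    X = X, y = y, subject_ids = subject_ids
  ), class = "relmm")
}

#' Random-intercept linear mixed model (formula interface)
#'
#' Fits `y = X beta + b_subject + eps` with `b_subject ~ N(0, sigma_b^2)`
#' and `eps ~ N(0, sigma^2)` by restricted maximum likelihood; the
#' within-subject dependence of repeated visits is captured by the random
#' intercept. This is the regression stage of the two-step analysis: the
#' fixed effects on standardized predictors are the reported effect sizes.
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame holding the variables.
#' @param subject bare column name or character name of the subject
#'   identifier in `data`.
#' @return object of class `relmm` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `residuals`, `fitted`, `simulate` and
#'   [wald_tests()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 2))
#' fit <- relmm(msel_composite ~ sex + batch_year, coh, subject = subject_id)
#' summary(fit)
#' @export
relmm <- function(formula, data, subject) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  sub_expr <- substitute(subject)
  subject_name <- tryCatch({
    v <- eval(sub_expr, parent.frame())
    if (is.character(v) && length(v) == 1L) v else deparse(sub_expr)
  }, error = function(e) deparse(sub_expr))
  if (!subject_name %in% names(data)) {
    stop("subject column '", subject_name, "' not found in data")
  }
  rows <- match(rownames(mf), rownames(data))
  fit <- fit_lmm_reml(X, y, data[[subject_name]][rows])
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' Wald test table of a fitted random-intercept model
#'
#' @param fit a `relmm` object.
#' @param roles optional named character vector mapping terms to roles
#'   (`covariate`, `hmo_main`, ...), carried into the output.
#' @return data frame with columns `term`, `effect_size`, `se`, `t`, `p`
#'   (and `role` when provided).
#' @export
wald_tests <- function(fit, roles = NULL) {
  out <- data.frame(term = names(coef(fit)),
                    effect_size = unname(coef(fit)),
                    se = unname(fit$se), t = unname(fit$t),
                    p = unname(fit$p), stringsAsFactors = FALSE)
  if (!is.null(roles)) out$role <- unname(roles[out$term])
  out
}

#' @export
coef.relmm <- function(object, ...) object$coefficients

#' @export
vcov.relmm <- function(object, ...) object$vcov

#' @export
fitted.relmm <- function(object, ...) object$fitted

#' @export
residuals.relmm <- function(object, type = c("marginal", "conditional"),
                            ...) {
  type <- match.arg(type)
  if (type == "marginal") return(object$residuals)
  object$residuals - object$ranef[as.character(object$subject_ids)]
}

#' @export
predict.relmm <- function(object, newX = NULL, subject_ids = NULL,
                          include_ranef = FALSE, ...) {
  X <- if (is.null(newX)) object$X else as.matrix(newX)
  pred <- drop(X %*% coef(object))
  if (include_ranef) {
    ids <- as.character(subject_ids %||% object$subject_ids)
    b <- object$ranef[ids]
    b[is.na(b)] <- 0  # unseen subjects predict at the population level
    pred <- pred + unname(b)
  }
  pred
}

#' @export
simulate.relmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ids <- factor(object$subject_ids, levels = unique(object$subject_ids))
  out <- replicate(nsim, {
    b <- rnorm(nlevels(ids), sd = sqrt(object$sigma_b2))
    object$fitted + b[as.integer(ids)] +
      rnorm(object$n_obs, sd = sqrt(object$sigma2))
  })
  as.data.frame(out)
}

#' @export
print.relmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  if (!is.null(x$call)) cat("Call:", deparse(x$call), "\n")
  cat(sprintf("  %d observations, %d subjects; df = %d\n",
              x$n_obs, x$n_subjects, x$df))
  cat(sprintf("  sigma_b = %.3f, sigma = %.3f (theta = %.4g)\n",
              sqrt(x$sigma_b2), sqrt(x$sigma2), x$theta))
  cat("Fixed effects:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.relmm <- function(object, ...) {
  structure(list(fit = object, table = wald_tests(object)),
            class = "summary.relmm")
}

#' @export
print.summary.relmm <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests (df =", x$fit$df, "):\n")
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("\nREML log-likelihood: %.3f\n", x$fit$reml_loglik))
  invisible(x)
}

#' @export
plot.relmm <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals,
                 xlab = "Fitted (fixed effects)",
                 ylab = "Marginal residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
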