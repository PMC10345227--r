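#' Fit the overlapping group LASSO at one penalty value
#'
#' Minimises `(1/2n) ||y - X w||^2 + lambda * sum_g w_g ||v_g||_2` on the
#' latent expanded design, where the leading `n_unpenalized` columns carry
#' no penalty and the remaining columns partition into disjoint groups.
#' The solver is a monotone accelerated proximal gradient method (group
#' soft-thresholding, backtracking line search) restricted to the active
#' group set, with full Karush-Kuhn-Tucker screening passes; it stops when
#' the relative objective change falls below `tol` and the KKT optimality
#' gap is below `kkt_tol`, or at `max_iter` iterations (then a warning is
#' issued and `converged` is `FALSE`).
#'
#' @param X_expanded expanded design matrix (see [expand_design()]).
#' @param y response vector.
#' @param expanded_groups list of column index vectors, one per penalized
#'   group (disjoint, covering all columns after the unpenalized block).
#' @param weights per-group penalty weights (default `sqrt(group size)`).
#' @param n_unpenalized number of leading unpenalized columns.
#' @param lambda penalty value (>= 0).
#' @param tol relative objective-change tolerance.
#' @param kkt_tol KKT optimality tolerance.
#' @param max_iter iteration cap.
#' @param init optional warm-start coefficient vector.
#' @return object of class `gl_fit` with `latent_coef`, `lambda`,
#'   `objective`, `kkt_gap`, `iterations`, `converged`, `selected`
#'   (logical per group), and the call inputs needed by [kkt_residuals()].
#' @export
fit_group_lasso <- function(X_expanded, y, expanded_groups,
                            weights = sqrt(lengths(expanded_groups)),
                            n_unpenalized = 0L, lambda,
                            tol = 1e-10, kkt_tol = 1e-6,
                            max_iter = 50000L, init = NULL) {
  stopifnot(nrow(X_expanded) == length(y), lambda >= 0)
  res <- gl_path_cpp(X_expanded, y, expanded_groups, weights,
                     as.integer(n_unpenalized), lambda, tol, kkt_tol,
                     as.integer(max_iter), init)
  v <- drop(res$coef)
  selected <- vapply(expanded_groups,
                     function(ix) sqrt(sum(v[ix]^2)) > 0, logical(1))
  if (!res$converged[1]) {
    warning(sprintf(
      "group LASSO did not reach KKT tolerance %g (gap %.3g) in %d iterations",
      kkt_tol, res$kkt_gap[1], res$iterations[1]))
  }
  structure(list(
    latent_coef = v, lambda = lambda, objective = res$objective[1],
    kkt_gap = res$kkt_gap[1], iterations = res$iterations[1],
    converged = res$converged[1], selected = selected,
    expanded_groups = expanded_groups, weights = weights,
    n_unpenalized = n_unpenalized
  ), class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  cat(sprintf(
    "Overlapping group LASSO fit: lambda = %.4g, %d/%d groups active,\n",
    x$lambda, sum(x$selected), length(x$selected)))
  cat(sprintf("  objective %.6g, KKT gap %.2e, %d iterations (%s)\n",
              x$objective, x$kkt_gap, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-group KKT optimality gaps of a group LASSO fit
#'
#' For active groups the gap is `||X_g' r / n - lambda * w_g * v_g /
#' ||v_g|| ||_2`; for inactive groups it is `max(0, ||X_g' r / n||_2 -
#' lambda * w_g)`. At an exact solution all gaps are zero.
#'
#' @param fit a [fit_group_lasso()] object.
#' @param X_expanded,y the data the fit was computed on.
#' @return numeric vector, one gap per penalized group.
#' @export
kkt_residuals <- function(fit, X_expanded, y) {
  n <- length(y)
  r <- y - drop(X_expanded %*% fit$latent_coef)
  g_all <- drop(crossprod(X_expanded, r)) / n
  vapply(seq_along(fit$expanded_groups), function(g) {
    ix <- fit$expanded_groups[[g]]
    vg <- fit$latent_coef[ix]
    nrm <- sqrt(sum(vg^2))
    if (nrm > 0) {
      sqrt(sum((g_all[ix] - fit$lambda * fit$weights[g] * vg / nrm)^2))
    } else {
      max(0, sqrt(sum(g_all[ix]^2)) - fit$lambda * fit$weights[g])
    }
  }, numeric(1))
}

#' Smallest penalty that zeroes every penalized group
#'
#' `lambda_max = max_g ||X_g' r0||_2 / (n * w_g)` where `r0` is the
#' residual of the unpenalized-columns-only least squares fit.
#'
#' @inheritParams fit_group_lasso
#' @return scalar `lambda_max`.
#' @export
lambda_max <- function(X_expanded, y, expanded_groups,
                       weights = sqrt(lengths(expanded_groups)),
                       n_unpenalized = 0L) {
  n <- length(y)
  r0 <- if (n_unpenalized > 0) {
    Xu <- X_expanded[, seq_len(n_unpenalized), drop = FALSE]
    y - drop(Xu %*% qr.coef(qr(Xu), y))
  } else y
  g <- drop(crossprod(X_expanded, r0)) / n
  max(vapply(seq_along(expanded_groups), function(gi) {
    sqrt(sum(g[expanded_groups[[gi]]]^2)) / weights[gi]
  }, numeric(1)))
}

#' Log-spaced penalty path
#'
#' @inheritParams fit_group_lasso
#' @param n_lambdas grid size (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return strictly decreasing numeric vector from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @export
lambda_path <- function(X_expanded, y, expanded_groups,
                        weights = sqrt(lengths(expanded_groups)),
                        n_unpenalized = 0L, n_lambdas = 100L,
                        lambda_min_ratio = 0.001) {
  lmax <- lambda_max(X_expanded, y, expanded_groups, weights, n_unpenalized)
  if (!is.finite(lmax) || lmax <= 0) {
    stop("degenerate design: lambda_max is not positive")
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambdas))
}

solve_path <- function(X_expanded, y, expanded_groups, weights,
                       n_unpenalized, lambdas, tol, kkt_tol, max_iter) {
  gl_path_cpp(X_expanded, y, expanded_groups, weights,
              as.integer(n_unpenalized), lambdas, tol, kkt_tol,
              as.integer(max_iter), NULL)
}

# Assign subjects (not rows) to k cross-validation folds.
subject_folds <- function(subject_ids, k) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k) {
    stop(sprintf("fewer subjects (%d) than folds (%d)",
                 length(subjects), k))
  }
  fold_of <- setNames(sample(rep_len(seq_len(k), length(subjects))),
                      sample(subjects))
  unname(fold_of[as.character(subject_ids)])
}

#' Choose the penalty by subject-level cross-validation
#'
#' Folds partition subjects, so all visits of a subject share a fold
#' (row-level folds would leak repeated measures). The penalty minimising
#' the mean held-out squared prediction error over a log-spaced path is
#' selected and the groups active in the full-data fit at that penalty are
#' returned.
#'
#' @inheritParams fit_group_lasso
#' @param subject_ids per-row subject identifiers.
#' @param k number of folds (default 10; at most the number of subjects).
#' @param n_lambdas,lambda_min_ratio path settings, see [lambda_path()].
#' @param cv_tol,cv_kkt_tol looser tolerances used for the fold fits; the
#'   final full-data fit uses `tol`/`kkt_tol`.
#' @return list with `lambda` (the selected value), `selected` (logical per
#'   group), `cv_error` (mean held-out MSE per path point), `lambdas`,
#'   `fit` (the full-data [fit_group_lasso()] at the selected penalty).
#' @export
cv_select <- function(X_expanded, y, expanded_groups,
                      weights = sqrt(lengths(expanded_groups)),
                      n_unpenalized = 0L, subject_ids, k = 10L,
                      n_lambdas = 100L, lambda_min_ratio = 0.001,
                      tol = 1e-10, kkt_tol = 1e-6, max_iter = 50000L,
                      cv_tol = 1e-7, cv_kkt_tol = 1e-4) {
  lambdas <- lambda_path(X_expanded, y, expanded_groups, weights,
                         n_unpenalized, n_lambdas, lambda_min_ratio)
  folds <- subject_folds(subject_ids, k)
  err <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- folds != f
    path <- solve_path(X_expanded[tr, , drop = FALSE], y[tr],
                       expanded_groups, weights, n_unpenalized, lambdas,
                       cv_tol, cv_kkt_tol, max_iter)
    pred <- X_expanded[!tr, , drop = FALSE] %*% path$coef
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  mean_err <- colMeans(err)
  best <- which.min(mean_err)
  fit <- fit_group_lasso(X_expanded, y, expanded_groups, weights,
                         n_unpenalized, lambdas[best], tol, kkt_tol,
                         max_iter)
  list(lambda = lambdas[best], selected = fit$selected,
       cv_error = mean_err, lambdas = lambdas, fit = fit)
}

#' Stability selection over repeated cross-validation
#'
#' Repeats [cv_select()] with independent fold randomizations and records
#' per-group selection frequencies. The final selected set contains the
#' groups chosen in at least `freq_cutoff` of the repetitions. If that set
#' contains no interaction group the fallback rule applies: the final
#' model is all HMO main effects plus all retained species main effects
#' (`fallback_used = TRUE`).
#'
#' @inheritParams cv_select
#' @param group_roles character vector per group (`hmo_main`, `mb_main`,
#'   `interaction`) used for the fallback rule.
#' @param reps number of repetitions (default 200).
#' @param freq_cutoff frequency threshold defining the final set.
#' @return object of class `stability_result`: `frequency` (per group),
#'   `selected` (logical per group, after fallback), `fallback_used`,
#'   `lambdas` (chosen penalty per repetition), `reps`.
#' @export
stability_select <- function(X_expanded, y, expanded_groups,
                             weights = sqrt(lengths(expanded_groups)),
                             n_unpenalized = 0L, subject_ids,
                             group_roles, reps = 200L, k = 10L,
                             freq_cutoff = 0.5, n_lambdas = 100L,
                             lambda_min_ratio = 0.001, tol = 1e-10,
                             kkt_tol = 1e-6, max_iter = 50000L,
                             cv_tol = 1e-7, cv_kkt_tol = 1e-4) {
  stopifnot(reps >= 1, length(group_roles) == length(expanded_groups))
  counts <- numeric(length(expanded_groups))
  lambdas_used <- numeric(reps)
  for (r in seq_len(reps)) {
    sel <- cv_select(X_expanded, y, expanded_groups, weights, n_unpenalized,
                     subject_ids, k, n_lambdas, lambda_min_ratio,
                     tol, kkt_tol, max_iter, cv_tol, cv_kkt_tol)
    counts <- counts + sel$selected
    lambdas_used[r] <- sel$lambda
  }
  freq <- counts / reps
  selected <- freq >= freq_cutoff
  fallback <- !any(selected & group_roles == "interaction")
  if (fallback) {
    selected <- group_roles %in% c("hmo_main", "mb_main")
  }
  structure(list(frequency = freq, selected = selected,
                 fallback_used = fallback, lambdas = lambdas_used,
                 reps = reps, freq_cutoff = freq_cutoff,
                 group_roles = group_roles),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Stability selection over %d repetitions: %d group(s) at frequency >= %.2f%s\n",
    x$reps, sum(x$frequency >= x$freq_cutoff), x$freq_cutoff,
    if (x$fallback_used) " - fallback to all main effects" else ""))
  top <- order(x$frequency, decreasing = TRUE)[seq_len(min(5, length(x$frequency)))]
  for (i in top) {
    cat(sprintf("  %-28s %.2f\n", x$group_roles[i], x$frequency[i]))
  }
  invisible(x)
}
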