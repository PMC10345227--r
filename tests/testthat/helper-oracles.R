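# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Literal transcription of the double-MAD definition.
brute_double_mad <- function(x) {
  m <- median(x)
  left <- median(abs(x[x <= m] - m))
  right <- median(abs(x[x >= m] - m))
  sapply(x, function(v) {
    if (v == m) return(0)
    smad <- if (v < m) left else right
    if (smad == 0) Inf else abs(v - m) / smad
  })
}

# Long-run subgradient descent on the group LASSO objective, followed by a
# smooth polish (BFGS on the support found, which is differentiable away
# from zero). Slow but independent of the proximal solver; adequate on
# tiny problems.
subgrad_group_lasso <- function(X, y, groups, weights, n_unpen, lambda,
                                iters = 2e4) {
  n <- nrow(X)
  p <- ncol(X)
  w <- numeric(p)
  best <- Inf
  best_w <- w
  obj <- function(w) {
    pen <- sum(vapply(seq_along(groups), function(g) {
      weights[g] * sqrt(sum(w[groups[[g]]]^2))
    }, numeric(1)))
    sum((y - X %*% w)^2) / (2 * n) + lambda * pen
  }
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  for (it in seq_len(iters)) {
    r <- y - X %*% w
    gr <- -crossprod(X, r) / n
    for (g in seq_along(groups)) {
      ix <- groups[[g]]
      nrm <- sqrt(sum(w[ix]^2))
      if (nrm > 0) {
        gr[ix] <- gr[ix] + lambda * weights[g] * w[ix] / nrm
      } # at zero, pick the zero subgradient
    }
    w <- w - (1 / (L * sqrt(it))) * gr
    o <- obj(w)
    if (o < best) {
      best <- o
      best_w <- w
    }
  }
  # polish on candidate supports (groups above a norm threshold), where the
  # objective is smooth; keep the best result over thresholds
  for (thr in c(0, 1e-4, 1e-3, 1e-2)) {
    w <- best_w
    live <- logical(p)
    live[seq_len(n_unpen)] <- TRUE
    for (g in seq_along(groups)) {
      ix <- groups[[g]]
      if (sqrt(sum(w[ix]^2)) <= thr) w[ix] <- 0 else live[ix] <- TRUE
    }
    if (!any(live)) next
    fn <- function(wl) {
      wf <- numeric(p)
      wf[live] <- wl
      obj(wf)
    }
    pol <- optim(w[live], fn, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    if (pol$value < best) {
      best <- pol$value
      w_full <- numeric(p)
      w_full[live] <- pol$par
      best_w <- w_full
    }
  }
  list(w = best_w, objective = best)
}

# Random group LASSO problem with an expanded-group layout.
random_gl_problem <- function(n = 50, n_groups = 5, max_size = 3,
                              n_unpen = 1) {
  sizes <- sample(seq_len(max_size), n_groups, replace = TRUE)
  p <- n_unpen + sum(sizes)
  X <- cbind(matrix(1, n, n_unpen), matrix(rnorm(n * sum(sizes)), n))
  groups <- split(n_unpen + seq_len(sum(sizes)),
                  rep(seq_len(n_groups), sizes))
  names(groups) <- NULL
  beta <- numeric(p)
  live <- sample(n_groups, max(1, n_groups %/% 3))
  for (g in live) beta[groups[[g]]] <- rnorm(sizes[g], sd = 2)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, groups = groups, weights = sqrt(sizes),
       n_unpen = n_unpen)
}

# Small default cohort shared across tests (generation is deterministic).
tiny_cohort <- function(n_subjects = 60, seed = 101, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}

# Settings keeping selection-stage tests quick.
fast_lasso <- function(reps = 5) {
  lasso_control(reps = reps, n_lambdas = 25, lambda_min_ratio = 0.02,
                cv_tol = 1e-6, cv_kkt_tol = 1e-3)
}
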