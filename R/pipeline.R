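#' Control settings for the selection stage
#'
#' @param n_lambdas,lambda_min_ratio penalty path, see [lambda_path()].
#' @param k_folds cross-validation folds (subject-level).
#' @param reps stability-selection repetitions.
#' @param freq_cutoff selection-frequency threshold for the final set.
#' @param tol,kkt_tol,max_iter solver settings for final fits.
#' @param cv_tol,cv_kkt_tol looser solver settings for fold fits.
#' @return named list of class `lasso_control`.
#' @export
lasso_control <- function(n_lambdas = 100L, lambda_min_ratio = 0.001,
                          k_folds = 10L, reps = 200L, freq_cutoff = 0.5,
                          tol = 1e-10, kkt_tol = 1e-6, max_iter = 50000L,
                          cv_tol = 1e-7, cv_kkt_tol = 1e-4) {
  structure(list(n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 k_folds = as.integer(k_folds), reps = as.integer(reps),
                 freq_cutoff = freq_cutoff, tol = tol, kkt_tol = kkt_tol,
                 max_iter = as.integer(max_iter), cv_tol = cv_tol,
                 cv_kkt_tol = cv_kkt_tol),
            class = "lasso_control")
}

# md5 of a deterministic serialisation of an R object.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

fit_one_model <- function(prep, outcome, stratification, lasso) {
  spec <- model_spec(outcome, stratification, species = prep$species)
  design <- build_design(prep, spec)
  groups <- build_groups(design)
  expn <- expand_design(design, groups)

  stab <- stability_select(
    expn$X_expanded, design$y, expn$expanded_groups,
    weights = groups$weights, n_unpenalized = expn$n_unpenalized,
    subject_ids = design$subject_ids, group_roles = groups$group_roles,
    reps = lasso$reps, k = lasso$k_folds, freq_cutoff = lasso$freq_cutoff,
    n_lambdas = lasso$n_lambdas, lambda_min_ratio = lasso$lambda_min_ratio,
    tol = lasso$tol, kkt_tol = lasso$kkt_tol, max_iter = lasso$max_iter,
    cv_tol = lasso$cv_tol, cv_kkt_tol = lasso$cv_kkt_tol)

  # Final fixed-effect columns: everything unpenalized plus the union of
  # the selected groups' member columns (hierarchy holds by construction).
  sel_cols <- sort(unique(c(
    groups$unpenalized,
    unlist(lapply(which(stab$selected), function(g) {
      groups$latent_map[groups$groups[[g]]]
    }))
  )))
  X_final <- design$X[, sel_cols, drop = FALSE]
  fit <- fit_lmm_reml(X_final, design$y, design$subject_ids)

  # Selection frequency of the most supportive group per term.
  term_freq <- vapply(colnames(X_final), function(cl) {
    j <- match(cl, names(design$roles))
    gs <- which(vapply(groups$groups, function(g) {
      j %in% groups$latent_map[g]
    }, logical(1)))
    if (!length(gs)) NA_real_ else max(stab$frequency[gs])
  }, numeric(1))

  tab <- wald_tests(fit, roles = design$roles[colnames(X_final)])
  tab$selection_frequency <- unname(term_freq[tab$term])
  list(spec = spec, design_cols = colnames(design$X), table = tab,
       fit = fit, stability = stab,
       excluded_rows = design$excluded_rows)
}

#' Run the full triad association analysis
#'
#' Executes the two-step analysis for every requested outcome and
#' stratification: preprocessing, design construction, stability-selected
#' hierarchical group LASSO (with the all-main-effects fallback when no
#' interaction survives), then the random-intercept REML fit on the
#' adjusting covariates plus selected terms, with Wald tests. Failures in
#' one outcome/stratification are logged and do not abort the others.
#'
#' @param cohort a cohort data frame ([generate_cohort()] or
#'   [read_cohort()]).
#' @param outcomes subset of the six MSEL scores.
#' @param stratifications subset of `unstratified`, `atetra_pos`,
#'   `atetra_neg`.
#' @param preprocess a [preprocess_config()].
#' @param lasso a [lasso_control()].
#' @param seed integer; all fold randomisation derives from it.
#' @return object of class `triad_results` with `models` (one entry per
#'   outcome x stratification: Wald table, `relmm` fit, stability result),
#'   `errors` and `provenance`.
#' @export
run_triad_analysis <- function(cohort,
                               outcomes = MSEL_NAMES,
                               stratifications = STRATIFICATIONS,
                               preprocess = preprocess_config(),
                               lasso = lasso_control(),
                               seed = 1L) {
  stopifnot(all(outcomes %in% MSEL_NAMES),
            all(stratifications %in% STRATIFICATIONS))
  prep <- preprocess_cohort(cohort, preprocess)
  models <- list()
  errors <- list()
  with_seed(seed, {
    for (oc in outcomes) {
      for (st in stratifications) {
        nm <- paste(oc, st, sep = "__")
        res <- tryCatch(fit_one_model(prep, oc, st, lasso),
                        error = function(e) e)
        if (inherits(res, "error")) {
          errors[[nm]] <- conditionMessage(res)
          message(sprintf("run_triad_analysis: %s failed: %s", nm,
                          errors[[nm]]))
        } else {
          models[[nm]] <- res
        }
      }
    }
  })
  if (!length(models)) {
    stop("all outcome/stratification models failed")
  }
  structure(list(
    models = models, errors = errors,
    provenance = list(
      seed = seed,
      config_hash = config_hash(list(preprocess = unclass(preprocess),
                                     lasso = unclass(lasso),
                                     outcomes = outcomes,
                                     stratifications = stratifications)),
      package_version = as.character(packageVersion("hmotriad")),
      n_obs = nrow(cohort),
      n_subjects = length(unique(cohort$subject_id)),
      retained_species = prep$species,
      fallback_used = vapply(models, function(m) m$stability$fallback_used,
                             logical(1))
    )
  ), class = "triad_results")
}

#' @export
print.triad_results <- function(x, ...) {
  cat(sprintf("Triad association results: %d fitted model(s)\n",
              length(x$models)))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    nsig <- sum(m$table$p < 0.05 & m$table$role != "intercept", na.rm = TRUE)
    cat(sprintf("  %-42s %s, %d term(s) with p < 0.05\n", nm,
                if (m$stability$fallback_used) "fallback (mains)"
                else "interactions selected", nsig))
  }
  if (length(x$errors)) {
    cat("Failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Significance summary of a results bundle
#'
#' Tabulates every non-intercept term with `p < 0.05` across all fitted
#' models, with the sign of its effect size — the compact display used to
#' survey which HMOs, species and interactions associate with which MSEL
#' domain under which stratification.
#'
#' @param results a `triad_results` bundle.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default, mirroring raw-p reporting) or `"BH"`
#'   for a Benjamini-Hochberg correction applied within each model.
#' @return data frame: `outcome`, `stratification`, `term`, `role`,
#'   `effect_size`, `sign` (`"+"`/`"-"`), `se`, `p`,
#'   `selection_frequency`.
#' @export
make_report <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(names(results$models), function(nm) {
    m <- results$models[[nm]]
    tab <- m$table
    pv <- if (adjust == "BH") stats::p.adjust(tab$p, "BH") else tab$p
    tab <- tab[!is.na(pv) & pv < alpha &
                 !tab$role %in% c("intercept"), , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    data.frame(outcome = m$spec$outcome,
               stratification = m$spec$stratification,
               term = tab$term, role = tab$role,
               effect_size = tab$effect_size,
               sign = ifelse(tab$effect_size >= 0, "+", "-"),
               se = tab$se, p = tab$p,
               selection_frequency = tab$selection_frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(outcome = character(), stratification = character(),
                      term = character(), role = character(),
                      effect_size = numeric(), sign = character(),
                      se = numeric(), p = numeric(),
                      selection_frequency = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
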