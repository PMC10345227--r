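#' Per-stratum summary (n, mean, sample SD)
#'
#' @param values numeric vector.
#' @param strata stratum label per value (missing values are dropped
#'   pairwise).
#' @return data frame with one row per stratum: `stratum`, `n`, `mean`,
#'   `sd` (sample SD, `n - 1` denominator).
#' @export
group_summary <- function(values, strata) {
  if (length(values) != length(strata)) {
    stop("values and strata differ in length")
  }
  ok <- !is.na(values) & !is.na(strata)
  values <- values[ok]
  strata <- strata[ok]
  levs <- unique(strata)
  if (!length(levs)) stop("no non-missing observations")
  out <- do.call(rbind, lapply(levs, function(l) {
    v <- values[strata == l]
    if (!length(v)) stop("empty stratum: ", l)
    data.frame(stratum = l, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pool two summary statistics exactly
#'
#' Combines two `(n, mean, sd)` summaries into the summary of the
#' concatenated raw data: `mean = (n1 m1 + n2 m2) / n` and
#' `var = [(n1-1) s1^2 + (n2-1) s2^2 + n1 (m1-m)^2 + n2 (m2-m)^2] /
#' (n - 1)`. Reproduces a pooled "Total" column from per-stratum rows.
#'
#' @param n1,mean1,sd1 first group's summary.
#' @param n2,mean2,sd2 second group's summary.
#' @return list with `n`, `mean`, `sd`.
#' @examples
#' pooled_summary(61, 104.87, 11.62, 109, 106.91, 12.93)
#' @export
pooled_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  n <- n1 + n2
  if (n < 2) stop("pooled SD undefined for fewer than 2 observations")
  m <- (n1 * mean1 + n2 * mean2) / n
  v <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2 +
          n1 * (mean1 - m)^2 + n2 * (mean2 - m)^2) / (n - 1)
  list(n = n, mean = m, sd = sqrt(v))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from `(n, mean, sd)` per group:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @inheritParams pooled_summary
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) stop("zero variance in both groups with equal means")
    return(list(t = Inf * sign(mean1 - mean2), df = n1 + n2 - 2, p = 0))
  }
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df = df))
}

#' Pooled-variance (Student) t-test from summary statistics
#'
#' Equal-variance counterpart of [welch_t()]; kept for comparison of the
#' two conventions on printed tables.
#'
#' @inheritParams pooled_summary
#' @return list with `t`, `df`, `p`.
#' @export
student_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df = df))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param tab contingency table (matrix of counts).
#' @return list with `stat`, `df`, `p`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(stat = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Cohort description tables by A-tetra stratum
#'
#' Emits per-stratum and pooled `(n, mean, sd)` summaries with Welch
#' p-values for the MSEL scores and species relative abundances of a
#' cohort, mirroring the usual cohort-characteristics layout.
#'
#' @param cohort a cohort data frame.
#' @param lod A-tetra limit of detection (mg/L).
#' @return data frame with one row per variable: stratum summaries and the
#'   Welch p-value comparing A-tetra+ versus A-tetra-.
#' @export
cohort_table <- function(cohort, lod = 4.4) {
  strat <- atetra_status(cohort[[hmo_col("atetra")]], lod)
  vars <- c(setNames(msel_col(MSEL_NAMES), paste0("msel_", MSEL_NAMES)),
            setNames(grep("^ra_", names(cohort), value = TRUE),
                     grep("^ra_", names(cohort), value = TRUE)),
            age_months = "age_months")
  rows <- lapply(names(vars), function(nm) {
    v <- cohort[[vars[[nm]]]]
    gs <- group_summary(v, strat)
    pos <- gs[gs$stratum == "positive", ]
    neg <- gs[gs$stratum == "negative", ]
    if (!nrow(pos) || !nrow(neg)) {
      return(data.frame(variable = nm, n_total = sum(gs$n),
                        mean_total = mean(v, na.rm = TRUE),
                        sd_total = sd(v[!is.na(v)]),
                        n_pos = NA, mean_pos = NA, sd_pos = NA,
                        n_neg = NA, mean_neg = NA, sd_neg = NA,
                        p_welch = NA_real_))
    }
    tot <- pooled_summary(pos$n, pos$mean, pos$sd, neg$n, neg$mean, neg$sd)
    wt <- welch_t(pos$n, pos$mean, pos$sd, neg$n, neg$mean, neg$sd)
    data.frame(variable = nm, n_total = tot$n, mean_total = tot$mean,
               sd_total = tot$sd, n_pos = pos$n, mean_pos = pos$mean,
               sd_pos = pos$sd, n_neg = neg$n, mean_neg = neg$mean,
               sd_neg = neg$sd, p_welch = wt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
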