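#' Double-MAD outlier scores
#'
#' Outlier score for asymmetric distributions: separate median absolute
#' deviations are computed for the values at or below the median (left MAD)
#' and at or above it (right MAD), and each value is scored as its absolute
#' deviation from the median divided by the MAD of its own side. Values
#' equal to the median score 0. No 1.4826 consistency constant is applied:
#' the method thresholds raw MAD ratios.
#'
#' @param values numeric vector (missing values allowed, returned as `NA`
#'   scores); at least three non-missing values are required.
#' @return numeric vector of scores; `Inf` where a value deviates from the
#'   median but its side-MAD is zero.
#' @examples
#' double_mad_scores(c(10, 11, 11, 11, 12, 12, 12, 13, 13, 100))
#' @export
double_mad_scores <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  x <- values[ok]
  m <- median(x)
  left <- median(abs(x[x <= m] - m))
  right <- median(abs(x[x >= m] - m))
  dev <- abs(x - m)
  side_mad <- ifelse(x < m, left, right)
  sc <- ifelse(dev == 0, 0, ifelse(side_mad == 0, Inf, dev / side_mad))
  out <- rep(NA_real_, length(values))
  out[ok] <- sc
  out
}

side_mads <- function(x) {
  m <- median(x, na.rm = TRUE)
  c(median = m,
    left = median(abs(x[!is.na(x) & x <= m] - m)),
    right = median(abs(x[!is.na(x) & x >= m] - m)))
}

#' Flag (and optionally treat) double-MAD outliers
#'
#' @param values numeric vector.
#' @param threshold positive scalar; a value is flagged iff its double-MAD
#'   score strictly exceeds it (default 3).
#' @param policy what to do with flagged values: `"keep"` only flags,
#'   `"set_missing"` replaces them with `NA`, `"winsorize"` clips them to
#'   `median +/- threshold * side-MAD`.
#' @return list with `flag` (logical vector), `values` (treated vector),
#'   `median`, `left_mad`, `right_mad`.
#' @export
flag_outliers <- function(values, threshold = 3,
                          policy = c("set_missing", "winsorize", "keep")) {
  policy <- match.arg(policy)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive (use Inf to disable)")
  }
  sc <- double_mad_scores(values)
  flag <- !is.na(sc) & sc > threshold
  out <- values
  if (policy == "set_missing") {
    out[flag] <- NA_real_
  } else if (policy == "winsorize") {
    sm <- side_mads(values)
    lo <- sm[["median"]] - threshold * sm[["left"]]
    hi <- sm[["median"]] + threshold * sm[["right"]]
    out[flag] <- pmin(pmax(values[flag], lo), hi)
  }
  list(flag = flag, values = out, median = side_mads(values)[["median"]],
       left_mad = side_mads(values)[["left"]],
       right_mad = side_mads(values)[["right"]])
}

#' Prevalence filter for species columns
#'
#' Retains a species iff the sum of its relative abundance over all samples
#' is strictly greater than `sum_threshold` (default 1): species with
#' infinitesimal total abundance carry little information and inflate the
#' number of variables.
#'
#' @param abundance matrix or data frame of relative abundances in `[0, 1]`
#'   (rows = samples, columns = species).
#' @param sum_threshold non-negative scalar.
#' @return character vector of retained species names, input order kept.
#' @export
filter_species <- function(abundance, sum_threshold = 1) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) == 0L || ncol(abundance) == 0L) {
    stop("abundance table is empty")
  }
  if (any(abundance < 0 | abundance > 1, na.rm = TRUE)) {
    stop("abundances must lie in [0, 1]")
  }
  sums <- colSums(abundance, na.rm = TRUE)
  colnames(abundance)[sums > sum_threshold]
}

#' Standardize to mean 0, sample SD 1
#'
#' Location-scale transform computed over the non-missing entries (sample
#' SD, `n - 1` denominator); missing values stay missing.
#'
#' @param values numeric vector with at least two distinct non-missing
#'   values.
#' @return standardized numeric vector.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L || length(unique(values[ok])) < 2L) {
    stop("standardize needs at least 2 distinct non-missing values")
  }
  (values - mean(values[ok])) / sd(values[ok])
}

#' Regress out a linear age trend
#'
#' Returns the residuals of `values ~ 1 + age` fitted by least squares over
#' the non-missing pairs; the residuals are orthogonal to the intercept and
#' to age. Used to remove postpartum-age trends from predictor columns
#' before association analysis (MSEL outcomes are already age-normed
#' T-scores and are not residualized).
#'
#' @param values numeric vector.
#' @param ages numeric vector of the same length, not constant.
#' @return residual vector (missing where `values` or `ages` is missing).
#' @export
residualize_on_age <- function(values, ages) {
  if (length(values) != length(ages)) stop("values and ages differ in length")
  ok <- !is.na(values) & !is.na(ages)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(ages[ok])) < 2L) stop("ages are constant")
  fit <- lm.fit(cbind(1, ages[ok]), values[ok])
  out <- rep(NA_real_, length(values))
  out[ok] <- fit$residuals
  out
}

#' A-tetrasaccharide detectability of a milk sample
#'
#' @param atetra_mgL A-tetra concentration(s) in mg/L.
#' @param lod limit of detection in mg/L (default 4.4).
#' @return `"positive"` where the concentration strictly exceeds the limit
#'   of detection, else `"negative"`.
#' @export
atetra_status <- function(atetra_mgL, lod = 4.4) {
  if (any(is.na(atetra_mgL))) stop("A-tetra concentration is missing")
  ifelse(atetra_mgL > lod, "positive", "negative")
}

#' Maternal secretor classification from milk HMOs
#'
#' Two printed rules: the ratio rule calls a sample secretor iff
#' 2'-FL / 3-FL > 6.5827; the threshold rule calls it non-secretor iff
#' 2'-FL < 15 mg/L.
#'
#' @param fl2 2'-FL concentration (mg/L).
#' @param fl3 3-FL concentration (mg/L); required (and strictly positive)
#'   for the ratio rule.
#' @param rule `"ratio"` or `"threshold"`.
#' @return `"secretor"` or `"non_secretor"` per sample.
#' @export
classify_secretor <- function(fl2, fl3 = NULL,
                              rule = c("ratio", "threshold")) {
  rule <- match.arg(rule)
  if (any(is.na(fl2))) stop("2'-FL concentration is missing")
  if (rule == "ratio") {
    if (is.null(fl3) || any(is.na(fl3))) stop("ratio rule needs 3-FL")
    if (any(fl3 == 0)) stop("ratio rule undefined for 3-FL = 0")
    ifelse(fl2 / fl3 > 6.5827, "secretor", "non_secretor")
  } else {
    ifelse(fl2 < 15, "non_secretor", "secretor")
  }
}

#' Preprocessing configuration
#'
#' @param mad_threshold double-MAD flagging threshold (> 0).
#' @param species_sum_threshold prevalence filter threshold (total relative
#'   abundance over samples must strictly exceed it).
#' @param atetra_lod_mgL A-tetra limit of detection in mg/L.
#' @param residualize_age regress predictors on age before analysis?
#' @param outlier_policy treatment of flagged abundance values.
#' @param pseudo_log_scale abundances are scored for outliers on the
#'   pseudo-log scale `asinh(x / pseudo_log_scale)` — the scale on which
#'   these right-skewed compositions are routinely displayed and on which
#'   side-MADs are well defined for sub-dominant species; set `NULL` to
#'   score raw abundances.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(mad_threshold = 3,
                              species_sum_threshold = 1,
                              atetra_lod_mgL = 4.4,
                              residualize_age = TRUE,
                              outlier_policy = c("set_missing", "winsorize",
                                                 "keep"),
                              pseudo_log_scale = 1e-3) {
  if (mad_threshold <= 0) stop_config("mad_threshold", "must be > 0")
  if (atetra_lod_mgL <= 0) stop_config("atetra_lod_mgL", "must be > 0")
  if (!is.null(pseudo_log_scale) && pseudo_log_scale <= 0) {
    stop_config("pseudo_log_scale", "must be > 0 or NULL")
  }
  structure(list(mad_threshold = mad_threshold,
                 species_sum_threshold = species_sum_threshold,
                 atetra_lod_mgL = atetra_lod_mgL,
                 residualize_age = isTRUE(residualize_age),
                 outlier_policy = match.arg(outlier_policy),
                 pseudo_log_scale = pseudo_log_scale),
            class = "preprocess_config")
}

#' Preprocess a cohort for association analysis
#'
#' Runs the preparation pipeline on a cohort table: per-species double-MAD
#' outlier flagging on the pseudo-log abundance scale (policy-dependent
#' treatment), species prevalence
#' filtering, A-tetra stratification labels, then standardization of all
#' HMO and retained species columns over all included samples (a single
#' scale keeps effect sizes comparable across strata) and optional
#' residualization of those standardized columns on age.
#'
#' @param cohort a cohort data frame ([generate_cohort()]/[read_cohort()]).
#' @param config a [preprocess_config()].
#' @return list with `data` (the cohort), `z` (data frame of processed
#'   standardized predictor columns named by HMO/species), `species`
#'   (retained species), `atetra` (per-row `"positive"`/`"negative"`),
#'   `outliers` (per-species report, see [flag_outliers()]).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  sp_all <- attr(cohort, "species_names") %||%
    sub("^ra_", "", grep("^ra_", names(cohort), value = TRUE))
  sp_all <- setdiff(sp_all, "other")
  ra <- as.data.frame(cohort)[, species_col(sp_all), drop = FALSE]

  s <- config$pseudo_log_scale
  fwd <- if (is.null(s)) identity else function(x) asinh(x / s)
  inv <- if (is.null(s)) identity else function(x) sinh(x) * s
  outliers <- list()
  for (sp in sp_all) {
    raw <- ra[[species_col(sp)]]
    fl <- flag_outliers(fwd(raw), config$mad_threshold,
                        config$outlier_policy)
    v <- inv(fl$values)
    v[!fl$flag] <- raw[!fl$flag]  # untouched values stay bit-identical
    ra[[species_col(sp)]] <- v
    outliers[[sp]] <- fl
  }
  retained_cols <- filter_species(ra, config$species_sum_threshold)
  species <- sub("^ra_", "", retained_cols)

  z <- list()
  for (h in HMO_NAMES) z[[h]] <- cohort[[hmo_col(h)]]
  for (sp in species) z[[sp]] <- ra[[species_col(sp)]]
  z <- lapply(z, standardize)
  if (config$residualize_age) {
    z <- lapply(z, residualize_on_age, ages = cohort$age_months)
  }

  list(data = cohort,
       z = as.data.frame(z, check.names = FALSE),
       species = species,
       atetra = atetra_status(cohort[[hmo_col("atetra")]],
                              config$atetra_lod_mgL),
       outliers = outliers,
       config = config)
}
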