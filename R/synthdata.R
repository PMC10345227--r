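#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds and validates the parameter set used by [generate_cohort()]. The
#' defaults emulate a 105-dyad mother-infant cohort observed between 2.9 and
#' 12 months of age with roughly 170 visits in total, eight human milk
#' oligosaccharide (HMO) concentrations with age trends (3-FL, 3'-SL and
#' A-tetra rising; 2'-FL, 6'-SL, LNT, LNnT and LNFP-I falling), a sparse
#' Dirichlet gut microbiota dominated by *Bifidobacterium longum*,
#' *bifidum* and *breve*, and six Mullen Scales of Early Learning (MSEL)
#' T-score outcomes produced by a random-intercept linear model on the
#' standardized predictors.
#'
#' @param n_subjects number of mother-infant dyads.
#' @param p_singleton probability that a subject has exactly one visit.
#' @param max_visits maximum visits per subject (at least 1).
#' @param p_extra_visit for multi-visit subjects the visit count is
#'   `2 + Binomial(max_visits - 2, p_extra_visit)`; the default 2/9 gives an
#'   expected total of 170 visits under the other defaults.
#' @param age_range_months closed interval of attainable ages, within (0, 12].
#' @param p_atetra_mother probability that a mother produces milk with
#'   detectable A-tetrasaccharide (constant within mother).
#' @param hmo_params data frame with one row per HMO: `mean0` (expected
#'   concentration in mg/L at age 0), `slope` (per-month trend on the log
#'   scale), `sigma` (lognormal noise SD), `atetra_mult` (multiplicative
#'   group offset applied to A-tetra positive mothers).
#' @param mb_base named base composition (12 species plus `other`) summing
#'   to one; these are the expected relative abundances at the centre age.
#' @param mb_slopes named per-month slopes on the latent log Dirichlet
#'   weight; positive values make a species relatively more abundant with
#'   age.
#' @param mb_concentration total Dirichlet concentration; smaller values
#'   give more dispersed (sparser) compositions.
#' @param mb_shape_floor lower bound on the per-species gamma shape (see
#'   [simulate_microbiota()]).
#' @param true_beta named covariate coefficients (T-score units) applied to
#'   every outcome: `sex_male`, `delivery_vaginal`, `education_graduate`,
#'   `site_A`, `batch_2019`, `batch_2020`.
#' @param true_hmo_beta,true_mb_beta named coefficients on the standardized
#'   HMO and species columns (default all zero).
#' @param true_gamma named interaction coefficients; names are
#'   `"<hmo>:<species>"` pairs, e.g. `"lnt:bif_longum"`.
#' @param gamma_stratum stratum in which `true_gamma` acts: `"all"`
#'   (default), or `"atetra_pos"`/`"atetra_neg"` to emulate an
#'   interaction specific to one A-tetra group (the coefficient is zero
#'   for rows outside that stratum).
#' @param intercepts named outcome intercepts (composite defaults to 100,
#'   the subdomain T-scores to 50).
#' @param sigma_subject SD of the subject random intercept (T-score units).
#' @param sigma_resid residual SD (T-score units).
#' @param composite_mode `"independent"` simulates the composite as its own
#'   outcome; `"derived"` sets it to `100 + 2 * (mean of the four
#'   non-gross-motor subdomain scores - 50)`.
#' @param p_male,p_vaginal,p_graduate,p_site_a,batch_probs covariate
#'   marginals; `batch_probs` are the 2018/2019/2020 batch proportions.
#' @param seed integer seed making the cohort reproducible.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 105L,
                          p_singleton = 60 / 105,
                          max_visits = 4L,
                          p_extra_visit = 2 / 9,
                          age_range_months = c(2.9, 12),
                          p_atetra_mother = 36 / 105,
                          hmo_params = default_hmo_params(),
                          mb_base = default_mb_base(),
                          mb_slopes = default_mb_slopes(),
                          mb_concentration = 1.3,
                          mb_shape_floor = 0.35,
                          true_beta = default_true_beta(),
                          true_hmo_beta = NULL,
                          true_mb_beta = NULL,
                          true_gamma = NULL,
                          gamma_stratum = c("all", "atetra_pos",
                                            "atetra_neg"),
                          intercepts = NULL,
                          sigma_subject = 5,
                          sigma_resid = 7,
                          composite_mode = c("independent", "derived"),
                          p_male = 0.38,
                          p_vaginal = 0.79,
                          p_graduate = 0.61,
                          p_site_a = 0.5,
                          batch_probs = c(`2018` = 0.25, `2019` = 0.45,
                                          `2020` = 0.30),
                          seed = 1L) {
  composite_mode <- match.arg(composite_mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects), p_singleton = p_singleton,
    max_visits = as.integer(max_visits), p_extra_visit = p_extra_visit,
    age_range_months = as.numeric(age_range_months),
    p_atetra_mother = p_atetra_mother,
    hmo_params = hmo_params, mb_base = mb_base, mb_slopes = mb_slopes,
    mb_concentration = mb_concentration, mb_shape_floor = mb_shape_floor,
    true_beta = fill_named(true_beta, default_true_beta()),
    true_hmo_beta = fill_named(true_hmo_beta, setNames(numeric(8), HMO_NAMES)),
    true_mb_beta = fill_named(true_mb_beta,
                              setNames(numeric(12), SPECIES_NAMES)),
    true_gamma = true_gamma %||% numeric(0),
    gamma_stratum = match.arg(gamma_stratum),
    intercepts = fill_named(intercepts, default_intercepts()),
    sigma_subject = sigma_subject, sigma_resid = sigma_resid,
    composite_mode = composite_mode,
    p_male = p_male, p_vaginal = p_vaginal, p_graduate = p_graduate,
    p_site_a = p_site_a, batch_probs = batch_probs,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

default_hmo_params <- function() {
  # mean0: expected mg/L at age 0 so that the cohort-average concentration is
  # close to the reported group means under a uniform age distribution on
  # [2.9, 12]; atetra_mult encodes the lower 3-FL level in A-tetra+ milk
  # (1243.26 / 1550.97).
  data.frame(
    hmo = HMO_NAMES,
    mean0 = c(2295, 836, 108, 150, 700, 250, 300, 20),
    slope = c(-0.06, 0.08, 0.03, -0.10, -0.05, -0.07, -0.06, 0.08),
    sigma = c(0.45, 0.45, 0.45, 0.45, 0.50, 0.50, 0.50, 0.60),
    atetra_mult = c(1, 1243.26 / 1550.97, 1, 1, 1, 1, 1, 1),
    row.names = HMO_NAMES, stringsAsFactors = FALSE
  )
}

default_mb_base <- function() {
  # Expected relative abundances of the 12 focal species at the centre age;
  # the remainder of the community is pooled in `other`.
  base <- c(
    bif_longum = 0.38, bif_bifidum = 0.09, bif_breve = 0.09,
    bif_pseudocatenulatum = 0.01, bif_kashiwanohense = 0.01,
    bif_catenulatum = 0.001, bif_unspecified = 0.01,
    b_vulgatus = 0.04, b_dorei = 0.02, b_fragilis = 0.03,
    b_uniformis = 0.003, b_ovatus = 0.01
  )
  c(base, other = 1 - sum(base))
}

default_mb_slopes <- function() {
  s <- setNames(numeric(13), c(SPECIES_NAMES, "other"))
  s["bif_longum"] <- -0.03
  s["bif_breve"] <- -0.04
  s["bif_catenulatum"] <- 0.05
  s["b_vulgatus"] <- 0.05
  s
}

default_true_beta <- function() {
  c(sex_male = -1, delivery_vaginal = 0.3, education_graduate = -1.5,
    site_A = 1.5, batch_2019 = -5, batch_2020 = -6)
}

default_intercepts <- function() {
  setNames(c(100, rep(50, 5)), MSEL_NAMES)
}

fill_named <- function(x, defaults) {
  if (is.null(x)) return(defaults)
  bad <- setdiff(names(x), names(defaults))
  if (length(bad)) {
    stop_config(deparse(substitute(x)),
                paste("unknown names:", paste(bad, collapse = ", ")))
  }
  defaults[names(x)] <- x
  defaults
}

validate_cohort_config <- function(cfg) {
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config(field, "must be a proportion in [0, 1]")
    }
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1) {
    stop_config("n_subjects", "must be a positive count")
  }
  chk_prop("p_singleton"); chk_prop("p_extra_visit")
  chk_prop("p_atetra_mother"); chk_prop("p_male"); chk_prop("p_vaginal")
  chk_prop("p_graduate"); chk_prop("p_site_a")
  if (cfg$max_visits < 1) stop_config("max_visits", "must be >= 1")
  ar <- cfg$age_range_months
  if (length(ar) != 2L || ar[1] >= ar[2] || ar[1] <= 0 || ar[2] > 12) {
    stop_config("age_range_months",
                "must be an increasing interval within (0, 12]")
  }
  if (cfg$sigma_subject < 0) stop_config("sigma_subject", "must be >= 0")
  if (cfg$sigma_resid < 0) stop_config("sigma_resid", "must be >= 0")
  hp <- cfg$hmo_params
  if (!is.data.frame(hp) || !all(HMO_NAMES %in% rownames(hp)) ||
      !all(c("mean0", "slope", "sigma", "atetra_mult") %in% names(hp))) {
    stop_config("hmo_params", "must cover all eight HMOs with columns mean0, slope, sigma, atetra_mult")
  }
  if (any(hp$mean0 <= 0) || any(hp$sigma < 0)) {
    stop_config("hmo_params", "mean0 must be > 0 and sigma >= 0")
  }
  if (any(cfg$mb_base <= 0)) {
    stop_config("mb_base", "all Dirichlet base proportions must be > 0")
  }
  if (abs(sum(cfg$mb_base) - 1) > 1e-8) {
    stop_config("mb_base", "base composition must sum to 1")
  }
  if (cfg$mb_concentration <= 0) {
    stop_config("mb_concentration", "must be > 0")
  }
  if (length(cfg$true_gamma)) {
    pairs <- strsplit(names(cfg$true_gamma), ":", fixed = TRUE)
    ok <- vapply(pairs, function(p) {
      length(p) == 2L && p[1] %in% HMO_NAMES && p[2] %in% SPECIES_NAMES
    }, logical(1))
    if (!all(ok)) {
      stop_config("true_gamma", "names must be '<hmo>:<species>' pairs")
    }
  }
  if (!all(abs(sum(cfg$batch_probs) - 1) < 1e-8) ||
      length(cfg$batch_probs) != 3L) {
    stop_config("batch_probs", "must be three proportions summing to 1")
  }
  invisible(cfg)
}

#' Simulate one milk HMO profile
#'
#' Draws the eight HMO concentrations for a milk sample at a given infant
#' age. Each concentration is lognormal around an age-dependent mean
#' `mean0 * exp(slope * age)`, so configured trend signs are trend signs of
#' the expected concentration. Mothers without detectable A-tetrasaccharide
#' have A-tetra fixed at 0 mg/L (below the limit of detection); for such
#' samples the 3-FL group offset does not apply.
#'
#' @param age_months infant age in months (non-negative scalar).
#' @param atetra_mother logical; does the mother produce detectable A-tetra?
#' @param params HMO parameter table as in [cohort_config()].
#' @return named numeric vector of eight concentrations in mg/L.
#' @export
simulate_hmo <- function(age_months, atetra_mother,
                         params = default_hmo_params()) {
  if (!is.numeric(age_months) || length(age_months) != 1L || age_months < 0) {
    stop("age_months must be a non-negative scalar")
  }
  p <- params[HMO_NAMES, ]
  mu <- p$mean0 * exp(p$slope * age_months)
  if (atetra_mother) mu <- mu * p$atetra_mult
  conc <- mu * exp(rnorm(8L, mean = -p$sigma^2 / 2, sd = p$sigma))
  if (!atetra_mother) conc[HMO_NAMES == "atetra"] <- 0
  setNames(conc, HMO_NAMES)
}

#' Simulate one gut microbiota composition
#'
#' Draws a normalized-gamma (Dirichlet-type) composition over the 12 focal
#' *Bifidobacterium* / *Bacteroides* species plus a pooled remainder. The
#' latent weight of species `s` at age `a` is `base_s * exp(slope_s * (a -
#' centre))`; each species draws an independent gamma variate with shape
#' `max(concentration * weight, shape_floor)` and mean equal to its
#' weight, and the vector is closed to sum 1. The shape floor keeps rare
#' species on realistic magnitudes (a pure Dirichlet with shape
#' `concentration * 0.001` would place their medians hundreds of orders of
#' magnitude below any sequencing detection floor) while preserving the
#' strong right skew and sparsity of infant gut profiles.
#'
#' @param age_months infant age in months.
#' @param base named base composition (must be positive, sums to 1).
#' @param slopes named per-month latent slopes.
#' @param concentration total concentration (> 0); smaller means more
#'   dispersed compositions.
#' @param centre_age age at which the latent weights equal `base`.
#' @param shape_floor lower bound on the per-species gamma shape.
#' @return named numeric vector (12 species + `other`) summing to 1.
#' @export
simulate_microbiota <- function(age_months,
                                base = default_mb_base(),
                                slopes = default_mb_slopes(),
                                concentration = 1.3,
                                centre_age = 7.45,
                                shape_floor = 0.35) {
  if (any(base <= 0)) stop("Dirichlet base weights must be positive")
  if (concentration <= 0) stop("Dirichlet concentration must be positive")
  slopes <- fill_named(slopes, setNames(numeric(length(base)), names(base)))
  w <- base * exp(slopes * (age_months - centre_age))
  k <- pmax(concentration * w, shape_floor)
  g <- rgamma(length(w), shape = k, scale = w / k)
  if (sum(g) == 0) g[which.max(w)] <- 1 # guard against all-zero draws
  setNames(g / sum(g), names(base))
}

# Fixed-point calibration of the latent base weights so that the expected
# *closed* composition, averaged over the visit-age distribution, matches
# the target means (closure biases the dominant species downward
# otherwise). Monte-Carlo based but deterministic under the caller's seed.
calibrate_mb_base <- function(target, concentration, shape_floor,
                              slopes, age_range, n_draws = 3000L,
                              iters = 4L) {
  slopes <- fill_named(slopes, setNames(numeric(length(target)),
                                        names(target)))
  centre <- mean(age_range)
  ages <- runif(n_draws, age_range[1], age_range[2])
  trend <- exp(outer(ages - centre, slopes)) # n_draws x n_species
  w <- target
  for (it in seq_len(iters)) {
    wa <- trend * rep(w, each = n_draws)
    k <- pmax(concentration * wa, shape_floor)
    g <- matrix(rgamma(length(k), shape = k, scale = wa / k),
                nrow = n_draws)
    p <- g / rowSums(g)
    mu <- colMeans(p)
    w <- w * (target / mu)
    w <- w / sum(w)
  }
  setNames(w, names(target))
}

#' Simulate one visit's MSEL scores
#'
#' Computes `score = intercept + covariate terms + sum(beta_hmo * z_hmo) +
#' sum(beta_mb * z_mb) + sum(gamma * z_hmo * z_mb) + b_i + eps` for each of
#' the six MSEL outcomes, with `eps ~ Normal(0, sigma_resid^2)` drawn
#' independently per outcome. Predictor values in `row` must already be on
#' the standardized scale the coefficients refer to.
#'
#' @param row named list or vector with the standardized predictors: the
#'   covariate dummies named as in `true_beta`, entries named after the
#'   HMOs and species (z-scores).
#' @param params list with elements `intercepts`, `true_beta`,
#'   `true_hmo_beta`, `true_mb_beta`, `true_gamma`, `sigma_resid`,
#'   `composite_mode` (see [cohort_config()]).
#' @param subject_intercept the subject's random intercept `b_i`.
#' @return named numeric vector of the six MSEL scores.
#' @export
simulate_msel <- function(row, params, subject_intercept = 0) {
  row <- unlist(row)
  need <- c(names(params$true_beta),
            names(params$true_hmo_beta)[params$true_hmo_beta != 0],
            names(params$true_mb_beta)[params$true_mb_beta != 0])
  missing_terms <- setdiff(need, names(row))
  if (length(missing_terms)) {
    stop("row lacks predictor(s): ", paste(missing_terms, collapse = ", "))
  }
  lp <- sum(params$true_beta * row[names(params$true_beta)])
  hb <- params$true_hmo_beta
  lp <- lp + sum(hb[hb != 0] * row[names(hb)[hb != 0]])
  mb <- params$true_mb_beta
  lp <- lp + sum(mb[mb != 0] * row[names(mb)[mb != 0]])
  if (length(params$true_gamma)) {
    for (nm in names(params$true_gamma)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (!all(pr %in% names(row))) {
        stop("row lacks predictor(s) for interaction ", nm)
      }
      lp <- lp + params$true_gamma[[nm]] * row[[pr[1]]] * row[[pr[2]]]
    }
  }
  sc <- params$intercepts + lp + subject_intercept +
    rnorm(length(params$intercepts), sd = params$sigma_resid)
  sc <- setNames(as.numeric(sc), names(params$intercepts))
  if (identical(params$composite_mode, "derived")) {
    sub4 <- c("visual_reception", "fine_motor", "receptive_language",
              "expressive_language")
    sc["composite"] <- 100 + 2 * (mean(sc[sub4]) - 50)
  }
  sc
}

#' Generate a synthetic mother-infant cohort
#'
#' Produces a long-format data frame with one row per visit: subject
#' metadata, the eight HMO concentrations (`*_mgL`), the relative abundances
#' of the 12 focal species plus remainder (`ra_*`), and the six MSEL scores
#' (`msel_*`). MSEL outcomes are generated from the random-intercept linear
#' model on standardized predictors, so the configured coefficients are
#' recoverable by the downstream pipeline. The generating truth (true
#' coefficients, subject intercepts, seed) is attached as the `"truth"`
#' attribute and can be written with [write_truth()].
#'
#' @param config a [cohort_config()] object.
#' @return a `triad_cohort` data frame (one row per visit).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20, seed = 7))
#' nrow(coh); attr(coh, "truth")$seed
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  singleton <- runif(n) < cfg$p_singleton
  n_visits <- ifelse(singleton, 1L,
                     2L + rbinom(n, max(cfg$max_visits - 2L, 0L),
                                 cfg$p_extra_visit))
  atetra_mother <- runif(n) < cfg$p_atetra_mother
  sex <- ifelse(runif(n) < cfg$p_male, "male", "female")
  delivery <- ifelse(runif(n) < cfg$p_vaginal, "vaginal", "cesarean")
  educ <- ifelse(runif(n) < cfg$p_graduate, "graduate", "below")
  site <- ifelse(runif(n) < cfg$p_site_a, "A", "B")
  batch <- sample(names(cfg$batch_probs), n, replace = TRUE,
                  prob = cfg$batch_probs)
  b_i <- rnorm(n, sd = cfg$sigma_subject)
  subj_id <- sprintf("S%03d", seq_len(n))

  mb_base_cal <- calibrate_mb_base(cfg$mb_base, cfg$mb_concentration,
                                   cfg$mb_shape_floor %||% 0.35,
                                   cfg$mb_slopes, cfg$age_range_months)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ages <- sort(runif(n_visits[i], cfg$age_range_months[1],
                       cfg$age_range_months[2]))
    hmo <- t(vapply(ages, simulate_hmo, numeric(8L),
                    atetra_mother = atetra_mother[i],
                    params = cfg$hmo_params))
    mb <- t(vapply(ages, simulate_microbiota, numeric(length(cfg$mb_base)),
                   base = mb_base_cal, slopes = cfg$mb_slopes,
                   concentration = cfg$mb_concentration,
                   centre_age = mean(cfg$age_range_months),
                   shape_floor = cfg$mb_shape_floor %||% 0.35))
    rows[[i]] <- data.frame(
      subject_id = subj_id[i], visit_index = seq_len(n_visits[i]),
      age_months = ages, sex = sex[i], delivery = delivery[i],
      maternal_education = educ[i], site = site[i],
      batch_year = as.integer(batch[i]),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    colnames(hmo) <- hmo_col(HMO_NAMES)
    colnames(mb) <- species_col(names(cfg$mb_base))
    rows[[i]] <- cbind(rows[[i]], hmo, mb)
  }
  dat <- do.call(rbind, rows)
  rownames(dat) <- NULL

  # Standardized predictor values on the scale the true coefficients use;
  # a degenerate (constant) column contributes zero signal.
  safe_z <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L || length(unique(v[ok])) < 2L) return(numeric(length(v)))
    standardize(v)
  }
  zs <- lapply(c(hmo_col(HMO_NAMES), species_col(SPECIES_NAMES)),
               function(cl) safe_z(dat[[cl]]))
  names(zs) <- c(HMO_NAMES, SPECIES_NAMES)
  cov_row <- data.frame(
    sex_male = as.numeric(dat$sex == "male"),
    delivery_vaginal = as.numeric(dat$delivery == "vaginal"),
    education_graduate = as.numeric(dat$maternal_education == "graduate"),
    site_A = as.numeric(dat$site == "A"),
    batch_2019 = as.numeric(dat$batch_year == 2019L),
    batch_2020 = as.numeric(dat$batch_year == 2020L)
  )
  params <- cfg[c("intercepts", "true_beta", "true_hmo_beta", "true_mb_beta",
                  "true_gamma", "sigma_resid", "composite_mode")]
  subj_index <- match(dat$subject_id, subj_id)
  in_gamma_stratum <- switch(cfg$gamma_stratum %||% "all",
                             all = rep(TRUE, nrow(dat)),
                             atetra_pos = atetra_mother[subj_index],
                             atetra_neg = !atetra_mother[subj_index])
  msel <- matrix(NA_real_, nrow(dat), length(MSEL_NAMES),
                 dimnames = list(NULL, msel_col(MSEL_NAMES)))
  for (r in seq_len(nrow(dat))) {
    row <- c(as.list(cov_row[r, ]), lapply(zs, `[[`, r))
    p_r <- params
    if (!in_gamma_stratum[r]) p_r$true_gamma <- numeric(0)
    msel[r, ] <- simulate_msel(row, p_r, b_i[subj_index[r]])
  }
  dat <- cbind(dat, as.data.frame(msel))

  attr(dat, "hmo_names") <- HMO_NAMES
  attr(dat, "species_names") <- names(cfg$mb_base)
  attr(dat, "truth") <- list(
    seed = cfg$seed,
    intercepts = cfg$intercepts,
    true_beta = cfg$true_beta,
    true_hmo_beta = cfg$true_hmo_beta,
    true_mb_beta = cfg$true_mb_beta,
    true_gamma = as.list(cfg$true_gamma),
    gamma_stratum = cfg$gamma_stratum %||% "all",
    sigma_subject = cfg$sigma_subject,
    sigma_resid = cfg$sigma_resid,
    subject_intercepts = setNames(as.list(b_i), subj_id),
    atetra_mother = setNames(as.list(atetra_mother), subj_id)
  )
  class(dat) <- c("triad_cohort", "data.frame")
  dat
}

#' Write the generating truth of a synthetic cohort to JSON
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no truth attribute")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
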