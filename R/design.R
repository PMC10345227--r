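#' Model specification for one outcome and stratification
#'
#' @param outcome one of the six MSEL scores (`composite`, `gross_motor`,
#'   `visual_reception`, `fine_motor`, `receptive_language`,
#'   `expressive_language`).
#' @param stratification `"unstratified"`, `"atetra_pos"` or `"atetra_neg"`.
#' @param species retained species names (from [preprocess_cohort()]).
#' @param hmo_names the HMO set (fixed default of eight).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, stratification = "unstratified",
                       species = SPECIES_NAMES, hmo_names = HMO_NAMES) {
  if (!outcome %in% MSEL_NAMES) {
    stop("unknown outcome: ", outcome)
  }
  if (!stratification %in% STRATIFICATIONS) {
    stop("unknown stratification: ", stratification)
  }
  structure(list(outcome = outcome, stratification = stratification,
                 hmo_names = hmo_names, species = species),
            class = "model_spec")
}

covariate_columns <- function(data) {
  # Treatment coding; references: female, cesarean, below-graduate, site B,
  # batch 2018.
  cbind(
    sex_male = as.numeric(data$sex == "male"),
    delivery_vaginal = as.numeric(data$delivery == "vaginal"),
    education_graduate = as.numeric(data$maternal_education == "graduate"),
    site_A = as.numeric(data$site == "A"),
    batch_2019 = as.numeric(data$batch_year == 2019L),
    batch_2020 = as.numeric(data$batch_year == 2020L)
  )
}

#' Build the fixed-effects design matrix
#'
#' Assembles `y` and `X` for one outcome and stratification. Columns are
#' `[intercept, covariate dummies, HMO mains, species mains, HMO x species
#' products, stratum indicator (stratified only)]`. Under a stratified
#' specification the standardized HMO values (and hence every interaction
#' column) are zero-masked on the rows outside the stratum, and an
#' unpenalized indicator for the *other* stratum is appended; species
#' columns are used for all rows. Interaction columns are elementwise
#' products of the (masked) standardized columns and are not
#' re-standardized. Rows with a missing outcome or missing predictor value
#' are excluded and recorded.
#'
#' @param prep output of [preprocess_cohort()].
#' @param spec a [model_spec()]; its `species` should be `prep$species`.
#' @return list of class `triad_design` with `y`, `X`, `subject_ids`,
#'   `roles` (per-column: `intercept`, `covariate`, `hmo_main`, `mb_main`,
#'   `interaction`, `indicator`), `penalized` (logical per column),
#'   `excluded_rows` (original row indices dropped), `spec`.
#' @export
build_design <- function(prep, spec) {
  data <- prep$data
  species <- spec$species
  hmos <- spec$hmo_names
  y <- data[[msel_col(spec$outcome)]]

  covs <- covariate_columns(data)
  Zh <- as.matrix(prep$z[, hmos, drop = FALSE])
  Zm <- as.matrix(prep$z[, species, drop = FALSE])
  colnames(Zh) <- hmos
  colnames(Zm) <- species

  indicator <- NULL
  if (spec$stratification == "atetra_pos") {
    in_stratum <- prep$atetra == "positive"
    indicator <- cbind(I_atetra_neg = as.numeric(!in_stratum))
  } else if (spec$stratification == "atetra_neg") {
    in_stratum <- prep$atetra == "negative"
    indicator <- cbind(I_atetra_pos = as.numeric(!in_stratum))
  } else {
    in_stratum <- rep(TRUE, nrow(data))
  }
  if (!any(in_stratum)) stop("empty stratum: ", spec$stratification)
  Zh_masked <- Zh * as.numeric(in_stratum)

  inter <- matrix(0, nrow(data), length(hmos) * length(species))
  inter_names <- character(ncol(inter))
  k <- 0L
  for (h in hmos) {
    for (s in species) {
      k <- k + 1L
      inter[, k] <- Zh_masked[, h] * Zm[, s]
      inter_names[k] <- paste0(h, ":", s)
    }
  }
  colnames(inter) <- inter_names

  X <- cbind(`(Intercept)` = 1, covs, Zh_masked, Zm, inter)
  roles <- c("intercept", rep("covariate", ncol(covs)),
             rep("hmo_main", length(hmos)), rep("mb_main", length(species)),
             rep("interaction", ncol(inter)))
  if (!is.null(indicator)) {
    X <- cbind(X, indicator)
    roles <- c(roles, "indicator")
  }

  keep <- !is.na(y) & rowSums(is.na(X)) == 0L
  excluded <- which(!keep)
  if (length(excluded)) {
    message(sprintf("build_design: excluding %d row(s) with missing values",
                    length(excluded)))
  }
  structure(list(
    y = y[keep], X = X[keep, , drop = FALSE],
    subject_ids = data$subject_id[keep],
    roles = setNames(roles, colnames(X)),
    penalized = setNames(roles %in% c("hmo_main", "mb_main", "interaction"),
                         colnames(X)),
    excluded_rows = excluded, spec = spec
  ), class = "triad_design")
}

#' Penalized group structure with interaction hierarchy
#'
#' Encodes the "interaction implies both main effects" hierarchy through
#' latent overlapping groups: one singleton group per HMO main, one per
#' species main, and one group `{HMO_j, MB_k, HMO_j x MB_k}` per
#' interaction pair. In the latent expansion every group owns private
#' copies of its member columns, so a collapsed support formed from
#' selected groups can only contain an interaction together with both of
#' its parents. Group weights are `sqrt(group size)`. Intercept,
#' covariates and the stratum indicator are unpenalized.
#'
#' @param design a [build_design()] result.
#' @return list of class `group_structure` with `groups` (list of latent
#'   column index vectors), `latent_map` (latent column -> design column
#'   index), `weights`, `group_roles` (`hmo_main`, `mb_main`,
#'   `interaction`), `group_labels`, `unpenalized` (design column indices).
#' @export
build_groups <- function(design) {
  roles <- design$roles
  cols <- names(roles)
  unpen <- which(!design$penalized)
  hmo_idx <- which(roles == "hmo_main")
  mb_idx <- which(roles == "mb_main")
  int_idx <- which(roles == "interaction")

  latent_map <- integer(0)
  groups <- list()
  g_roles <- character(0)
  g_labels <- character(0)
  add_group <- function(members, role, label) {
    start <- length(latent_map)
    latent_map <<- c(latent_map, members)
    groups[[length(groups) + 1L]] <<- start + seq_along(members)
    g_roles <<- c(g_roles, role)
    g_labels <<- c(g_labels, label)
  }
  for (j in hmo_idx) add_group(j, "hmo_main", cols[j])
  for (j in mb_idx) add_group(j, "mb_main", cols[j])
  for (j in int_idx) {
    parents <- strsplit(cols[j], ":", fixed = TRUE)[[1]]
    pj <- match(parents[1], cols)
    pk <- match(parents[2], cols)
    if (is.na(pj) || is.na(pk)) {
      stop("interaction column ", cols[j], " lacks a parent main effect")
    }
    add_group(c(pj, pk, j), "interaction", cols[j])
  }
  structure(list(
    groups = groups, latent_map = latent_map,
    weights = sqrt(lengths(groups)),
    group_roles = g_roles, group_labels = g_labels,
    unpenalized = unpen, n_design_cols = length(cols)
  ), class = "group_structure")
}

#' Latent expansion of a design for the overlapping group LASSO
#'
#' Returns the matrix `[X_unpenalized, X_latent]` where each latent group's
#' member columns are copied into a private block, plus the bookkeeping
#' needed to collapse latent coefficients back onto the design columns.
#'
#' @param design a [build_design()] result.
#' @param groups the matching [build_groups()] structure.
#' @return list with `X_expanded`, `expanded_groups` (index vectors into
#'   `X_expanded` for each penalized group), `n_unpenalized`, `collapse_map`
#'   (expanded column -> design column).
#' @export
expand_design <- function(design, groups) {
  Xu <- design$X[, groups$unpenalized, drop = FALSE]
  Xl <- design$X[, groups$latent_map, drop = FALSE]
  nu <- ncol(Xu)
  list(
    X_expanded = cbind(Xu, Xl),
    expanded_groups = lapply(groups$groups, function(g) g + nu),
    n_unpenalized = nu,
    collapse_map = c(groups$unpenalized, groups$latent_map)
  )
}

#' Collapse expanded coefficients onto the design columns
#'
#' @param v coefficient vector on the expanded space.
#' @param expansion an [expand_design()] result.
#' @param n_cols number of design columns.
#' @return numeric vector of length `n_cols` (latent copies summed).
#' @export
collapse_coef <- function(v, expansion, n_cols) {
  beta <- numeric(n_cols)
  for (i in seq_along(v)) {
    j <- expansion$collapse_map[i]
    beta[j] <- beta[j] + v[i]
  }
  beta
}
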