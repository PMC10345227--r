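#' Write a cohort table to TSV
#'
#' Deterministic column order, UTF-8, tab-separated, header row. Numeric
#' cells are serialised with `%.17g` so a write/read round trip reproduces
#' the doubles exactly; missing values become empty cells.
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  ord <- c(intersect(METADATA_COLS, names(df)),
           sort(grep("_mgL$", names(df), value = TRUE)),
           sort(grep("^ra_", names(df), value = TRUE)),
           sort(grep("^msel_", names(df), value = TRUE)))
  ord <- c(ord, setdiff(names(df), ord))
  df <- df[, ord, drop = FALSE]
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- ""
      df[[cl]] <- v
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a cohort table from TSV
#'
#' Expects the schema written by [write_cohort()]: the metadata columns,
#' eight HMO concentration columns suffixed `_mgL`, at least one species
#' relative-abundance column prefixed `ra_`, and optionally the six
#' `msel_*` score columns. Empty cells and `"NA"` are read as missing.
#'
#' @param path TSV path.
#' @return a `triad_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  missing_meta <- setdiff(METADATA_COLS, names(df))
  if (length(missing_meta)) {
    stop("schema error: missing required column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  missing_hmo <- setdiff(hmo_col(HMO_NAMES), names(df))
  if (length(missing_hmo)) {
    stop("schema error: missing required column(s): ",
         paste(missing_hmo, collapse = ", "))
  }
  ra_cols <- grep("^ra_", names(df), value = TRUE)
  if (!length(ra_cols)) {
    stop("schema error: no species relative-abundance (ra_) column")
  }
  for (cl in c(hmo_col(HMO_NAMES), ra_cols)) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(
        as.numeric(df[[cl]]))))
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   cl, bad[1]))
    }
  }
  for (cl in ra_cols) {
    bad <- which(!is.na(df[[cl]]) & (df[[cl]] < 0 | df[[cl]] > 1))
    if (length(bad)) {
      stop(sprintf(
        "validation error: abundance out of [0, 1] in column '%s', row %d",
        cl, bad[1]))
    }
  }
  dup <- duplicated(df[, c("subject_id", "visit_index")])
  if (any(dup)) {
    stop("validation error: duplicated subject_id/visit_index pair at row ",
         which(dup)[1])
  }
  attr(df, "hmo_names") <- HMO_NAMES
  attr(df, "species_names") <- sub("^ra_", "", ra_cols)
  class(df) <- c("triad_cohort", "data.frame")
  df
}

#' Write an analysis results bundle to disk
#'
#' One TSV per outcome x stratification (columns `term`, `role`,
#' `effect_size`, `se`, `t`, `p`, `selection_frequency`, plus the variance
#' components and fit sizes repeated per row) and one `provenance.json`
#' with the seed, configuration hash, software version and per-model
#' fallback flags.
#'
#' @param results a results bundle from [run_triad_analysis()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!inherits(results, "triad_results")) {
    stop("results must be a 'triad_results' bundle")
  }
  missing_models <- names(results$models)[vapply(results$models, is.null,
                                                logical(1))]
  if (length(missing_models)) {
    stop("partial bundle; missing outcome models: ",
         paste(missing_models, collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results$models)) {
    m <- results$models[[nm]]
    tab <- m$table
    tab$sigma_b <- sqrt(m$fit$sigma_b2)
    tab$sigma_resid <- sqrt(m$fit$sigma2)
    tab$n_obs <- m$fit$n_obs
    tab$n_subjects <- m$fit$n_subjects
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv_precise(tab, f)
    files <- c(files, f)
  }
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(results$provenance, prov, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, prov))
}

# TSV writer keeping full double precision (%.17g), empty cells for NA.
write_tsv_precise <- function(df, path) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- ""
      df[[cl]] <- v
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the function arguments: top-level `seed`, `outcomes`,
#' `stratifications`, `output_dir`, an `input` path or a `simulate` block
#' (fields of [cohort_config()]), a `preprocess` block (fields of
#' [preprocess_config()]) and a `lasso` block (`n_lambdas`,
#' `lambda_min_ratio`, `k_folds`, `reps`, `freq_cutoff`, `tol`,
#' `max_iter`).
#'
#' @param path YAML file.
#' @return a named list ready for [run_triad_analysis()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$preprocess <- do.call(preprocess_config, cfg$preprocess %||% list())
  cfg
}
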