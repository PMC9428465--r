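#' Read a plate-series CSV
#'
#' Expects the dialect `taxon,temp_c,replicate,time_h,od600,is_blank`.
#' Unknown columns are ignored with a warning; missing required columns or
#' non-numeric OD values raise errors naming the offender.
#'
#' @param path Path to the CSV file.
#' @return A tibble plate series.
#' @export
read_plate_csv <- function(path) {
  df <- read_typed_csv(
    path,
    required = c("taxon", "temp_c", "replicate", "time_h", "od600",
      "is_blank"),
    numeric_cols = c("temp_c", "replicate", "time_h", "od600"),
    logical_cols = "is_blank",
    what = "plate series"
  )
  if (any(df$time_h < 0)) stop_input("negative time_h in %s", path)
  df
}

#' Read a colony-count CSV (`temp_c,replicate,taxon,count`)
#'
#' @inheritParams read_plate_csv
#' @return A tibble count table.
#' @export
read_counts_csv <- function(path) {
  df <- read_typed_csv(
    path,
    required = c("temp_c", "replicate", "taxon", "count"),
    numeric_cols = c("temp_c", "replicate", "count"),
    logical_cols = character(0),
    what = "count table"
  )
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop_input("counts must be non-negative integers in %s", path)
  }
  df
}

#' Read a growth-rate CSV (`taxon,temp_c,mean_r_per_h,n_reps_used`)
#'
#' @inheritParams read_plate_csv
#' @return A tibble rate table.
#' @export
read_rates_csv <- function(path) {
  read_typed_csv(
    path,
    required = c("taxon", "temp_c", "mean_r_per_h"),
    numeric_cols = c("temp_c", "mean_r_per_h"),
    logical_cols = character(0),
    what = "rate table"
  )
}

read_typed_csv <- function(path, required, numeric_cols, logical_cols,
                           what) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, required, sprintf("%s (%s)", what, path))
  if (nrow(df) == 0) stop_input("%s has an empty data section", path)
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warning(sprintf(
      "ignoring unknown column(s) in %s: %s", path,
      paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      stop_input(
        "non-numeric value in column '%s' of %s at data row %d",
        col, path, bad[1]
      )
    }
    df[[col]] <- v
  }
  for (col in logical_cols) {
    df[[col]] <- as.logical(df[[col]])
  }
  tibble::as_tibble(df[required])
}

#' Write a table as RFC-4180 CSV
#'
#' @param x Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = which(
    vapply(x, is.character, logical(1))
  ))
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Reads the pipeline configuration (paths, seed, fitting and filtering
#' parameters, and an optional `simulate` block forwarded to
#' [sim_config()]).
#'
#' @param path Path to the YAML file.
#' @return A list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Build a run configuration in code
#'
#' @param seed Global seed; per-stage substreams are derived from it.
#' @param n_starts Restarts for the thermal-curve fit.
#' @param growth_n_starts Restarts per logistic fit.
#' @param tref_c Reference temperature (Celsius).
#' @param min_prevalence Prevalence threshold for [filter_rare()].
#' @param n_perm PERMANOVA permutations.
#' @param simulate List of [sim_config()] overrides, or `NULL` to skip
#'   simulation (then `plate_csv` and `counts_csv` must point at data).
#' @param plate_csv,counts_csv Input paths when not simulating.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, n_starts = 1000, growth_n_starts = 25,
                       tref_c = 18, min_prevalence = 0.25, n_perm = 999,
                       simulate = list(), plate_csv = NULL,
                       counts_csv = NULL) {
  as_run_config(list(
    seed = seed, n_starts = n_starts, growth_n_starts = growth_n_starts,
    tref_c = tref_c, min_prevalence = min_prevalence, n_perm = n_perm,
    simulate = simulate, plate_csv = plate_csv, counts_csv = counts_csv
  ))
}

as_run_config <- function(cfg) {
  defaults <- list(
    seed = 1, n_starts = 1000, growth_n_starts = 25, tref_c = 18,
    min_prevalence = 0.25, n_perm = 999, simulate = NULL,
    plate_csv = NULL, counts_csv = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[nm] <- defaults[nm]
  }
  if (cfg$min_prevalence < 0 || cfg$min_prevalence > 1) {
    stop_input("min_prevalence must be in [0, 1]")
  }
  if (is.null(cfg$simulate) &&
    (is.null(cfg$plate_csv) || is.null(cfg$counts_csv))) {
    stop_input(
      "config must either include a `simulate` block or name both plate_csv and counts_csv"
    )
  }
  structure(cfg, class = "run_config")
}
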