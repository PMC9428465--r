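#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded stages do not perturb the global random stream.
#' With `seed = NULL` the code runs on the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

## Derive a per-stage seed from a global one so that pipeline stages are
## individually reproducible. Keeps results inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  offsets <- c(
    simulate = 11L, growth = 23L, tpc = 37L,
    community = 53L, stats = 71L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}
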