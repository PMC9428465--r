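#' Relative abundance of taxa
#'
#' @param counts Named non-negative counts by taxon.
#' @return Proportions `count_i / total`, summing to 1.
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop_input("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop_input("empty community: all counts are zero")
  counts / total
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * log(p_i))` in nats, with `0 * log(0)` taken as 0.
#'
#' @param proportions Proportions in `[0, 1]` summing to 1 (tolerance 1e-9).
#' @return H' in nats; 0 for a monoculture, `log(R)` for an even community.
#' @export
shannon <- function(proportions) {
  if (any(proportions < 0) || any(proportions > 1)) {
    stop_input("proportions must lie in [0, 1]")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop_input(
      "proportions must sum to 1 (got %.12f)", sum(proportions)
    )
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' `J = H' / log(R)`: the realised fraction of the maximum diversity
#' attainable with `R` taxa. Undefined (NA) for a monoculture, where the
#' denominator `log(1)` vanishes.
#'
#' @param H Shannon diversity (nats).
#' @param R Species richness (count of taxa present).
#' @return J in `[0, 1]`, or `NA` when `R == 1`.
#' @export
pielou <- function(H, R) {
  if (R < 1) stop_input("empty community: richness is zero")
  if (H < 0) stop_input("H must be non-negative")
  if (R == 1) {
    return(NA_real_)
  }
  H / log(R)
}

#' Species richness
#'
#' @param counts Named counts by taxon.
#' @return Number of taxa with a positive count.
#' @export
richness <- function(counts) {
  sum(counts > 0)
}

#' Rank-abundance curve
#'
#' Taxon proportions sorted descending; ties broken by taxon label
#' (ascending), ranks `1..R`. Steep curves indicate dominance by few taxa.
#'
#' @param counts Named counts by taxon; total must be positive.
#' @return A tibble with columns `rank`, `taxon`, `proportion` (taxa with
#'   zero counts are dropped).
#' @export
rank_abundance <- function(counts) {
  p <- relative_abundance(counts)
  p <- p[p > 0]
  ord <- order(-p, names(p))
  tibble::tibble(
    rank = seq_along(ord),
    taxon = names(p)[ord],
    proportion = unname(p[ord])
  )
}

#' Prevalence filter for rare taxa
#'
#' Within each temperature, keeps only taxa present (count > 0) in strictly
#' more than `min_prevalence` of that temperature's replicate communities;
#' a taxon can therefore be retained at one temperature and dropped at
#' another. The strict inequality means a taxon at exactly the threshold
#' prevalence is removed.
#'
#' @param counts_table Data frame with columns `temp_c`, `replicate`,
#'   `taxon`, `count`.
#' @param min_prevalence Prevalence threshold in `[0, 1]`; default 0.25.
#' @return The filtered table, same columns.
#' @export
filter_rare <- function(counts_table, min_prevalence = 0.25) {
  assert_columns(
    counts_table, c("temp_c", "replicate", "taxon", "count"), "count table"
  )
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop_input("min_prevalence must be in [0, 1]")
  }
  prev <- counts_table |>
    dplyr::group_by(.data$temp_c, .data$taxon) |>
    dplyr::summarise(
      prevalence = mean(.data$count > 0),
      .groups = "drop"
    )
  keep <- prev[prev$prevalence > min_prevalence, c("temp_c", "taxon")]
  dplyr::semi_join(counts_table, keep, by = c("temp_c", "taxon"))
}

#' Diversity metrics for every replicate community
#'
#' Computes richness, Shannon H', and Pielou J for each (temperature,
#' replicate) community of a colony-count table.
#'
#' @inheritParams filter_rare
#' @return A tibble with columns `temp_c`, `replicate`, `richness`,
#'   `shannon_h`, `pielou_j` (`pielou_j` is `NA` for monocultures).
#' @export
diversity_table <- function(counts_table) {
  assert_columns(
    counts_table, c("temp_c", "replicate", "taxon", "count"), "count table"
  )
  counts_table |>
    dplyr::group_by(.data$temp_c, .data$replicate) |>
    dplyr::summarise(
      richness = richness(.data$count),
      shannon_h = if (sum(.data$count) > 0) {
        shannon(relative_abundance(.data$count))
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pielou_j = dplyr::if_else(
        .data$richness >= 2,
        .data$shannon_h / log(.data$richness),
        NA_real_
      )
    )
}

#' Long-format relative abundances for every replicate community
#'
#' @inheritParams filter_rare
#' @return A tibble with columns `temp_c`, `replicate`, `taxon`,
#'   `rel_abund`. Replicates with zero total count are dropped.
#' @export
relative_abundance_table <- function(counts_table) {
  assert_columns(
    counts_table, c("temp_c", "replicate", "taxon", "count"), "count table"
  )
  counts_table |>
    dplyr::group_by(.data$temp_c, .data$replicate) |>
    dplyr::filter(sum(.data$count) > 0) |>
    dplyr::mutate(rel_abund = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("temp_c", "replicate", "taxon", "rel_abund")
}
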