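# Temporal ranges from occupied time bins: FAD = oldest bound of the oldest
# occupied bin, LAD = youngest bound of the youngest occupied bin. Ages are
# bin-boundary based because occurrences carry interval ages only.

#' Per-taxon temporal ranges from binned occurrences
#'
#' @param occ Binned occurrence tibble (needs `bin`, `bin_max_ma`,
#'   `bin_min_ma` from [assign_bins()]).
#' @param rank `"species"`, `"genus"` or `"family"`.
#' @return A tibble: `taxon`, `fad_ma`, `lad_ma`, `duration_ma`, `n_bins`
#'   (distinct occupied bins), `n_occurrences`.
#' @export
tax_range_time <- function(occ, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  occ$taxon <- taxon_at_rank(occ, rank)
  occ <- filter(occ, !is.na(.data$taxon), !is.na(.data$bin))
  if (nrow(occ) == 0) {
    return(tibble(taxon = character(0), fad_ma = numeric(0),
                  lad_ma = numeric(0), duration_ma = numeric(0),
                  n_bins = integer(0), n_occurrences = integer(0)))
  }
  occ %>%
    group_by(.data$taxon) %>%
    summarise(
      fad_ma = max(.data$bin_max_ma),
      lad_ma = min(.data$bin_min_ma),
      n_bins = n_distinct(.data$bin),
      n_occurrences = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(duration_ma = .data$fad_ma - .data$lad_ma, .after = "lad_ma")
}

#' Temporal overlap and time added between datasets
#'
#' For each taxon present in the combined dataset `D`, compares each
#' subset's temporal range with the total:
#' `overlap_pct = 100 * |range(S) ∩ range(D)| / |range(D)|` and
#' `added_pct = 100 * (|range(D)| - |range(D \ S)|) / |range(D)|`
#' (the share of the total range lost if `S` were removed). Taxa whose
#' combined occurrences span more than `max_bins_filter` bins are dropped
#' (set `Inf` to disable), limiting the influence of poorly age-resolved
#' taxa. When the total range has zero duration (a single bin of zero
#' length cannot occur with valid bins, so only when the subset is absent),
#' overlap is 100 if the subset occupies the taxon's bin and 0 otherwise.
#'
#' @param partition A [partition_datasets()] result, binned.
#' @param rank Taxonomic rank for range computation.
#' @param max_bins_filter Maximum number of distinct bins a taxon may
#'   occupy in the combined dataset (default 2); `Inf` disables the filter.
#' @return A tibble: `taxon`, `subset`, `fad_ma`, `lad_ma`,
#'   `duration_ma`, `duration_total_ma`, `overlap_pct`, `added_pct`.
#' @export
range_overlap_time <- function(partition, rank = c("genus", "family", "species"),
                               max_bins_filter = 2) {
  rank <- arg_match(rank)
  total <- tax_range_time(partition$D, rank)
  if (is.finite(max_bins_filter)) {
    total <- filter(total, .data$n_bins <= max_bins_filter)
  }
  subsets <- list(dark = partition$A, published = partition$B, pbdb = partition$C)
  complements <- list(
    dark = partition$B,
    published = partition$A,
    pbdb = filter(partition$D, !.data$in_pbdb)
  )
  purrr::imap(subsets, function(sub_occ, label) {
    rng <- tax_range_time(sub_occ, rank)
    rng_wo <- tax_range_time(complements[[label]], rank)
    total %>%
      dplyr::inner_join(rng, by = "taxon", suffix = c("_total", "")) %>%
      left_join(
        select(rng_wo, "taxon", wo_fad = "fad_ma", wo_lad = "lad_ma"),
        by = "taxon"
      ) %>%
      mutate(
        subset = label,
        dur_total = .data$fad_ma_total - .data$lad_ma_total,
        inter = pmax(0, pmin(.data$fad_ma, .data$fad_ma_total) -
                       pmax(.data$lad_ma, .data$lad_ma_total)),
        overlap_pct = if_else(.data$dur_total > 0,
                              100 * .data$inter / .data$dur_total, 100),
        dur_wo = if_else(is.na(.data$wo_fad), 0, .data$wo_fad - .data$wo_lad),
        added_pct = if_else(.data$dur_total > 0,
                            100 * (.data$dur_total - .data$dur_wo) / .data$dur_total,
                            0)
      ) %>%
      mutate(duration_ma = .data$fad_ma - .data$lad_ma) %>%
      select(
        "taxon", "subset", "fad_ma", "lad_ma", "duration_ma",
        duration_total_ma = "dur_total", "overlap_pct", "added_pct"
      )
  }) %>%
    bind_rows()
}

#' Relative positions of occurrences within their taxon's temporal range
#'
#' For each occurrence of a taxon whose combined temporal range has positive
#' duration, the relative position is
#' `r = (FAD_total - bin midpoint) / (FAD_total - LAD_total)`, clamped to
#' \[0, 1\]; `r = 0` is the oldest end of the range. Single-bin taxa are
#' excluded (duration spans one bin, so all positions coincide).
#'
#' @param partition A [partition_datasets()] result, binned.
#' @param rank Taxonomic rank.
#' @return A tibble: `taxon`, `subset` (dark/published/pbdb), `bin`,
#'   `position`.
#' @export
occurrence_positions <- function(partition, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  total <- tax_range_time(partition$D, rank) %>%
    filter(.data$n_bins > 1, .data$duration_ma > 0)
  base <- partition$D
  base$taxon <- taxon_at_rank(base, rank)
  base <- base %>%
    filter(!is.na(.data$taxon), !is.na(.data$bin)) %>%
    dplyr::inner_join(select(total, "taxon", "fad_ma", "lad_ma", "duration_ma"),
                      by = "taxon") %>%
    mutate(position = pmin(pmax(
      (.data$fad_ma - .data$bin_midpoint) / .data$duration_ma, 0), 1))
  bind_rows(
    base %>% filter(.data$in_dark) %>% mutate(subset = "dark"),
    base %>% filter(.data$in_published) %>% mutate(subset = "published"),
    base %>% filter(.data$in_pbdb) %>% mutate(subset = "pbdb")
  ) %>%
    select("taxon", "subset", "bin", "position")
}
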