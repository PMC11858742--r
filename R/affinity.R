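# Standardized relative affinity (SRA) of clades for carbonate versus
# siliciclastic substrates. RA = k/n - pi is the excess of a family's
# carbonate proportion over the background; SRA standardises RA against a
# binomial null (k* ~ Binomial(n, pi)) so that 0 means mixed/no affinity,
# positive values a carbonate affinity, negative a siliciclastic one.

#' Background carbonate proportion of a reference pool
#'
#' The carbonate fraction of the lithology-known occurrences in the
#' reference pool (by default, all occurrences of the combined dataset in
#' the interval). Intervals whose background is exactly 0 or 1 cannot
#' calibrate a null and are flagged unanalysable.
#'
#' @param reference Occurrence tibble for the interval.
#' @return A list: `pi` (carbonate proportion or `NA`), `n_known`,
#'   `analysable`.
#' @export
background_proportion <- function(reference) {
  known <- reference$lithology %in% c("carbonate", "siliciclastic")
  n_known <- sum(known)
  if (n_known == 0) {
    return(list(pi = NA_real_, n_known = 0L, analysable = FALSE))
  }
  p <- sum(reference$lithology[known] == "carbonate") / n_known
  list(pi = p, n_known = n_known, analysable = p > 0 && p < 1)
}

#' Standardized relative affinity of one family in one interval
#'
#' Draws `B` binomial null replicates `k* ~ Binomial(n, pi)`, forms the null
#' relative affinities `RA* = k*/n - pi`, and returns
#' `SRA = (RA - mean(RA*)) / sd(RA*)`. Families with fewer than `n_min`
#' lithology-known occurrences are withheld (`SRA = NA`,
#' `flag = "n_below_min"`). Reproducible given `seed`.
#'
#' @param k Carbonate occurrences of the family in the interval.
#' @param n Lithology-known occurrences of the family (`k <= n`).
#' @param pi Background carbonate proportion in (0, 1).
#' @param B Null replicates (default 5000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param n_min Minimum sample size (default 5).
#' @return A one-row tibble: `n`, `k`, `pi`, `ra`, `sra`, `B`, `flag`.
#' @export
sra <- function(k, n, pi, B = 5000, seed = NULL, n_min = 5) {
  if (k < 0 || k > n) abort_pd("k must lie in [0, n]", "pd_input_error")
  if (pi <= 0 || pi >= 1) abort_pd("pi must lie in (0, 1)", "pd_input_error")
  ra <- k / n - pi
  if (n < n_min) {
    return(tibble(n = n, k = k, pi = pi, ra = ra, sra = NA_real_, B = B,
                  flag = "n_below_min"))
  }
  if (!is.null(seed)) set.seed(seed)
  k_null <- stats::rbinom(B, n, pi)
  ra_null <- k_null / n - pi
  s <- stats::sd(ra_null)
  tibble(
    n = n, k = k, pi = pi, ra = ra,
    sra = if (s > 0) (ra - mean(ra_null)) / s else NA_real_,
    B = B,
    flag = if (s > 0) NA_character_ else "degenerate_null"
  )
}

#' Substrate affinity of families through time, per dataset
#'
#' Computes the SRA of each requested family in each interval (the `bin`
#' column; conventionally a series- or sub-period-level binning) for each
#' dataset, against a background proportion taken from the combined
#' dataset's interval pool (or a user-supplied reference).
#'
#' @param partition A [partition_datasets()] result, binned at the interval
#'   level used for affinity.
#' @param families Character vector of family names to analyse; `NULL`
#'   analyses every family meeting `n_min` in at least one interval.
#' @param B,n_min,seed Passed to [sra()].
#' @param reference Optional occurrence tibble to use as the background
#'   pool instead of the combined dataset.
#' @return A tibble: `dataset`, `family`, `bin`, `n`, `k`, `pi`, `ra`,
#'   `sra`, `flag`.
#' @export
substrate_affinity <- function(partition, families = NULL, B = 5000,
                               n_min = 5, seed = 1, reference = NULL) {
  ref_all <- reference %||% partition$D
  datasets <- list(dark = partition$A, published = partition$B,
                   pbdb = partition$C, total = partition$D)
  if (is.null(families)) {
    fam_all <- partition$D
    fam_all$fam <- taxon_at_rank(fam_all, "family")
    families <- fam_all %>%
      filter(!is.na(.data$fam)) %>%
      pull("fam") %>%
      unique() %>%
      sort()
  }
  set.seed(seed)
  purrr::imap(datasets, function(occ, label) {
    occ$fam <- taxon_at_rank(occ, "family")
    occ <- occ %>%
      filter(!is.na(.data$bin), !is.na(.data$fam), .data$fam %in% families,
             .data$lithology %in% c("carbonate", "siliciclastic"))
    if (nrow(occ) == 0) return(tibble())
    grid <- distinct(occ, .data$fam, .data$bin)
    purrr::pmap(grid, function(fam, bin) {
      bg <- background_proportion(filter(ref_all, !is.na(.data$bin), .data$bin == !!bin))
      rows <- occ[occ$fam == fam & occ$bin == bin, ]
      n <- nrow(rows)
      k <- sum(rows$lithology == "carbonate")
      if (!bg$analysable) {
        return(tibble(dataset = label, family = fam, bin = bin, n = n, k = k,
                      pi = bg$pi, ra = NA_real_, sra = NA_real_,
                      flag = "background_unanalysable"))
      }
      res <- sra(k, n, bg$pi, B = B, n_min = n_min)
      mutate(res, dataset = label, family = fam, bin = bin, .before = 1) %>%
        select("dataset", "family", "bin", "n", "k", "pi", "ra", "sra", "flag")
    }) %>%
      bind_rows()
  }) %>%
    bind_rows()
}
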