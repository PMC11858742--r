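# Metadata composition of the datasets and the statistical comparisons
# between them: chi-squared on category counts, Kruskal-Wallis / Wilcoxon on
# ordinal grades, and the domestic/foreign repository breakdown.

#' Category proportions of a metadata variable per dataset
#'
#' Computes per-dataset proportions of `lithology`, `grainsize`, `rank` or
#' (given a specimen table) `taph_grade`. Proportions are over rows with a
#' known value; the unknown share is reported separately so known-category
#' proportions sum to 1. `unit = "specimen"` weights occurrence-level
#' variables by `n_specimens`; taphonomic grade is inherently specimen-level
#' and requires `specimens`.
#'
#' @param partition A [partition_datasets()] result.
#' @param variable One of `"lithology"`, `"grainsize"`, `"rank"`,
#'   `"taph_grade"`.
#' @param unit `"occurrence"` or `"specimen"`.
#' @param specimens Specimen tibble (`occurrence_id`, `taph_grade`);
#'   required for `variable = "taph_grade"`.
#' @return A tibble: `dataset`, `category`, `n`, `proportion`,
#'   `unknown_share`.
#' @export
composition_table <- function(partition,
                              variable = c("lithology", "grainsize", "rank", "taph_grade"),
                              unit = c("occurrence", "specimen"),
                              specimens = NULL) {
  variable <- arg_match(variable)
  unit <- arg_match(unit)
  if (variable == "taph_grade") {
    if (is.null(specimens)) {
      abort_pd("taph_grade composition needs the specimen table", "pd_input_error")
    }
    unit <- "specimen"
  }
  purrr::map(names(partition), function(ds) {
    occ <- partition[[ds]]
    if (nrow(occ) == 0) {
      return(tibble(dataset = ds, category = NA_character_, n = 0,
                    proportion = NA_real_, unknown_share = NA_real_,
                    empty = TRUE))
    }
    if (variable == "taph_grade") {
      values <- specimens %>%
        filter(.data$occurrence_id %in% occ$occurrence_id) %>%
        pull("taph_grade") %>%
        as.character()
      w <- rep(1, length(values))
    } else {
      values <- occ[[variable]]
      w <- if (unit == "specimen") occ$n_specimens else rep(1, nrow(occ))
    }
    known <- !is.na(values) & values != "unknown"
    total <- sum(w)
    known_total <- sum(w[known])
    if (known_total == 0) {
      return(tibble(dataset = ds, category = NA_character_, n = 0,
                    proportion = NA_real_, unknown_share = 1, empty = FALSE))
    }
    tibble(category = values[known], w = w[known]) %>%
      group_by(.data$category) %>%
      summarise(n = sum(.data$w), .groups = "drop") %>%
      mutate(
        dataset = ds,
        proportion = .data$n / known_total,
        unknown_share = (total - known_total) / total,
        empty = FALSE
      ) %>%
      select("dataset", "category", "n", "proportion", "unknown_share", "empty")
  }) %>%
    bind_rows()
}

#' Pearson chi-squared test on a category-by-dataset count matrix
#'
#' @param counts Non-negative count matrix with at least two rows and two
#'   columns; margins must all be positive.
#' @return A one-row tibble: `statistic` (X^2), `df`, `p_value`, `n`,
#'   `method`.
#' @export
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort_pd("chi-squared needs at least a 2 x 2 count matrix", "pd_input_error")
  }
  if (any(counts < 0)) abort_pd("counts must be non-negative", "pd_input_error")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_pd("chi-squared undefined with an all-zero row or column", "pd_input_error")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n = sum(counts),
    method = "Pearson chi-squared"
  )
}

# Qualitative label for epsilon-squared.
effect_label <- function(eps2) {
  case_when(
    eps2 >= 0.26 ~ "large",
    eps2 >= 0.08 ~ "medium",
    eps2 >= 0.01 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Kruskal-Wallis rank test with epsilon-squared effect size
#'
#' Tie-corrected H statistic across two or more groups, with the
#' epsilon-squared effect size \eqn{\epsilon^2 = H / (n - 1)} and a
#' qualitative label (small/medium/large at 0.01/0.08/0.26).
#'
#' @param values Numeric (or ordinal-coded) observations.
#' @param groups Group labels, same length as `values`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`,
#'   `epsilon_squared`, `effect`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort_pd("Kruskal-Wallis needs at least two non-empty groups", "pd_input_error")
  }
  ht <- stats::kruskal.test(values, groups)
  n <- length(values)
  eps2 <- unname(ht$statistic) / (n - 1)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    epsilon_squared = eps2,
    effect = effect_label(eps2),
    n = n,
    method = "Kruskal-Wallis"
  )
}

#' Wilcoxon rank-sum test for two groups
#'
#' @param x,y Numeric observations for the two groups (non-empty).
#' @return A one-row tibble: `statistic` (W), `p_value`, `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort_pd("both groups must be non-empty", "pd_input_error")
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = length(x) + length(y),
    method = "Wilcoxon rank-sum"
  )
}

#' Domestic versus foreign repository contributions per country
#'
#' For each dataset, credits every occurrence to its housing country and
#' splits that country's share into domestic (found and housed in the same
#' country) and foreign (found elsewhere) contributions, as percentages of
#' the dataset's occurrences with both countries known. Rows with a missing
#' country are excluded and counted.
#'
#' @param partition A [partition_datasets()] result.
#' @param top_k Number of top housing countries to return per dataset.
#' @return A tibble: `dataset`, `country_housed`, `origin`
#'   (domestic/foreign), `n`, `percent`; attribute `"excluded"` counts
#'   rows dropped per dataset for missing countries.
#' @export
domestic_foreign <- function(partition, top_k = 15) {
  excluded <- integer(0)
  out <- purrr::map(names(partition), function(ds) {
    occ <- partition[[ds]]
    ok <- !is.na(occ$country_found) & occ$country_found != "" &
      !is.na(occ$country_housed) & occ$country_housed != ""
    excluded[ds] <<- sum(!ok)
    occ <- occ[ok, ]
    if (nrow(occ) == 0) return(tibble())
    tab <- occ %>%
      mutate(origin = if_else(.data$country_found == .data$country_housed,
                              "domestic", "foreign")) %>%
      count(.data$country_housed, .data$origin, name = "n") %>%
      mutate(dataset = ds, percent = 100 * .data$n / sum(.data$n))
    top <- tab %>%
      group_by(.data$country_housed) %>%
      summarise(tot = sum(.data$percent), .groups = "drop") %>%
      arrange(dplyr::desc(.data$tot)) %>%
      slice(seq_len(min(top_k, dplyr::n()))) %>%
      pull("country_housed")
    filter(tab, .data$country_housed %in% top) %>%
      select("dataset", "country_housed", "origin", "n", "percent")
  }) %>%
    bind_rows()
  attr(out, "excluded") <- excluded
  out
}
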