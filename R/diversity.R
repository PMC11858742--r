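# Richness through time: raw sampled-in-bin counts and coverage-based
# (quorum-standardised) rarefaction of incidence-frequency data, with Chao2
# extrapolation beyond the observed number of sampling units.
#
# Incidence notation per bin: T sampling units (collections), Y_i the number
# of units containing taxon i, U = sum(Y_i), Q1/Q2 the counts of taxa found
# in exactly one / two units.

#' Raw per-bin diversity and collection counts
#'
#' Sampled-in-bin distinct taxon and collection counts for each dataset.
#'
#' @param partition A [partition_datasets()] result, binned.
#' @param rank Taxonomic rank for the richness count.
#' @return A tibble: `dataset`, `bin`, `bin_midpoint`, `richness`,
#'   `collections`, `occurrences`.
#' @export
raw_diversity <- function(partition, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  purrr::imap(
    list(dark = partition$A, published = partition$B,
         pbdb = partition$C, total = partition$D),
    function(occ, label) {
      occ$taxon <- taxon_at_rank(occ, rank)
      occ %>%
        filter(!is.na(.data$bin)) %>%
        group_by(.data$bin, .data$bin_midpoint) %>%
        summarise(
          richness = n_distinct(.data$taxon[!is.na(.data$taxon)]),
          collections = n_distinct(.data$collection_id),
          occurrences = dplyr::n(),
          .groups = "drop"
        ) %>%
        mutate(dataset = label, .before = 1)
    }
  ) %>%
    bind_rows()
}

#' Incidence-frequency summary of one bin
#'
#' @param occ Occurrences of a single bin (one dataset).
#' @param rank Taxonomic rank.
#' @return A list of class `"incidence_summary"`: `T` (sampling units =
#'   collections), `Y` (named incidence frequencies), `U`, `S_obs`, `Q1`,
#'   `Q2`.
#' @export
incidence_summary <- function(occ, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  occ$taxon <- taxon_at_rank(occ, rank)
  tab <- occ %>%
    filter(!is.na(.data$taxon)) %>%
    distinct(.data$taxon, .data$collection_id)
  T_units <- n_distinct(occ$collection_id)
  Y <- table(tab$taxon)
  new_incidence(T_units, setNames(as.integer(Y), names(Y)))
}

new_incidence <- function(T_units, Y) {
  Y <- Y[Y > 0]
  structure(
    list(
      T = as.integer(T_units),
      Y = Y,
      U = sum(Y),
      S_obs = length(Y),
      Q1 = sum(Y == 1),
      Q2 = sum(Y == 2)
    ),
    class = "incidence_summary"
  )
}

#' Build an incidence summary from a taxon-by-collection matrix
#'
#' @param mat Binary (or count, truncated to presence) matrix, rows = taxa,
#'   columns = sampling units.
#' @return An `"incidence_summary"`.
#' @export
incidence_from_matrix <- function(mat) {
  mat <- as.matrix(mat) > 0
  Y <- rowSums(mat)
  names(Y) <- rownames(mat) %||% paste0("t", seq_len(nrow(mat)))
  new_incidence(ncol(mat), Y[Y > 0])
}

#' Estimated sample coverage of the full incidence sample
#'
#' The incidence analogue of Good-Turing coverage:
#' \deqn{\hat C(T) = 1 - \frac{Q_1}{U}\,
#'   \frac{(T-1)Q_1}{(T-1)Q_1 + 2 Q_2}.}
#'
#' @param inc An `"incidence_summary"`.
#' @return Coverage estimate in \[0, 1\].
#' @export
coverage_estimate <- function(inc) {
  if (inc$U == 0) abort_pd("coverage undefined with U = 0", "pd_input_error")
  if (inc$T < 2) abort_pd("coverage needs T >= 2 sampling units", "pd_input_error")
  if (inc$Q1 == 0) return(1)
  A <- (inc$T - 1) * inc$Q1 / ((inc$T - 1) * inc$Q1 + 2 * inc$Q2)
  1 - inc$Q1 / inc$U * A
}

# log C(a, t) / C(b, t) with real-valued t (gamma continuation); zero when
# t > a.
lchoose_ratio <- function(a, b, t) {
  out <- lgamma(a + 1) - lgamma(a - t + 1) - lgamma(b + 1) + lgamma(b - t + 1)
  out[t > a + 1e-12] <- -Inf
  out
}

#' Rarefied or extrapolated richness at t sampling units
#'
#' For `t <= T` the exact hypergeometric expectation
#' \deqn{S(t) = S_{obs} - \sum_i \binom{T-Y_i}{t} / \binom{T}{t},}
#' continued to real `t` through the gamma function. For `t > T`, Chao2-based
#' extrapolation
#' \deqn{S(T+m) = S_{obs} + \hat Q_0 \left[1 - \left(1 -
#'   \frac{Q_1}{Q_1 + T \hat Q_0}\right)^m\right],}
#' with \eqn{\hat Q_0 = \frac{T-1}{T} Q_1^2 / (2 Q_2)} (and the bias-corrected
#' fallback \eqn{\frac{T-1}{T} Q_1 (Q_1 - 1) / 2} when `Q2 = 0`).
#'
#' @param inc An `"incidence_summary"`.
#' @param t Number of sampling units (>= 1; may be fractional).
#' @return Expected richness (vectorised over `t`).
#' @export
rarefy_richness <- function(inc, t) {
  if (any(t < 1)) abort_pd("t must be >= 1", "pd_input_error")
  vapply(t, function(ti) {
    if (ti <= inc$T) {
      ratio <- exp(lchoose_ratio(inc$T - inc$Y, inc$T, ti))
      inc$S_obs - sum(ratio)
    } else {
      m <- ti - inc$T
      Q0 <- chao2_q0(inc)
      if (Q0 == 0) return(as.numeric(inc$S_obs))
      inc$S_obs + Q0 * (1 - (1 - inc$Q1 / (inc$Q1 + inc$T * Q0))^m)
    }
  }, numeric(1))
}

chao2_q0 <- function(inc) {
  if (inc$Q1 == 0) return(0)
  if (inc$Q2 > 0) {
    (inc$T - 1) / inc$T * inc$Q1^2 / (2 * inc$Q2)
  } else {
    (inc$T - 1) / inc$T * inc$Q1 * (inc$Q1 - 1) / 2
  }
}

# Expected coverage of a rarefied (t < T) or extrapolated (t >= T) sample,
# continuous and nondecreasing in t.
coverage_at <- function(inc, t) {
  vapply(t, function(ti) {
    if (ti < inc$T) {
      ratio <- exp(lchoose_ratio(inc$T - inc$Y, inc$T - 1, ti))
      1 - sum(inc$Y / inc$U * ratio)
    } else {
      if (inc$Q1 == 0) return(1)
      A <- (inc$T - 1) * inc$Q1 / ((inc$T - 1) * inc$Q1 + 2 * inc$Q2)
      1 - inc$Q1 / inc$U * A^(ti - inc$T + 1)
    }
  }, numeric(1))
}

#' Coverage-standardised richness at a quorum level
#'
#' Inverts the coverage curve to find the effective number of sampling units
#' `t*` at which the expected coverage equals the quorum `q` (bisection for
#' the rarefaction branch; closed form for the extrapolation branch), then
#' returns the rarefied/extrapolated richness at `t*`. Extrapolations beyond
#' `2T` are flagged; bins with too little data (`T < 3`, or all taxa
#' singletons so that coverage never reaches `q`) are reported as missing.
#'
#' @param inc An `"incidence_summary"`.
#' @param q Coverage quorum in (0, 1).
#' @param max_extrapolation Multiple of `T` beyond which the estimate is
#'   flagged (default 2).
#' @return A one-row tibble: `quorum`, `t_star`, `richness`, `coverage_T`,
#'   `type` (`"interpolated"`/`"extrapolated"`/`"observed"`), `flag`
#'   (`NA`, `"beyond_2T"` or `"insufficient_data"`).
#' @export
estimate_at_quorum <- function(inc, q, max_extrapolation = 2) {
  if (q <= 0 || q >= 1) abort_pd("quorum must lie in (0, 1)", "pd_input_error")
  miss <- tibble(quorum = q, t_star = NA_real_, richness = NA_real_,
                 coverage_T = NA_real_, type = NA_character_,
                 flag = "insufficient_data")
  if (inc$T < 3 || inc$U == 0) return(miss)
  cT <- coverage_estimate(inc)
  if (inc$Q1 == inc$U) return(miss) # all taxa singletons: coverage stuck at 0
  if (abs(q - cT) < 1e-12) {
    return(tibble(quorum = q, t_star = as.numeric(inc$T),
                  richness = as.numeric(inc$S_obs), coverage_T = cT,
                  type = "observed", flag = NA_character_))
  }
  if (q < cT) {
    c1 <- coverage_at(inc, 1)
    if (q <= c1) {
      t_star <- 1
    } else {
      t_star <- stats::uniroot(
        function(t) coverage_at(inc, t) - q,
        lower = 1, upper = inc$T, tol = 1e-9
      )$root
    }
    type <- "interpolated"
  } else {
    # extrapolation branch: 1 - (Q1/U) A^(t - T + 1) = q
    A <- (inc$T - 1) * inc$Q1 / ((inc$T - 1) * inc$Q1 + 2 * inc$Q2)
    if (inc$Q1 == 0 || A >= 1) return(miss)
    t_star <- inc$T - 1 + log(inc$U / inc$Q1 * (1 - q)) / log(A)
    type <- "extrapolated"
  }
  flag <- if (t_star > max_extrapolation * inc$T) "beyond_2T" else NA_character_
  tibble(
    quorum = q, t_star = t_star,
    richness = rarefy_richness(inc, t_star),
    coverage_T = cT, type = type, flag = flag
  )
}

#' Coverage-based rarefaction across datasets, bins and quorum levels
#'
#' @param partition A [partition_datasets()] result, binned.
#' @param rank Taxonomic rank.
#' @param quorum Quorum levels (default `c(0.4, 0.5, 0.6)`).
#' @param min_T Minimum sampling units per bin (default 3); smaller bins
#'   are reported as missing.
#' @return A tibble keyed by `dataset`, `bin`, `quorum` with the
#'   [estimate_at_quorum()] columns.
#' @export
diversity_at_quorum <- function(partition, rank = c("genus", "family", "species"),
                                quorum = c(0.4, 0.5, 0.6), min_T = 3) {
  rank <- arg_match(rank)
  datasets <- list(dark = partition$A, published = partition$B,
                   pbdb = partition$C, total = partition$D)
  purrr::imap(datasets, function(occ, label) {
    occ <- filter(occ, !is.na(.data$bin))
    purrr::map(unique(occ$bin), function(b) {
      inc <- incidence_summary(filter(occ, .data$bin == b), rank)
      purrr::map(quorum, function(q) {
        if (inc$T < min_T || inc$S_obs == 0) {
          tibble(quorum = q, t_star = NA_real_, richness = NA_real_,
                 coverage_T = NA_real_, type = NA_character_,
                 flag = "insufficient_data")
        } else {
          estimate_at_quorum(inc, q)
        }
      }) %>%
        bind_rows() %>%
        mutate(dataset = label, bin = b, .before = 1)
    }) %>%
      bind_rows()
  }) %>%
    bind_rows()
}

#' Good's u coverage proxy for a set of occurrences
#'
#' `u = 1 - (number of taxa occurring exactly once) / (total occurrences)`.
#'
#' @param occ Occurrence tibble (one bin, one dataset).
#' @param rank Taxonomic rank.
#' @return Good's u in \[0, 1\], or `NA` for an empty input.
#' @export
goods_u <- function(occ, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  taxa <- taxon_at_rank(occ, rank)
  taxa <- taxa[!is.na(taxa)]
  if (length(taxa) == 0) return(NA_real_)
  tab <- table(taxa)
  1 - sum(tab == 1) / length(taxa)
}

#' Spearman correlations between diversity series with BH correction
#'
#' Runs Spearman rank correlations between a reference series and each
#' candidate series after a log transform, on pairwise-complete bins, and
#' adjusts the p-values across the submitted batch with the
#' Benjamini-Hochberg procedure.
#'
#' @param series A tibble with a `bin` column, a reference column `ref`,
#'   and one column per comparison series.
#' @param ref Name of the reference column.
#' @param transform `"log"` (default; requires positive values, zeros use
#'   log1p with a note) or `"none"`.
#' @return A tibble: `series`, `n`, `rho`, `p_value`, `p_adjusted`,
#'   `transform`.
#' @export
correlate_series <- function(series, ref, transform = c("log", "none")) {
  transform <- arg_match(transform)
  candidates <- setdiff(names(series), c("bin", ref))
  tf <- function(x) {
    if (transform == "none") return(list(x = x, note = "none"))
    if (any(x < 0, na.rm = TRUE)) {
      abort_pd("log transform undefined for negative values", "pd_input_error")
    }
    if (any(x == 0, na.rm = TRUE)) list(x = log1p(x), note = "log1p")
    else list(x = log(x), note = "log")
  }
  out <- purrr::map(candidates, function(colname) {
    ok <- stats::complete.cases(series[[ref]], series[[colname]])
    if (sum(ok) < 4) {
      return(tibble(series = colname, n = sum(ok), rho = NA_real_,
                    p_value = NA_real_, transform = NA_character_))
    }
    x <- tf(series[[ref]][ok])
    y <- tf(series[[colname]][ok])
    if (stats::sd(x$x) == 0 || stats::sd(y$x) == 0) {
      return(tibble(series = colname, n = sum(ok), rho = NA_real_,
                    p_value = NA_real_, transform = "constant"))
    }
    ht <- suppressWarnings(stats::cor.test(x$x, y$x, method = "spearman"))
    tibble(series = colname, n = sum(ok), rho = unname(ht$estimate),
           p_value = ht$p.value, transform = paste(x$note, y$note, sep = "/"))
  }) %>%
    bind_rows()
  mutate(out, p_adjusted = stats::p.adjust(.data$p_value, method = "BH"))
}
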