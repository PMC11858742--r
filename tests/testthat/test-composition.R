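make_lith_partition <- function() {
  occ <- validate_occurrences(dplyr::bind_rows(
    make_occ(20, lithology = c(rep("carbonate", 17), rep("siliciclastic", 3))),
    make_occ(10, in_dark = FALSE, in_published = TRUE,
             lithology = c(rep("carbonate", 4), rep("siliciclastic", 6))) |>
      dplyr::mutate(occurrence_id = paste0("p", 1:10))
  ))
  partition_datasets(occ)
}

test_that("composition tables report known-category proportions and unknown share", {
  part <- make_lith_partition()
  tab <- composition_table(part, "lithology")
  dark <- dplyr::filter(tab, dataset == "A")
  expect_equal(dark$proportion[dark$category == "carbonate"], 0.85)
  expect_equal(dark$proportion[dark$category == "siliciclastic"], 0.15)
  expect_equal(sum(dark$proportion), 1, tolerance = 1e-12)

  # all-unknown dataset: no category rows carry mass, unknown share = 1
  occ_u <- validate_occurrences(dplyr::bind_rows(
    make_occ(3, lithology = "unknown"),
    make_occ(1, in_dark = FALSE, in_published = TRUE,
             occurrence_id = "pX")
  ))
  tab_u <- composition_table(partition_datasets(occ_u), "lithology")
  expect_equal(dplyr::filter(tab_u, dataset == "A")$unknown_share, 1)

  # specimen unit weights by n_specimens
  occ_w <- validate_occurrences(dplyr::bind_rows(
    make_occ(2, lithology = c("carbonate", "siliciclastic"),
             n_specimens = c(9, 1)),
    make_occ(1, in_dark = FALSE, in_published = TRUE, occurrence_id = "pY")
  ))
  tab_w <- composition_table(partition_datasets(occ_w), "lithology",
                             unit = "specimen")
  expect_equal(
    dplyr::filter(tab_w, dataset == "A", category == "carbonate")$proportion,
    0.9
  )
})

test_that("chi-squared matches hand computations and is permutation invariant", {
  expect_equal(chi_squared(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_squared(matrix(10, 2, 2))$p_value, 1)

  perfect <- chi_squared(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(perfect$statistic, 40) # perfect 2x2 association gives X^2 = n
  expect_equal(perfect$df, 1)

  expect_equal(chi_squared(matrix(7, 3, 2))$statistic, 0)

  m <- matrix(c(12, 5, 9, 3, 14, 8), 3, 2)
  ref <- chi_squared(m)
  perm <- chi_squared(m[c(3, 1, 2), c(2, 1)])
  expect_equal(perm$statistic, ref$statistic, tolerance = 1e-12)

  expect_error(chi_squared(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE)),
               class = "pd_input_error")
  expect_error(chi_squared(matrix(1:3, 3, 1)), class = "pd_input_error")
})

test_that("Kruskal-Wallis reports tie-corrected H with epsilon-squared", {
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  set.seed(1)
  v <- c(rnorm(16), rnorm(15, 2))
  g <- rep(c("a", "b"), c(16, 15))
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$epsilon_squared, kw$statistic / (kw$n - 1)) # n = 31
  expect_true(kw$effect %in% c("negligible", "small", "medium", "large"))
  # epsilon^2 of H = 3 at n = 31 would be exactly 0.1 under the same formula
  expect_equal(3 / (31 - 1), 0.1)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), class = "pd_input_error")
})

test_that("rank-sum p for disjoint-support groups matches exact enumeration", {
  x <- 1:10
  y <- 101:110
  res <- wilcoxon_rank_sum(x, y)
  # exact two-sided p for complete separation: 2 / choose(20, 10)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_error(wilcoxon_rank_sum(numeric(0), y), class = "pd_input_error")
})

test_that("domestic/foreign split credits the housing country", {
  occ <- validate_occurrences(dplyr::bind_rows(
    make_occ(3, country_found = "US", country_housed = "US"),
    make_occ(2, country_found = "GB", country_housed = "US",
             occurrence_id = c("f1", "f2")),
    make_occ(1, in_dark = FALSE, in_published = TRUE, occurrence_id = "pZ",
             country_found = "DE", country_housed = "DE")
  ))
  tab <- domestic_foreign(partition_datasets(occ))
  dark <- dplyr::filter(tab, dataset == "A")
  expect_equal(sum(dark$percent), 100)
  expect_equal(dplyr::filter(dark, origin == "domestic")$n, 3)
  expect_equal(dplyr::filter(dark, origin == "foreign")$n, 2)
  expect_true(all(dark$country_housed == "US")) # foreign rows credited to US

  pub <- dplyr::filter(tab, dataset == "B")
  expect_equal(pub$percent, 100)
  expect_equal(pub$origin, "domestic")
})

test_that("composition tests are calibrated under a null (no channel bias) scenario", {
  # identical channel configurations: lithology should differ only by chance
  n_sig <- 0
  for (i in 1:30) {
    taxa <- generate_taxa(15, seed = 100 + i, affinity_range = c(0.5, 0.5))
    ch <- default_channels()
    ch$dark <- channel_config(n_occurrences = 250, carbonate_prob = 0.6)
    ch$published <- channel_config(n_occurrences = 250, carbonate_prob = 0.6)
    sim <- sample_occurrences(taxa, ch, seed = 200 + i)
    occ <- dplyr::filter(sim$occurrences, lithology != "unknown")
    tab <- table(occ$lithology, occ$in_dark)
    p <- chi_squared(tab)$p_value
    if (p < 0.05) n_sig <- n_sig + 1
  }
  # binomial(30, 0.05): P(X > 6) < 1e-3
  expect_lte(n_sig, 6)
})
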