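random_incidence <- function(S, T, p = 0.15) {
  mat <- matrix(rbinom(S * T, 1, p), S, T)
  mat[rowSums(mat) > 0, , drop = FALSE]
}

test_that("raw diversity counts distinct taxa and collections per bin", {
  occ <- assign_bins(validate_occurrences(make_occ(
    4, genus = c("a", "b", "b", "c"),
    collection_id = c("c1", "c1", "c2", "c2")
  )), carboniferous_bins())
  out <- raw_diversity(partition_datasets(occ), "genus")
  dark <- dplyr::filter(out, dataset == "dark")
  expect_equal(dark$richness, 3)
  expect_equal(dark$collections, 2)
  pub <- dplyr::filter(out, dataset == "published")
  expect_equal(nrow(pub), 0) # empty dataset: no bins
})

test_that("coverage estimates match the closed form and its limits", {
  # Q1 = 0: complete coverage
  inc0 <- incidence_from_matrix(rbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(coverage_estimate(inc0), 1)

  # all singletons, Q2 = 0: coverage 0
  inc1 <- incidence_from_matrix(diag(3))
  expect_equal(coverage_estimate(inc1), 0)

  # random matrices: independent recomputation of the estimator
  set.seed(31)
  for (i in 1:10) {
    mat <- random_incidence(25, 40)
    inc <- incidence_from_matrix(mat)
    Y <- rowSums(mat > 0); U <- sum(Y); T <- ncol(mat)
    Q1 <- sum(Y == 1); Q2 <- sum(Y == 2)
    expected <- if (Q1 == 0) 1 else {
      1 - Q1 / U * ((T - 1) * Q1 / ((T - 1) * Q1 + 2 * Q2))
    }
    expect_equal(coverage_estimate(inc), expected, tolerance = 1e-12)
  }
})

test_that("interpolated richness matches its sampling expectations", {
  set.seed(37)
  mat <- random_incidence(30, 50, 0.12)
  inc <- incidence_from_matrix(mat)
  T <- ncol(mat)

  expect_equal(rarefy_richness(inc, T), inc$S_obs, tolerance = 1e-9)
  expect_equal(rarefy_richness(inc, 1), inc$U / T, tolerance = 1e-9)

  # brute-force subsampling oracle at t = T/2
  reps <- 3000
  sub <- replicate(reps, sum(rowSums(mat[, sample(T, T / 2), drop = FALSE]) > 0))
  se <- sd(sub) / sqrt(reps)
  expect_lt(abs(rarefy_richness(inc, T / 2) - mean(sub)), 3 * se + 0.02)

  # nondecreasing and concave in t
  tt <- 1:T
  s <- rarefy_richness(inc, tt)
  expect_true(all(diff(s) > -1e-9))
  expect_true(all(diff(diff(s)) < 1e-9))

  expect_error(rarefy_richness(inc, 0.5), class = "pd_input_error")
})

test_that("extrapolation continues the curve and respects the Chao2 ceiling", {
  set.seed(41)
  mat <- random_incidence(30, 30, 0.1)
  inc <- incidence_from_matrix(mat)
  s_T <- rarefy_richness(inc, inc$T)
  s_2T <- rarefy_richness(inc, 2 * inc$T)
  expect_gte(s_2T, s_T)
  Q0 <- palaeodark:::chao2_q0(inc)
  expect_lte(s_2T, inc$S_obs + Q0 + 1e-9)
  # continuity at the T boundary
  expect_equal(rarefy_richness(inc, inc$T + 1e-9), s_T, tolerance = 1e-6)
})

test_that("quorum estimates invert the coverage curve", {
  set.seed(44)
  mat <- random_incidence(40, 45, 0.06) # sparse, so singletons exist
  inc <- incidence_from_matrix(mat)
  cT <- coverage_estimate(inc)
  expect_lt(cT, 1)

  # fixed point: quorum at the observed coverage returns S_obs
  at_cT <- estimate_at_quorum(inc, cT)
  expect_equal(at_cT$richness, inc$S_obs, tolerance = 1e-6)
  expect_equal(at_cT$t_star, inc$T)

  # round trip within 1e-6 on the rarefaction and extrapolation branches
  for (q in c(0.5, 0.7, (cT + 1) / 2)) {
    est <- estimate_at_quorum(inc, q)
    expect_equal(palaeodark:::coverage_at(inc, est$t_star), q, tolerance = 1e-6)
  }
  expect_equal(estimate_at_quorum(inc, (cT + 1) / 2)$type, "extrapolated")

  # monotone in the quorum
  qs <- c(0.3, 0.5, 0.7, 0.9)
  rich <- vapply(qs, function(q) estimate_at_quorum(inc, q)$richness, numeric(1))
  expect_true(all(diff(rich) > -1e-9))

  # an all-singleton bin cannot reach any quorum
  lonely <- incidence_from_matrix(diag(5))
  expect_equal(estimate_at_quorum(lonely, 0.5)$flag, "insufficient_data")
})

test_that("quorum-standardised estimates are invariant to row order and duplication", {
  sim <- simulate_scenario(small_scenario(), seed = 29)
  occ <- assign_bins(deduplicate_occurrences(sim$occurrences),
                     palaeozoic_bins("sub_period"))
  part1 <- partition_datasets(occ)
  part2 <- partition_datasets(occ[sample(nrow(occ)), ])
  q1 <- diversity_at_quorum(part1, quorum = 0.5)
  q2 <- diversity_at_quorum(part2, quorum = 0.5)
  j <- dplyr::inner_join(q1, q2, by = c("dataset", "bin", "quorum"))
  expect_equal(j$richness.x, j$richness.y, tolerance = 1e-9)
})

test_that("Good's u counts singletons against total occurrences", {
  occ_all_single <- make_occ(4, genus = c("a", "b", "c", "d"))
  expect_equal(goods_u(occ_all_single, "genus"), 0)
  occ_none <- make_occ(4, genus = c("a", "a", "b", "b"))
  expect_equal(goods_u(occ_none, "genus"), 1)
  occ_mix <- make_occ(10, genus = c(rep("a", 5), rep("b", 3), "c", "d"))
  expect_equal(goods_u(occ_mix, "genus"), 0.8)
  expect_true(is.na(goods_u(make_occ(1, rank = "above_family", genus = ""))))
})

test_that("Spearman correlations use log transforms and BH adjustment", {
  d <- tibble::tibble(bin = letters[1:8], total = c(2, 4, 6, 8, 10, 12, 14, 16))
  d$double <- 2 * d$total
  d$noise <- c(5, 3, 8, 1, 9, 2, 7, 4)
  out <- correlate_series(d, ref = "total")
  expect_equal(dplyr::filter(out, series == "double")$rho, 1)
  # BH preserves the p-value ordering
  ord <- order(out$p_value)
  expect_equal(order(out$p_adjusted), ord)
  # a batch of one test keeps its raw p
  one <- correlate_series(d[, c("bin", "total", "double")], ref = "total")
  expect_equal(one$p_adjusted, one$p_value)
  # constant series flagged
  d$flat <- 1
  flat <- dplyr::filter(correlate_series(d, ref = "total"), series == "flat")
  expect_true(is.na(flat$rho))
})
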