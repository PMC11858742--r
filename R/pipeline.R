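# End-to-end orchestration: ingest (or simulate) -> dedup -> bin ->
# partition -> composition -> biogeography -> temporal -> diversity ->
# affinity -> drivers, one tidy CSV per stage plus a JSON manifest.

#' Assemble an analysis configuration
#'
#' @param occurrences Path to a canonical occurrence CSV, or an occurrence
#'   tibble.
#' @param specimens Optional specimen CSV path or tibble (needed for
#'   taphonomic composition).
#' @param bins `"stage"`, `"sub_period"`, a CSV path, or a time-bin tibble.
#' @param affinity_bins Interval table for substrate affinity (default
#'   `"sub_period"`).
#' @param covariates Optional covariate CSV path or tibble (bin-aligned,
#'   `bin` column) for the driver models.
#' @param resolution Occupancy grid resolution, degrees.
#' @param quorum Coverage quorum levels.
#' @param rank Analysis rank for ranges/diversity.
#' @param sra_B,sra_n_min SRA null replicates and minimum sample size.
#' @param max_bins_filter Temporal-range taxon filter (see
#'   [range_overlap_time()]).
#' @param countries_top_k Top housing countries reported.
#' @param seed Integer seed propagated to all stochastic stages.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(occurrences, specimens = NULL, bins = "stage",
                            affinity_bins = "sub_period", covariates = NULL,
                            resolution = 1, quorum = c(0.4, 0.5, 0.6),
                            rank = "genus", sra_B = 5000, sra_n_min = 5,
                            max_bins_filter = 2, countries_top_k = 15,
                            seed = 1) {
  structure(
    list(
      occurrences = occurrences, specimens = specimens, bins = bins,
      affinity_bins = affinity_bins, covariates = covariates,
      resolution = resolution, quorum = quorum, rank = rank,
      sra_B = sra_B, sra_n_min = sra_n_min,
      max_bins_filter = max_bins_filter, countries_top_k = countries_top_k,
      seed = seed
    ),
    class = "analysis_config"
  )
}

resolve_bins <- function(spec) {
  if (is.data.frame(spec)) return(validate_time_bins(spec))
  if (spec %in% c("stage", "sub_period")) return(palaeozoic_bins(spec))
  read_time_bins(spec)
}

resolve_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(as_tibble(x))
  reader(x)
}

#' Run the full dark-data comparison pipeline
#'
#' Executes every stage on one occurrence dataset and, when `out_dir` is
#' given, writes one tidy CSV per stage plus a JSON manifest recording the
#' seed, row counts and dropped-row accounting. Stage errors abort with a
#' stage-tagged message; outputs written before the failure are retained
#' next to a `FAILED` marker file.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory.
#' @return A list of stage results: `partition`, `composition`,
#'   `composition_tests`, `countries`, `occupancy`, `geo_ranges`,
#'   `lat_ranges`, `temporal`, `positions`, `raw_diversity`,
#'   `quorum_diversity`, `correlations`, `affinity`, `drivers` (or `NULL`
#'   where inputs were not supplied), plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tbl, name) {
    if (!is.null(out_dir) && is.data.frame(tbl)) {
      path <- file.path(out_dir, paste0(name, ".csv"))
      readr::write_csv(tbl, path)
      written <<- c(written, basename(path))
    }
    tbl
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort_pd(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "pd_stage_error")
    })
  }

  occ <- stage("ingest", resolve_table(config$occurrences, read_occurrences))
  specimens <- resolve_table(config$specimens,
                             function(p) readr::read_csv(p, show_col_types = FALSE))
  n_input <- nrow(occ)
  occ <- stage("dedup", deduplicate_occurrences(occ))
  bins <- stage("bins", resolve_bins(config$bins))
  occ <- stage("binning", assign_bins(occ, bins))
  unassigned <- attr(occ, "unassigned")
  part <- stage("partition", partition_datasets(occ))

  comp <- stage("composition", {
    vars <- c("lithology", "grainsize", "rank")
    tabs <- purrr::map(vars, ~ mutate(composition_table(part, .x), variable = .x))
    if (!is.null(specimens)) {
      tabs <- c(tabs, list(
        mutate(composition_table(part, "taph_grade", specimens = specimens),
               variable = "taph_grade")
      ))
    }
    bind_rows(tabs)
  })
  emit(comp, "composition")

  comp_tests <- stage("composition_tests", {
    lith <- part$D %>%
      filter(.data$lithology != "unknown") %>%
      mutate(dataset = if_else(.data$in_dark, "dark", "published"))
    tests <- list()
    if (nrow(lith) > 0 && n_distinct(lith$lithology) > 1 &&
        n_distinct(lith$dataset) > 1) {
      tests$lithology <- chi_squared(table(lith$lithology, lith$dataset))
    }
    if (!is.null(specimens)) {
      sp <- specimens %>%
        dplyr::inner_join(select(part$D, "occurrence_id", "in_dark"),
                          by = "occurrence_id") %>%
        mutate(dataset = if_else(.data$in_dark, "dark", "published"))
      if (n_distinct(sp$dataset) > 1) {
        tests$taph_chi <- chi_squared(table(sp$taph_grade, sp$dataset))
        tests$taph_kw <- select(
          kruskal_wallis(sp$taph_grade, sp$dataset),
          "statistic", "df", "p_value", "n", "method"
        )
      }
    }
    bind_rows(tests, .id = "test")
  })
  emit(comp_tests, "composition_tests")

  countries <- stage("countries", domestic_foreign(part, config$countries_top_k))
  emit(countries, "countries")

  occup <- stage("occupancy", occupancy(part, config$resolution))
  emit(occup, "occupancy")

  geo <- stage("geo_ranges", range_overlap_added(part, config$rank))
  emit(geo, "geo_ranges")
  lat <- stage("lat_ranges", lat_range_metrics(part, config$rank))
  emit(lat, "lat_ranges")

  temporal <- stage("temporal",
                    range_overlap_time(part, config$rank, config$max_bins_filter))
  emit(temporal, "temporal_ranges")
  positions <- stage("positions", occurrence_positions(part, config$rank))
  emit(positions, "occurrence_positions")

  rawdiv <- stage("raw_diversity", raw_diversity(part, config$rank))
  emit(rawdiv, "raw_diversity")
  qdiv <- stage("quorum_diversity",
                diversity_at_quorum(part, config$rank, config$quorum))
  emit(qdiv, "quorum_diversity")

  correlations <- stage("correlations", {
    wide <- rawdiv %>%
      select("dataset", "bin", "richness") %>%
      tidyr::pivot_wider(names_from = "dataset", values_from = "richness",
                         values_fill = 0)
    if (nrow(wide) >= 4 && "total" %in% names(wide)) {
      correlate_series(wide, ref = "total")
    } else {
      tibble()
    }
  })
  emit(correlations, "correlations")

  aff <- stage("affinity", {
    abins <- resolve_bins(config$affinity_bins)
    occ_a <- assign_bins(select(occ, -dplyr::starts_with("bin")), abins)
    substrate_affinity(partition_datasets(occ_a), B = config$sra_B,
                       n_min = config$sra_n_min, seed = config$seed)
  })
  emit(aff, "substrate_affinity")

  drivers <- NULL
  if (!is.null(config$covariates)) {
    drivers <- stage("drivers", {
      cov_raw <- resolve_table(config$covariates,
                               function(p) readr::read_csv(p, show_col_types = FALSE))
      cov <- prepare_covariates(cov_raw)
      purrr::imap(
        list(dark = "dark", published = "published", pbdb = "pbdb",
             total = "total"),
        function(ds, label) {
          resp <- rawdiv %>%
            filter(.data$dataset == ds) %>%
            select("bin", "richness")
          joined <- dplyr::inner_join(cov, resp, by = "bin")
          if (nrow(joined) <= ncol(cov) + 3) return(NULL)
          sel <- dredge_gls(joined$richness,
                            joined[setdiff(names(cov), "bin")])
          mutate(glance(sel), dataset = label, n_bins = nrow(joined),
                 .before = 1)
        }
      ) %>%
        bind_rows()
    })
    emit(drivers, "drivers")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("palaeodark")),
    seed = config$seed,
    n_input_rows = n_input,
    n_after_dedup = nrow(occ),
    n_unassigned_bins = unassigned,
    partition_sizes = as.list(setNames(partition_sizes(part)$n,
                                       partition_sizes(part)$dataset)),
    stage_outputs = written
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(
    partition = part, composition = comp, composition_tests = comp_tests,
    countries = countries, occupancy = occup, geo_ranges = geo,
    lat_ranges = lat, temporal = temporal, positions = positions,
    raw_diversity = rawdiv, quorum_diversity = qdiv,
    correlations = correlations, affinity = aff, drivers = drivers,
    manifest = manifest
  )
}

#' Simulate a scenario and run the pipeline on it
#'
#' Generates a synthetic dataset with known ground truth, runs
#' [run_pipeline()] on it, and joins the recovered geographic-range
#' estimates to the generator's truth.
#'
#' @param scenario A scenario list (see [read_scenario()]); `NULL` uses the
#'   default scenario.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param config_overrides Named list of [analysis_config()] arguments to
#'   override.
#' @return The [run_pipeline()] result plus `simulation` (the generator
#'   output) and `recovery` (per-taxon true vs estimated area and the mean
#'   added share of the dark data).
#' @export
simulate_and_run <- function(scenario = NULL, seed = 1, out_dir = NULL,
                             config_overrides = list()) {
  scenario <- scenario %||% list(n_taxa = 60, seed = seed, taxa_args = list(),
                                 channels = default_channels())
  sim <- simulate_scenario(scenario, seed = seed)
  cfg <- exec(
    analysis_config,
    occurrences = sim$occurrences,
    specimens = sim$specimens,
    seed = seed,
    !!!config_overrides
  )
  res <- run_pipeline(cfg, out_dir = out_dir)
  geo <- res$geo_ranges
  recovery <- NULL
  if (!is.null(geo) && nrow(geo) > 0) {
    est <- geo %>%
      filter(.data$subset == "dark") %>%
      group_by(.data$taxon) %>%
      summarise(
        est_area_km2 = max(.data$area_total_km2),
        est_added_pct = mean(.data$added_pct),
        .groups = "drop"
      )
    recovery <- sim$truth %>%
      dplyr::inner_join(est, by = c(genus = "taxon"))
  }
  c(res, list(simulation = sim, recovery = recovery))
}
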