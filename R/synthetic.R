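# Seeded synthetic occurrence generator. Each simulated taxon has an exactly
# known spatial range (a spherical cap, so its area has a closed form), an
# exactly known temporal range, and a known carbonate affinity; channels
# (dark / published / pbdb) sample those truths with configurable biases.

#' Channel sampling configuration
#'
#' Describes how one provenance channel (museum-only "dark", published, or
#' the database subset of published) samples the true fossil record.
#' Defaults emulate the compositional contrasts typical of museum-only
#' versus published occurrence data: museum material dominated by carbonate
#' lithologies (~85%), coarser grain sizes and poorer taphonomic grades,
#' drawn disproportionately from the older ("bottom-weighted") part of each
#' taxon's range, and covering the full geographic range while the published
#' channel reaches only part of it.
#'
#' @param n_occurrences Expected number of occurrences the channel draws.
#' @param carbonate_prob Probability an occurrence is carbonate-hosted when
#'   the taxon itself has neutral (0.5) affinity; taxon affinity shifts it.
#' @param coarse_prob Probability of coarse grain size (given known).
#' @param unknown_lith_prob,unknown_grain_prob Probability the field is
#'   recorded as `"unknown"`.
#' @param taph_probs Length-5 probability vector over taphonomic grades 1-5
#'   (1 = best preserved).
#' @param temporal_shape Second shape parameter of the Beta(1, shape)
#'   distribution of the occurrence's relative position in its taxon's
#'   range, measured from the old end: `shape > 1` is bottom-weighted,
#'   `shape = 1` uniform.
#' @param range_fraction Fraction of each taxon's true cap area the channel
#'   can reach (a concentric sub-cap); 1 = the full range.
#' @param rank_probs Probability vector over identification levels
#'   (species, genus, family, above_family).
#' @param countries Character vector of countries the channel collects in.
#' @param domestic_prob Probability a specimen is housed in the country
#'   where it was found.
#' @param collection_block_deg,collection_block_ma Spatial (degrees) and
#'   temporal (Myr) grain of the collection clustering: occurrences of a
#'   channel sharing a block form one collection.
#' @return A list of class `"channel_config"`.
#' @export
channel_config <- function(n_occurrences = 1000,
                           carbonate_prob = 0.5,
                           coarse_prob = 0.15,
                           unknown_lith_prob = 0.05,
                           unknown_grain_prob = 0.2,
                           taph_probs = c(0.1, 0.2, 0.3, 0.25, 0.15),
                           temporal_shape = 1,
                           range_fraction = 1,
                           rank_probs = c(0.35, 0.35, 0.2, 0.1),
                           countries = c("US", "GB", "DE", "FR", "RU"),
                           domestic_prob = 0.8,
                           collection_block_deg = 5,
                           collection_block_ma = 10) {
  stopifnot(
    n_occurrences >= 0, length(taph_probs) == 5, all(taph_probs >= 0),
    length(rank_probs) == 4, all(rank_probs >= 0),
    temporal_shape > 0, range_fraction >= 0, range_fraction <= 1
  )
  probs <- c(carbonate_prob, coarse_prob, unknown_lith_prob,
             unknown_grain_prob, domestic_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_pd("channel probabilities must lie in [0, 1]", "pd_config_error")
  }
  structure(
    list(
      n_occurrences = n_occurrences,
      carbonate_prob = carbonate_prob,
      coarse_prob = coarse_prob,
      unknown_lith_prob = unknown_lith_prob,
      unknown_grain_prob = unknown_grain_prob,
      taph_probs = taph_probs / sum(taph_probs),
      temporal_shape = temporal_shape,
      range_fraction = range_fraction,
      rank_probs = rank_probs / sum(rank_probs),
      countries = countries,
      domestic_prob = domestic_prob,
      collection_block_deg = collection_block_deg,
      collection_block_ma = collection_block_ma
    ),
    class = "channel_config"
  )
}

#' Default channel configurations for the dark / published / pbdb channels
#'
#' The default scenario mirrors the structure of a combined Palaeozoic
#' occurrence compilation: 976 museum-only and 1247 published occurrences
#' with 590/1247 of the published rows database-entered; a
#' carbonate-dominated (0.85), coarse-leaning (0.26), taphonomically poorer
#' and bottom-weighted dark channel covering each taxon's full range; and a
#' published channel restricted to a concentric 65% of each true range, so
#' museum data add ~35% of range area on average.
#'
#' @param pbdb_fraction Probability a published occurrence is also database-
#'   entered.
#' @return A list with elements `dark`, `published` (both
#'   `"channel_config"`) and `pbdb_fraction`.
#' @export
default_channels <- function(pbdb_fraction = 590 / 1247) {
  list(
    dark = channel_config(
      n_occurrences = 976,
      carbonate_prob = 0.85,
      coarse_prob = 0.26,
      taph_probs = c(0.05, 0.1, 0.2, 0.3, 0.35),
      temporal_shape = 2,
      range_fraction = 1,
      rank_probs = c(0.3, 0.4, 0.24, 0.06),
      countries = c("US", "GB", "DE"),
      domestic_prob = 0.85
    ),
    published = channel_config(
      n_occurrences = 1247,
      carbonate_prob = 0.62,
      coarse_prob = 0.15,
      taph_probs = c(0.2, 0.25, 0.25, 0.2, 0.1),
      temporal_shape = 1,
      range_fraction = 0.65,
      rank_probs = c(0.35, 0.3, 0.2, 0.15),
      countries = c("US", "GB", "DE", "FR", "RU", "CN", "AU"),
      domestic_prob = 0.7
    ),
    pbdb_fraction = pbdb_fraction
  )
}

#' Generate taxa with known true ranges
#'
#' Draws `n_taxa` taxa, each with a true spatial range (a spherical cap with
#' centre and radius), a true temporal range (first and last appearance, Ma)
#' and a true carbonate affinity. Reproducible given `seed`.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param seed Integer seed.
#' @param n_families Number of families the genera are spread over.
#' @param radius_km Mean cap radius, km (exponential draw; 0 gives point
#'   ranges).
#' @param age_span_ma Oldest and youngest possible ages, Ma.
#' @param duration_mean_ma Mean taxon duration, Myr.
#' @param affinity_range Range of carbonate affinities to draw uniformly.
#' @param lat_sd Latitudinal spread (degrees) of range centres around the
#'   palaeoequator.
#' @return A tibble of taxa: `taxon_id`, `family`, `genus`, `species`,
#'   `centre_lon`, `centre_lat`, `radius_km`, `fad_ma`, `lad_ma`,
#'   `carbonate_affinity`, `abundance`.
#' @export
generate_taxa <- function(n_taxa, seed = 1, n_families = 8,
                          radius_km = 800, age_span_ma = c(538.8, 251.902),
                          duration_mean_ma = 40,
                          affinity_range = c(0.2, 0.9),
                          lat_sd = 25) {
  if (n_taxa < 1) abort_pd("n_taxa must be >= 1", "pd_config_error")
  if (radius_km < 0 || duration_mean_ma <= 0) {
    abort_pd("radius_km must be >= 0 and duration_mean_ma > 0", "pd_config_error")
  }
  if (any(affinity_range < 0 | affinity_range > 1)) {
    abort_pd("affinity_range must lie in [0, 1]", "pd_config_error")
  }
  old <- max(age_span_ma)
  young <- min(age_span_ma)
  set.seed(seed)
  fam <- sprintf("Fam%02d", sample.int(n_families, n_taxa, replace = TRUE))
  duration <- pmin(stats::rexp(n_taxa, 1 / duration_mean_ma) + 2, old - young)
  fad <- stats::runif(n_taxa, young + duration, old)
  tibble(
    taxon_id = sprintf("T%04d", seq_len(n_taxa)),
    family = fam,
    genus = sprintf("Genus%04d", seq_len(n_taxa)),
    species = sprintf("Genus%04d sp%04d", seq_len(n_taxa), seq_len(n_taxa)),
    centre_lon = stats::runif(n_taxa, -180, 180),
    centre_lat = pmax(pmin(stats::rnorm(n_taxa, 0, lat_sd), 85), -85),
    radius_km = if (radius_km == 0) 0 else stats::rexp(n_taxa, 1 / radius_km),
    fad_ma = fad,
    lad_ma = fad - duration,
    carbonate_affinity = stats::runif(n_taxa, affinity_range[1], affinity_range[2]),
    abundance = stats::rexp(n_taxa, 1)
  )
}

#' True per-taxon quantities implied by a generated taxon set
#'
#' @param taxa Output of [generate_taxa()].
#' @return A tibble with the closed-form true cap area (km^2,
#'   \eqn{2\pi R^2 (1 - \cos(r/R))}), latitudinal width implied by the cap,
#'   duration (Myr) and carbonate affinity of each taxon.
#' @export
ground_truth <- function(taxa) {
  R <- EARTH_RADIUS_KM
  ang <- pmin(taxa$radius_km / R, pi)
  tibble(
    taxon_id = taxa$taxon_id,
    genus = taxa$genus,
    family = taxa$family,
    true_area_km2 = 2 * pi * R^2 * (1 - cos(ang)),
    true_lat_width_deg = pmin(2 * ang * 180 / pi, 180),
    true_duration_ma = taxa$fad_ma - taxa$lad_ma,
    carbonate_affinity = taxa$carbonate_affinity
  )
}

# Uniform points on the spherical cap of angular radius alpha around
# (lon0, lat0): cos(colatitude) uniform on [cos(alpha), 1], then rotate.
sample_cap <- function(n, lon0, lat0, alpha) {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lon", "lat"))))
  }
  z <- stats::runif(n, cos(alpha), 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - z^2, 0))
  # local frame at the north pole, then rotate pole -> (lon0, lat0)
  v <- cbind(s * cos(phi), s * sin(phi), z)
  th <- pi / 2 - lat0 * pi / 180 # rotate by colatitude about y, then lon about z
  ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  lam <- lon0 * pi / 180
  rz <- rbind(c(cos(lam), -sin(lam), 0), c(sin(lam), cos(lam), 0), c(0, 0, 1))
  w <- v %*% t(ry) %*% t(rz)
  cbind(
    lon = atan2(w[, 2], w[, 1]) * 180 / pi,
    lat = asin(pmax(pmin(w[, 3], 1), -1)) * 180 / pi
  )
}

# Angular radius of the concentric sub-cap holding `fraction` of the area of
# a cap with angular radius alpha: 1 - cos(alpha') = fraction * (1 - cos(alpha)).
subcap_alpha <- function(alpha, fraction) {
  acos(1 - fraction * (1 - cos(alpha)))
}

sample_channel <- function(taxa, cfg, channel) {
  n <- cfg$n_occurrences
  if (n == 0) return(list(occ = tibble(), spec = tibble()))
  pick <- sample.int(nrow(taxa), n, replace = TRUE,
                     prob = taxa$abundance / sum(taxa$abundance))
  tx <- taxa[pick, ]
  alpha <- subcap_alpha(pmin(tx$radius_km / EARTH_RADIUS_KM, pi), cfg$range_fraction)

  pts <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    pts[i, ] <- sample_cap(1, tx$centre_lon[i], tx$centre_lat[i],
                           max(alpha[i], 1e-9))
  }

  # relative temporal position from the old end; bottom-weighted if shape > 1
  r <- stats::rbeta(n, 1, cfg$temporal_shape)
  age <- tx$fad_ma - r * (tx$fad_ma - tx$lad_ma)
  half <- stats::runif(n, 1, 6)
  max_ma <- age + half
  min_ma <- pmax(age - half, 0)

  # taxon affinity shifts the channel's carbonate probability: at affinity a
  # and channel base p, odds multiply, keeping both in (0,1)
  p_carb <- stats::plogis(stats::qlogis(pmin(pmax(cfg$carbonate_prob, 1e-6), 1 - 1e-6)) +
                            stats::qlogis(pmin(pmax(tx$carbonate_affinity, 1e-6), 1 - 1e-6)))
  lith_known <- stats::runif(n) >= cfg$unknown_lith_prob
  lith <- if_else(!lith_known, "unknown",
                  if_else(stats::runif(n) < p_carb, "carbonate", "siliciclastic"))
  grain_known <- stats::runif(n) >= cfg$unknown_grain_prob
  grain <- if_else(!grain_known, "unknown",
                   if_else(stats::runif(n) < cfg$coarse_prob, "coarse", "fine"))

  rank <- sample(RANK_LEVELS, n, replace = TRUE, prob = cfg$rank_probs)
  found <- sample(cfg$countries, n, replace = TRUE)
  housed <- if_else(stats::runif(n) < cfg$domestic_prob, found,
                    sample(cfg$countries, n, replace = TRUE))
  n_spec <- 1 + stats::rpois(n, 0.5)

  # collections cluster occurrences sharing a spatial block and an age
  # slice within a channel
  coll <- sprintf(
    "%s_%d_%d_%d", channel,
    floor(pts[, 1] / cfg$collection_block_deg),
    floor(pts[, 2] / cfg$collection_block_deg),
    floor(age / cfg$collection_block_ma)
  )
  occ <- tibble(
    occurrence_id = sprintf("%s%05d", toupper(substr(channel, 1, 1)), seq_len(n)),
    taxon_id = tx$taxon_id,
    species = if_else(rank == "species", tx$species, ""),
    genus = if_else(rank %in% c("species", "genus"), tx$genus, ""),
    family = if_else(rank != "above_family", tx$family, ""),
    rank = rank,
    collection_id = coll,
    lon = pts[, 1],
    lat = pts[, 2],
    plon = pts[, 1],
    plat = pts[, 2],
    max_ma = max_ma,
    min_ma = min_ma,
    lithology = lith,
    grainsize = grain,
    country_found = found,
    country_housed = housed,
    n_specimens = as.numeric(n_spec),
    in_dark = channel == "dark",
    in_published = channel != "dark",
    in_pbdb = FALSE,
    true_age_ma = age,
    true_rel_position = r
  )
  spec <- tibble(
    occurrence_id = rep(occ$occurrence_id, n_spec),
    specimen_id = paste0(rep(occ$occurrence_id, n_spec), "_s",
                         sequence(n_spec)),
    taph_grade = sample(1:5, sum(n_spec), replace = TRUE, prob = cfg$taph_probs)
  )
  list(occ = occ, spec = spec)
}

#' Sample occurrences from true taxa through biased channels
#'
#' Draws museum-only ("dark") and published occurrences from each taxon's
#' true spatial cap and temporal range, applies the channel-specific
#' lithology, grain-size, taphonomy, identification-rank, geography and
#' temporal-position biases, and marks a random subset of published rows as
#' database-entered. The result satisfies all occurrence invariants and the
#' partition algebra by construction.
#'
#' @param taxa Output of [generate_taxa()].
#' @param channels A list as returned by [default_channels()].
#' @param seed Integer seed; all draws derive from it.
#' @return A list: `occurrences` (validated occurrence tibble, plus
#'   `taxon_id`, `true_age_ma`, `true_rel_position` bookkeeping columns),
#'   `specimens` (tibble with `specimen_id`, `occurrence_id`, `taph_grade`),
#'   `taxa`, and `truth` (= [ground_truth()]).
#' @export
sample_occurrences <- function(taxa, channels = default_channels(), seed = 1) {
  set.seed(seed)
  dark <- sample_channel(taxa, channels$dark, "dark")
  pub <- sample_channel(taxa, channels$published, "published")
  if (nrow(pub$occ) > 0) {
    pub$occ$in_pbdb <- stats::runif(nrow(pub$occ)) < channels$pbdb_fraction
  }
  occ <- bind_rows(dark$occ, pub$occ)
  spec <- bind_rows(dark$spec, pub$spec)
  occ <- validate_occurrences(occ)
  stopifnot(nrow(attr(occ, "rejected")) == 0)
  list(occurrences = occ, specimens = spec, taxa = taxa, truth = ground_truth(taxa))
}

#' Read a synthetic-scenario configuration file
#'
#' A YAML file with optional top-level keys `n_taxa`, `seed`, `taxa`
#' (hyperparameters passed to [generate_taxa()]), `dark`, `published`
#' (fields of [channel_config()]) and `pbdb_fraction`.
#'
#' @param path YAML path.
#' @return A list: `n_taxa`, `seed`, `taxa_args`, `channels`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort_pd(paste0("scenario file not found: ", path), "pd_io_error")
  }
  cfg <- yaml::read_yaml(path)
  channels <- default_channels(cfg$pbdb_fraction %||% (590 / 1247))
  for (ch in c("dark", "published")) {
    if (!is.null(cfg[[ch]])) {
      channels[[ch]] <- exec(channel_config, !!!utils::modifyList(
        unclass(channels[[ch]]), cfg[[ch]]
      ))
    }
  }
  list(
    n_taxa = cfg$n_taxa %||% 60,
    seed = cfg$seed %||% 1,
    taxa_args = cfg$taxa %||% list(),
    channels = channels
  )
}

#' Run a scenario: generate taxa, then sample occurrences
#'
#' @param scenario Output of [read_scenario()], or a list with the same
#'   shape.
#' @param seed Optional seed overriding the scenario's.
#' @return As [sample_occurrences()].
#' @export
simulate_scenario <- function(scenario, seed = NULL) {
  seed <- seed %||% scenario$seed
  taxa <- exec(generate_taxa, n_taxa = scenario$n_taxa, seed = seed,
               !!!scenario$taxa_args)
  sample_occurrences(taxa, scenario$channels, seed = seed + 1L)
}
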