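# Canonical occurrence table: one row per taxonomic occurrence (a taxon at a
# collection). Provenance is carried by three flags: in_dark (museum-only),
# in_published, in_pbdb. Museum-only and published rows are mutually
# exclusive; database rows are a subset of published rows.

OCC_REQUIRED <- c(
  "occurrence_id", "species", "genus", "family", "rank", "collection_id",
  "lon", "lat", "max_ma", "min_ma", "lithology", "grainsize",
  "country_found", "country_housed", "n_specimens",
  "in_dark", "in_published", "in_pbdb"
)
OCC_OPTIONAL <- c("plon", "plat")
RANK_LEVELS <- c("species", "genus", "family", "above_family")
LITH_LEVELS <- c("carbonate", "siliciclastic", "unknown")
GRAIN_LEVELS <- c("fine", "coarse", "unknown")

#' Read a canonical occurrence CSV
#'
#' Reads, renames (via `schema`) and validates an occurrence table. Each row
#' is one taxonomic occurrence: a taxon recorded at a collection, with modern
#' (and optionally palaeo-) coordinates, an age interval in Ma, lithology /
#' grain-size metadata, repository countries and provenance flags
#' distinguishing museum-only ("dark") from published and database-entered
#' records.
#'
#' Rows violating the type invariants (age bounds, coordinate ranges, flag
#' algebra) are dropped with row-indexed diagnostics attached as the
#' `"rejected"` attribute; a missing required column is an error.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(lon = "longitude")`.
#' @return A validated occurrence tibble. Attribute `"rejected"` holds a
#'   tibble of dropped rows with `row` and `reason` columns.
#' @export
read_occurrences <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort_pd(paste0("occurrence file not found: ", path), "pd_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    hit <- schema[schema %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- names(hit)
  }
  missing <- setdiff(OCC_REQUIRED, names(raw))
  if (length(missing) > 0) {
    abort_pd(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      "pd_schema_error"
    )
  }
  validate_occurrences(raw)
}

#' Validate an occurrence data frame
#'
#' Coerces types and enforces the row invariants: `max_ma > min_ma >= 0`,
#' `lat` in \[-90, 90\], `lon` in \[-180, 180) (360-wrapped first),
#' `n_specimens >= 1`, `in_pbdb` implies `in_published`, and museum-only
#' versus published mutually exclusive. Offending rows are removed and
#' reported via the `"rejected"` attribute.
#'
#' @param occ A data frame with the canonical occurrence columns.
#' @return A validated occurrence tibble (see [read_occurrences()]).
#' @export
validate_occurrences <- function(occ) {
  occ <- as_tibble(occ)
  missing <- setdiff(OCC_REQUIRED, names(occ))
  if (length(missing) > 0) {
    abort_pd(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      "pd_schema_error"
    )
  }
  if (!"plon" %in% names(occ)) occ$plon <- NA_real_
  if (!"plat" %in% names(occ)) occ$plat <- NA_real_

  num_cols <- c("lon", "lat", "plon", "plat", "max_ma", "min_ma", "n_specimens")
  occ <- occ %>%
    mutate(
      across(all_of(num_cols), ~ suppressWarnings(as.numeric(.x))),
      across(c("in_dark", "in_published", "in_pbdb"), as.logical),
      across(
        c("occurrence_id", "collection_id", "species", "genus", "family",
          "rank", "lithology", "grainsize", "country_found", "country_housed"),
        as.character
      ),
      lithology = if_else(is.na(.data$lithology), "unknown", .data$lithology),
      grainsize = if_else(is.na(.data$grainsize), "unknown", .data$grainsize),
      lon = wrap_lon(.data$lon),
      plon = wrap_lon(.data$plon)
    )

  reason <- rep(NA_character_, nrow(occ))
  flag <- function(bad, msg) {
    bad <- !is.na(bad) & bad
    reason[is.na(reason) & bad] <<- msg
  }
  flag(is.na(occ$lon) | is.na(occ$lat), "unparsable coordinates (lon/lat)")
  flag(is.na(occ$max_ma) | is.na(occ$min_ma), "unparsable age bounds (max_ma/min_ma)")
  flag(occ$lat < -90 | occ$lat > 90, "lat outside [-90, 90]")
  flag(occ$min_ma < 0, "min_ma negative")
  flag(occ$max_ma <= occ$min_ma, "max_ma not greater than min_ma")
  flag(is.na(occ$n_specimens) | occ$n_specimens < 1, "n_specimens < 1")
  flag(!occ$rank %in% RANK_LEVELS, "unknown rank level")
  flag(!occ$lithology %in% LITH_LEVELS, "unknown lithology level")
  flag(!occ$grainsize %in% GRAIN_LEVELS, "unknown grainsize level")
  flag(
    is.na(occ$in_dark) | is.na(occ$in_published) | is.na(occ$in_pbdb),
    "unparsable provenance flag"
  )
  flag(occ$in_pbdb & !occ$in_published, "in_pbdb without in_published")
  flag(occ$in_dark == occ$in_published, "in_dark and in_published must differ")

  bad <- !is.na(reason)
  rejected <- tibble(
    row = which(bad),
    occurrence_id = occ$occurrence_id[bad],
    reason = reason[bad]
  )
  out <- occ[!bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rlang::warn(paste0(
      nrow(rejected), " occurrence row(s) rejected; first: row ",
      rejected$row[1], " (", rejected$reason[1], ")"
    ))
  }
  attr(out, "rejected") <- rejected
  out
}

wrap_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[!is.finite(lon)] <- NA_real_
  out
}

#' Read a Paleobiology Database occurrence export
#'
#' Adapter mapping a PBDB occurrence CSV (fields such as `accepted_name`,
#' `accepted_rank`, `lng`, `lat`, `collection_no`) into the canonical
#' occurrence schema. Database rows are published by definition, so every row
#' gets `in_pbdb = in_published = TRUE` and `in_dark = FALSE`. Rows lacking
#' coordinates are retained with palaeocoordinates absent.
#'
#' @param path Path to a PBDB occurrence export CSV.
#' @return A validated occurrence tibble.
#' @export
read_pbdb_dialect <- function(path) {
  if (!file.exists(path)) {
    abort_pd(paste0("PBDB file not found: ", path), "pd_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  core <- c("accepted_name", "accepted_rank", "max_ma", "min_ma", "collection_no")
  if (!all(core %in% names(raw))) {
    abort_pd(
      paste0(
        "file does not look like a PBDB occurrence export; missing: ",
        paste(setdiff(core, names(raw)), collapse = ", ")
      ),
      "pd_dialect_error"
    )
  }
  n <- nrow(raw)
  get <- function(col, default = NA) {
    if (col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  rank <- tolower(as.character(get("accepted_rank", "genus")))
  rank <- case_when(
    rank == "species" ~ "species",
    rank %in% c("genus", "subgenus") ~ "genus",
    rank %in% c("family", "subfamily") ~ "family",
    TRUE ~ "above_family"
  )
  accepted <- as.character(get("accepted_name", ""))
  genus <- as.character(get("genus", NA))
  genus <- if_else(
    is.na(genus) | genus == "",
    if_else(rank %in% c("species", "genus"), stringr::word(accepted, 1), ""),
    genus
  )
  lon <- suppressWarnings(as.numeric(get("lng")))
  lat <- suppressWarnings(as.numeric(get("lat")))
  no_coords <- is.na(lon) | is.na(lat)
  out <- tibble(
    occurrence_id = as.character(get("occurrence_no", seq_len(n))),
    species = if_else(rank == "species", accepted, ""),
    genus = genus,
    family = as.character(get("family", "")),
    rank = rank,
    collection_id = as.character(get("collection_no")),
    lon = if_else(is.na(lon), 0, lon),
    lat = if_else(is.na(lat), 0, lat),
    plon = suppressWarnings(as.numeric(get("paleolng"))),
    plat = suppressWarnings(as.numeric(get("paleolat"))),
    max_ma = suppressWarnings(as.numeric(get("max_ma"))),
    min_ma = suppressWarnings(as.numeric(get("min_ma"))),
    lithology = normalise_lithology(as.character(get("lithology1", "unknown"))),
    grainsize = "unknown",
    country_found = as.character(get("cc", "")),
    country_housed = "",
    n_specimens = 1,
    in_dark = FALSE,
    in_published = TRUE,
    in_pbdb = TRUE,
    coords_missing = no_coords
  )
  validate_occurrences(out)
}

normalise_lithology <- function(x) {
  x <- tolower(x)
  case_when(
    stringr::str_detect(x, "carbonate|limestone|dolomit|chalk|marl") ~ "carbonate",
    stringr::str_detect(x, "siliciclastic|sandstone|shale|mudstone|siltstone|clay|conglomerate") ~ "siliciclastic",
    TRUE ~ "unknown"
  )
}

#' Collapse duplicate occurrences within collections
#'
#' Keeps at most one row per (finest identified taxon name, collection) pair.
#' The finest name is the species if identified to species, else genus, else
#' family. Specimen counts are summed across merged rows and provenance flags
#' OR-combined, so total specimen counts and the partition algebra are
#' conserved. Idempotent.
#'
#' @param occ A validated occurrence tibble.
#' @return An occurrence tibble with duplicates merged.
#' @export
deduplicate_occurrences <- function(occ) {
  occ %>%
    mutate(.key = finest_name(.data$species, .data$genus, .data$family,
                              .data$rank, .data$occurrence_id)) %>%
    group_by(.data$.key, .data$collection_id) %>%
    summarise(
      across(!any_of(c("n_specimens", "in_dark", "in_published", "in_pbdb")), first),
      n_specimens = sum(.data$n_specimens),
      in_dark = any(.data$in_dark),
      in_published = any(.data$in_published),
      in_pbdb = any(.data$in_pbdb),
      .groups = "drop"
    ) %>%
    # an occurrence both in a museum-only and a published row counts as published
    mutate(in_dark = .data$in_dark & !.data$in_published) %>%
    select(-".key") %>%
    arrange(.data$occurrence_id)
}

finest_name <- function(species, genus, family, rank, fallback) {
  out <- case_when(
    rank == "species" & !is.na(species) & species != "" ~ species,
    rank %in% c("species", "genus") & !is.na(genus) & genus != "" ~ genus,
    !is.na(family) & family != "" ~ family,
    TRUE ~ NA_character_
  )
  # unidentifiable rows never merge with each other
  if_else(is.na(out), paste0(".unid_", fallback), out)
}

#' Taxon label at a fixed analysis rank
#'
#' Returns the genus / family / species label for each row, or `NA` where
#' the row is not identified finely enough for that rank.
#'
#' @param occ Occurrence tibble.
#' @param rank One of `"species"`, `"genus"`, `"family"`.
#' @return Character vector of length `nrow(occ)`.
#' @export
taxon_at_rank <- function(occ, rank = c("genus", "family", "species")) {
  rank <- arg_match(rank)
  ord <- match(occ$rank, RANK_LEVELS) # 1 species ... 4 above_family
  need <- match(rank, RANK_LEVELS)
  lab <- occ[[rank]]
  lab[is.na(lab) | lab == "" | ord > need] <- NA_character_
  lab
}
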