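# Fixtures built in code: a minimal valid occurrence row factory, a small
# two-bin Carboniferous table, and a compact synthetic scenario.

make_occ <- function(n = 1, ...) {
  base <- tibble::tibble(
    occurrence_id = sprintf("o%03d", seq_len(n)),
    species = "",
    genus = paste0("G", seq_len(n)),
    family = "FamA",
    rank = "genus",
    collection_id = sprintf("c%03d", seq_len(n)),
    lon = 10, lat = 45, plon = 12, plat = 40,
    max_ma = 330, min_ma = 320,
    lithology = "carbonate", grainsize = "fine",
    country_found = "US", country_housed = "US",
    n_specimens = 1,
    in_dark = TRUE, in_published = FALSE, in_pbdb = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

carboniferous_bins <- function() {
  tibble::tibble(
    name = c("Mississippian", "Pennsylvanian"),
    max_ma = c(358.9, 323.2),
    min_ma = c(323.2, 298.9),
    level = "sub_period"
  )
}

# A small, fast scenario used by several tests; equal-grain channels keep
# runtime low while preserving all channel biases.
small_scenario <- function(n_taxa = 25, n_dark = 400, n_published = 500) {
  ch <- default_channels()
  ch$dark$n_occurrences <- n_dark
  ch$published$n_occurrences <- n_published
  list(n_taxa = n_taxa, seed = 1, taxa_args = list(), channels = ch)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
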