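test_that("read_occurrences ingests a well-formed file and enforces row invariants", {
  occ <- make_occ(3)
  path <- write_temp_csv(occ)
  out <- read_occurrences(path)
  expect_equal(nrow(out), 3)
  expect_equal(out$genus, c("G1", "G2", "G3"))
  expect_equal(nrow(attr(out, "rejected")), 0)

  bad <- make_occ(3)
  bad$lat[2] <- 123
  expect_warning(out2 <- read_occurrences(write_temp_csv(bad)), "row 2")
  expect_equal(nrow(out2), 2)
  rej <- attr(out2, "rejected")
  expect_equal(rej$row, 2)
  expect_match(rej$reason, "lat")

  stray <- make_occ(1, in_dark = FALSE, in_published = FALSE, in_pbdb = TRUE)
  expect_warning(out3 <- read_occurrences(write_temp_csv(stray)), "in_pbdb")
  expect_equal(nrow(out3), 0)

  incomplete <- make_occ(1)[, -3]
  expect_error(read_occurrences(write_temp_csv(incomplete)),
               class = "pd_schema_error")
})

test_that("PBDB exports map into the canonical schema", {
  pbdb <- tibble::tibble(
    occurrence_no = c(101, 102),
    collection_no = c(9, 10),
    accepted_name = c("Archaeocidaris", "Lepidesthes colei"),
    accepted_rank = c("genus", "species"),
    family = c("Archaeocidaridae", "Lepidesthidae"),
    lng = c(-95.1, NA),
    lat = c(38.2, NA),
    max_ma = c(330, 310),
    min_ma = c(320, 300),
    cc = c("US", "US")
  )
  out <- read_pbdb_dialect(write_temp_csv(pbdb))
  expect_equal(nrow(out), 2)
  expect_equal(out$rank, c("genus", "species"))
  expect_equal(out$genus[1], "Archaeocidaris")
  expect_equal(out$species[2], "Lepidesthes colei")
  expect_true(all(out$in_pbdb) && all(out$in_published) && !any(out$in_dark))
  # rows without coordinates are retained, flagged, with palaeocoords absent
  expect_true(out$coords_missing[2])
  expect_true(is.na(out$plon[2]))

  empty <- pbdb[0, ]
  expect_equal(nrow(read_pbdb_dialect(write_temp_csv(empty))), 0)

  not_pbdb <- tibble::tibble(taxon = "x", age = 1)
  expect_error(read_pbdb_dialect(write_temp_csv(not_pbdb)),
               class = "pd_dialect_error")
})

test_that("deduplication merges same-taxon same-collection rows and conserves specimens", {
  occ <- make_occ(4,
    genus = c("Ga", "Ga", "Ga", "Gb"),
    collection_id = c("c1", "c1", "c2", "c1"),
    n_specimens = c(2, 3, 1, 5)
  )
  out <- deduplicate_occurrences(validate_occurrences(occ))
  expect_equal(nrow(out), 3) # Ga/c1 merged; Ga/c2 and Gb/c1 kept
  expect_equal(sum(out$n_specimens), sum(occ$n_specimens))
  merged <- out[out$genus == "Ga" & out$collection_id == "c1", ]
  expect_equal(merged$n_specimens, 5)
  # idempotent
  expect_equal(nrow(deduplicate_occurrences(out)), 3)
})

test_that("dedup keys on the finest identified name and resolves provenance", {
  # same genus name but one row identified to species: different keys
  occ <- make_occ(2, species = c("Ga sp1", ""), rank = c("species", "genus"),
                  genus = "Ga", collection_id = "c1")
  out <- deduplicate_occurrences(validate_occurrences(occ))
  expect_equal(nrow(out), 2)

  # a museum-only and a published row of the same occurrence merge to published
  occ2 <- make_occ(2, collection_id = "c1", genus = "Ga",
                   in_dark = c(TRUE, FALSE), in_published = c(FALSE, TRUE))
  out2 <- deduplicate_occurrences(validate_occurrences(occ2))
  expect_equal(nrow(out2), 1)
  expect_false(out2$in_dark)
  expect_true(out2$in_published)
})

test_that("majority binning picks the bin with the largest interval share", {
  bins <- carboniferous_bins()
  # [330, 320]: 6.8 Myr in the Mississippian vs 3.2 in the Pennsylvanian
  occ <- validate_occurrences(make_occ(1, max_ma = 330, min_ma = 320))
  out <- assign_bins(occ, bins)
  expect_equal(out$bin, "Mississippian")
  expect_equal(out$bin_overlap, 6.8 / 10, tolerance = 1e-12)

  # wholly inside one bin
  inside <- assign_bins(validate_occurrences(make_occ(1, max_ma = 320, min_ma = 310)), bins)
  expect_equal(inside$bin, "Pennsylvanian")
  expect_equal(inside$bin_overlap, 1)

  # exact 50/50 split goes to the older bin
  tie <- assign_bins(validate_occurrences(make_occ(1, max_ma = 328.2, min_ma = 318.2)), bins)
  expect_equal(tie$bin, "Mississippian")

  # disjoint from every bin: unassigned and counted
  off <- assign_bins(validate_occurrences(make_occ(1, max_ma = 500, min_ma = 490)), bins)
  expect_true(is.na(off$bin))
  expect_equal(attr(off, "unassigned"), 1)

  # strict mode discards sub-majority assignments
  wide <- validate_occurrences(make_occ(1, max_ma = 390, min_ma = 310))
  expect_true(is.na(assign_bins(wide, bins, rule = "majority_strict")$bin))
})

test_that("binning is deterministic, idempotent, and accounts for every row", {
  set.seed(42)
  n <- 200
  occ <- validate_occurrences(make_occ(n,
    max_ma = runif(n, 300, 540), min_ma = NA
  ) |> dplyr::mutate(min_ma = max_ma - runif(n, 0.5, 30)))
  bins <- palaeozoic_bins("stage")
  a <- assign_bins(occ, bins)
  b <- assign_bins(occ, bins)
  expect_identical(a$bin, b$bin)
  expect_identical(assign_bins(a, bins)$bin, a$bin)
  counts <- table(a$bin, useNA = "no")
  expect_equal(sum(counts) + attr(a, "unassigned"), n)
})

test_that("the four-way partition satisfies its algebra", {
  occ <- validate_occurrences(dplyr::bind_rows(
    make_occ(5, in_dark = TRUE, in_published = FALSE, in_pbdb = FALSE),
    make_occ(7, in_dark = FALSE, in_published = TRUE,
             in_pbdb = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)) |>
      dplyr::mutate(occurrence_id = paste0("p", seq_len(7)))
  ))
  part <- partition_datasets(occ)
  sz <- partition_sizes(part)
  expect_equal(sz$n, c(5, 7, 3, 12))
  expect_equal(sz$n[4], sz$n[1] + sz$n[2]) # |D| = |A| + |B|
  expect_true(all(part$C$occurrence_id %in% part$B$occurrence_id)) # C subset of B
  expect_length(intersect(part$A$occurrence_id, part$B$occurrence_id), 0)

  contradictory <- make_occ(1)
  contradictory$in_published <- TRUE # and in_dark TRUE
  expect_error(partition_datasets(contradictory), class = "pd_flag_error")
})

test_that("the packaged bin tables are contiguous and ordered", {
  for (lvl in c("stage", "sub_period")) {
    bins <- palaeozoic_bins(lvl)
    expect_true(all(diff(bins$max_ma) < 0))
    expect_equal(bins$min_ma[-nrow(bins)], bins$max_ma[-1])
    expect_equal(bins$max_ma[1], 538.8)
    expect_equal(bins$min_ma[nrow(bins)], 251.902)
  }
  sp <- palaeozoic_bins("sub_period")
  expect_true(all(c("Mississippian", "Pennsylvanian") %in% sp$name))
})
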