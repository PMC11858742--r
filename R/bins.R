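# Geological time bins: ordered old -> young, contiguous, non-overlapping.

#' Read a time-bin table
#'
#' Reads a CSV with columns `name,max_ma,min_ma,level` and validates that the
#' bins are non-overlapping, contiguous in age and strictly ordered from old
#' to young.
#'
#' @param path CSV path.
#' @return A time-bin tibble ordered old to young.
#' @export
read_time_bins <- function(path) {
  if (!file.exists(path)) {
    abort_pd(paste0("time-bin file not found: ", path), "pd_io_error")
  }
  bins <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_time_bins(bins)
}

#' @rdname read_time_bins
#' @param bins A data frame with columns `name`, `max_ma`, `min_ma`, `level`.
#' @export
validate_time_bins <- function(bins) {
  need <- c("name", "max_ma", "min_ma")
  missing <- setdiff(need, names(bins))
  if (length(missing) > 0) {
    abort_pd(
      paste0("time-bin table missing column(s): ", paste(missing, collapse = ", ")),
      "pd_schema_error"
    )
  }
  bins <- as_tibble(bins)
  if (!"level" %in% names(bins)) bins$level <- "stage"
  bins <- arrange(bins, dplyr::desc(.data$max_ma))
  if (any(bins$max_ma <= bins$min_ma)) {
    abort_pd("each bin needs max_ma > min_ma", "pd_bin_error")
  }
  if (nrow(bins) > 1) {
    adjacent <- abs(bins$min_ma[-nrow(bins)] - bins$max_ma[-1]) < 1e-9
    if (!all(adjacent)) {
      abort_pd("time bins must be contiguous (older min_ma == younger max_ma)",
               "pd_bin_error")
    }
  }
  bins
}

#' Packaged Palaeozoic time-bin tables
#'
#' Stage-level (Fortunian through Changhsingian, 538.8--251.902 Ma) and
#' sub-period-level bins. The sub-period table resolves the periods of the
#' Palaeozoic but splits the Carboniferous into the Mississippian and the
#' Pennsylvanian.
#'
#' @param level `"stage"` or `"sub_period"`.
#' @return A time-bin tibble.
#' @export
palaeozoic_bins <- function(level = c("stage", "sub_period")) {
  level <- arg_match(level)
  file <- switch(level,
    stage = "palaeozoic_stages.csv",
    sub_period = "palaeozoic_sub_periods.csv"
  )
  read_time_bins(system.file("extdata", file, package = "palaeodark",
                             mustWork = TRUE))
}

#' Assign occurrences to time bins by majority overlap
#'
#' Each occurrence's age interval `[min_ma, max_ma]` is assigned to the bin
#' containing the greatest share of that interval; exact ties go to the older
#' bin. With `rule = "majority_strict"` an occurrence is only assigned when a
#' single bin holds more than half of its interval, and is left unassigned
#' otherwise. Occurrences whose interval is disjoint from every bin are left
#' unassigned and counted.
#'
#' @param occ Validated occurrence tibble.
#' @param bins Time-bin tibble (see [read_time_bins()]).
#' @param rule `"majority"` (default) or `"majority_strict"`.
#' @return `occ` with columns `bin` (bin name or `NA`), `bin_max_ma`,
#'   `bin_min_ma`, `bin_midpoint` and `bin_overlap` (fraction of the age
#'   interval inside the assigned bin). Attribute `"unassigned"` counts the
#'   rows left without a bin.
#' @export
assign_bins <- function(occ, bins, rule = c("majority", "majority_strict")) {
  rule <- arg_match(rule)
  bins <- validate_time_bins(bins)
  # overlap matrix: rows = occurrences, cols = bins (old -> young)
  ov <- outer(occ$max_ma, bins$max_ma, pmin) - outer(occ$min_ma, bins$min_ma, pmax)
  ov[ov < 0] <- 0
  # ties.method = "first" on old->young columns implements the older-bin tie-break
  best <- max.col(ov, ties.method = "first")
  best_ov <- ov[cbind(seq_len(nrow(ov)), best)]
  frac <- best_ov / (occ$max_ma - occ$min_ma)
  assigned <- best_ov > 0
  if (rule == "majority_strict") assigned <- assigned & frac > 0.5

  out <- occ %>%
    mutate(
      bin = if_else(assigned, bins$name[best], NA_character_),
      bin_max_ma = if_else(assigned, bins$max_ma[best], NA_real_),
      bin_min_ma = if_else(assigned, bins$min_ma[best], NA_real_),
      bin_midpoint = (.data$bin_max_ma + .data$bin_min_ma) / 2,
      bin_overlap = if_else(assigned, frac, NA_real_)
    )
  attr(out, "unassigned") <- sum(!assigned)
  out
}

#' Partition occurrences into the four analysis datasets
#'
#' Builds the four-way comparison the package is organised around:
#' `A` museum-only ("dark") rows, `B` published rows, `C` the
#' database-entered subset of `B`, and `D` the combined dataset (all rows).
#' By construction `D = A` \eqn{\cup} `B` with `A` and `B` disjoint and
#' `C` \eqn{\subseteq} `B`.
#'
#' @param occ Validated occurrence tibble.
#' @return A named list of class `"dataset_partition"` with elements
#'   `A`, `B`, `C`, `D` (occurrence tibbles).
#' @export
partition_datasets <- function(occ) {
  contradiction <- occ$in_dark & occ$in_published
  if (any(contradiction)) {
    abort_pd(
      paste0(sum(contradiction), " row(s) flagged both museum-only and published"),
      "pd_flag_error"
    )
  }
  pbdb_stray <- occ$in_pbdb & !occ$in_published
  if (any(pbdb_stray)) {
    abort_pd(
      paste0(sum(pbdb_stray), " row(s) flagged in_pbdb but not in_published"),
      "pd_flag_error"
    )
  }
  out <- list(
    A = filter(occ, .data$in_dark),
    B = filter(occ, .data$in_published),
    C = filter(occ, .data$in_pbdb),
    D = occ
  )
  structure(out, class = c("dataset_partition", "list"))
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat("<dataset_partition>\n")
  cat(sprintf("  A (dark):      %d occurrences\n", nrow(x$A)))
  cat(sprintf("  B (published): %d occurrences\n", nrow(x$B)))
  cat(sprintf("  C (pbdb):      %d occurrences\n", nrow(x$C)))
  cat(sprintf("  D (combined):  %d occurrences\n", nrow(x$D)))
  invisible(x)
}

#' Sizes of the four partition datasets
#'
#' @param partition A `"dataset_partition"`.
#' @return A tibble with one row per dataset and its occurrence count.
#' @export
partition_sizes <- function(partition) {
  tibble(
    dataset = names(partition),
    n = unname(vapply(partition, nrow, integer(1)))
  )
}
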