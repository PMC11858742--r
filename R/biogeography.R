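# Spatial range metrics on palaeocoordinates: fixed-resolution grid-cell
# occupancy, convex-hull range size as spherical polygon area, and
# latitudinal ranges, each compared between the combined dataset and its
# subsets.

grid_cells <- function(plon, plat, resolution) {
  ok <- is.finite(plon) & is.finite(plat)
  plon <- wrap_lon(plon[ok])
  plat <- plat[ok]
  unique(paste0(floor(plon / resolution), ":", floor(plat / resolution)))
}

#' Grid-cell occupancy per dataset
#'
#' Counts occupied cells of a fixed-resolution longitude/latitude grid
#' (cells indexed by `floor(coordinate / resolution)`, i.e. labelled by
#' their south-west corner) for each dataset, globally and per time bin.
#' For each bin it also reports the cells contributed uniquely by the dark
#' and by the published dataset and their ratio. Rows lacking
#' palaeocoordinates are excluded and counted in the `"excluded"` attribute.
#'
#' @param partition A [partition_datasets()] result; occurrences must carry
#'   `plon`/`plat` and (for per-bin output) a `bin` column from
#'   [assign_bins()].
#' @param resolution Cell size in degrees (default 1).
#' @return A tibble with one row per (`bin`, including `"(global)"`):
#'   occupied-cell counts per dataset, `unique_dark`, `unique_published`,
#'   `shared`, and `dark_published_ratio`.
#' @export
occupancy <- function(partition, resolution = 1) {
  has_bin <- "bin" %in% names(partition$D)
  bins <- if (has_bin) unique(stats::na.omit(partition$D$bin)) else character(0)
  scopes <- c("(global)", bins)
  excluded <- sum(!is.finite(partition$D$plon) | !is.finite(partition$D$plat))
  out <- purrr::map(scopes, function(b) {
    sub <- function(occ) {
      if (b == "(global)") occ else filter(occ, !is.na(.data$bin), .data$bin == b)
    }
    cells <- purrr::map(partition, ~ grid_cells(sub(.x)$plon, sub(.x)$plat, resolution))
    unique_dark <- setdiff(cells$A, cells$B)
    unique_pub <- setdiff(cells$B, cells$A)
    tibble(
      bin = b,
      cells_dark = length(cells$A),
      cells_published = length(cells$B),
      cells_pbdb = length(cells$C),
      cells_total = length(cells$D),
      unique_dark = length(unique_dark),
      unique_published = length(unique_pub),
      shared = length(intersect(cells$A, cells$B)),
      dark_published_ratio = length(unique_dark) /
        ifelse(length(unique_pub) == 0, NA_real_, length(unique_pub))
    )
  }) %>%
    bind_rows()
  attr(out, "excluded") <- excluded
  attr(out, "resolution") <- resolution
  out
}

# Recentre longitudes so the point cloud is contiguous: rotate the frame so
# the largest circular gap between sorted longitudes straddles the
# antimeridian. Returns the shifted longitudes and the applied shift.
recentre_lon <- function(lon) {
  u <- sort(unique(wrap_lon(lon)))
  if (length(u) < 2) return(list(lon = wrap_lon(lon), shift = 0, span = 0))
  gaps <- c(diff(u), u[1] + 360 - u[length(u)])
  g <- which.max(gaps)
  span <- 360 - gaps[g]
  # place the gap across +/-180: the first point after the gap maps near -180
  start <- if (g == length(u)) u[1] else u[g + 1]
  shift <- -180 - start
  list(lon = wrap_lon(lon + shift), shift = shift, span = span)
}

# Interior spherical angle at vertex b of the geodesic triangle a-b-c,
# working on unit vectors.
lonlat_to_xyz <- function(lon, lat) {
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

# Spherical excess of a triangle via l'Huilier's theorem.
spherical_triangle_excess <- function(a, b, c) {
  side <- function(u, v) {
    # numerically stable central angle
    2 * asin(pmin(1, sqrt(sum((u - v)^2)) / 2))
  }
  A <- side(b, c); B <- side(a, c); C <- side(a, b)
  s <- (A + B + C) / 2
  t <- tan(s / 2) * tan((s - A) / 2) * tan((s - B) / 2) * tan((s - C) / 2)
  4 * atan(sqrt(max(t, 0)))
}

polygon_excess <- function(xyz) {
  excess <- 0
  for (i in 2:(nrow(xyz) - 1)) {
    excess <- excess + spherical_triangle_excess(xyz[1, ], xyz[i, ], xyz[i + 1, ])
  }
  excess
}

#' Convex-hull geographic range of a point set
#'
#' Builds the spherical (geodesic) convex hull of palaeocoordinates and
#' measures its area as spherical polygon excess on a sphere of authalic
#' radius 6371.0088 km. The hull is constructed in a gnomonic projection
#' about the spherical centroid of the points, in which geodesics are
#' straight lines, so the result is the smallest geodesically convex region
#' containing the points; subset hulls are therefore always contained in
#' (and never larger than) the full hull. Fewer than three distinct,
#' non-collinear points give area 0. Point clouds that do not fit inside a
#' hemisphere around their centroid cannot be projected; they fall back to a
#' planar hull in a recentred longitude/latitude frame, flagged
#' (`frame = "planar"`) with a warning.
#'
#' @param plon,plat Palaeocoordinates, decimal degrees.
#' @return A list of class `"hull_range"`: `area_km2`, `vertices` (tibble
#'   `plon`, `plat`, anticlockwise), `n_points`, `frame` (`"spherical"` or
#'   `"planar"`).
#' @export
hull_range <- function(plon, plat) {
  ok <- is.finite(plon) & is.finite(plat)
  plon <- wrap_lon(plon[ok])
  plat <- plat[ok]
  n <- length(plon)
  if (n == 0) {
    abort_pd("hull_range needs at least one point", "pd_input_error")
  }
  xyz <- lonlat_to_xyz(plon, plat)
  ctr <- colSums(xyz)
  ctr_norm <- sqrt(sum(ctr^2))
  hemispheric <- FALSE
  cos_limit <- cos(89.5 * pi / 180)
  if (ctr_norm > 1e-9) {
    ctr <- ctr / ctr_norm
    # refine towards the minimum enclosing cap centre (Badoiu-Clarkson
    # style) so mildly off-centre clouds still project
    for (i in seq_len(200)) {
      cosd <- drop(xyz %*% ctr)
      if (min(cosd) > cos_limit) break
      far <- which.min(cosd)
      ctr <- ctr + (1 / (i + 1)) * (xyz[far, ] - ctr)
      ctr <- ctr / sqrt(sum(ctr^2))
    }
    cosd <- drop(xyz %*% ctr)
    hemispheric <- min(cosd) > cos_limit
  }

  if (hemispheric) {
    frame <- "spherical"
    # gnomonic projection about the centroid: geodesics map to lines
    e1 <- if (abs(ctr[3]) < 0.9) c(-ctr[2], ctr[1], 0) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * ctr) * ctr
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(
      ctr[2] * e1[3] - ctr[3] * e1[2],
      ctr[3] * e1[1] - ctr[1] * e1[3],
      ctr[1] * e1[2] - ctr[2] * e1[1]
    )
    u <- drop(xyz %*% e1) / cosd
    v <- drop(xyz %*% e2) / cosd
    uv <- cbind(u, v)
  } else {
    rlang::warn("point cloud does not fit in a hemisphere; falling back to a planar hull in a recentred frame")
    frame <- "planar"
    uv <- cbind(recentre_lon(plon)$lon, plat)
  }

  keep <- !duplicated(round(uv, 12))
  if (sum(keep) < 3) {
    return(structure(
      list(area_km2 = 0,
           vertices = tibble(plon = plon[keep], plat = plat[keep]),
           n_points = n, frame = frame),
      class = "hull_range"
    ))
  }
  idx <- which(keep)[grDevices::chull(uv[keep, 1], uv[keep, 2])]
  idx <- rev(idx) # chull is clockwise; report anticlockwise
  area <- if (length(idx) < 3) 0 else {
    polygon_excess(xyz[idx, , drop = FALSE]) * EARTH_RADIUS_KM^2
  }
  structure(
    list(area_km2 = area,
         vertices = tibble(plon = plon[idx], plat = plat[idx]),
         n_points = n, frame = frame),
    class = "hull_range"
  )
}

#' @export
print.hull_range <- function(x, ...) {
  cat(sprintf("<hull_range> %d points, %d vertices, area %.1f km^2 (%s frame)\n",
              x$n_points, nrow(x$vertices), x$area_km2, x$frame))
  invisible(x)
}

hull_area <- function(plon, plat) {
  if (length(plon) == 0) return(NA_real_)
  hull_range(plon, plat)$area_km2
}

#' Per-taxon geographic range overlap and area added, per bin
#'
#' For each taxon (at `rank`) and time bin, measures the convex-hull range
#' area from the combined dataset `D` and compares each subset `S` to it:
#' `overlap_pct = 100 * Area(S) / Area(D)` and
#' `added_pct = 100 * (Area(D) - Area(D \ S)) / Area(D)` (the share of the
#' total range that would be lost without `S`). Taxon-bin combinations where
#' `Area(D) = 0` (point or collinear total ranges) are excluded and counted.
#'
#' @param partition A [partition_datasets()] result with `bin` columns
#'   (see [assign_bins()]) and palaeocoordinates.
#' @param rank `"genus"` or `"family"`.
#' @param min_points Minimum combined occurrences per taxon-bin (default 3).
#' @return A tibble: `taxon`, `bin`, `area_total_km2`, and per subset
#'   (`dark`, `published`, `pbdb`) `area_km2`, `overlap_pct`, `added_pct`.
#'   Attribute `"excluded"` counts degenerate taxon-bin combinations.
#' @export
range_overlap_added <- function(partition, rank = c("genus", "family"),
                                min_points = 3) {
  rank <- arg_match(rank)
  D <- partition$D
  D$taxon <- taxon_at_rank(D, rank)
  D <- D %>%
    filter(!is.na(.data$taxon), !is.na(.data$bin),
           is.finite(.data$plon), is.finite(.data$plat))
  excluded <- 0L
  groups <- D %>% count(.data$taxon, .data$bin) %>% filter(.data$n >= min_points)
  out <- purrr::pmap(groups, function(taxon, bin, n) {
    rows <- D[D$taxon == taxon & D$bin == bin, ]
    a_total <- hull_area(rows$plon, rows$plat)
    if (!is.finite(a_total) || a_total <= 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    one_subset <- function(in_sub, label) {
      sub <- rows[in_sub, ]
      rest <- rows[!in_sub, ]
      a_sub <- if (nrow(sub) > 0) hull_area(sub$plon, sub$plat) else 0
      a_rest <- if (nrow(rest) > 0) hull_area(rest$plon, rest$plat) else 0
      tibble(
        subset = label,
        area_km2 = a_sub,
        overlap_pct = 100 * a_sub / a_total,
        added_pct = 100 * (a_total - a_rest) / a_total
      )
    }
    bind_rows(
      one_subset(rows$in_dark, "dark"),
      one_subset(rows$in_published, "published"),
      one_subset(rows$in_pbdb, "pbdb")
    ) %>%
      mutate(taxon = taxon, bin = bin, area_total_km2 = a_total,
             .before = 1)
  }) %>%
    bind_rows()
  attr(out, "excluded") <- excluded
  out
}

#' Summarise range overlap/added across taxa
#'
#' @param ranges Output of [range_overlap_added()] (or
#'   [lat_range_metrics()]).
#' @param metric Column to summarise, e.g. `"overlap_pct"` or `"added_pct"`.
#' @return A tibble of mean and median of `metric` per subset.
#' @export
summarise_ranges <- function(ranges, metric = "added_pct") {
  ranges %>%
    group_by(.data$subset) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data[[metric]], na.rm = TRUE),
      median = stats::median(.data[[metric]], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Per-taxon latitudinal range metrics, per bin
#'
#' Latitudinal interval (from palaeolatitudes) of each taxon per bin from
#' the combined dataset and each subset, with width, interval-overlap
#' percentage against the total, signed midpoint shift (positive =
#' northward), width difference, and the width added by the complementary
#' data, both as a share of the total width and of the subset width.
#'
#' @inheritParams range_overlap_added
#' @param min_points Minimum combined occurrences per taxon-bin (default 1).
#' @return A tibble keyed by `taxon`, `bin`, `subset` with `lat_min`,
#'   `lat_max`, `width`, `midpoint`, `overlap_pct`, `width_diff`,
#'   `midpoint_shift`, `added_pct_of_total`, `added_pct_of_subset`.
#' @export
lat_range_metrics <- function(partition, rank = c("genus", "family"),
                              min_points = 1) {
  rank <- arg_match(rank)
  D <- partition$D
  D$taxon <- taxon_at_rank(D, rank)
  D <- D %>%
    filter(!is.na(.data$taxon), !is.na(.data$bin), is.finite(.data$plat))
  groups <- D %>% count(.data$taxon, .data$bin) %>% filter(.data$n >= min_points)
  purrr::pmap(groups, function(taxon, bin, n) {
    rows <- D[D$taxon == taxon & D$bin == bin, ]
    lo_t <- min(rows$plat); hi_t <- max(rows$plat)
    width_t <- hi_t - lo_t
    mid_t <- (hi_t + lo_t) / 2
    one_subset <- function(in_sub, label) {
      sub <- rows[in_sub, ]
      if (nrow(sub) == 0) return(NULL)
      rest <- rows[!in_sub, ]
      lo <- min(sub$plat); hi <- max(sub$plat)
      inter <- max(0, min(hi, hi_t) - max(lo, lo_t))
      width_wo <- if (nrow(rest) > 0) max(rest$plat) - min(rest$plat) else 0
      tibble(
        subset = label,
        lat_min = lo, lat_max = hi,
        width = hi - lo,
        midpoint = (hi + lo) / 2,
        overlap_pct = if (width_t > 0) 100 * inter / width_t
                      else 100 * as.numeric(inter >= 0),
        width_diff = width_t - (hi - lo),
        midpoint_shift = (hi + lo) / 2 - mid_t,
        added_pct_of_total = if (width_t > 0) 100 * (width_t - width_wo) / width_t
                             else 0,
        added_pct_of_subset = if (width_wo > 0) 100 * (width_t - width_wo) / width_wo
                              else NA_real_
      )
    }
    bind_rows(
      one_subset(rows$in_dark, "dark"),
      one_subset(rows$in_published, "published"),
      one_subset(rows$in_pbdb, "pbdb")
    ) %>%
      mutate(taxon = taxon, bin = bin, lat_width_total = width_t,
             lat_midpoint_total = mid_t, .before = 1)
  }) %>%
    bind_rows()
}
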