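# Point-density profiles: LiDAR impacts per cubic meter, binned along canopy
# height (cubic bins) and along canopy thickness (seven sections whose width
# follows from the canopy x extent and the partition factor).

#' Height point-density profile
#'
#' Overlays cubic bins (default 0.4 m) anchored at the canopy's minimum
#' corner and reports, per height layer, the mean point density over the
#' occupied bins of that layer (impacts per m^3). Averaging over occupied
#' bins only keeps crown asymmetry from diluting the layer means; set
#' `occupied_only = FALSE` to average over all bins of the bounding box
#' instead.
#'
#' @param canopy_cloud Canopy cloud (non-empty).
#' @param bin_size Bin edge length (m).
#' @param occupied_only Average densities over occupied bins only (default)
#'   or over all bins of the layer's bounding slab.
#' @return Tibble of class `height_density_profile`: `layer`, `y_lo`, `y_hi`,
#'   `n_points`, `occupied_bins`, `mean_density` (points m^-3); bin size and
#'   total point count kept as attributes.
#' @export
height_density_profile <- function(canopy_cloud, bin_size = 0.4,
                                   occupied_only = TRUE) {
  assert_cloud(canopy_cloud, min_points = 1L, arg = "canopy_cloud")
  stopifnot(bin_size > 0)
  ox <- min(canopy_cloud$x); oy <- min(canopy_cloud$y); oz <- min(canopy_cloud$z)
  nx <- n_bins_for(max(canopy_cloud$x) - ox, bin_size)
  ny <- n_bins_for(max(canopy_cloud$y) - oy, bin_size)
  nz <- n_bins_for(max(canopy_cloud$z) - oz, bin_size)
  ix <- bin_index(canopy_cloud$x, ox, bin_size, nx)
  iy <- bin_index(canopy_cloud$y, oy, bin_size, ny)
  iz <- bin_index(canopy_cloud$z, oz, bin_size, nz)
  vol <- bin_size^3
  counts <- dplyr::count(tibble::tibble(ix = ix, iy = iy, iz = iz),
                         .data$ix, .data$iy, .data$iz)
  per_layer <- counts %>%
    dplyr::group_by(.data$iy) %>%
    dplyr::summarise(n_points = sum(.data$n),
                     occupied_bins = dplyr::n(),
                     mean_density = if (occupied_only) {
                       mean(.data$n / vol)
                     } else {
                       sum(.data$n / vol) / (nx * nz)
                     },
                     .groups = "drop")
  out <- tibble::tibble(layer = seq_len(ny) ) %>%
    dplyr::mutate(iy = .data$layer - 1L,
                  y_lo = oy + (.data$layer - 1L) * bin_size,
                  y_hi = oy + .data$layer * bin_size) %>%
    dplyr::left_join(per_layer, by = "iy") %>%
    dplyr::mutate(n_points = dplyr::coalesce(.data$n_points, 0L),
                  occupied_bins = dplyr::coalesce(.data$occupied_bins, 0L),
                  mean_density = dplyr::coalesce(.data$mean_density, 0)) %>%
    dplyr::select(-"iy")
  attr(out, "bin_size") <- bin_size
  attr(out, "total_points") <- nrow(canopy_cloud)
  class(out) <- c("height_density_profile", class(out))
  out
}

# Section labels across x from east (min x) to west (max x), center section
# in the middle when the count is odd: E1 E2 E3 C W3 W2 W1 for 7 sections.
section_labels <- function(n_sections, west_positive = TRUE) {
  m <- n_sections %/% 2L
  east <- paste0("E", seq_len(m))
  west <- paste0("W", rev(seq_len(m)))
  labs <- if (n_sections %% 2L == 1L) c(east, "C", west) else c(east, west)
  if (west_positive) labs else rev(labs)
}

#' Thickness point-density profile
#'
#' Partitions the canopy's x range (plant thickness) into `2a` equal
#' half-open sections of width `Wb = ((max_x - min_x) / 2) / a`, laid out as
#' the regular sequence `mu +/- k Wb` about the canopy midpoint `mu`. With
#' the default partition factor `a = 3.5` this yields the seven sections
#' E1, E2, E3, C, W3, W2, W1 (outermost to innermost per exposition, center
#' C). Each section's volume is `Wb` times the y and z extents of its own
#' points (floored at `min_extent` so single-point sections stay finite);
#' density is points per that volume and empty sections have density 0.
#' Percentages of total density are filled via [density_percentages()].
#'
#' @param canopy_cloud Canopy cloud with positive x extent.
#' @param a Partition factor; `2a` sections are created.
#' @param min_extent Floor for per-section y/z extents (m).
#' @param west_positive Is +x the west side (the row-frame convention)?
#' @return Tibble of class `thickness_density_profile`: `section`, `x_lo`,
#'   `x_hi`, `n_points`, `density` (points m^-3), `percentage`; `Wb`, `mu`,
#'   `a` and the total point count kept as attributes.
#' @export
thickness_density_profile <- function(canopy_cloud, a = 3.5,
                                      min_extent = 0.01,
                                      west_positive = TRUE) {
  assert_cloud(canopy_cloud, min_points = 1L, arg = "canopy_cloud")
  stopifnot(a > 0)
  xr <- range(canopy_cloud$x)
  if (diff(xr) <= 0) {
    rlang::abort("Canopy x extent must be positive.",
                 class = "olivescan_geometry_error")
  }
  wb <- (diff(xr) / 2) / a
  n_sec <- max(1L, as.integer(ceiling(2 * a - 1e-9)))
  mu <- mean(xr)
  edges <- mu + wb * (seq_len(n_sec + 1L) - 1L - n_sec / 2)
  idx <- bin_index(canopy_cloud$x, edges[1], wb, n_sec)
  labs <- section_labels(n_sec, west_positive)
  stats_per <- purrr::map_dfr(seq(0, n_sec - 1L), function(k) {
    sel <- idx == k
    n <- sum(sel)
    if (n == 0L) {
      return(tibble::tibble(n_points = 0L, density = 0))
    }
    ye <- max(diff(range(canopy_cloud$y[sel])), min_extent)
    ze <- max(diff(range(canopy_cloud$z[sel])), min_extent)
    tibble::tibble(n_points = n, density = n / (wb * ye * ze))
  })
  out <- tibble::tibble(
    section = factor(labs, levels = labs),
    x_lo = edges[-(n_sec + 1L)], x_hi = edges[-1],
    stats_per, percentage = NA_real_
  )
  attr(out, "Wb") <- wb
  attr(out, "mu") <- mu
  attr(out, "a") <- a
  attr(out, "total_points") <- nrow(canopy_cloud)
  class(out) <- c("thickness_density_profile", class(out))
  if (any(out$density > 0)) out <- density_percentages(out)
  out
}

#' Express section densities as percentages of the total
#'
#' @param profile A `thickness_density_profile`.
#' @return The profile with `percentage = 100 * density / sum(density)`.
#' @export
density_percentages <- function(profile) {
  stopifnot(inherits(profile, "thickness_density_profile"))
  tot <- sum(profile$density)
  if (tot <= 0) {
    rlang::abort("All section densities are zero.",
                 class = "olivescan_geometry_error")
  }
  profile$percentage <- 100 * profile$density / tot
  profile
}

#' Density profiles for every plant of a segmented row cloud
#'
#' @param cloud Segmented row cloud (`plant_id`, `label`).
#' @param bin_size Height bin size (m).
#' @param a Thickness partition factor.
#' @return List with tibbles `height` and `thickness`, each with a
#'   `plant_id` column.
#' @export
density_tables <- function(cloud, bin_size = 0.4, a = 3.5) {
  stopifnot(all(c("plant_id", "label") %in% names(cloud)))
  keep <- !is.na(cloud$plant_id) & cloud$label == "canopy"
  parts <- split(cloud[keep, ], cloud$plant_id[keep])
  height <- purrr::map_dfr(parts, function(p) {
    prof <- height_density_profile(p, bin_size)
    tibble::tibble(plant_id = p$plant_id[1], tibble::as_tibble(prof))
  })
  thickness <- purrr::map_dfr(parts, function(p) {
    prof <- thickness_density_profile(p, a)
    tibble::tibble(plant_id = p$plant_id[1], tibble::as_tibble(prof))
  })
  list(height = height, thickness = thickness)
}
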