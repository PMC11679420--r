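# Reconstruction: polar frames -> Cartesian clouds, pass assembly, reference
# marker detection, pairing of the two row sides, ground removal and plant /
# trunk segmentation. The row frame is x = 0 at the marker plane with +x
# pointing west, y = 0 at fitted ground, z along travel.

#' Convert one polar frame to Cartesian points
#'
#' Beam convention: angle 0 degrees is the horizontal beam toward the row,
#' +90 straight up. A beam of range `r` at angle `theta` recorded at
#' along-track position `z` maps to `(r cos(theta), sensor_height +
#' r sin(theta), z)` in the pass-local frame, where x' is horizontal
#' distance from the sensor toward the row. Sentinel (`-1`) beams and beams
#' outside the working range produce no point, and angles outside the
#' oriented 270 degree sector (-45..225) are discarded.
#'
#' @param frame Data frame with columns `angle` (degrees) and `range` (m or
#'   sentinel `-1`).
#' @param pass A [scan_pass_spec()].
#' @param z Along-track coordinate of the frame (m); defaults to the
#'   frame's `z` column.
#' @return Tibble of points `x`, `y`, `z` in the pass-local frame.
#' @examples
#' pass <- scan_pass_spec("east")
#' polar_to_cartesian(data.frame(angle = 0, range = 2), pass, z = 5)
#' @export
polar_to_cartesian <- function(frame, pass, z = NULL) {
  stopifnot(is.data.frame(frame), all(c("angle", "range") %in% names(frame)))
  if (is.null(z)) {
    if (!"z" %in% names(frame)) {
      rlang::abort("Supply `z` or include a z column in `frame`.")
    }
    z <- frame$z
  }
  z <- rep_len(z, nrow(frame))
  keep <- frame$range >= pass$min_range & frame$range <= pass$max_range &
    frame$angle >= -45 - 1e-9 & frame$angle <= 225 + 1e-9
  r <- frame$range[keep]
  th <- frame$angle[keep] * pi / 180
  as_cloud(r * cos(th), pass$sensor_height + r * sin(th), z[keep])
}

#' Assemble a scan series into a point cloud
#'
#' Converts every frame of a pass with [polar_to_cartesian()] and
#' concatenates the results along the travel axis.
#'
#' @param series A `scan_series` (see [simulate_scan()] / [read_scan_csv()]).
#' @return Tibble point cloud (`x`, `y`, `z`, `label = "unknown"`) in the
#'   pass-local frame, with the pass spec kept in the `"pass"` attribute.
#' @export
assemble_pass <- function(series) {
  pass <- attr(series, "pass")
  if (is.null(pass)) rlang::abort("`series` lacks a pass specification.")
  if (nrow(series) == 0L) return(as_cloud(double(), double(), double()))
  zs <- unique(series[, c("station", "z")])
  zs <- zs[order(zs$station), ]
  if (is.unsorted(zs$z, strictly = FALSE) && is.unsorted(-zs$z)) {
    rlang::abort("Station z positions are not monotone.",
                 class = "olivescan_format_error")
  }
  if (nrow(zs) > 2L) {
    sp <- diff(zs$z)
    if (max(abs(sp - sp[1])) > 1e-6) {
      rlang::abort("Station spacing is not constant.",
                   class = "olivescan_format_error")
    }
  }
  cloud <- polar_to_cartesian(series, pass)
  attr(cloud, "pass") <- pass
  cloud
}

#' Detect mid-row reference markers
#'
#' Finds the pole-plus-square reference targets placed midway between
#' consecutive plants: small clusters whose top lies between 0.8 and 1.3 m,
#' with horizontal extent at most 0.35 m, separated from any crown point
#' (y > 1.3 m) by at least `isolation` in z.
#'
#' @param cloud Point cloud (pass-local or row frame).
#' @param isolation Minimum z distance to crown points (m).
#' @return Tibble of markers sorted by z: `marker_id`, `x`, `y`, `z`
#'   (square-top centroid) and `support_point_count`. May be empty.
#' @export
detect_markers <- function(cloud, isolation = 0.5) {
  assert_cloud(cloud)
  low <- cloud[cloud$y > 0.25 & cloud$y <= 1.3, , drop = FALSE]
  if (nrow(low) == 0L) {
    return(tibble::tibble(marker_id = integer(), x = double(), y = double(),
                          z = double(), support_point_count = integer()))
  }
  ord <- order(low$z)
  low <- low[ord, ]
  cl <- cumsum(c(1, diff(low$z) > 0.3))
  crown_z <- cloud$z[cloud$y > 1.3]
  res <- purrr::map_dfr(split(seq_len(nrow(low)), cl), function(idx) {
    g <- low[idx, ]
    top <- max(g$y)
    if (top < 0.8 || top > 1.3) return(NULL)
    if (diff(range(g$x)) > 0.35 || diff(range(g$z)) > 0.35) return(NULL)
    if (length(crown_z) &&
        min(abs(crown_z - stats::median(g$z))) < isolation) return(NULL)
    topg <- g[g$y >= top - 0.25, ]
    tibble::tibble(x = mean(topg$x), y = mean(topg$y), z = mean(topg$z),
                   support_point_count = nrow(g))
  })
  if (nrow(res) == 0L) {
    return(tibble::tibble(marker_id = integer(), x = double(), y = double(),
                          z = double(), support_point_count = integer()))
  }
  res <- res[order(res$z), ]
  tibble::tibble(marker_id = seq_len(nrow(res)), res)
}

#' Pair the two row sides into one row-frame cloud
#'
#' Places both passes in the common row frame using the detected reference
#' markers: the west pass is offset so its markers sit at x = 0, the east
#' pass is mirrored onto negative x with the same origin, and the east pass
#' is shifted in z by the least-squares marker correspondence. With +x = west
#' the two half-canopies close around the marker plane.
#'
#' @param east_cloud,west_cloud Pass-local clouds from [assemble_pass()].
#' @param east_markers,west_markers Marker tables from [detect_markers()];
#'   at least one marker per side is required.
#' @return Row-frame cloud with a `side` column ("E"/"W"); the point count is
#'   the sum of the inputs. The achieved z alignment residual (m) is stored
#'   in the `"marker_residual"` attribute.
#' @export
pair_sides <- function(east_cloud, west_cloud, east_markers, west_markers) {
  assert_cloud(east_cloud, arg = "east_cloud")
  assert_cloud(west_cloud, arg = "west_cloud")
  if (nrow(east_markers) == 0L || nrow(west_markers) == 0L) {
    rlang::abort("At least one reference marker per side is required.",
                 class = "olivescan_pairing_error")
  }
  me <- mean(east_markers$x)
  mw <- mean(west_markers$x)
  east <- east_cloud
  west <- west_cloud
  east$x <- east$x - me
  west$x <- mw - west$x

  # z correspondence: pair markers by rank if counts agree, otherwise each
  # east marker with the nearest west marker.
  ze <- sort(east_markers$z); zw <- sort(west_markers$z)
  if (length(ze) == length(zw)) {
    pairs <- cbind(ze, zw)
  } else {
    j <- vapply(ze, function(z) which.min(abs(zw - z)), integer(1))
    pairs <- cbind(ze, zw[j])
  }
  delta <- mean(pairs[, 2] - pairs[, 1])
  east$z <- east$z + delta
  residual <- max(abs(pairs[, 2] - (pairs[, 1] + delta)))
  if (residual >= 0.1) {
    rlang::warn(sprintf(
      "Marker alignment residual %.3f m exceeds 0.1 m.", residual))
  }
  east$side <- "E"
  west$side <- "W"
  out <- dplyr::bind_rows(west, east)
  attr(out, "marker_residual") <- residual
  out
}

#' Remove ground returns
#'
#' Fits the local ground level as a low percentile of point height within
#' windows along the row, labels points within `height_cut` of it as ground
#' and drops them. Points at least 0.5 m above the fitted ground are never
#' removed.
#'
#' @param cloud Row-frame point cloud.
#' @param height_cut Height above fitted ground below which points are
#'   classified as ground (m).
#' @param window Width of the z windows used for the ground fit (m).
#' @param percentile Percentile of y used as the local ground level.
#' @return The cloud without ground points; removed points are kept in the
#'   `"removed"` attribute (labelled `"ground"`) so point counts stay
#'   auditable.
#' @export
remove_ground <- function(cloud, height_cut = 0.15, window = 1,
                          percentile = 0.05) {
  assert_cloud(cloud)
  if (nrow(cloud) == 0L) return(cloud)
  win <- floor((cloud$z - min(cloud$z)) / window)
  glev <- tapply(cloud$y, win, stats::quantile, probs = percentile,
                 names = FALSE)
  g <- glev[match(win, as.numeric(names(glev)))]
  rel <- cloud$y - g
  # ground candidates sit near y = 0 (the row frame's fitted ground); crowns
  # start well above, so points at 0.5 m or higher are never touched
  is_ground <- rel < pmin(height_cut, 0.5 - 1e-9) & cloud$y < 0.5
  removed <- cloud[is_ground, , drop = FALSE]
  if (nrow(removed)) removed$label <- "ground"
  out <- cloud[!is_ground, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "pass") <- attr(cloud, "pass")
  out
}

#' Label reference-marker points
#'
#' Marks points belonging to detected reference targets so they are excluded
#' from per-plant clouds (they sit between plants and would otherwise inflate
#' canopy extents).
#'
#' @param cloud Row-frame cloud.
#' @param markers Marker table from [detect_markers()].
#' @return The cloud with marker points relabelled `"marker"`.
#' @export
label_markers <- function(cloud, markers) {
  assert_cloud(cloud)
  if (nrow(markers) == 0L || nrow(cloud) == 0L) return(cloud)
  is_m <- rep(FALSE, nrow(cloud))
  for (i in seq_len(nrow(markers))) {
    is_m <- is_m | (abs(cloud$z - markers$z[i]) <= 0.25 &
                      cloud$y <= 1.35 &
                      abs(cloud$x - markers$x[i]) <= 0.3)
  }
  cloud$label[is_m] <- "marker"
  cloud
}

#' Split a row cloud into per-plant clouds
#'
#' Plant boundaries are the marker z positions; when no markers are
#' available, boundaries fall back to minima of a 0.2 m z histogram of point
#' counts (inter-plant gaps), and if no gap exists the whole cloud becomes a
#' single plant with a warning. A point exactly on a boundary belongs to the
#' lower-z plant. Points labelled `"marker"` are not assigned to any plant.
#'
#' @param row_cloud Ground-removed row-frame cloud.
#' @param markers Marker table (may be empty).
#' @return The cloud with a `plant_id` column (NA for marker points);
#'   boundaries used are stored in the `"boundaries"` attribute.
#' @export
split_plants <- function(row_cloud, markers = NULL) {
  assert_cloud(row_cloud, min_points = 1L, arg = "row_cloud")
  bounds <- if (!is.null(markers) && nrow(markers) > 0L) {
    sort(markers$z)
  } else {
    gap_boundaries(row_cloud$z)
  }
  if (length(bounds) == 0L) {
    rlang::warn("No plant boundaries found; returning a single plant.")
    row_cloud$plant_id <- 1L
  } else {
    # left-open intervals: a point at a boundary joins the lower-z plant
    row_cloud$plant_id <- findInterval(row_cloud$z, bounds,
                                       left.open = TRUE) + 1L
  }
  if ("label" %in% names(row_cloud)) {
    row_cloud$plant_id[row_cloud$label == "marker"] <- NA_integer_
  }
  attr(row_cloud, "boundaries") <- bounds
  row_cloud
}

# Histogram-gap fallback for plant boundaries: internal minima of a 0.2 m
# z histogram whose counts drop below 20% of the median occupied bin.
gap_boundaries <- function(z, bin = 0.2) {
  if (length(z) < 2L) return(numeric())
  lo <- min(z)
  n <- n_bins_for(max(z) - lo, bin)
  counts <- tabulate(bin_index(z, lo, bin, n) + 1L, nbins = n)
  thr <- 0.2 * stats::median(counts[counts > 0])
  in_gap <- counts <= thr
  # collapse runs of gap bins to their centers, ignore edge runs
  r <- rle(in_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) / 2
  keep <- r$values & starts > 1L & ends < n
  lo + (mid[keep] - 0.5) * bin
}

#' Separate trunk from canopy within one plant cloud
#'
#' Works upward through 0.1 m height layers: a layer is trunk while the RMS
#' horizontal spread of its points about the trunk axis (the horizontal
#' centroid of the lowest occupied layer) stays below `spread_max`; the first
#' wider layer starts the canopy. Clouds with no narrow bottom layers yield
#' an empty trunk.
#'
#' @param plant_cloud Cloud of a single plant (ground removed).
#' @param layer Layer height (m).
#' @param spread_max RMS horizontal spread threshold (m).
#' @return The cloud with `label` set to `"trunk"` or `"canopy"`; the trunk /
#'   canopy split height (m) is stored in the `"split_height"` attribute.
#' @export
separate_trunk <- function(plant_cloud, layer = 0.1, spread_max = 0.3) {
  assert_cloud(plant_cloud, min_points = 1L, arg = "plant_cloud")
  y0 <- min(plant_cloud$y)
  n <- n_bins_for(max(plant_cloud$y) - y0, layer)
  li <- bin_index(plant_cloud$y, y0, layer, n)
  lowest <- plant_cloud[li == min(li), , drop = FALSE]
  ax <- mean(lowest$x); az <- mean(lowest$z)
  is_trunk <- rep(FALSE, nrow(plant_cloud))
  split_h <- y0
  for (k in seq(0, n - 1L)) {
    idx <- li == k
    if (!any(idx)) next  # empty layer does not break trunk contiguity
    rms <- sqrt(mean((plant_cloud$x[idx] - ax)^2 +
                       (plant_cloud$z[idx] - az)^2))
    if (rms < spread_max) {
      is_trunk[idx] <- TRUE
      split_h <- y0 + (k + 1) * layer
    } else {
      break
    }
  }
  plant_cloud$label <- ifelse(is_trunk, "trunk", "canopy")
  attr(plant_cloud, "split_height") <- split_h
  plant_cloud
}

#' Segment every plant of a split row cloud
#'
#' Applies [separate_trunk()] per plant of a cloud carrying a `plant_id`
#' column (see [split_plants()]).
#'
#' @param cloud Split row cloud.
#' @return The cloud with trunk/canopy labels filled per plant.
#' @export
segment_plants <- function(cloud) {
  stopifnot("plant_id" %in% names(cloud))
  parts <- split(cloud, cloud$plant_id)
  done <- purrr::map(parts, separate_trunk)
  out <- dplyr::bind_rows(done)
  rest <- cloud[is.na(cloud$plant_id), , drop = FALSE]
  dplyr::bind_rows(out, rest)
}
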