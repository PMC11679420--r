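# Line-scan LiDAR simulation: at each record station along the travel axis a
# fan of rays is cast in the plane perpendicular to travel. Ground, trunks and
# markers are opaque; foliage envelopes return at their boundaries with
# probability 1 - porosity, otherwise the ray continues through.

#' Scan pass specification
#'
#' Parameters of one LiDAR pass along one side of the row, mirroring a
#' side-mounted 2D scanner on a ground vehicle: 270 degree sector at 0.33
#' degree resolution, 0.05-10 m working range, sensor at 1.95 m, one recorded
#' frame every 0.2 m of travel.
#'
#' @param side `"east"` or `"west"`: which side of the row the sensor
#'   travels on. The row frame has +x pointing west.
#' @param sensor_height Sensor height above ground (m).
#' @param lateral_offset Sensor distance from the row axis (m).
#' @param record_spacing Travel distance between recorded frames (m).
#' @param speed Vehicle speed (m s^-1); metadata only, the geometry is fully
#'   determined by `record_spacing`.
#' @param scan_frequency Scanner frequency (Hz); metadata only.
#' @param angular_resolution Angular step between beams (degrees).
#' @param scan_sector Angular width of the scanned sector (degrees). The
#'   blind sector faces away from the row: beam angles run from -45 to +225
#'   degrees, with 0 horizontal toward the row and 90 straight up.
#' @param min_range,max_range Working range (m); hits outside it are recorded
#'   as the no-return sentinel `-1`.
#' @param range_noise_sd Gaussian range noise standard deviation (m); noisy
#'   ranges are clipped back into the working range.
#' @param seed Integer seed for the porosity acceptance draws and range noise.
#'
#' @return A list of class `scan_pass_spec`.
#' @export
scan_pass_spec <- function(side = c("east", "west"),
                           sensor_height = 1.95,
                           lateral_offset = 3.0,
                           record_spacing = 0.2,
                           speed = 1.38,
                           scan_frequency = 15,
                           angular_resolution = 0.33,
                           scan_sector = 270,
                           min_range = 0.05,
                           max_range = 10,
                           range_noise_sd = 0.01,
                           seed = 1L) {
  side <- match.arg(side)
  if (!(min_range < max_range)) {
    rlang::abort("min_range must be < max_range.",
                 class = "olivescan_config_error")
  }
  if (!(angular_resolution > 0 && angular_resolution <= scan_sector)) {
    rlang::abort("angular_resolution must be in (0, scan_sector].",
                 class = "olivescan_config_error")
  }
  structure(list(side = side, sensor_height = sensor_height,
                 lateral_offset = lateral_offset,
                 record_spacing = record_spacing, speed = speed,
                 scan_frequency = scan_frequency,
                 angular_resolution = angular_resolution,
                 scan_sector = scan_sector, min_range = min_range,
                 max_range = max_range, range_noise_sd = range_noise_sd,
                 seed = as.integer(seed)),
            class = "scan_pass_spec")
}

#' Beam angles of a pass
#'
#' @param pass A [scan_pass_spec()].
#' @return Beam angles in degrees, from `-45` up to at most
#'   `-45 + scan_sector`, in steps of the angular resolution.
#' @export
scan_angles <- function(pass) {
  seq(-45, by = pass$angular_resolution,
      length.out = floor(pass$scan_sector / pass$angular_resolution) + 1L)
}

# Scene geometry in the pass-local frame: x' is horizontal distance from the
# sensor toward the row, y is height. For a west-side pass x' = offset - x;
# for an east-side pass x' = x + offset (the row frame has +x = west).
pass_local_x <- function(x, pass) {
  if (pass$side == "west") pass$lateral_offset - x else x + pass$lateral_offset
}

# Rectangular opaque obstacles cut by the scan plane at station z_s:
# trunks (vertical strip of half-width sqrt(r^2 - dz^2)), marker poles and
# marker boards. Returns a data.frame of boxes (x1 < x2, y1 < y2).
station_boxes <- function(scene, pass, z_s) {
  out <- list()
  pl <- scene$plants
  dz <- abs(z_s - pl$base_z)
  hit <- dz < pl$trunk_radius
  if (any(hit)) {
    w <- sqrt(pl$trunk_radius[hit]^2 - dz[hit]^2)
    cx <- pass_local_x(0, pass)
    out$trunk <- data.frame(x1 = cx - w, x2 = cx + w, y1 = 0,
                            y2 = pl$trunk_height[hit])
  }
  mk <- scene$markers
  if (nrow(mk) > 0L) {
    half <- mk$square_side / 2
    bhit <- abs(z_s - mk$z) <= half
    if (any(bhit)) {
      cx <- pass_local_x(mk$x[bhit], pass)
      out$board <- data.frame(x1 = cx - 0.01, x2 = cx + 0.01,
                              y1 = mk$pole_height[bhit],
                              y2 = mk$pole_height[bhit] +
                                mk$square_side[bhit])
    }
    phit <- abs(z_s - mk$z) <= 0.02
    if (any(phit)) {
      cx <- pass_local_x(mk$x[phit], pass)
      out$pole <- data.frame(x1 = cx - 0.02, x2 = cx + 0.02, y1 = 0,
                             y2 = mk$pole_height[phit])
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Foliage ellipses cut by the scan plane at station z_s.
station_ellipses <- function(branches, pass, z_s) {
  dz <- abs(z_s - branches$cz)
  hit <- dz < branches$ez
  if (!any(hit)) return(NULL)
  b <- branches[hit, ]
  shrink <- sqrt(pmax(1 - (dz[hit] / b$ez)^2, 0))
  data.frame(cx = pass_local_x(b$cx, pass), cy = b$cy,
             a = b$ex * shrink, b = b$ey * shrink, porosity = b$porosity)
}

# Ray / axis-aligned box intersection, vectorised over beams.
# Origin (0, h), direction (c, s). Returns entry parameter t (Inf = miss).
ray_box_entry <- function(cb, sb, h, x1, x2, y1, y2) {
  tx1 <- (x1 - 0) / cb; tx2 <- (x2 - 0) / cb
  ty1 <- (y1 - h) / sb; ty2 <- (y2 - h) / sb
  txlo <- pmin(tx1, tx2); txhi <- pmax(tx1, tx2)
  tylo <- pmin(ty1, ty2); tyhi <- pmax(ty1, ty2)
  # beams parallel to an axis: division by ~0 yields +-Inf which the
  # min/max slab logic handles; NaN (0/0) means the origin lies on the slab
  txlo[is.nan(txlo)] <- -Inf; txhi[is.nan(txhi)] <- Inf
  tylo[is.nan(tylo)] <- -Inf; tyhi[is.nan(tyhi)] <- Inf
  lo <- pmax(txlo, tylo); hi <- pmin(txhi, tyhi)
  t <- ifelse(lo <= hi & hi > 0, ifelse(lo > 0, lo, hi), Inf)
  t
}

# Ray / ellipse intersection, vectorised over beams. Returns a list with the
# two boundary parameters (entry, exit); Inf = miss.
ray_ellipse <- function(cb, sb, h, ex, ey, a, bb) {
  A <- (cb / a)^2 + (sb / bb)^2
  B <- 2 * (cb * (0 - ex) / a^2 + sb * (h - ey) / bb^2)
  C <- ((0 - ex) / a)^2 + ((h - ey) / bb)^2 - 1
  disc <- B^2 - 4 * A * C
  ok <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-B - sq) / (2 * A)
  t2 <- (-B + sq) / (2 * A)
  t1[!ok] <- Inf; t2[!ok] <- Inf
  list(t1 = t1, t2 = t2)
}

#' Simulate a LiDAR pass over a scene
#'
#' Casts, at each record station, one ray per beam angle in the plane
#' perpendicular to travel, and records the range to the first accepted
#' surface: ground, trunks and reference markers are opaque; a foliage
#' envelope boundary returns with probability `1 - porosity`, otherwise the
#' ray continues (so interior structure behind a porous crown surface is
#' reachable). Ranges get truncated Gaussian noise and are clipped to the
#' working range; beams with no accepted hit in range record the sentinel
#' `-1`.
#'
#' @param scene An `orchard_scene`.
#' @param pass A [scan_pass_spec()].
#' @param stations Optional vector of station z positions (m); defaults to
#'   covering the whole row at `record_spacing`.
#'
#' @return A `scan_series`: a tibble with one row per (station, beam) --
#'   columns `station`, `z`, `angle` (degrees) and `range` (m or `-1`) --
#'   with the pass spec stored in the `"pass"` attribute.
#' @export
simulate_scan <- function(scene, pass, stations = NULL) {
  stopifnot(inherits(scene, "orchard_scene"),
            inherits(pass, "scan_pass_spec"))
  br <- scene$branches
  crown_reach <- if (nrow(br)) max(abs(br$cx) + br$ex) else 0
  if (pass$lateral_offset <= crown_reach) {
    rlang::abort("Sensor path lies inside the crown envelope; increase lateral_offset.",
                 class = "olivescan_geometry_error")
  }
  if (is.null(stations)) {
    z_max <- scene$config$n_plants * scene$config$plant_spacing
    stations <- seq(0, z_max, by = pass$record_spacing)
  }
  angles <- scan_angles(pass)
  theta <- angles * pi / 180
  cb <- cos(theta); sb <- sin(theta)
  h <- pass$sensor_height
  nb <- length(angles)

  ranges <- with_seed(pass$seed, {
    vapply(stations, function(z_s) {
      best <- rep(Inf, nb)
      # ground plane y = 0 (opaque)
      tg <- ifelse(sb < 0, -h / sb, Inf)
      best <- pmin(best, tg)
      boxes <- station_boxes(scene, pass, z_s)
      if (!is.null(boxes)) {
        for (j in seq_len(nrow(boxes))) {
          if (boxes$x1[j] <= 0 && boxes$x2[j] >= 0 &&
              boxes$y1[j] <= h && boxes$y2[j] >= h) {
            rlang::abort("Sensor lies inside a solid obstacle.",
                         class = "olivescan_geometry_error")
          }
          tb <- ray_box_entry(cb, sb, h, boxes$x1[j], boxes$x2[j],
                              boxes$y1[j], boxes$y2[j])
          best <- pmin(best, tb)
        }
      }
      ell <- station_ellipses(br, pass, z_s)
      if (!is.null(ell)) {
        for (j in seq_len(nrow(ell))) {
          tt <- ray_ellipse(cb, sb, h, ell$cx[j], ell$cy[j],
                            ell$a[j], ell$b[j])
          p_acc <- 1 - ell$porosity[j]
          for (t in tt) {
            acc <- is.finite(t) & t > 1e-9 & stats::runif(nb) < p_acc
            best[acc] <- pmin(best[acc], t[acc])
          }
        }
      }
      r <- best
      miss <- !is.finite(r) | r > pass$max_range | r < pass$min_range
      if (pass$range_noise_sd > 0) {
        r <- r + stats::rnorm(nb, 0, pass$range_noise_sd)
        r <- pmin(pmax(r, pass$min_range), pass$max_range)
      }
      r <- pmax(r, 0)
      r[miss] <- -1
      r
    }, numeric(nb))
  })

  out <- tibble::tibble(
    station = rep(seq_along(stations), each = nb),
    z = rep(stations, each = nb),
    angle = rep(angles, times = length(stations)),
    range = as.vector(ranges)
  )
  attr(out, "pass") <- pass
  class(out) <- c("scan_series", class(out))
  out
}
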