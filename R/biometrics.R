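# Canopy biometrics (HPL, HCL, HTL, DCL) and the four volume estimators:
# slice-wise convex hull (VCH), voxel occupancy (VV), and the cylinder /
# sphere geometric simplifications (VCY, VSP).

#' Maximum plant height (HPL)
#'
#' @param plant_cloud Cloud of one plant (trunk and canopy).
#' @return Maximum point height (m).
#' @export
plant_height <- function(plant_cloud) {
  assert_cloud(plant_cloud, min_points = 1L, arg = "plant_cloud")
  max(plant_cloud$y)
}

#' Canopy height (HCL)
#'
#' @param canopy_cloud Cloud of the canopy alone.
#' @return Vertical extent (max y - min y) of the canopy (m).
#' @export
canopy_height <- function(canopy_cloud) {
  assert_cloud(canopy_cloud, min_points = 1L, arg = "canopy_cloud")
  max(canopy_cloud$y) - min(canopy_cloud$y)
}

#' Trunk height (HTL)
#'
#' The trunk height is what remains of the total plant height once the
#' canopy height is subtracted.
#'
#' @param hpl Plant height (m).
#' @param hcl Canopy height (m).
#' @return `hpl - hcl` (m).
#' @export
trunk_height <- function(hpl, hcl) {
  if (any(hcl > hpl + 1e-9)) {
    rlang::abort("Canopy height exceeds plant height.",
                 class = "olivescan_inconsistency_error")
  }
  hpl - hcl
}

#' Maximum canopy diameter (DCL)
#'
#' Maximum pairwise horizontal distance (x, z plane) between canopy points:
#' the maximum caliper of the horizontal projection, computed on the convex
#' hull of the projection.
#'
#' @param canopy_cloud Canopy cloud with at least two points.
#' @return Diameter (m).
#' @export
canopy_diameter <- function(canopy_cloud) {
  assert_cloud(canopy_cloud, min_points = 2L, arg = "canopy_cloud")
  u <- canopy_cloud$x; v <- canopy_cloud$z
  keep <- !duplicated(cbind(u, v))
  u <- u[keep]; v <- v[keep]
  if (length(u) > 3L) {
    h <- grDevices::chull(u, v)
    u <- u[h]; v <- v[h]
  }
  max(stats::dist(cbind(u, v)))
}

#' Cylinder volume simplification (VCY)
#'
#' The canopy is inscribed in a cylinder of the measured diameter and height.
#'
#' @param diameter Canopy diameter (m).
#' @param height Canopy height (m).
#' @return `pi (d/2)^2 h` (m^3).
#' @export
cylinder_volume <- function(diameter, height) {
  stopifnot(all(diameter >= 0), all(height >= 0))
  pi * (diameter / 2)^2 * height
}

#' Sphere volume simplification (VSP)
#'
#' The canopy is inscribed in a sphere whose radius is the mean of the
#' supplied measurements divided by two (by default the canopy diameter and
#' canopy height).
#'
#' @param diameter Canopy diameter (m).
#' @param canopy_height Canopy height (m).
#' @param measures Optional numeric vector overriding which measurements are
#'   averaged for the radius.
#' @return `(4/3) pi r^3` (m^3).
#' @export
sphere_volume <- function(diameter, canopy_height, measures = NULL) {
  if (is.null(measures)) measures <- c(diameter, canopy_height)
  stopifnot(all(measures >= 0))
  r <- mean(measures) / 2
  4 / 3 * pi * r^3
}

#' Slice-wise convex hull volume (VCH)
#'
#' Partitions the cloud into half-open slices along one axis, computes the 2D
#' convex hull area of each slice's projection onto the remaining two axes,
#' and sums `slice_width * area` over slices. Slices with fewer than three
#' affinely independent projected points contribute zero area.
#'
#' @param canopy_cloud Canopy cloud.
#' @param slice_width Slice width (m).
#' @param axis Slicing axis: `"x"` (plant thickness, the default), `"y"` or
#'   `"z"`.
#' @param origin Optional anchor for the first slice boundary; defaults to
#'   the cloud's minimum along the slicing axis. Supplying a fixed origin
#'   makes the estimator monotone under point deletion.
#' @return Object of class `vch_estimate`: list with `volume` (m^3),
#'   `slice_width`, `axis`, and a `slices` tibble (`slice`, `lo`, `hi`,
#'   `n_points`, `area`).
#' @export
convex_hull_volume <- function(canopy_cloud, slice_width = 0.1, axis = "x",
                               origin = NULL) {
  assert_cloud(canopy_cloud, min_points = 1L, arg = "canopy_cloud")
  stopifnot(slice_width > 0)
  axis <- match.arg(axis, c("x", "y", "z"))
  others <- setdiff(c("x", "y", "z"), axis)
  v <- canopy_cloud[[axis]]
  if (is.null(origin)) origin <- min(v)
  n <- n_bins_for(max(v) - origin, slice_width)
  idx <- bin_index(v, origin, slice_width, n)
  areas <- vapply(seq(0, n - 1L), function(k) {
    sel <- idx == k
    if (!any(sel)) return(0)
    hull_area(canopy_cloud[[others[1]]][sel], canopy_cloud[[others[2]]][sel])
  }, numeric(1))
  counts <- tabulate(idx + 1L, nbins = n)
  slices <- tibble::tibble(
    slice = seq_len(n),
    lo = origin + (seq_len(n) - 1L) * slice_width,
    hi = origin + seq_len(n) * slice_width,
    n_points = counts, area = areas
  )
  structure(list(volume = sum(slice_width * areas),
                 slice_width = slice_width, axis = axis, slices = slices),
            class = "vch_estimate")
}

#' @export
print.vch_estimate <- function(x, ...) {
  cat("<vch_estimate> VCH =", format(x$volume), "m^3 over",
      nrow(x$slices), "slices of", x$slice_width, "m along", x$axis, "\n")
  invisible(x)
}

#' Voxel occupancy volume (VV)
#'
#' Overlays a cubic grid of voxels of volume `v` anchored at the cloud's
#' minimum corner and returns `N * v`, where `N` is the number of voxels
#' containing at least one point.
#'
#' @param canopy_cloud Canopy cloud (may be empty).
#' @param v Voxel volume (m^3).
#' @param origin Optional length-3 grid anchor `(x, y, z)`; defaults to the
#'   cloud minimum corner. A fixed origin makes occupancy monotone under
#'   point deletion.
#' @return Object of class `vv_estimate`: list with `volume` (m^3),
#'   `n_voxels`, `voxel_volume` and `side` (m).
#' @export
voxel_volume <- function(canopy_cloud, v = 1e-5, origin = NULL) {
  stopifnot(v > 0)
  assert_cloud(canopy_cloud, arg = "canopy_cloud")
  side <- v^(1 / 3)
  if (nrow(canopy_cloud) == 0L) {
    return(structure(list(volume = 0, n_voxels = 0L, voxel_volume = v,
                          side = side), class = "vv_estimate"))
  }
  if (is.null(origin)) {
    origin <- c(min(canopy_cloud$x), min(canopy_cloud$y), min(canopy_cloud$z))
  }
  ix <- bin_index(canopy_cloud$x, origin[1], side,
                  n_bins_for(max(canopy_cloud$x) - origin[1], side))
  iy <- bin_index(canopy_cloud$y, origin[2], side,
                  n_bins_for(max(canopy_cloud$y) - origin[2], side))
  iz <- bin_index(canopy_cloud$z, origin[3], side,
                  n_bins_for(max(canopy_cloud$z) - origin[3], side))
  n_occ <- nrow(unique(cbind(ix, iy, iz)))
  structure(list(volume = n_occ * v, n_voxels = n_occ, voxel_volume = v,
                 side = side), class = "vv_estimate")
}

#' @export
print.vv_estimate <- function(x, ...) {
  cat("<vv_estimate> VV =", format(x$volume), "m^3 (", x$n_voxels,
      "voxels of", format(x$voxel_volume), "m^3 )\n")
  invisible(x)
}

#' Per-plant biometrics table
#'
#' Computes HPL, HCL, HTL and DCL for every plant of a segmented row cloud
#' (columns `plant_id` and `label` with trunk/canopy values, as produced by
#' [split_plants()] + [segment_plants()]).
#'
#' @param cloud Segmented row cloud.
#' @return Tibble with one row per plant: `plant_id`, `n_points`, `HPL`,
#'   `HCL`, `HTL`, `DCL` (m).
#' @export
biometrics_table <- function(cloud) {
  stopifnot(all(c("plant_id", "label") %in% names(cloud)))
  parts <- split(cloud[!is.na(cloud$plant_id), ],
                 cloud$plant_id[!is.na(cloud$plant_id)])
  purrr::map_dfr(parts, function(p) {
    canopy <- p[p$label == "canopy", ]
    if (nrow(canopy) == 0L) canopy <- p
    hpl <- plant_height(p)
    hcl <- canopy_height(canopy)
    tibble::tibble(plant_id = p$plant_id[1], n_points = nrow(p),
                   HPL = hpl, HCL = hcl, HTL = trunk_height(hpl, hcl),
                   DCL = canopy_diameter(canopy))
  })
}

#' Per-plant volume estimates table
#'
#' Computes the four volume estimators per plant of a segmented row cloud:
#' VCH and VV from the canopy points, VCY and VSP from the canopy diameter
#' and height.
#'
#' @param cloud Segmented row cloud.
#' @param slice_width Slice width for VCH (m).
#' @param voxel_vol Voxel volume for VV (m^3).
#' @param axis Slicing axis for VCH.
#' @return Tibble with one row per plant: `plant_id`, `VCH`, `VV`, `VCY`,
#'   `VSP` (m^3), `n_slices`, `n_voxels`.
#' @export
volumes_table <- function(cloud, slice_width = 0.1, voxel_vol = 1e-5,
                          axis = "x") {
  stopifnot(all(c("plant_id", "label") %in% names(cloud)))
  parts <- split(cloud[!is.na(cloud$plant_id), ],
                 cloud$plant_id[!is.na(cloud$plant_id)])
  purrr::map_dfr(parts, function(p) {
    canopy <- p[p$label == "canopy", ]
    if (nrow(canopy) == 0L) canopy <- p
    vch <- convex_hull_volume(canopy, slice_width, axis = axis)
    vv <- voxel_volume(canopy, voxel_vol)
    dcl <- canopy_diameter(canopy)
    hcl <- canopy_height(canopy)
    tibble::tibble(plant_id = p$plant_id[1],
                   VCH = vch$volume, VV = vv$volume,
                   VCY = cylinder_volume(dcl, hcl),
                   VSP = sphere_volume(dcl, hcl),
                   n_slices = nrow(vch$slices), n_voxels = vv$n_voxels)
  })
}
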