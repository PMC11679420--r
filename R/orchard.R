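# Synthetic orchard: parametric olive row with per-branch foliage envelopes,
# mid-row reference markers, and a pruning operator with known removed mass.

#' Orchard generation parameters
#'
#' Builds the parameter list consumed by [generate_orchard()]. Defaults
#' describe a traditional olive row: ten developed plants on a 5 x 6 m
#' layout, mean total height 3.5 m, crown base 0.7 m, and three primary
#' branches per plant arranged around the trunk, each carrying a few branch
#' units with ellipsoidal foliage envelopes. Three cultivar presets modulate
#' vigor (height multiplier) and crown density (foliage porosity).
#'
#' @param n_plants Number of plants in the row.
#' @param plant_spacing Distance between consecutive plants along the row (m).
#' @param row_spacing Distance between rows (m, metadata only: a single row is
#'   generated).
#' @param mean_height,sd_height Mean and standard deviation of total plant
#'   height (m).
#' @param crown_base,sd_crown_base Mean and standard deviation of the trunk
#'   height, i.e. the height at which the crown starts (m).
#' @param n_primary Number of primary branches per plant.
#' @param units_per_primary Number of branch units carried by each primary
#'   branch. Pruning removes whole units.
#' @param trunk_radius Trunk radius (m).
#' @param wood_density Wood density used by the branch allometry (kg m^-3).
#' @param branch_radius_per_length Branch radius per unit branch length
#'   (dimensionless taper); wood mass of a unit is
#'   `wood_density * length * pi * (branch_radius_per_length * length)^2`.
#' @param marker_pole_height Height of the mid-row reference poles (m).
#' @param marker_square_side Side of the square board topping each pole (m).
#' @param cultivars Character vector of preset names to draw from; see
#'   Details.
#'
#' @details The presets are `san_francesco` (high vigor, assurgent habit, low
#'   crown density), `piangente` (medium vigor, pendulous habit, high crown
#'   density) and `scarlinese` (medium vigor, assurgent habit, high crown
#'   density).
#'
#' @return A named list of class `orchard_config`.
#' @export
orchard_config <- function(n_plants = 10L,
                           plant_spacing = 5,
                           row_spacing = 6,
                           mean_height = 3.5,
                           sd_height = 0.3,
                           crown_base = 0.7,
                           sd_crown_base = 0.08,
                           n_primary = 3L,
                           units_per_primary = 3L,
                           trunk_radius = 0.12,
                           wood_density = 800,
                           branch_radius_per_length = 0.019,
                           marker_pole_height = 1.0,
                           marker_square_side = 0.2,
                           cultivars = c("san_francesco", "piangente",
                                         "scarlinese")) {
  cfg <- list(
    n_plants = as.integer(n_plants), plant_spacing = plant_spacing,
    row_spacing = row_spacing, mean_height = mean_height,
    sd_height = sd_height, crown_base = crown_base,
    sd_crown_base = sd_crown_base, n_primary = as.integer(n_primary),
    units_per_primary = as.integer(units_per_primary),
    trunk_radius = trunk_radius, wood_density = wood_density,
    branch_radius_per_length = branch_radius_per_length,
    marker_pole_height = marker_pole_height,
    marker_square_side = marker_square_side,
    cultivars = match.arg(cultivars, several.ok = TRUE)
  )
  geom <- c("n_plants", "plant_spacing", "row_spacing", "mean_height",
            "crown_base", "trunk_radius", "wood_density")
  bad <- geom[vapply(cfg[geom], function(v) !is.finite(v) || v <= 0,
                     logical(1))]
  if (length(bad)) {
    rlang::abort(paste0("Non-positive orchard geometry: ",
                        paste(bad, collapse = ", ")),
                 class = "olivescan_config_error")
  }
  structure(cfg, class = "orchard_config")
}

# Vigor multipliers average to 1 across presets so the row's expected height
# equals the configured mean height.
.presets <- list(
  san_francesco = list(vigor = 1.08, porosity = 0.50, elev = 72),
  piangente     = list(vigor = 0.96, porosity = 0.25, elev = 62),
  scarlinese    = list(vigor = 0.96, porosity = 0.30, elev = 70)
)

#' Generate a synthetic olive row
#'
#' Draws a ground-truth orchard scene: one row of plants at fixed spacing,
#' each with a cylindrical trunk and a set of branch units whose foliage is
#' an ellipsoidal envelope; mid-row reference markers (pole plus square
#' board) sit midway between consecutive plants. The scene is the ground
#' truth against which scan simulation and reconstruction are checked.
#'
#' @param config An [orchard_config()] list.
#' @param seed Integer seed; identical `(config, seed)` reproduce an
#'   identical scene.
#'
#' @return An object of class `orchard_scene`: a list with tibbles `plants`
#'   (one row per plant), `branches` (one row per branch unit, including the
#'   envelope center `cx, cy, cz`, semi-axes `ex, ey, ez`, porosity and
#'   `wood_mass` in kg), `markers`, plus the `config` and `seed` used.
#' @examples
#' scene <- generate_orchard(orchard_config(n_plants = 2), seed = 1)
#' scene$plants
#' @export
generate_orchard <- function(config = orchard_config(), seed = 1L) {
  if (!inherits(config, "orchard_config")) config <- do.call(orchard_config, config)
  cfg <- config
  with_seed(seed, {
    plants <- tibble::tibble(
      plant_id = seq_len(cfg$n_plants),
      base_z = (seq_len(cfg$n_plants) - 0.5) * cfg$plant_spacing,
      cultivar = sample(cfg$cultivars, cfg$n_plants, replace = TRUE),
      trunk_height = pmin(pmax(
        stats::rnorm(cfg$n_plants, cfg$crown_base, cfg$sd_crown_base),
        0.4), 1.0),
      trunk_radius = cfg$trunk_radius
    )
    plants$height <- vapply(seq_len(cfg$n_plants), function(i) {
      v <- .presets[[plants$cultivar[i]]]$vigor
      max(stats::rnorm(1, cfg$mean_height * v, cfg$sd_height), 1.5)
    }, numeric(1))

    branches <- purrr::map_dfr(seq_len(cfg$n_plants), function(i) {
      p <- plants[i, ]
      preset <- .presets[[p$cultivar]]
      rot <- stats::runif(1, 0, 2 * pi)
      purrr::map_dfr(seq_len(cfg$n_primary), function(b) {
        phi0 <- rot + 2 * pi * (b - 1) / cfg$n_primary
        elev0 <- preset$elev + stats::runif(1, -4, 4)
        # leader unit reaches the plant top; secondary units are shorter
        lam <- c(1, stats::runif(cfg$units_per_primary - 1L, 0.6, 0.95))
        purrr::map_dfr(seq_len(cfg$units_per_primary), function(u) {
          # units fan out across the primary's azimuthal sector so their
          # foliage envelopes tile the crown instead of piling up
          sector <- 2 * pi / cfg$n_primary
          phi <- phi0 + sector * (u - (cfg$units_per_primary + 1) / 2) /
            cfg$units_per_primary + stats::runif(1, -0.12, 0.12)
          elev <- (elev0 + stats::runif(1, -6, 6)) * pi / 180
          ax <- 0.15 * cos(phi)
          az <- p$base_z + 0.15 * sin(phi)
          ay <- p$trunk_height
          # leader length solves envelope top = plant height (see vignette)
          l_lead <- ((p$height + p$trunk_height) / 2 - ay) / (0.8 * sin(elev))
          len <- max(lam[u] * l_lead, 0.5)
          cx <- ax + 0.8 * len * cos(elev) * cos(phi)
          cy <- ay + 0.8 * len * sin(elev)
          cz <- az + 0.8 * len * cos(elev) * sin(phi)
          # canopies are kept from closing over the inter-plant gap (and the
          # reference markers in it), as row management prunes them that way
          z_slack <- max(cfg$plant_spacing / 2 - 0.8 - 0.42 * len, 0.1)
          cz <- pmin(pmax(cz, p$base_z - z_slack), p$base_z + z_slack)
          # crowns also stay clear of the inter-row sensor path (~3 m from
          # the axis), so thickness reach is capped at 2.45 m
          x_slack <- max(2.45 - 0.5 * len, 0.05)
          cx <- sign(cx) * min(abs(cx), x_slack)
          tibble::tibble(
            plant_id = p$plant_id,
            branch_id = (b - 1L) * cfg$units_per_primary + u,
            primary = b,
            attach_x = ax, attach_y = ay, attach_z = az,
            dir_x = cos(elev) * cos(phi), dir_y = sin(elev),
            dir_z = cos(elev) * sin(phi),
            length = len,
            cx = cx, cy = cy, cz = cz,
            ex = 0.50 * len, ey = max(cy - p$trunk_height, 0.15),
            ez = 0.42 * len,
            porosity = pmin(pmax(
              preset$porosity + stats::rnorm(1, 0, 0.05), 0.05), 0.8),
            wood_mass = cfg$wood_density * len *
              pi * (cfg$branch_radius_per_length * len)^2
          )
        })
      })
    })

    markers <- if (cfg$n_plants > 1L) {
      tibble::tibble(
        marker_id = seq_len(cfg$n_plants - 1L),
        x = 0, y = 0,
        z = seq_len(cfg$n_plants - 1L) * cfg$plant_spacing,
        pole_height = cfg$marker_pole_height,
        square_side = cfg$marker_square_side
      )
    } else {
      tibble::tibble(marker_id = integer(), x = double(), y = double(),
                     z = double(), pole_height = double(),
                     square_side = double())
    }

    structure(list(plants = plants, branches = branches, markers = markers,
                   config = cfg, seed = as.integer(seed)),
              class = "orchard_scene")
  })
}

#' @export
print.orchard_scene <- function(x, ...) {
  cat("<orchard_scene> ", nrow(x$plants), " plants, ",
      nrow(x$branches), " branch units, ", nrow(x$markers),
      " markers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# True crown volume of one plant: Monte-Carlo volume of the union of its
# foliage envelopes, with a per-plant derived seed so before/after pruning
# use the same sample of points (guaranteeing after <= before).
plant_crown_volume <- function(branches, seed, n_mc = 20000L) {
  if (nrow(branches) == 0L) return(0)
  lo <- c(min(branches$cx - branches$ex), min(branches$cy - branches$ey),
          min(branches$cz - branches$ez))
  hi <- c(max(branches$cx + branches$ex), max(branches$cy + branches$ey),
          max(branches$cz + branches$ez))
  box <- prod(hi - lo)
  with_seed(seed, {
    px <- stats::runif(n_mc, lo[1], hi[1])
    py <- stats::runif(n_mc, lo[2], hi[2])
    pz <- stats::runif(n_mc, lo[3], hi[3])
    inside <- rep(FALSE, n_mc)
    for (j in seq_len(nrow(branches))) {
      b <- branches[j, ]
      inside <- inside |
        (((px - b$cx) / b$ex)^2 + ((py - b$cy) / b$ey)^2 +
           ((pz - b$cz) / b$ez)^2 <= 1)
    }
    box * mean(inside)
  })
}

#' Prune a synthetic orchard
#'
#' Removes whole branch units from each plant until the removed wood mass
#' reaches `intensity` times the plant's total branch mass, preferring units
#' that protrude most along the thickness axis (largest `|x|` reach) and
#' attach lowest -- the criteria a pruner uses when removing branches that
#' protrude into the inter-row. Each removed unit's mass is attributed to the
#' canopy side (east/west) its attachment points to.
#'
#' @param scene An `orchard_scene`.
#' @param intensity Fraction (0..1) of each plant's branch wood mass to
#'   remove; recycled across plants, so per-plant intensities can be given.
#' @param seed Integer seed (tie-break jitter and truth-volume sampling).
#'
#' @return A list with `scene` (the pruned `orchard_scene`) and `truth`, a
#'   tibble with one row per plant: removed branch ids (list-column),
#'   `weight_east`, `weight_west`, `weight_total` (kg) and the Monte-Carlo
#'   true crown volume before/after (m^3).
#' @export
apply_pruning <- function(scene, intensity = 0.25, seed = 1L) {
  stopifnot(inherits(scene, "orchard_scene"))
  if (any(!is.finite(intensity)) || any(intensity < 0) || any(intensity > 1)) {
    rlang::abort("`intensity` must be in [0, 1].",
                 class = "olivescan_config_error")
  }
  n <- nrow(scene$plants)
  intensity <- rep_len(intensity, n)
  with_seed(seed, {
    res <- purrr::map(seq_len(n), function(i) {
      pid <- scene$plants$plant_id[i]
      br <- scene$branches[scene$branches$plant_id == pid, ]
      total <- sum(br$wood_mass)
      target <- intensity[i] * total
      # tie-break jitter is drawn unconditionally so the removal order is
      # identical across intensities under the same seed (nested removals)
      jitter <- stats::rnorm(nrow(br), 0, 1e-3)
      vol_before <- plant_crown_volume(br, child_seed(scene$seed, pid))
      if (target <= 0 || nrow(br) == 0L) {
        return(list(keep = br$branch_id,
                    truth = tibble::tibble(
                      plant_id = pid, removed_branch_ids = list(integer()),
                      weight_east = 0, weight_west = 0, weight_total = 0,
                      volume_before = vol_before, volume_after = vol_before)))
      }
      protrusion <- abs(br$cx) + br$ex
      score <- protrusion - 0.5 * br$cy + jitter
      ord <- order(score, decreasing = TRUE)
      cum <- cumsum(br$wood_mass[ord])
      # remove whole units up to the mass closest to the target (the last
      # unit is kept on the tree if stopping earlier lands nearer the target)
      k <- which(cum >= target - 1e-12)[1]
      if (k > 1L && abs(cum[k - 1L] - target) < abs(cum[k] - target)) {
        k <- k - 1L
      }
      removed <- ord[seq_len(k)]
      rem <- br[removed, ]
      west <- rem$attach_x >= 0
      kept <- br[-removed, , drop = FALSE]
      vol_after <- plant_crown_volume(kept, child_seed(scene$seed, pid))
      list(keep = kept$branch_id,
           truth = tibble::tibble(
             plant_id = pid,
             removed_branch_ids = list(sort(rem$branch_id)),
             weight_east = sum(rem$wood_mass[!west]),
             weight_west = sum(rem$wood_mass[west]),
             weight_total = sum(rem$wood_mass),
             volume_before = vol_before, volume_after = vol_after))
    })
    truth <- purrr::map_dfr(res, "truth")
    kept_ids <- purrr::map2(scene$plants$plant_id, res,
                            function(pid, r) {
                              tibble::tibble(plant_id = pid, branch_id = r$keep)
                            }) %>% purrr::list_rbind()
    pruned <- scene
    pruned$branches <- dplyr::semi_join(scene$branches, kept_ids,
                                        by = c("plant_id", "branch_id"))
    list(scene = pruned, truth = truth)
  })
}

# Ground-truth geometric summaries used by the recovery tests.
scene_truth <- function(scene) {
  br <- scene$branches
  purrr::map_dfr(seq_len(nrow(scene$plants)), function(i) {
    p <- scene$plants[i, ]
    b <- br[br$plant_id == p$plant_id, ]
    if (nrow(b) == 0L) {
      return(tibble::tibble(plant_id = p$plant_id, height = p$trunk_height,
                            trunk_height = p$trunk_height, crown_width = 0,
                            crown_base = NA_real_))
    }
    tibble::tibble(
      plant_id = p$plant_id,
      height = max(b$cy + b$ey),
      trunk_height = p$trunk_height,
      crown_base = min(b$cy - b$ey),
      crown_width = max(b$cx + b$ex) - min(b$cx - b$ex)
    )
  })
}
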