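# End-to-end experiment runner: synthesize -> scan (NP) -> prune -> scan (P)
# -> reconstruct -> segment -> biometrics/volumes -> density -> spectral and
# statistics, mirroring the field workflow on synthetic ground truth.

#' Pipeline configuration
#'
#' Aggregates every tunable parameter of the experiment with defaults equal
#' to the field-protocol values: 0.1 m hull slices, 1e-5 m^3 voxels, 0.4 m density
#' bins, partition factor 3.5, 100 spectral samples per side and alpha 0.05.
#'
#' @param orchard Orchard parameters (passed to [orchard_config()]).
#' @param pruning_intensity Fraction of branch wood mass to remove per
#'   plant, recycled across plants. The default varies across the row,
#'   emulating plants selected for their different development and pruning
#'   need.
#' @param sensor_height,lateral_offset,record_spacing,angular_resolution
#'   Scan-pass geometry shared by both sides (see [scan_pass_spec()]).
#' @param range_noise_sd LiDAR range noise standard deviation (m).
#' @param slice_width VCH slice width (m).
#' @param voxel_volume VV voxel volume (m^3).
#' @param bin_size Height-density bin size (m).
#' @param partition_factor Thickness partition factor `a`.
#' @param sample_n Spectral samples retained per side and plant.
#' @param alpha Significance level.
#' @param spectral_k,spectral_noise_sd Spectral response parameters (see
#'   [simulate_spectral()]).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(orchard = list(),
                            pruning_intensity = seq(0.05, 0.5, length.out = 10),
                            sensor_height = 1.95,
                            lateral_offset = 3.0,
                            record_spacing = 0.2,
                            angular_resolution = 0.33,
                            range_noise_sd = 0.01,
                            slice_width = 0.1,
                            voxel_volume = 1e-5,
                            bin_size = 0.4,
                            partition_factor = 3.5,
                            sample_n = 100L,
                            alpha = 0.05,
                            spectral_k = 0.20,
                            spectral_noise_sd = 0.12,
                            seed = 1L) {
  if (inherits(orchard, "orchard_config")) orchard <- unclass(orchard)
  cfg <- list(orchard = orchard, pruning_intensity = pruning_intensity,
              sensor_height = sensor_height, lateral_offset = lateral_offset,
              record_spacing = record_spacing,
              angular_resolution = angular_resolution,
              range_noise_sd = range_noise_sd, slice_width = slice_width,
              voxel_volume = voxel_volume, bin_size = bin_size,
              partition_factor = partition_factor,
              sample_n = as.integer(sample_n), alpha = alpha,
              spectral_k = spectral_k, spectral_noise_sd = spectral_noise_sd,
              seed = as.integer(seed))
  pos <- c("record_spacing", "slice_width", "voxel_volume", "bin_size",
           "partition_factor", "alpha")
  bad <- pos[vapply(cfg[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad)) {
    rlang::abort(paste0("Non-positive pipeline parameter(s): ",
                        paste(bad, collapse = ", ")),
                 class = "olivescan_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' Stable across sessions; changing any parameter changes the hash. Recorded
#' in every output table's metadata.
#'
#' @param config A [pipeline_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass_deep(config))
}

pass_specs_from_config <- function(config, seed_e, seed_w) {
  list(
    east = scan_pass_spec("east", sensor_height = config$sensor_height,
                          lateral_offset = config$lateral_offset,
                          record_spacing = config$record_spacing,
                          angular_resolution = config$angular_resolution,
                          range_noise_sd = config$range_noise_sd,
                          seed = seed_e),
    west = scan_pass_spec("west", sensor_height = config$sensor_height,
                          lateral_offset = config$lateral_offset,
                          record_spacing = config$record_spacing,
                          angular_resolution = config$angular_resolution,
                          range_noise_sd = config$range_noise_sd,
                          seed = seed_w)
  )
}

#' Reconstruct a row from its two scan series
#'
#' Assembles both passes, detects the reference markers on each, pairs the
#' sides into the row frame, removes ground returns and labels marker points.
#'
#' @param east_series,west_series `scan_series` objects for the two sides.
#' @param height_cut Ground-removal height cut (m).
#' @return List with `cloud` (row-frame, ground removed, marker points
#'   labelled), `markers` (row-frame marker table) and `log` (per-stage point
#'   counts).
#' @export
reconstruct_row <- function(east_series, west_series, height_cut = 0.15) {
  ce <- assemble_pass(east_series)
  cw <- assemble_pass(west_series)
  me <- detect_markers(ce)
  mw <- detect_markers(cw)
  row <- pair_sides(ce, cw, me, mw)
  n_raw <- nrow(row)
  rowg <- remove_ground(row, height_cut = height_cut)
  markers <- detect_markers(rowg)
  rowg <- label_markers(rowg, markers)
  log <- tibble::tibble(
    stage = c("east_points", "west_points", "paired", "after_ground_removal",
              "marker_labelled"),
    n = c(nrow(ce), nrow(cw), n_raw, nrow(rowg),
          sum(rowg$label == "marker")))
  list(cloud = rowg, markers = markers, log = log)
}

#' Analyze one reconstructed row state
#'
#' Splits the row cloud into plants, separates trunks, and computes the
#' biometrics, volume and density tables.
#'
#' @param cloud Row-frame cloud (ground removed).
#' @param markers Marker table used for plant boundaries.
#' @param config A [pipeline_config()].
#' @return List of tibbles: `biometrics`, `volumes`, `density_height`,
#'   `density_thickness`, plus the segmented `cloud`.
#' @export
analyze_row <- function(cloud, markers, config = pipeline_config()) {
  seg <- segment_plants(split_plants(cloud, markers))
  bio <- biometrics_table(seg)
  vol <- volumes_table(seg, slice_width = config$slice_width,
                       voxel_vol = config$voxel_volume)
  dens <- density_tables(seg, bin_size = config$bin_size,
                         a = config$partition_factor)
  list(biometrics = bio, volumes = vol,
       density_height = dens$height, density_thickness = dens$thickness,
       cloud = seg)
}

assign_plants_by_z <- function(z, markers) {
  if (nrow(markers) == 0L) return(rep(1L, length(z)))
  findInterval(z, sort(markers$z), left.open = TRUE) + 1L
}

# External-canopy density per plant and side: mean density of the two
# outermost sections of that exposition (labels 1 and 2).
external_density <- function(thickness_tbl) {
  thickness_tbl %>%
    dplyr::filter(.data$section %in% c("E1", "E2", "W1", "W2")) %>%
    dplyr::mutate(side = substr(as.character(.data$section), 1, 1)) %>%
    dplyr::group_by(.data$plant_id, .data$side) %>%
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
}

#' Run the full synthetic experiment
#'
#' Executes the whole workflow on a synthetic orchard: generate the scene,
#' scan both sides and sample the spectral sensor before pruning, prune with
#' known removed mass, scan again, reconstruct and segment both states,
#' compute biometrics, the four volume estimators and the density profiles,
#' clean and sample the spectral data, and run the protocol's statistics
#' (volume-change vs pruning-weight correlations; pre/post band comparisons;
#' external density vs band/index correlations).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `report_bundle`: a list of tibbles
#'   (`biometrics`, `pruning`, `volume_weight_correlations`,
#'   `density_height`, `density_thickness`, `spectral_summary`,
#'   `density_vi_correlations`, `log`) plus `meta` (seeds, config hash).
#'   Deterministic given the config seed.
#' @export
run_experiment <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  scene <- generate_orchard(do.call(orchard_config, config$orchard),
                            seed = child_seed(seed, 1))

  passes_np <- pass_specs_from_config(config, child_seed(seed, 2),
                                      child_seed(seed, 3))
  scan_np_e <- simulate_scan(scene, passes_np$east)
  scan_np_w <- simulate_scan(scene, passes_np$west)
  spec_np <- dplyr::bind_rows(
    simulate_spectral(scene, passes_np$east, k = config$spectral_k,
                      noise_sd = config$spectral_noise_sd),
    simulate_spectral(scene, passes_np$west, k = config$spectral_k,
                      noise_sd = config$spectral_noise_sd))

  pr <- apply_pruning(scene, intensity = config$pruning_intensity,
                      seed = child_seed(seed, 4))
  passes_p <- pass_specs_from_config(config, child_seed(seed, 5),
                                     child_seed(seed, 6))
  scan_p_e <- simulate_scan(pr$scene, passes_p$east)
  scan_p_w <- simulate_scan(pr$scene, passes_p$west)
  spec_p <- dplyr::bind_rows(
    simulate_spectral(pr$scene, passes_p$east, k = config$spectral_k,
                      noise_sd = config$spectral_noise_sd),
    simulate_spectral(pr$scene, passes_p$west, k = config$spectral_k,
                      noise_sd = config$spectral_noise_sd))

  rec_np <- reconstruct_row(scan_np_e, scan_np_w)
  rec_p <- reconstruct_row(scan_p_e, scan_p_w)
  an_np <- analyze_row(rec_np$cloud, rec_np$markers, config)
  an_p <- analyze_row(rec_p$cloud, rec_p$markers, config)

  biometrics <- dplyr::bind_rows(
    dplyr::left_join(an_np$biometrics, an_np$volumes, by = "plant_id") %>%
      dplyr::mutate(state = "NP", .after = "plant_id"),
    dplyr::left_join(an_p$biometrics, an_p$volumes, by = "plant_id") %>%
      dplyr::mutate(state = "P", .after = "plant_id"))

  # volume change vs removed wood mass
  dv <- dplyr::inner_join(an_np$volumes, an_p$volumes, by = "plant_id",
                          suffix = c("_np", "_p")) %>%
    dplyr::inner_join(pr$truth[, c("plant_id", "weight_total")],
                      by = "plant_id")
  vw <- purrr::map_dfr(c("VCH", "VV", "VCY", "VSP"), function(v) {
    d <- dv[[paste0(v, "_np")]] - dv[[paste0(v, "_p")]]
    tidy(pearson_correlation(d, dv$weight_total,
                             label = paste0("d", v, "~weight")))
  })

  # spectral: clean, assign plant/side, sample, summarise, compare
  bounds_np <- rec_np$markers
  spectral <- dplyr::bind_rows(
    dplyr::mutate(spec_np, state = "NP"),
    dplyr::mutate(spec_p, state = "P")) %>%
    clean_spectral() %>%
    dplyr::mutate(plant_id = assign_plants_by_z(.data$z, bounds_np))
  sampled <- spectral %>%
    dplyr::group_by(.data$state, .data$plant_id) %>%
    dplyr::group_modify(function(d, key) {
      sample_per_side(d, n = config$sample_n,
                      seed = child_seed(seed, 7 + key$plant_id))
    }) %>%
    dplyr::ungroup()

  bands <- c("red", "red_edge", "nir", "ndvi", "ndre")
  spectral_summary <- purrr::map_dfr(bands, function(b) {
    np <- sampled[[b]][sampled$state == "NP"]
    p <- sampled[[b]][sampled$state == "P"]
    cmp <- pre_post_comparison(np, p, alpha = config$alpha, variable = b)
    glance(cmp) %>%
      dplyr::mutate(mean_np = cmp$mean_np, sd_np = cmp$sd_np,
                    letter_np = cmp$letters[["NP"]],
                    mean_p = cmp$mean_p, sd_p = cmp$sd_p,
                    letter_p = cmp$letters[["P"]])
  })

  # external-canopy density vs band/index, per state
  dvi <- purrr::map_dfr(c(NP = "NP", P = "P"), function(st) {
    thick <- if (st == "NP") an_np$density_thickness else an_p$density_thickness
    ext <- external_density(thick)
    per_side <- sampled %>%
      dplyr::filter(.data$state == st) %>%
      dplyr::group_by(.data$plant_id, .data$side) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(bands), mean),
                       .groups = "drop") %>%
      dplyr::inner_join(ext, by = c("plant_id", "side"))
    purrr::map_dfr(bands, function(b) {
      if (nrow(per_side) < 3L || stats::sd(per_side[[b]]) == 0 ||
          stats::sd(per_side$density) == 0) {
        return(tibble::tibble(state = st, pair = paste0(b, "~density"),
                              r = NA_real_, p = NA_real_,
                              n = nrow(per_side), significant = NA))
      }
      tidy(pearson_correlation(per_side[[b]], per_side$density,
                               label = paste0(b, "~density"))) %>%
        dplyr::mutate(state = st, .before = 1)
    })
  })

  log <- dplyr::bind_rows(
    dplyr::mutate(rec_np$log, state = "NP", .before = 1),
    dplyr::mutate(rec_p$log, state = "P", .before = 1))

  structure(list(
    biometrics = biometrics,
    pruning = pr$truth,
    volume_weight_correlations = vw,
    density_height = dplyr::bind_rows(
      dplyr::mutate(an_np$density_height, state = "NP", .before = 1),
      dplyr::mutate(an_p$density_height, state = "P", .before = 1)),
    density_thickness = dplyr::bind_rows(
      dplyr::mutate(an_np$density_thickness, state = "NP", .before = 1),
      dplyr::mutate(an_p$density_thickness, state = "P", .before = 1)),
    spectral_summary = spectral_summary,
    density_vi_correlations = dvi,
    log = log,
    meta = list(seed = seed, config_hash = config_hash(config),
                config = config)
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$meta$seed, "hash", x$meta$config_hash, "\n")
  cat("  plants:", length(unique(x$biometrics$plant_id)),
      " states:", paste(unique(x$biometrics$state), collapse = "/"), "\n")
  cat("  tables: biometrics, pruning, volume_weight_correlations,",
      "density_height,\n    density_thickness, spectral_summary,",
      "density_vi_correlations, log\n")
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `report_bundle`.
#' @param ... Unused.
#' @export
glance.report_bundle <- function(x, ...) {
  b <- x$biometrics
  tibble::tibble(
    n_plants = length(unique(b$plant_id)),
    mean_weight_removed = mean(x$pruning$weight_total),
    mean_VCH_np = mean(b$VCH[b$state == "NP"]),
    mean_VV_np = mean(b$VV[b$state == "NP"]),
    r_dVV_weight = x$volume_weight_correlations$r[
      x$volume_weight_correlations$pair == "dVV~weight"],
    seed = x$meta$seed,
    config_hash = x$meta$config_hash
  )
}

#' Write every table of a report bundle as CSV
#'
#' Each file carries the stage seed and config hash as '#' comment header
#' lines.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("biometrics", "pruning", "volume_weight_correlations",
              "density_height", "density_thickness", "spectral_summary",
              "density_vi_correlations", "log")
  paths <- vapply(tables, function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    df <- bundle[[tb]]
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                          ~vapply(.x, paste, character(1),
                                                  collapse = ";")))
    writeLines(c(paste0("# seed: ", bundle$meta$seed),
                 paste0("# config_hash: ", bundle$meta$config_hash)), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
    path
  }, character(1))
  invisible(paths)
}
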