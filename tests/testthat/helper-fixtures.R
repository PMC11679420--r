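# Fixtures built in code: small scenes, analytic solids and sampled clouds.

make_cloud <- function(x, y, z, label = "unknown") {
  tibble::tibble(x = as.double(x), y = as.double(y), z = as.double(z),
                 label = label)
}

# Uniform sample of a solid sphere (radius r, centered at `center`).
solid_sphere_cloud <- function(n, r = 1, center = c(0, 0, 0), seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- r * stats::runif(n)^(1 / 3)
    make_cloud(center[1] + rad * u[, 1], center[2] + rad * u[, 2],
               center[3] + rad * u[, 3])
  })
}

# Grid sample of a cube of side `side`, aligned to the voxel corners of a
# grid with voxel volume `v` (grid step = voxel side, plus the closing face).
cube_corner_cloud <- function(side = 0.43, v = 1e-5) {
  s <- v^(1 / 3)
  g <- c(seq(0, side - 1e-9, by = s), side)
  make_cloud(rep(g, times = length(g)^2),
             rep(rep(g, each = length(g)), times = length(g)),
             rep(g, each = length(g)^2))
}

# Points sampled on the foliage-envelope surfaces of one plant of a scene.
surface_crown_cloud <- function(scene, plant_id, n_per_branch = 60, seed = 1) {
  br <- scene$branches[scene$branches$plant_id == plant_id, ]
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(br)), function(j) {
      b <- br[j, ]
      u <- matrix(stats::rnorm(3 * n_per_branch), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      make_cloud(b$cx + b$ex * u[, 1], b$cy + b$ey * u[, 2],
                 b$cz + b$ez * u[, 3], label = "canopy")
    })
  })
}

# Small scene + noiseless scans for reconstruction tests.
small_scene <- function(n_plants = 2, seed = 3) {
  generate_orchard(orchard_config(n_plants = n_plants), seed = seed)
}

noiseless_pass <- function(side, seed = 1) {
  scan_pass_spec(side, range_noise_sd = 0, seed = seed)
}

# Squared ellipsoid form value of points against one branch envelope row.
envelope_q <- function(cloud, b) {
  ((cloud$x - b$cx) / b$ex)^2 + ((cloud$y - b$cy) / b$ey)^2 +
    ((cloud$z - b$cz) / b$ez)^2
}
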