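# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Run `expr` under a temporary RNG state. `seed` must be a single finite
# integer-like value; all stochastic operations in the package go through this
# so identical (input, seed) pairs reproduce results bit-for-bit.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific child seed (kept inside 32-bit integer range).
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}

assert_cloud <- function(cloud, min_points = 0L, arg = "cloud") {
  if (!is.data.frame(cloud) || !all(c("x", "y", "z") %in% names(cloud))) {
    abort(sprintf("`%s` must be a data frame with columns x, y, z.", arg))
  }
  if (nrow(cloud) < min_points) {
    abort(sprintf("`%s` must contain at least %d point(s).", arg, min_points))
  }
  if (nrow(cloud) > 0L &&
      !all(is.finite(cloud$x) & is.finite(cloud$y) & is.finite(cloud$z))) {
    abort(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  invisible(cloud)
}

#' Point-cloud label vocabulary
#'
#' Closed set of per-point categories used throughout the package and in the
#' CSV/PLY interchange formats.
#'
#' @return Character vector of the allowed labels.
#' @export
cloud_labels <- function() c("ground", "canopy", "trunk", "marker", "unknown")

as_cloud <- function(x, y, z, label = "unknown") {
  tibble::tibble(x = as.double(x), y = as.double(y), z = as.double(z),
                 label = label)
}

# Half-open binning with the last (closing) boundary folded into the final
# bin, so bins are contiguous and cover [min, max]. Returns 0-based indices.
bin_index <- function(v, origin, width, n_bins) {
  i <- floor((v - origin) / width + 1e-9)
  pmin(pmax(i, 0), n_bins - 1L)
}

n_bins_for <- function(extent, width) {
  max(1L, as.integer(ceiling(extent / width - 1e-9)))
}

# Shoelace area of the convex hull of 2D points; degenerate inputs give 0.
hull_area <- function(u, v) {
  keep <- !duplicated(cbind(u, v))
  u <- u[keep]; v <- v[keep]
  if (length(u) < 3L) return(0)
  h <- grDevices::chull(u, v)
  if (length(h) < 3L) return(0)
  uu <- u[h]; vv <- v[h]
  abs(sum(uu * c(vv[-1], vv[1]) - c(uu[-1], uu[1]) * vv)) / 2
}
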