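# Interchange formats. CSV is canonical (UTF-8, '.' decimal, mandatory
# header); point clouds are also exchanged as ASCII PLY with a label scalar.
# Scan CSVs carry the pass specification in '#' comment lines.

label_codes <- function() {
  stats::setNames(seq_along(cloud_labels()) - 1L, cloud_labels())
}

pass_fields <- c("side", "sensor_height", "lateral_offset", "record_spacing",
                 "speed", "scan_frequency", "angular_resolution",
                 "scan_sector", "min_range", "max_range", "range_noise_sd",
                 "seed")

#' Write / read a scan series as CSV
#'
#' Dialect: '#'-prefixed `key: value` header lines holding the pass
#' specification, then a CSV with columns `station`, `z`, `angle_deg`,
#' `range_m`. The no-return sentinel is `-1`; any other range outside the
#' pass working range is rejected with its line number.
#'
#' @param series A `scan_series`.
#' @param path File path.
#' @return `write_scan_csv` returns `path` invisibly; `read_scan_csv`
#'   returns a `scan_series`.
#' @export
write_scan_csv <- function(series, path) {
  pass <- attr(series, "pass")
  if (is.null(pass)) rlang::abort("`series` lacks a pass specification.")
  meta <- vapply(pass_fields, function(f) {
    paste0("# ", f, ": ", format(pass[[f]], digits = 17))
  }, character(1))
  writeLines(meta, path)
  out <- tibble::tibble(station = series$station, z = series$z,
                        angle_deg = series$angle, range_m = series$range)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    meta[[key]] <- val
  }
  missing_meta <- setdiff(pass_fields, names(meta))
  if (length(missing_meta)) {
    rlang::abort(paste0("Scan CSV is missing pass metadata: ",
                        paste(missing_meta, collapse = ", ")),
                 class = "olivescan_format_error")
  }
  num <- setdiff(pass_fields, "side")
  args <- c(list(side = meta$side),
            lapply(stats::setNames(num, num), function(f) as.numeric(meta[[f]])))
  pass <- do.call(scan_pass_spec, args)

  df <- suppressWarnings(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE))
  if (nrow(df) == 0L) {
    rlang::warn("Empty scan file; returning an empty series.")
    out <- tibble::tibble(station = integer(), z = double(),
                          angle = double(), range = double())
    attr(out, "pass") <- pass
    class(out) <- c("scan_series", class(out))
    return(out)
  }
  need <- c("station", "z", "angle_deg", "range_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("Scan CSV is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "olivescan_format_error")
  }
  bad <- which(df$range_m != -1 &
                 (df$range_m < pass$min_range | df$range_m > pass$max_range))
  if (length(bad)) {
    rlang::abort(sprintf(
      "Range outside working range [%g, %g] at data line %d.",
      pass$min_range, pass$max_range, bad[1]),
      class = "olivescan_format_error")
  }
  st <- unique(df[, c("station", "z")])
  if (is.unsorted(st$z[order(st$station)], strictly = FALSE) &&
      is.unsorted(-st$z[order(st$station)])) {
    rlang::abort("Station z positions are not monotone.",
                 class = "olivescan_format_error")
  }
  out <- tibble::tibble(station = as.integer(df$station), z = df$z,
                        angle = df$angle_deg, range = df$range_m)
  attr(out, "pass") <- pass
  class(out) <- c("scan_series", class(out))
  out
}

#' Write / read labeled point clouds (CSV or ASCII PLY)
#'
#' CSV columns are `x`, `y`, `z`, `label`; the PLY flavour is ASCII 1.0 with
#' double precision coordinates and an integer `label` scalar encoding the
#' closed vocabulary of [cloud_labels()]. Round-trips preserve coordinates
#' exactly (shortest round-trip decimal representation) and labels.
#'
#' @param cloud Point cloud tibble (`x`, `y`, `z`, optional `label`).
#' @param path File path; the format follows the extension (`.ply` is PLY,
#'   anything else CSV).
#' @return `write_pointcloud` returns `path` invisibly; `read_pointcloud`
#'   returns the cloud.
#' @export
write_pointcloud <- function(cloud, path) {
  assert_cloud(cloud)
  label <- if ("label" %in% names(cloud)) cloud$label else
    rep("unknown", nrow(cloud))
  bad <- setdiff(unique(label), cloud_labels())
  if (length(bad)) {
    rlang::abort(paste0("Unknown point label(s): ", paste(bad, collapse = ", ")),
                 class = "olivescan_format_error")
  }
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    codes <- label_codes()
    header <- c(
      "ply", "format ascii 1.0",
      paste("comment label codes:",
            paste(sprintf("%d=%s", codes, names(codes)), collapse = " ")),
      paste("element vertex", nrow(cloud)),
      "property double x", "property double y", "property double z",
      "property int label", "end_header")
    body <- sprintf("%.17g %.17g %.17g %d", cloud$x, cloud$y, cloud$z,
                    codes[label])
    writeLines(c(header, body), path)
  } else {
    readr::write_csv(tibble::tibble(x = cloud$x, y = cloud$y, z = cloud$z,
                                    label = label), path)
  }
  invisible(path)
}

#' @rdname write_pointcloud
#' @export
read_pointcloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    end <- match("end_header", lines)
    if (lines[1] != "ply" || is.na(end)) {
      rlang::abort("Malformed PLY header.", class = "olivescan_format_error")
    }
    nv_line <- grep("^element vertex", lines[seq_len(end)], value = TRUE)
    if (length(nv_line) != 1L) {
      rlang::abort("Malformed PLY header: missing vertex element.",
                   class = "olivescan_format_error")
    }
    nv <- as.integer(sub("^element vertex\\s+", "", nv_line))
    body <- lines[seq(end + 1L, length.out = nv)]
    if (nv == 0L) {
      return(as_cloud(double(), double(), double(), character()))
    }
    parts <- do.call(rbind, strsplit(body, "\\s+"))
    codes <- label_codes()
    lab_idx <- as.integer(parts[, 4]) + 1L
    if (any(is.na(lab_idx)) || any(lab_idx < 1L) ||
        any(lab_idx > length(codes))) {
      rlang::abort("Unknown label code in PLY body.",
                   class = "olivescan_format_error")
    }
    as_cloud(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
             as.numeric(parts[, 3]), names(codes)[lab_idx])
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("x", "y", "z")
    if (!all(need %in% names(df))) {
      rlang::abort("Point-cloud CSV must have columns x, y, z.",
                   class = "olivescan_format_error")
    }
    label <- if ("label" %in% names(df)) df$label else
      rep("unknown", nrow(df))
    bad <- setdiff(unique(label), cloud_labels())
    if (length(bad)) {
      rlang::abort(paste0("Unknown point label(s): ",
                          paste(bad, collapse = ", ")),
                   class = "olivescan_format_error")
    }
    as_cloud(df$x, df$y, df$z, label)
  }
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()] list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
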