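# Vegetation indices, sample cleaning, per-side sampling and the protocol's
# statistics: Pearson correlation with the |r| > 0.6 & p < 0.05 significance
# rule, and pre/post-pruning comparison (ANOVA + Tukey HSD with Bonferroni
# alpha correction).

#' Normalized difference vegetation indices
#'
#' `NDVI = (NIR - RED) / (NIR + RED)` and `NDRE = (NIR - RE) / (NIR + RE)`.
#'
#' @param red,re,nir Reflectances in the red, red-edge and near-infrared
#'   bands (vectorized).
#' @return Tibble with columns `ndvi` and `ndre`.
#' @examples
#' compute_vis(red = 0.077, re = 0.207, nir = 0.341)
#' @export
compute_vis <- function(red, re, nir) {
  if (any(nir + red == 0) || any(nir + re == 0)) {
    rlang::abort("Undefined index: a band sum is zero.",
                 class = "olivescan_index_error")
  }
  tibble::tibble(ndvi = (nir - red) / (nir + red),
                 ndre = (nir - re) / (nir + re))
}

#' Clean multispectral samples
#'
#' Drops samples with any negative band value (the sensor's empty-area
#' sentinel between plants), then samples whose NDVI or NDRE falls outside
#' the vegetation range `[0, 1]`. Order-preserving and idempotent. Missing
#' index columns are computed from the bands.
#'
#' @param samples Tibble with columns `red`, `red_edge`, `nir` and optionally
#'   `ndvi`, `ndre`.
#' @return The cleaned tibble.
#' @export
clean_spectral <- function(samples) {
  stopifnot(all(c("red", "red_edge", "nir") %in% names(samples)))
  ok <- samples$red > 0 & samples$red_edge > 0 & samples$nir > 0
  out <- samples[ok, , drop = FALSE]
  if (nrow(out) > 0L && !all(c("ndvi", "ndre") %in% names(out))) {
    vis <- compute_vis(out$red, out$red_edge, out$nir)
    out$ndvi <- vis$ndvi
    out$ndre <- vis$ndre
  }
  if (nrow(out) == 0L) return(out)
  keep <- out$ndvi >= 0 & out$ndvi <= 1 & out$ndre >= 0 & out$ndre <= 1
  out[keep, , drop = FALSE]
}

#' Sample a fixed number of points per canopy side
#'
#' Uniform sampling without replacement of `n` points per side (E and W);
#' when fewer than `n` are available on a side, all of them are kept with a
#' warning. The original row order is preserved.
#'
#' @param samples Tibble with a `side` column ("E"/"W").
#' @param n Points to retain per side.
#' @param seed Integer seed.
#' @return Subset of `samples`.
#' @export
sample_per_side <- function(samples, n = 100L, seed = 1L) {
  stopifnot("side" %in% names(samples))
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(samples)), samples$side),
                         function(i) {
      if (length(i) <= n) {
        if (length(i) < n) {
          rlang::warn(sprintf("Only %d samples available on one side (requested %d); keeping all.",
                              length(i), n))
        }
        i
      } else {
        sample(i, n)
      }
    }), use.names = FALSE)
    samples[sort(idx), , drop = FALSE]
  })
}

#' Pearson correlation with the field-protocol significance rule
#'
#' Product-moment correlation with the p-value from the exact t reference
#' distribution on n - 2 degrees of freedom; a pair is significant when
#' `|r| > 0.6` and `p < 0.05`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero variance).
#' @param label Optional pair label.
#' @return Object of class `olive_correlation` (list with `label`, `r`, `p`,
#'   `n`, `significant`); see [generics::tidy()].
#' @export
pearson_correlation <- function(x, y, label = NULL) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length.")
  if (length(x) < 3L) rlang::abort("At least 3 observations are required.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Zero variance: correlation undefined.",
                 class = "olivescan_correlation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  structure(list(label = label %||% "x~y", r = r, p = p, n = length(x),
                 significant = abs(r) > 0.6 && p < 0.05),
            class = "olive_correlation")
}

#' @export
print.olive_correlation <- function(x, ...) {
  cat(sprintf("<olive_correlation> %s: r = %.3f, p = %.4g, n = %d%s\n",
              x$label, x$r, x$p, x$n,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' @rdname pearson_correlation
#' @param x An `olive_correlation` object.
#' @param ... Unused.
#' @export
tidy.olive_correlation <- function(x, ...) {
  tibble::tibble(pair = x$label, r = x$r, p = x$p, n = x$n,
                 significant = x$significant)
}

#' Pre/post-pruning comparison
#'
#' One-way ANOVA comparing a variable before (NP) and after (P) a treatment,
#' followed by Tukey's HSD at a Bonferroni-corrected alpha; groups that do
#' not differ share a letter code. An optional normalizing pre-transform can
#' be applied to both groups.
#'
#' @param values_np,values_p Numeric vectors for the untreated / treated
#'   group (each n >= 2).
#' @param alpha Significance level before correction.
#' @param transform Pre-transform applied to both groups: `"identity"`,
#'   `"log"` or `"rank"`.
#' @param n_comparisons Number of simultaneous comparisons for the Bonferroni
#'   correction of `alpha`.
#' @param variable Optional variable label.
#' @return Object of class `olive_comparison`; see [generics::tidy()] and
#'   [generics::glance()].
#' @export
pre_post_comparison <- function(values_np, values_p, alpha = 0.05,
                                transform = c("identity", "log", "rank"),
                                n_comparisons = 1L, variable = NULL) {
  transform <- match.arg(transform)
  if (length(values_np) < 2L || length(values_p) < 2L) {
    rlang::abort("Each group needs at least 2 observations.",
                 class = "olivescan_comparison_error")
  }
  vals <- c(values_np, values_p)
  grp <- factor(rep(c("NP", "P"), c(length(values_np), length(values_p))),
                levels = c("NP", "P"))
  tv <- switch(transform,
               identity = vals,
               log = {
                 if (any(vals <= 0)) rlang::abort("log transform needs positive values.")
                 log(vals)
               },
               rank = rank(vals))
  fit <- stats::aov(tv ~ grp)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p_anova <- an[["Pr(>F)"]][1]
  hsd <- tryCatch(stats::TukeyHSD(fit)$grp[, "p adj"],
                  error = function(e) NA_real_)
  p_tukey <- unname(hsd)
  alpha_adj <- alpha / max(1L, n_comparisons)
  different <- is.finite(p_tukey) && p_tukey < alpha_adj
  structure(list(
    variable = variable %||% "value",
    mean_np = mean(values_np), sd_np = stats::sd(values_np),
    mean_p = mean(values_p), sd_p = stats::sd(values_p),
    statistic = fstat, p_anova = p_anova, p_tukey = p_tukey,
    alpha = alpha, alpha_adj = alpha_adj, transform = transform,
    n_np = length(values_np), n_p = length(values_p),
    letters = if (different) c(NP = "a", P = "b") else c(NP = "a", P = "a")
  ), class = "olive_comparison")
}

#' @export
print.olive_comparison <- function(x, ...) {
  cat(sprintf(
    "<olive_comparison> %s: NP %.3f+/-%.3f (%s) vs P %.3f+/-%.3f (%s), F = %.3g, p = %.4g\n",
    x$variable, x$mean_np, x$sd_np, x$letters["NP"], x$mean_p, x$sd_p,
    x$letters["P"], x$statistic, x$p_anova))
  invisible(x)
}

#' @rdname pre_post_comparison
#' @param x An `olive_comparison` object.
#' @param ... Unused.
#' @export
tidy.olive_comparison <- function(x, ...) {
  tibble::tibble(
    variable = x$variable,
    group = c("NP", "P"),
    mean = c(x$mean_np, x$mean_p),
    sd = c(x$sd_np, x$sd_p),
    n = c(x$n_np, x$n_p),
    letter = unname(x$letters)
  )
}

#' @rdname pre_post_comparison
#' @export
glance.olive_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, statistic = x$statistic,
                 p_anova = x$p_anova, p_tukey = x$p_tukey,
                 alpha_adj = x$alpha_adj, transform = x$transform,
                 significant = all(x$letters == c("a", "b")))
}
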