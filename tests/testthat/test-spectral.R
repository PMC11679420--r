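test_that("vegetation indices evaluate their ratio formulas", {
  expect_equal(compute_vis(0.3, 0.2, 0.3)$ndvi, 0)
  v <- compute_vis(0.077, 0.207, 0.341)
  expect_equal(v$ndvi, 0.63158, tolerance = 1e-4)
  expect_equal(v$ndre, 0.24453, tolerance = 1e-4)
  expect_error(compute_vis(-0.3, 0.2, 0.3), class = "olivescan_index_error")
  # positive reflectances keep both indices strictly inside (-1, 1)
  withr::with_seed(2, {
    r <- runif(200, 0.001, 1); re <- runif(200, 0.001, 1)
    n <- runif(200, 0.001, 1)
  })
  vv <- compute_vis(r, re, n)
  expect_true(all(vv$ndvi > -1 & vv$ndvi < 1 & vv$ndre > -1 & vv$ndre < 1))
})

test_that("cleaning drops sentinels and out-of-range indices, idempotently", {
  s <- tibble::tibble(
    red = c(0.08, -1, 0.08, 0.07),
    red_edge = c(0.2, 0.2, 0.2, 0.21),
    nir = c(0.34, 0.35, 0.33, 0.36),
    ndvi = c(0.62, 0.6, 1.2, 0.67),
    ndre = c(0.25, 0.2, 0.3, 0.26))
  cl <- clean_spectral(s)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$red, c(0.08, 0.07))    # order preserved
  expect_identical(clean_spectral(cl), cl)
  # indices are computed from the bands when absent
  cl2 <- clean_spectral(s[, c("red", "red_edge", "nir")])
  expect_true(all(c("ndvi", "ndre") %in% names(cl2)))
})

test_that("per-side sampling retains n per side, with the fallback warning", {
  withr::with_seed(3, {
    s <- tibble::tibble(side = rep(c("E", "W"), each = 150),
                        ndvi = runif(300, 0.4, 0.8))
  })
  kept <- sample_per_side(s, n = 100, seed = 4)
  expect_equal(nrow(kept), 200L)
  expect_equal(as.integer(table(kept$side)), c(100L, 100L))
  expect_identical(sample_per_side(s, n = 100, seed = 4), kept)
  short <- s[c(1:40, 151:300), ]
  expect_warning(k2 <- sample_per_side(short, n = 100, seed = 4),
                 "keeping all")
  expect_equal(sum(k2$side == "E"), 40L)
})

test_that("correlation matches hand and brute-force evaluations", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  # brute-force product-moment oracle, double loop over deviations
  withr::with_seed(6, {
    u <- rnorm(40); v <- 0.3 * u + rnorm(40)
  })
  n <- length(u)
  num <- 0; du <- 0; dv <- 0
  for (i in seq_len(n)) {
    num <- num + (u[i] - mean(u)) * (v[i] - mean(v))
    du <- du + (u[i] - mean(u))^2
    dv <- dv + (v[i] - mean(v))^2
  }
  r_bf <- num / sqrt(du * dv)
  t_bf <- r_bf * sqrt((n - 2) / (1 - r_bf^2))
  p_bf <- 2 * stats::pt(-abs(t_bf), n - 2)
  got <- pearson_correlation(u, v)
  expect_equal(got$r, r_bf, tolerance = 1e-12)
  expect_equal(got$p, p_bf, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5),
               class = "olivescan_correlation_error")
  expect_error(pearson_correlation(1:2, 1:2))
})

test_that("significance needs both a strong r and a small p", {
  # tiny sample: r can exceed 0.6 while p stays large
  got <- pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$r, 0.6)
  expect_false(got$significant)
  strong <- pearson_correlation(1:30, 1:30 + rnorm(30, 0, 2))
  expect_true(strong$p < 0.05)
  td <- tidy(strong)
  expect_equal(td$significant, abs(td$r) > 0.6 && td$p < 0.05)
})

test_that("pre/post comparison assigns letters like the field tables", {
  g <- c(rnorm(50), 5)
  same <- pre_post_comparison(g, g)
  expect_equal(unname(same$letters), c("a", "a"))
  withr::with_seed(7, {
    a <- rnorm(200); b <- rnorm(200, 5)
  })
  diff <- pre_post_comparison(a, b)
  expect_equal(unname(diff$letters), c("a", "b"))
  expect_lt(diff$p_anova, 1e-10)
  # two groups: Tukey's HSD must reproduce the two-sample ANOVA p
  expect_equal(diff$p_tukey, diff$p_anova, tolerance = 1e-9)
  m <- pre_post_comparison(a, a + 0.01)
  expect_equal(m$p_tukey, m$p_anova, tolerance = 1e-9)
  expect_error(pre_post_comparison(1, 1:3),
               class = "olivescan_comparison_error")
  gl <- glance(diff)
  expect_true(gl$significant)
  td <- tidy(diff)
  expect_equal(td$mean, c(mean(a), mean(b)))
})

test_that("comparison transforms and Bonferroni correction apply", {
  withr::with_seed(11, {
    a <- rlnorm(60); b <- rlnorm(60, 0.1)
  })
  lg <- pre_post_comparison(a, b, transform = "log")
  expect_equal(lg$transform, "log")
  rk <- pre_post_comparison(a, b, transform = "rank")
  expect_equal(rk$transform, "rank")
  bc <- pre_post_comparison(a, b, n_comparisons = 5)
  expect_equal(bc$alpha_adj, 0.01)
})

test_that("null pruning effects keep the type-I error near nominal", {
  withr::with_seed(13, {
    hits <- vapply(seq_len(1000), function(i) {
      a <- rnorm(50); b <- rnorm(50)
      all(pre_post_comparison(a, b)$letters == c("a", "b"))
    }, logical(1))
  })
  expect_lte(mean(hits), 0.07)
})
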