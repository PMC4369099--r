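test_that("count summaries compute exact moments and include zeros", {
  s <- summarize_counts(c(10, 10, 10))
  expect_equal(c(s$mean, s$median, s$cv), c(10, 10, 0))
  s2 <- summarize_counts(c(0, 0, 0, 40))
  expect_equal(s2$mean, 10)
  expect_equal(s2$median, 0)
  expect_error(summarize_counts(c(-1, 3)), class = "lincfish_input_error")
  expect_error(summarize_counts(numeric(0)), class = "lincfish_input_error")
})

test_that("summaries are permutation-invariant in cells", {
  set.seed(1)
  x <- rpois(50, 12)
  a <- summarize_counts(x)
  b <- summarize_counts(sample(x))
  expect_equal(a[, c("mean", "median", "sd", "cv")],
               b[, c("mean", "median", "sd", "cv")])
})

test_that("histogram bins are 3-wide to 50 then 10-wide to 300", {
  h <- count_histogram(c(0, 2, 3, 49, 50, 55, 299, 300, 350))
  expect_equal(h$bin_lo[1:3], c(0, 3, 6))
  expect_true(all(diff(h$bin_lo[h$bin_lo < 48]) == 3))
  expect_true(all(diff(h$bin_lo[h$bin_lo >= 50]) == 10))
  expect_equal(sum(h$n), 9)             # nothing dropped, top bin open
  expect_equal(h$n[h$bin_lo == 0], 2)   # 0 and 2
  expect_equal(h$n[h$bin_lo == 3], 1)   # right-open bins
})

test_that("empirical Poisson CV matches the 1/sqrt(mean) reference", {
  expect_equal(poisson_reference(1), 1)
  expect_equal(poisson_reference(100), 0.1)
  set.seed(2)
  x <- rpois(10000, 20)
  expect_lt(abs(summarize_counts(x)$cv - poisson_reference(20)) /
              poisson_reference(20), 0.05)
  expect_error(poisson_reference(0), class = "lincfish_input_error")
})

test_that("mean-median regression recovers exact linear relationships", {
  d <- tibble::tibble(mean = c(5, 10, 20, 40), median = c(5, 10, 20, 40))
  f <- mean_median_regression(d)
  expect_equal(c(f$slope, f$intercept, f$pearson_r), c(1, 0, 1))
  d2 <- tibble::tibble(mean = seq(5, 60, 5))
  d2$median <- 0.87 * d2$mean - 1.25
  f2 <- mean_median_regression(d2)
  expect_equal(f2$slope, 0.87, tolerance = 1e-12)
  expect_equal(f2$intercept, -1.25, tolerance = 1e-10)
  expect_error(mean_median_regression(tibble::tibble(mean = c(3, 3, 3),
                                                     median = 1:3)),
               class = "lincfish_degenerate")
})

test_that("a unimodal cohort sits on a near-identity mean-median line", {
  set.seed(3)
  summaries <- purrr::map_dfr(1:20, function(i) {
    mu <- runif(1, 5, 80)
    summarize_counts(sample_counts(
      count_model("negative_binomial", mean = mu, size = 8), 60))
  })
  f <- mean_median_regression(summaries)
  expect_gt(f$slope, 0.7); expect_lte(f$slope, 1.05)
  expect_gt(f$pearson_r, 0.9)
})

test_that("bimodal cohorts show mean far above median, unlike unimodal ones", {
  x <- sample_counts(count_model("bimodal_mixture"), 500, seed = 4)
  s <- summarize_counts(x)
  expect_gt(s$mean / s$median, 2)
  y <- sample_counts(count_model("poisson", mean = 33.5), 500, seed = 4)
  expect_lt(summarize_counts(y)$mean / summarize_counts(y)$median, 1.2)
})

test_that("jackpot bound matches its closed form and inverts exactly", {
  expect_equal(jackpot_bound(1, 0.95), 0.95)
  expect_equal(jackpot_bound(100, 0.95), 1 - 0.05^0.01)
  f <- jackpot_bound(500, 0.95)
  expect_equal(1 - (1 - f)^500, 0.95, tolerance = 1e-12)
  expect_equal(round(100 * f, 1), 0.6)  # ~0.6% of cells at n = 500
  expect_error(jackpot_bound(0, 0.95), class = "lincfish_input_error")
  expect_error(jackpot_bound(10, 1), class = "lincfish_input_error")
})

test_that("marker correlation detects exact proportionality", {
  set.seed(5)
  g <- rpois(40, 20)
  r <- correlate_with_marker(g, 2 * g)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$n_outliers_removed, 0)
})

test_that("outlier cells beyond median + 5 MAD are removed and reported", {
  set.seed(6)
  g <- rpois(40, 20); m <- rpois(40, 20)
  g[1] <- 500  # a jackpot-like artifact cell
  r <- correlate_with_marker(g, m)
  expect_equal(r$n_outliers_removed, 1)
  expect_equal(r$n_cells, 39)
  expect_error(correlate_with_marker(1:5, 1:5), class = "lincfish_input_error")
})

test_that("latent correlation is recovered from noisy count pairs", {
  set.seed(7)
  lat <- rnorm(50)
  g <- rpois(50, exp(2.5 + 0.8 * lat))
  m <- rpois(50, exp(2.5 + 0.8 * lat))
  r <- correlate_with_marker(g, m)
  expect_gt(r$pearson_r, 0.5)
})

test_that("panel correlations control false sign labels via BH", {
  set.seed(8)
  n_genes <- 30
  counts <- purrr::map_dfr(seq_len(n_genes + 1), function(i)
    tibble::tibble(gene = if (i > n_genes) "CCNA2" else paste0("g", i),
                   cell_id = 1:40, count = rpois(40, 25)))
  res <- correlate_panel(counts, marker = "CCNA2")
  expect_equal(nrow(res), n_genes)
  # all genes are null: labels should essentially all be "none"
  expect_lte(sum(res$sign != "none"), 2)
  expect_error(correlate_panel(counts, marker = "nope"),
               class = "lincfish_input_error")
})

test_that("spot counts include zero-count cells", {
  sp <- tibble::tibble(cell_id = c(1, 1, 2), channel = "rna",
                       is_autofluorescent = c(FALSE, TRUE, FALSE))
  cells <- tibble::tibble(cell_id = 1:3)
  out <- spot_counts(sp, cells)
  expect_equal(out$count[match(1:3, out$cell_id)], c(1, 1, 0))
})
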