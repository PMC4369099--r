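test_that("LoG filter maps constant images to ~0 and is linear", {
  const <- array(500, dim = c(2, 32, 32))
  out <- log_filter(const, 1.3)
  expect_lt(max(abs(out)), 1e-9 * 500)
  # linearity: filter(a * I) = a * filter(I)
  set.seed(1)
  img <- array(runif(2 * 32 * 32, 0, 100), dim = c(2, 32, 32))
  expect_equal(log_filter(3 * img, 1.3), 3 * log_filter(img, 1.3),
               tolerance = 1e-10)
  expect_error(log_filter(array(1, c(0, 4, 4))), class = "lincfish_input_error")
})

test_that("an impulse produces its filter maximum at the impulse", {
  img <- array(0, dim = c(1, 41, 41))
  img[1, 21, 17] <- 1
  out <- log_filter(img, 1.5)
  idx <- which(out == max(out), arr.ind = TRUE)
  expect_equal(unname(idx[1, 2:3]), c(21, 17))
})

test_that("a rendered spot on a linear ramp is localized within 1 px", {
  side <- 41
  yy <- matrix(0:(side - 1), side, side); xx <- t(yy)
  ramp <- 100 + 2 * xx + 1 * yy
  spot <- 80 * exp(-((yy - 20)^2 + (xx - 23)^2) / (2 * 1.3^2))
  img <- array(ramp + spot, dim = c(1, side, side))
  out <- log_filter(img, 1.3)
  inner <- out[1, 5:37, 5:37]
  idx <- which(out[1, , ] == max(inner), arr.ind = TRUE)
  expect_lte(abs(idx[1, 1] - 21), 1)
  expect_lte(abs(idx[1, 2] - 24), 1)
})

test_that("candidate maxima separate distinct impulses and merge close ones", {
  mask <- matrix(1L, 41, 41)
  img <- array(0, dim = c(3, 41, 41))
  img[2, 10, 10] <- 5; img[2, 10, 20] <- 4
  out <- candidate_maxima(log_filter(img, 1.3), mask)
  expect_equal(nrow(out), 2)
  # 1 px apart: brighter survives the 3-voxel exclusion
  img2 <- array(0, dim = c(3, 41, 41))
  img2[2, 10, 10] <- 5; img2[2, 10, 11] <- 4
  out2 <- candidate_maxima(log_filter(img2, 1.3), mask)
  expect_equal(nrow(out2), 1)
  expect_equal(unname(c(out2$y, out2$x)), c(9, 9))
})

test_that("high-SNR spots dominate the candidate ranking", {
  exp <- tiny_experiment(seed = 21, mean_count = 60, nz = 16, side = 128,
                         snr = 15)
  tr <- exp$truth[exp$truth$channel == "rna", ]
  cand <- candidate_maxima(log_filter(exp$stacks$rna, 1.3), exp$cell_labels)
  expect_gte(nrow(cand), nrow(tr))
  top <- head(cand, nrow(tr))
  # nearly all top-n candidates sit on true molecules (rare merges excepted)
  dmin <- sapply(seq_len(nrow(top)), function(i)
    min(sqrt((tr$y - top$y[i])^2 + (tr$x - top$x[i])^2)))
  expect_gte(mean(dmin <= 1.5), 0.92)
})

test_that("threshold curves are monotone and collapse at a common intensity", {
  # degenerate curve: every candidate at intensity 10, so the count drops
  # from 50 to 0 exactly at threshold 10 (counting is strictly above)
  cand10 <- tibble::tibble(intensity = rep(10, 50))
  tc <- threshold_curve(cand10, 20)
  expect_equal(nrow(tc$curve), 1)
  expect_equal(tc$curve$threshold, 10)
  expect_equal(tc$curve$count, 0L)
  expect_equal(count_at_threshold(cand10, 10 - 1e-9), 50L)
  cand <- tibble::tibble(intensity = c(rep(50, 100), runif(1000, 0.1, 5)))
  tc2 <- threshold_curve(cand, 50)
  expect_true(all(diff(tc2$curve$count) <= 0))
  mid <- tc2$curve$count[tc2$curve$threshold > 5 & tc2$curve$threshold < 50]
  expect_true(all(mid == 100))
})

test_that("plateau selection finds the separated-population threshold", {
  set.seed(3)
  cand <- tibble::tibble(intensity = c(rep(50, 100), rexp(1000, 1)))
  tc <- select_plateau_threshold(threshold_curve(cand, 60))
  thr <- chosen_threshold(tc)
  expect_gt(thr, 5); expect_lt(thr, 50)
  expect_equal(count_at_threshold(cand, thr), 100)
  expect_equal(tc$chosen_by, "auto")
})

test_that("pure-noise intensity curves raise a no-plateau error", {
  set.seed(4)
  for (s in 1:3) {
    cand <- tibble::tibble(intensity = rexp(2000, 1))
    expect_error(select_plateau_threshold(threshold_curve(cand, 60)),
                 class = "lincfish_no_plateau")
  }
})

test_that("manual threshold override is honored and recorded", {
  cand <- tibble::tibble(intensity = c(rep(50, 10), rep(1, 10)))
  tc <- select_plateau_threshold(threshold_curve(cand, 20), manual = 25)
  expect_equal(chosen_threshold(tc), 25)
  expect_equal(tc$chosen_by, "manual_override")
})

test_that("plateau count tracks true molecule number within 10%", {
  exp <- tiny_experiment(seed = 31, mean_count = 80, nz = 20, side = 128)
  true_n <- sum(exp$truth$channel == "rna")
  cand <- candidate_maxima(log_filter(exp$stacks$rna, 1.3), exp$cell_labels)
  tc <- select_plateau_threshold(threshold_curve(cand, 60))
  n_at <- count_at_threshold(cand, chosen_threshold(tc))
  expect_lt(abs(n_at - true_n) / true_n, 0.10)
})

test_that("Gaussian amplitude fit is exact on noiseless spots", {
  st <- gaussian_patch_stack(amplitude = 100, offset = 10, y0 = 10.3, x0 = 11.6)
  fit <- fit_gaussian_amplitude(st, z = 0, y = 10, x = 12)
  expect_true(fit$fit_ok)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$y, 10.3, tolerance = 1e-3)
  expect_equal(fit$x, 11.6, tolerance = 1e-3)
})

test_that("Gaussian amplitude fit is unbiased under noise", {
  amps <- sapply(1:40, function(s) {
    st <- gaussian_patch_stack(amplitude = 100, offset = 10, noise_sd = 5,
                               seed = s)
    fit_gaussian_amplitude(st, z = 0, y = 10, x = 12)$amplitude
  })
  # Monte-Carlo: mean amplitude within 3 sd-of-mean of truth
  expect_lt(abs(mean(amps) - 100), 3 * sd(amps) / sqrt(length(amps)))
})

test_that("flat windows fall back with a flag and edges clip gracefully", {
  flat <- array(7, dim = c(1, 21, 21))
  fit <- fit_gaussian_amplitude(flat, 0, 10, 10)
  expect_false(fit$fit_ok)
  st <- gaussian_patch_stack(y0 = 1, x0 = 1)
  fit_edge <- fit_gaussian_amplitude(st, 0, 1, 1)
  expect_true(fit_edge$fit_ok)
  expect_equal(fit_edge$amplitude, 100, tolerance = 1e-3)
  expect_error(fit_gaussian_amplitude(st, 0, 100, 100),
               class = "lincfish_input_error")
})

test_that("autofluorescence flags exactly the co-localizing spots", {
  sp <- tibble::tibble(cell_id = 1, z = c(5, 5, 5), y = c(10, 30, 50),
                       x = c(10, 30, 50))
  expect_false(any(exclude_autofluorescent(sp, sp[0, ])$is_autofluorescent))
  gfp <- tibble::tibble(cell_id = 1, z = 5, y = 10, x = 10)
  out <- exclude_autofluorescent(sp, gfp)
  expect_identical(out$is_autofluorescent, c(TRUE, FALSE, FALSE))
  # different cell id: not flagged even at identical coordinates
  gfp2 <- tibble::tibble(cell_id = 2, z = 5, y = 10, x = 10)
  expect_false(any(exclude_autofluorescent(sp, gfp2)$is_autofluorescent))
})

test_that("autofluorescent particles are excluded from molecule counts", {
  exp <- generate_experiment(synth_config(
    n_cells = 1, field_shape_zyx = c(20, 128, 128),
    count_model = count_model("poisson", mean = 50),
    autofluor_density = 10, seed = 41))
  sp <- detect_spots(exp)
  true_rna <- sum(exp$truth$channel == "rna" & exp$truth$kind == "rna")
  counted <- sum(!sp$is_autofluorescent)
  expect_lt(abs(counted - true_rna) / true_rna, 0.10)
  expect_gt(sum(sp$is_autofluorescent), 0)
})

test_that("detection is deterministic and empty cells give empty spot sets", {
  exp <- tiny_experiment(seed = 51, mean_count = 30)
  a <- detect_spots(exp); b <- detect_spots(exp)
  expect_identical(as.data.frame(a), as.data.frame(b))
  exp0 <- tiny_experiment(seed = 52, mean_count = 0)
  sp0 <- detect_spots(exp0)
  expect_equal(nrow(sp0), 0)
  expect_equal(attr(sp0, "status")$status, "no_plateau")
})

test_that("detected positions match ground truth one-to-one at high SNR", {
  exp <- tiny_experiment(seed = 61, mean_count = 40, snr = 15)
  sp <- detect_spots(exp)
  tr <- exp$truth[exp$truth$channel == "rna", ]
  # greedy matching oracle at 1 px
  pairs <- match_spots(tr, sp, window = 1, z_window = 1)
  expect_gte(nrow(pairs) / nrow(tr), 0.9)
})
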