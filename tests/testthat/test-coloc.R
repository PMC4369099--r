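# brute-force all-pairs greedy matcher: the independent oracle
oracle_match <- function(a, b, window, z_window = 1) {
  cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  cand$d <- sqrt((a$y[cand$i] - b$y[cand$j])^2 + (a$x[cand$i] - b$x[cand$j])^2)
  cand$dz <- abs(a$z[cand$i] - b$z[cand$j])
  cand <- cand[cand$d <= window & cand$dz <= z_window, ]
  cand <- cand[order(cand$d, cand$i, cand$j), ]
  used_i <- used_j <- integer(0); out <- list()
  for (k in seq_len(nrow(cand))) {
    if (cand$i[k] %in% used_i || cand$j[k] %in% used_j) next
    out[[length(out) + 1]] <- cand[k, ]
    used_i <- c(used_i, cand$i[k]); used_j <- c(used_j, cand$j[k])
  }
  do.call(rbind, out)
}

rand_spots <- function(n, side = 100, nz = 8) {
  tibble::tibble(z = sample(0:(nz - 1), n, TRUE),
                 y = runif(n, 0, side - 1), x = runif(n, 0, side - 1))
}

test_that("identical spot lists match completely at distance zero", {
  set.seed(1)
  a <- rand_spots(25)
  pairs <- match_spots(a, a, window = 2)
  expect_equal(nrow(pairs), 25)
  expect_true(all(pairs$distance == 0))
  expect_equal(nrow(match_spots(a[0, ], a, window = 2)), 0)
  expect_equal(nrow(match_spots(a, a[0, ], window = 2)), 0)
})

test_that("a shifted grid matches fully at the known distance", {
  g <- expand.grid(y = seq(10, 90, 20), x = seq(10, 70, 20))
  a <- tibble::tibble(z = 3, y = g$y, x = g$x)
  b <- tibble::tibble(z = 3, y = g$y + 1, x = g$x + 1)
  pairs <- match_spots(a, b, window = 3)
  expect_equal(nrow(pairs), 20)
  expect_equal(pairs$distance, rep(sqrt(2), 20))
  # agrees with the brute-force oracle
  orc <- oracle_match(a, b, window = 3)
  expect_equal(nrow(orc), 20)
  expect_setequal(paste(pairs$idx_a, pairs$idx_b),
                  paste(orc$i, orc$j))
})

test_that("matching is injective, symmetric and bounded", {
  set.seed(7)
  for (rep in 1:5) {
    a <- rand_spots(40); b <- rand_spots(30)
    ab <- match_spots(a, b, window = 3)
    ba <- match_spots(b, a, window = 3)
    expect_lte(nrow(ab), min(nrow(a), nrow(b)))
    expect_equal(anyDuplicated(ab$idx_a), 0)
    expect_equal(anyDuplicated(ab$idx_b), 0)
    expect_setequal(paste(ab$idx_a, ab$idx_b), paste(ba$idx_b, ba$idx_a))
    orc <- oracle_match(a, b, window = 3)
    expect_equal(nrow(ab), NROW(orc))
  }
})

test_that("shift estimation is a per-axis median, robust to an outlier", {
  pairs <- tibble::tibble(idx_a = 1:5, idx_b = 1:5, distance = 1,
                          dy = c(1, 1, 1, 1, 1), dx = rep(-0.5, 5),
                          dz = 0)
  expect_equal(as.vector(estimate_shift(pairs)), c(1, -0.5, 0))
  pairs$dy[5] <- 50
  expect_equal(unname(estimate_shift(pairs)["dy"]), 1)
  few <- pairs[1:2, ]
  s <- estimate_shift(few)
  expect_equal(as.vector(s), c(0, 0, 0))
  expect_false(attr(s, "confident"))
})

test_that("two-stage registration recovers a 2 px shift and improves matching", {
  set.seed(11)
  a <- rand_spots(60, side = 120)
  b <- a
  b$y <- b$y + 2 + runif(60, -0.3, 0.3)
  b$x <- b$x + 1 + runif(60, -0.3, 0.3)
  res <- colocalize_two_stage(a, b, coarse = 4, fine = 1.5)
  expect_lt(abs(res$shift["dy"] - 2), 0.3)
  expect_lt(abs(res$shift["dx"] - 1), 0.3)
  expect_gte(res$n_matched / 60, 0.95)
  # registration never hurts: unregistered fine-window matching does worse
  naive <- match_spots(a, b, window = 1.5)
  expect_gte(res$n_matched, nrow(naive))
  # self-colocalization: everything matches at zero shift
  self <- colocalize_two_stage(a, a, coarse = 4, fine = 2)
  expect_equal(self$n_matched, 60)
  expect_equal(as.vector(self$shift), c(0, 0, 0))
})

test_that("random co-occurrence stays near the analytic chance level", {
  set.seed(13)
  side <- 512; n <- 200; fine <- 1.5; nz <- 8
  a <- rand_spots(n, side = side, nz = nz)
  b <- rand_spots(n, side = side, nz = nz)
  res <- colocalize_two_stage(a, b, coarse = fine, fine = fine)
  # expected chance pairs ~ n * (n * pi * fine^2 / side^2) * P(|dz| <= 1)
  p_z <- mean(outer(0:(nz - 1), 0:(nz - 1), function(u, v) abs(u - v) <= 1))
  expected <- n * n * pi * fine^2 / side^2 * p_z
  expect_lte(res$n_matched, 2 * expected + 3)
})

test_that("overlap significance is extreme for self-overlap and 1 for none", {
  set.seed(17)
  mask <- matrix(1L, 120, 120)
  a <- rand_spots(25, side = 120)
  res <- overlap_significance(a, a, mask, fine = 2, n_perm = 999, seed = 5)
  expect_lte(res$p_value, 0.01)
  far <- a; far$x <- far$x + 500  # disjoint: no pair can fall in-window
  res0 <- overlap_significance(a, far, mask, fine = 0.5, z_window = 1,
                               n_perm = 199, seed = 5)
  expect_equal(res0$n_matched, 0L)
  expect_equal(res0$p_value, 1.0)
  expect_error(overlap_significance(a, a, matrix(0L, 5, 5)),
               class = "lincfish_input_error")
})

test_that("permutation p-values are reproducible for a fixed seed", {
  set.seed(19)
  mask <- matrix(1L, 80, 80)
  a <- rand_spots(20, side = 80)
  b <- rand_spots(20, side = 80)
  p1 <- overlap_significance(a, b, mask, n_perm = 199, seed = 3)$p_value
  p2 <- overlap_significance(a, b, mask, n_perm = 199, seed = 3)$p_value
  expect_identical(p1, p2)
})
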