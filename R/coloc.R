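#' Match spots across two channels
#'
#' Pairs spots of list `a` with spots of list `b` by greedy
#' mutual-nearest-neighbour matching: all candidate pairs within `window` px
#' lateral (Euclidean in y, x) and `z_window` slices axially are sorted by
#' ascending distance (ties broken by index in `a`, then `b`) and accepted
#' whenever both members are still unmatched. The result is injective and
#' symmetric in its arguments.
#'
#' @param a,b Spot tibbles with `z`, `y`, `x` columns (one cell's spots).
#' @param window Lateral matching radius in px.
#' @param z_window Maximum axial separation in slices.
#' @return Tibble of pairs: `idx_a`, `idx_b` (row indices), `distance`
#'   (lateral), `dy`, `dx`, `dz` (displacement b - a).
#' @export
match_spots <- function(a, b, window = 2, z_window = 1) {
  if (window <= 0) abort_input("window must be > 0")
  empty <- tibble::new_tibble(list(
    idx_a = integer(0), idx_b = integer(0), distance = numeric(0),
    dy = numeric(0), dx = numeric(0), dz = numeric(0)), nrow = 0L)
  na <- length(a$y); nb <- length(b$y)  # lists of coordinates also accepted
  if (na == 0 || nb == 0) return(empty)
  dy <- outer(a$y, b$y, function(u, v) v - u)
  dx <- outer(a$x, b$x, function(u, v) v - u)
  dz <- outer(a$z, b$z, function(u, v) v - u)
  dd <- sqrt(dy^2 + dx^2)
  ok <- which(dd <= window & abs(dz) <= z_window)
  if (length(ok) == 0) return(empty)
  ia <- ((ok - 1) %% na) + 1
  ib <- ((ok - 1) %/% na) + 1
  dist_ok <- dd[ok]
  ord <- order(dist_ok, ia, ib)
  ia <- ia[ord]; ib <- ib[ord]; ok <- ok[ord]; dist_ok <- dist_ok[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(length(ok))
  for (i in seq_along(ok)) {
    if (!used_a[ia[i]] && !used_b[ib[i]]) {
      keep[i] <- TRUE
      used_a[ia[i]] <- TRUE; used_b[ib[i]] <- TRUE
    }
  }
  tibble::new_tibble(list(
    idx_a = ia[keep], idx_b = ib[keep], distance = dist_ok[keep],
    dy = dy[ok[keep]], dx = dx[ok[keep]], dz = dz[ok[keep]]),
    nrow = sum(keep))
}

#' Estimate the rigid inter-channel shift from matched pairs
#'
#' The per-axis median displacement (b relative to a) over matched pairs —
#' robust to a minority of mismatches. With fewer than 3 pairs the shift is
#' returned as zero with `confident = FALSE`.
#'
#' @param pairs Pair tibble from [match_spots()] (needs `dy`, `dx`, `dz`).
#' @return Named numeric `c(dy, dx, dz)` with attribute `confident`.
#' @export
estimate_shift <- function(pairs) {
  if (nrow(pairs) < 3) {
    out <- c(dy = 0, dx = 0, dz = 0)
    attr(out, "confident") <- FALSE
    return(out)
  }
  out <- c(dy = median(pairs$dy), dx = median(pairs$dx),
           dz = median(pairs$dz))
  attr(out, "confident") <- TRUE
  out
}

#' Two-stage co-localization with channel registration
#'
#' Stage 1 matches at a relatively large window; the matched pairs register
#' the two channels (median displacement = rigid shift); channel `b` is
#' shifted into `a`'s frame and matching is rerun at the smaller window.
#'
#' @param a,b Spot tibbles (`z`, `y`, `x`).
#' @param coarse,fine Lateral windows in px, `coarse >= fine > 0`.
#' @param z_window Axial tolerance in slices.
#' @return A `coloc_result`: `pairs` (tibble `idx_a`, `idx_b`, `distance`
#'   after registration), `shift` (dy, dx, dz applied to `b`), `n_a`, `n_b`,
#'   `n_matched`, `coarse`, `fine`, `shift_confident`.
#' @export
colocalize_two_stage <- function(a, b, coarse = 4, fine = 2, z_window = 1) {
  if (!(coarse >= fine && fine > 0))
    abort_input("need coarse >= fine > 0")
  stage1 <- match_spots(a, b, window = coarse, z_window = z_window)
  shift <- estimate_shift(stage1)
  b2 <- b
  if (nrow(b) > 0) {
    b2$y <- b$y - shift["dy"]
    b2$x <- b$x - shift["dx"]
    b2$z <- b$z - shift["dz"]
  }
  pairs <- match_spots(a, b2, window = fine, z_window = z_window)
  structure(list(pairs = pairs, shift = shift,
                 n_a = nrow(a), n_b = nrow(b), n_matched = nrow(pairs),
                 coarse = coarse, fine = fine,
                 shift_confident = isTRUE(attr(shift, "confident"))),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d / (%d, %d) spots matched | shift (dy %.2f, dx %.2f, dz %.2f) | windows %g/%g px\n",
              x$n_matched, x$n_a, x$n_b,
              x$shift["dy"], x$shift["dx"], x$shift["dz"],
              x$coarse, x$fine))
  invisible(x)
}

#' @export
tidy.coloc_result <- function(x, ...) x$pairs

#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_matched = x$n_matched,
         frac_a_matched = ifelse(x$n_a > 0, x$n_matched / x$n_a, NA_real_),
         shift_dy = unname(x$shift["dy"]), shift_dx = unname(x$shift["dx"]),
         shift_dz = unname(x$shift["dz"]),
         shift_confident = x$shift_confident,
         coarse = x$coarse, fine = x$fine)
}

#' Permutation test for per-cell spot overlap
#'
#' Tests whether spots of `b` co-localize with spots of `a` more than
#' expected by chance given the cell (or nucleus) geometry: the positions of
#' `b` are resampled uniformly within the mask `n_perm` times (keeping each
#' spot's z-slice), matching is rerun at the `fine` window, and
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param a,b Spot tibbles for one cell.
#' @param mask Logical or label matrix of allowed (y, x) pixels (e.g. the
#'   cell's nucleus mask); nonzero = allowed.
#' @param fine Matching window in px.
#' @param z_window Axial tolerance in slices.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for reproducibility.
#' @return One-row tibble: `n_a`, `n_b`, `n_matched`, `null_mean`, `p_value`.
#' @export
overlap_significance <- function(a, b, mask, fine = 2, z_window = 1,
                                 n_perm = 999, seed = 1) {
  if (n_perm < 100) abort_input("n_perm must be >= 100")
  pix <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pix) == 0) abort_input("empty mask")
  obs <- nrow(match_spots(a, b, window = fine, z_window = z_window))
  if (obs == 0)
    return(tibble(n_a = nrow(a), n_b = nrow(b), n_matched = 0L,
                  null_mean = NA_real_, p_value = 1.0))
  set.seed(seed)
  nb <- nrow(b)
  null <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nrow(pix), nb, replace = TRUE)
    bi <- list(z = b$z,
               y = pix[idx, 1] - 1 + runif(nb, -0.5, 0.5),
               x = pix[idx, 2] - 1 + runif(nb, -0.5, 0.5))
    null[i] <- nrow(match_spots(a, bi, window = fine, z_window = z_window))
  }
  tibble(n_a = nrow(a), n_b = nrow(b), n_matched = obs,
         null_mean = mean(null),
         p_value = (1 + sum(null >= obs)) / (1 + n_perm))
}
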