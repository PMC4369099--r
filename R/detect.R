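#' Detection parameters
#'
#' @param sigma Lateral LoG sigma in pixels; match to the PSF sigma.
#' @param exclusion_radius Minimum 3-D Euclidean distance (voxels) between
#'   candidate particles; within it, the brighter candidate wins.
#' @param n_thresholds Number of log-spaced thresholds scanned for the
#'   threshold curve.
#' @param fit_window Side (odd, px) of the square window for the 2-D
#'   Gaussian amplitude fit.
#' @param af_radius,af_dz Lateral radius (px) and axial tolerance (slices)
#'   within which an RNA spot co-localizing with a GFP-channel spot is
#'   flagged autofluorescent.
#' @param plateau_rise Minimum excess of the pre-plateau log-log descent over
#'   the plateau slope required to accept a plateau (see
#'   [select_plateau_threshold()]).
#' @param plateau_min_count Minimum particle count supporting a plateau.
#' @param threshold_overrides Named list `channel -> threshold` of manual
#'   threshold overrides.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(sigma = 1.3, exclusion_radius = 3, n_thresholds = 60,
                          fit_window = 7, af_radius = 2, af_dz = 1,
                          plateau_rise = 0.5, plateau_min_count = 10,
                          threshold_overrides = list()) {
  if (sigma <= 0) abort_input("sigma must be > 0")
  if (fit_window %% 2 != 1) abort_input("fit_window must be odd")
  structure(list(sigma = sigma, exclusion_radius = exclusion_radius,
                 n_thresholds = n_thresholds, fit_window = fit_window,
                 af_radius = af_radius, af_dz = af_dz,
                 plateau_rise = plateau_rise,
                 plateau_min_count = plateau_min_count,
                 threshold_overrides = threshold_overrides),
            class = "detect_params")
}

#' Laplacian-of-Gaussian kernel
#'
#' Negated (spot-positive) LoG kernel, mean-subtracted so the response to a
#' constant image is exactly zero.
#'
#' @param sigma Gaussian sigma in pixels.
#' @param half_size Kernel half-width; defaults to `ceiling(4 * sigma)`.
#' @return A square odd-sized matrix summing to zero.
#' @export
log_kernel <- function(sigma, half_size = ceiling(4 * sigma)) {
  if (sigma <= 0) abort_input("sigma must be > 0")
  r <- -half_size:half_size
  d2 <- outer(r^2, r^2, `+`)
  k <- -(d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k - mean(k)
}

#' LoG-filter an image stack
#'
#' Applies the zero-mean spot-enhancing kernel of [log_kernel()] to every
#' z-slice independently (2-D, matching the 2-D Gaussian spot model).
#' Removes smooth nonuniform background and enhances diffraction-limited
#' particles. The filter is linear and maps constant images to ~0.
#'
#' @param stack Numeric `(z, y, x)` array (a single matrix is treated as one
#'   slice).
#' @param sigma LoG sigma in pixels.
#' @return Filtered array of the same shape.
#' @export
log_filter <- function(stack, sigma = 1.3) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1, dim(stack)))
  if (!is.array(stack) || length(dim(stack)) != 3 || length(stack) == 0)
    abort_input("stack must be a non-empty (z, y, x) array")
  k <- log_kernel(sigma)
  out <- stack
  for (z in seq_len(dim(stack)[1]))
    out[z, , ] <- EBImage::filter2(stack[z, , ], k, boundary = "replicate")
  out
}

# logical array of strict 26-neighbourhood 3-D regional maxima
local_maxima_3d <- function(a) {
  d <- dim(a)
  p <- array(-Inf, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  res <- array(TRUE, d)
  iz <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); ix <- 2:(d[3] + 1)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    res <- res & (a > p[iz + dz, iy + dy, ix + dx])
  }
  res
}

#' Candidate particle maxima
#'
#' Defines candidate particles as strict 3-D regional maxima of the filtered
#' stack with positive response, lying inside a cell mask, thinned so that no
#' two candidates lie within `exclusion_radius` voxels of each other (the
#' brighter one wins).
#'
#' @param filtered LoG-filtered `(z, y, x)` array.
#' @param cell_labels Integer label matrix `(y, x)`; 0 = background.
#' @param exclusion_radius Euclidean exclusion radius in voxels.
#' @return Tibble `cell_id, z, y, x` (0-based voxel coordinates),
#'   `intensity` (filtered value), sorted by decreasing intensity.
#' @export
candidate_maxima <- function(filtered, cell_labels, exclusion_radius = 3) {
  if (is.matrix(filtered)) filtered <- array(filtered, dim = c(1, dim(filtered)))
  d <- dim(filtered)
  if (d[2] != nrow(cell_labels) || d[3] != ncol(cell_labels))
    abort_input("filtered stack and mask differ in y/x extent")
  # relative floor guards against numerical dust from the FFT convolution
  floor_val <- 1e-9 * max(abs(filtered))
  mx <- local_maxima_3d(filtered) & filtered > floor_val
  idx <- which(mx, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(tibble(cell_id = integer(0), z = numeric(0), y = numeric(0),
                  x = numeric(0), intensity = numeric(0)))
  lab <- cell_labels[idx[, 2:3, drop = FALSE]]
  keep <- lab > 0
  idx <- idx[keep, , drop = FALSE]; lab <- lab[keep]
  int <- filtered[idx]
  ord <- order(-int)
  idx <- idx[ord, , drop = FALSE]; lab <- lab[ord]; int <- int[ord]
  # greedy exclusion: brightest first, suppress a ball around each keeper
  suppressed <- array(FALSE, d)
  rr <- ceiling(exclusion_radius)
  keepi <- logical(length(int))
  for (i in seq_along(int)) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    if (suppressed[z, y, x]) next
    keepi[i] <- TRUE
    zi <- max(1, z - rr):min(d[1], z + rr)
    yi <- max(1, y - rr):min(d[2], y + rr)
    xi <- max(1, x - rr):min(d[3], x + rr)
    ball <- outer(outer((zi - z)^2, (yi - y)^2, `+`), (xi - x)^2, `+`) <=
      exclusion_radius^2
    suppressed[zi, yi, xi] <- suppressed[zi, yi, xi] | ball
  }
  tibble(cell_id = as.integer(lab[keepi]),
         z = idx[keepi, 1] - 1, y = idx[keepi, 2] - 1, x = idx[keepi, 3] - 1,
         intensity = int[keepi])
}

#' Threshold-versus-count curve
#'
#' Scans log-spaced intensity thresholds between the dimmest and brightest
#' candidate and counts candidates strictly above each threshold — the curve
#' whose plateau identifies the particle-calling threshold.
#'
#' @param candidates Tibble from [candidate_maxima()] (needs `intensity`).
#' @param n_thresholds Number of thresholds scanned.
#' @return A `threshold_curve`: list with `curve` (tibble `threshold`,
#'   `count`), `chosen_threshold` (NA until selected), `chosen_by`.
#' @export
threshold_curve <- function(candidates, n_thresholds = 60) {
  int <- candidates$intensity
  int <- int[int > 0]
  if (length(int) == 0)
    abort("no candidates to build a threshold curve from",
          class = "lincfish_detection_error")
  lo <- min(int); hi <- max(int)
  thr <- if (hi > lo) exp(seq(log(lo), log(hi), length.out = n_thresholds)) else lo
  counts <- vapply(thr, function(t) sum(int > t), integer(1))
  structure(list(curve = tibble(threshold = thr, count = counts),
                 chosen_threshold = NA_real_, chosen_by = NA_character_,
                 n_candidates = length(int)),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("<threshold_curve>", nrow(x$curve), "thresholds in [",
      format(min(x$curve$threshold), digits = 4), ",",
      format(max(x$curve$threshold), digits = 4), "]")
  if (!is.na(x$chosen_threshold))
    cat(" | chosen", format(x$chosen_threshold, digits = 4),
        paste0("(", x$chosen_by, ")"))
  cat("\n")
  invisible(x)
}

#' @export
tidy.threshold_curve <- function(x, ...) x$curve

#' @export
glance.threshold_curve <- function(x, ...) {
  tibble(n_candidates = x$n_candidates,
         chosen_threshold = x$chosen_threshold,
         chosen_by = x$chosen_by)
}

#' Select the plateau threshold
#'
#' Finds the flattest region of the log(count) versus log(threshold) curve:
#' the threshold range over which the particle count is insensitive to the
#' exact cutoff, which separates dim background maxima from genuine spots.
#' The smoothed log-log slope is computed; candidate plateaus are interior
#' local minima of |slope| preceded (at lower thresholds) by a descent at
#' least `rise` steeper — pure background gives a monotonically steepening
#' curve with no such minimum and raises a `no plateau` error, the signature
#' of a probe set with no discernible signal.
#'
#' @param curve A [threshold_curve()].
#' @param rise Required slope contrast between the initial background descent
#'   and the plateau (log-log units).
#' @param min_count Minimum particle count at the plateau: with fewer
#'   particles the discrete tail of the curve produces flat runs that mimic
#'   a plateau.
#' @param manual Optional manual threshold override; skips the automatic rule
#'   and records `chosen_by = "manual_override"`.
#' @return The input curve with `chosen_threshold` and `chosen_by` set.
#'   `chosen_threshold(curve)` extracts the value; `count_at_threshold()`
#'   the particle count above it.
#' @export
select_plateau_threshold <- function(curve, rise = 0.5, min_count = 10,
                                     manual = NULL) {
  stopifnot(inherits(curve, "threshold_curve"))
  if (!is.null(manual)) {
    curve$chosen_threshold <- manual
    curve$chosen_by <- "manual_override"
    return(curve)
  }
  cv <- curve$curve[curve$curve$count > 0, ]
  if (nrow(cv) < 6) abort_no_plateau()
  lt <- log(cv$threshold); lc <- log(cv$count)
  m <- nrow(cv)
  # centred log-log slope, then 3-point running-mean smoothing
  s <- (lc[3:m] - lc[1:(m - 2)]) / (lt[3:m] - lt[1:(m - 2)])
  g <- abs(s)
  if (length(g) >= 3)
    g <- c(g[1], (g[-c(1, length(g))] + g[-(1:2)] + g[-c(length(g) - 1, length(g))]) / 3,
           g[length(g)])
  ok <- rep(FALSE, length(g))
  for (i in 2:(length(g) - 1)) {
    local_min <- g[i] <= g[i - 1] && g[i] <= g[i + 1]
    preceded <- max(g[1:(i - 1)]) >= g[i] + rise
    supported <- cv$count[i + 1] >= min_count
    ok[i] <- local_min && preceded && supported
  }
  if (!any(ok)) abort_no_plateau()
  best <- which(ok)[which.min(g[ok])]
  curve$chosen_threshold <- cv$threshold[best + 1]  # +1: slope is centred
  curve$chosen_by <- "auto"
  curve
}

#' @rdname select_plateau_threshold
#' @export
chosen_threshold <- function(curve) curve$chosen_threshold

#' Count candidates above a threshold
#' @param candidates Tibble with an `intensity` column.
#' @param threshold Intensity cutoff (strict).
#' @return Integer count.
#' @export
count_at_threshold <- function(candidates, threshold) {
  sum(candidates$intensity > threshold)
}

#' Fit a 2-D Gaussian amplitude to a candidate spot
#'
#' Least-squares fit of a radially symmetric 2-D Gaussian plus constant
#' offset on a `window x window` patch of the candidate's brightest z-slice
#' of the raw (unfiltered) stack. Returns the peak amplitude above the local
#' offset and the sub-pixel centre. A degenerate (flat) patch or failed fit
#' falls back to the candidate's raw value with `fit_ok = FALSE`.
#'
#' @param stack Raw `(z, y, x)` array.
#' @param z,y,x Candidate voxel position (0-based integers).
#' @param window Odd patch side in px (default 7).
#' @return List `amplitude`, `y`, `x` (sub-pixel, 0-based), `sigma`,
#'   `offset`, `fit_ok`.
#' @export
fit_gaussian_amplitude <- function(stack, z, y, x, window = 7) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1, dim(stack)))
  d <- dim(stack)
  iz <- z + 1; iy <- y + 1; ix <- x + 1
  if (iz < 1 || iz > d[1] || iy < 1 || iy > d[2] || ix < 1 || ix > d[3])
    abort_input("candidate outside image bounds")
  h <- (window - 1) / 2
  yi <- max(1, iy - h):min(d[2], iy + h)
  xi <- max(1, ix - h):min(d[3], ix + h)
  patch <- stack[iz, yi, xi]
  raw <- stack[iz, iy, ix]
  fallback <- list(amplitude = raw, y = as.numeric(y), x = as.numeric(x),
                   sigma = NA_real_, offset = NA_real_, fit_ok = FALSE)
  if (sd(patch) == 0) return(fallback)
  df <- data.frame(v = as.vector(patch),
                   py = rep(yi - 1, times = length(xi)),
                   px = rep(xi - 1, each = length(yi)))
  start <- list(A = max(patch) - min(patch), y0 = y, x0 = x,
                s = 1.3, b = min(patch))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ b + A * exp(-((py - y0)^2 + (px - x0)^2) / (2 * s^2)),
      data = df, start = start,
      lower = c(A = 0, y0 = min(df$py), x0 = min(df$px), s = 0.3, b = -Inf),
      upper = c(A = Inf, y0 = max(df$py), x0 = max(df$px), s = window, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12))),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  cf <- coef(fit)
  list(amplitude = unname(cf["A"]), y = unname(cf["y0"]), x = unname(cf["x0"]),
       sigma = unname(cf["s"]), offset = unname(cf["b"]), fit_ok = TRUE)
}

#' Flag RNA spots that co-localize with GFP-channel spots
#'
#' Spots in the GFP (no-probe) channel mark autofluorescent particles; any
#' RNA spot within `radius` px laterally and `dz` slices axially of one is
#' flagged `is_autofluorescent` and excluded from molecule counts.
#'
#' @param spots RNA spot tibble (`cell_id`, `z`, `y`, `x`, ...).
#' @param gfp_spots GFP-channel spot tibble (same columns).
#' @param radius Lateral radius in px.
#' @param dz Axial tolerance in slices.
#' @return `spots` with a logical `is_autofluorescent` column.
#' @export
exclude_autofluorescent <- function(spots, gfp_spots, radius = 2, dz = 1) {
  spots$is_autofluorescent <- FALSE
  if (nrow(spots) == 0 || is.null(gfp_spots) || nrow(gfp_spots) == 0)
    return(spots)
  for (i in seq_len(nrow(spots))) {
    g <- gfp_spots[gfp_spots$cell_id == spots$cell_id[i], ]
    if (nrow(g) == 0) next
    dxy <- sqrt((g$y - spots$y[i])^2 + (g$x - spots$x[i])^2)
    dzz <- abs(g$z - spots$z[i])
    spots$is_autofluorescent[i] <- any(dxy <= radius & dzz <= dz)
  }
  spots
}

#' Detect single-molecule spots in an experiment
#'
#' The full quantification chain per RNA channel: LoG filtering, in-mask 3-D
#' candidate maxima, one plateau threshold per channel and image (background
#' varies between hybridizations), 2-D Gaussian amplitude fits, nuclear
#' flagging against the nucleus mask, and exclusion of spots co-localizing
#' with GFP-channel (autofluorescent) spots. A channel with no discernible
#' plateau yields zero spots and is flagged in the status table rather than
#' failing the run.
#'
#' @param experiment A `fish_experiment` (from [generate_experiment()] or
#'   [read_experiment()]), or any list with `stacks`, `cell_labels`,
#'   `nucleus_labels`.
#' @param channels RNA channels to quantify; defaults to every stack except
#'   `dapi` and `gfp`.
#' @param params A [detect_params()].
#' @return Tibble of spots: `cell_id`, `channel`, `z`, `y`, `x` (0-based;
#'   `y`, `x` sub-pixel), `amplitude`, `raw_intensity`, `fit_ok`,
#'   `is_nuclear`, `is_autofluorescent`. Attributes: `threshold_curves`
#'   (named list of [threshold_curve()]s), `status` (tibble per channel).
#' @export
detect_spots <- function(experiment, channels = NULL, params = detect_params()) {
  stacks <- experiment$stacks
  if (is.null(stacks) || length(stacks) == 0)
    abort_input("experiment has no image stacks")
  if (is.null(channels))
    channels <- setdiff(names(stacks), c("dapi", "gfp"))

  gfp_spots <- NULL
  if ("gfp" %in% names(stacks) && !is.null(stacks$gfp))
    gfp_spots <- detect_channel(stacks$gfp, experiment, params,
                                fit = FALSE)$spots

  curves <- list(); status <- list(); out <- list()
  for (ch in channels) {
    res <- detect_channel(stacks[[ch]], experiment, params, fit = TRUE,
                          manual = params$threshold_overrides[[ch]])
    sp <- res$spots
    if (nrow(sp) > 0) sp$channel <- ch
    sp <- exclude_autofluorescent(sp, gfp_spots,
                                  radius = params$af_radius, dz = params$af_dz)
    sp$is_nuclear <- mask_lookup(experiment$nucleus_labels, sp$y, sp$x) ==
      sp$cell_id
    curves[[ch]] <- res$curve
    status[[ch]] <- tibble(channel = ch, status = res$status,
                           threshold = res$threshold)
    out[[ch]] <- sp
  }
  spots <- dplyr::bind_rows(out)
  if (nrow(spots) > 0)
    spots <- spots[, c("cell_id", "channel", "z", "y", "x", "amplitude",
                       "raw_intensity", "fit_ok", "is_nuclear",
                       "is_autofluorescent")]
  attr(spots, "threshold_curves") <- curves
  attr(spots, "status") <- dplyr::bind_rows(status)
  attr(spots, "gfp_spots") <- gfp_spots
  spots
}

empty_spots <- function() {
  tibble(cell_id = integer(0), channel = character(0), z = numeric(0),
         y = numeric(0), x = numeric(0), amplitude = numeric(0),
         raw_intensity = numeric(0), fit_ok = logical(0),
         is_nuclear = logical(0), is_autofluorescent = logical(0))
}

# one channel: filter -> candidates -> plateau -> (optional) Gaussian fits
detect_channel <- function(stack, experiment, params, fit = TRUE,
                           manual = NULL) {
  filtered <- log_filter(stack, params$sigma)
  cand <- candidate_maxima(filtered, experiment$cell_labels,
                           params$exclusion_radius)
  if (nrow(cand) == 0)
    return(list(spots = empty_spots(), curve = NULL, status = "no_candidates",
                threshold = NA_real_))
  curve <- threshold_curve(cand, params$n_thresholds)
  curve <- tryCatch(
    select_plateau_threshold(curve, rise = params$plateau_rise,
                             min_count = params$plateau_min_count,
                             manual = manual),
    lincfish_no_plateau = function(e) NULL)
  if (is.null(curve))
    return(list(spots = empty_spots(), curve = NULL, status = "no_plateau",
                threshold = NA_real_))
  thr <- chosen_threshold(curve)
  keep <- cand[cand$intensity > thr, ]
  sp <- tibble(cell_id = keep$cell_id, channel = NA_character_,
               z = keep$z, y = keep$y, x = keep$x,
               amplitude = NA_real_, raw_intensity = keep$intensity,
               fit_ok = NA, is_nuclear = NA, is_autofluorescent = FALSE)
  if (fit && nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      f <- fit_gaussian_amplitude(stack, keep$z[i], keep$y[i], keep$x[i],
                                  params$fit_window)
      sp$amplitude[i] <- f$amplitude
      sp$y[i] <- f$y; sp$x[i] <- f$x
      sp$fit_ok[i] <- f$fit_ok
    }
  } else if (nrow(sp) > 0) {
    sp$amplitude <- sp$raw_intensity
    sp$fit_ok <- FALSE
  }
  list(spots = sp, curve = curve, status = "ok", threshold = thr)
}
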