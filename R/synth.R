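#' Generate a seeded synthetic smFISH experiment
#'
#' Builds a complete in-silico experiment with the statistical structure the
#' downstream analyses assume: 2-D elliptical cell and nucleus label masks on
#' a non-overlapping grid, per-cell true molecule counts drawn from the
#' configured [count_model()], molecule positions (nuclear vs cytoplasmic by
#' `nuclear_fraction`, with optional multi-molecule nuclear foci), and 3-D
#' image stacks per channel: DAPI (nuclear stain), GFP (autofluorescence
#' only) and either one RNA channel (`rna`) or the dual-label pair
#' (`even`/`odd`). Spots are rendered as separable 3-D Gaussians with
#' log-normal amplitude variation (sd 20%) on a smooth gradient background
#' plus Gaussian read noise.
#'
#' All randomness is driven by `config$seed`: identical configurations yield
#' bit-identical stacks and ground truth.
#'
#' @param config A [synth_config()].
#' @param render_images If `FALSE`, skip voxel rendering and return masks and
#'   ground truth only (orders of magnitude faster; useful when an analysis
#'   consumes spot tables rather than images).
#' @return A `fish_experiment`: list with `stacks` (named list of numeric
#'   `(z, y, x)` arrays, or `NULL` entries when not rendered), `cell_labels`
#'   and `nucleus_labels` (integer label matrices, background 0), `cells`
#'   (tibble: `cell_id`, `cell_type`, `mitotic`), `truth` (tibble, one row
#'   per rendered molecule: `cell_id`, `channel`, `mol_id`, `kind`, `z`,
#'   `y`, `x` 0-based voxel coordinates, `in_nucleus`, `focus_id`,
#'   `amplitude`), and `config`.
#' @examples
#' exp <- generate_experiment(synth_config(n_cells = 1, seed = 1,
#'   field_shape_zyx = c(12, 64, 64),
#'   count_model = count_model("poisson", mean = 10)))
#' dim(exp$stacks$rna)
#' @export
generate_experiment <- function(config, render_images = TRUE) {
  validate_synth_config(config)
  set.seed(config$seed)
  nz <- config$field_shape_zyx[1]
  ny <- config$field_shape_zyx[2]
  nx <- config$field_shape_zyx[3]

  masks <- place_cell_masks(config)
  cells <- tibble(
    cell_id = seq_len(config$n_cells),
    cell_type = rep(config$cell_type, config$n_cells),
    mitotic = runif(config$n_cells) < config$mitotic_fraction
  )

  rna_channels <- if (config$dual_label) c("even", "odd") else "rna"
  base_amp <- config$snr * config$noise_sd

  truth <- generate_truth(config, masks, cells, rna_channels, base_amp)

  stacks <- setNames(vector("list", 2 + length(rna_channels)),
                     c("dapi", "gfp", rna_channels))
  if (render_images) {
    psf <- c(xy = config$psf_sigma_xy_px, z = config$psf_sigma_z_px)
    for (ch in names(stacks)) {
      st <- render_background(config, nz, ny, nx)
      if (ch == "dapi") {
        nucvol <- array(rep(400 * (masks$nucleus_labels > 0), each = nz),
                        dim = c(nz, ny, nx))
        st <- st + nucvol
      }
      rows <- truth[truth$channel == ch, ]
      if (nrow(rows) > 0)
        st <- render_spots(st, rows, psf["xy"], psf["z"])
      stacks[[ch]] <- st
    }
  }

  structure(list(stacks = stacks,
                 cell_labels = masks$cell_labels,
                 nucleus_labels = masks$nucleus_labels,
                 cells = cells, truth = truth, config = config),
            class = "fish_experiment")
}

#' @export
print.fish_experiment <- function(x, ...) {
  cat("<fish_experiment>", nrow(x$cells), "cells |",
      paste(names(x$stacks), collapse = ", "), "| field",
      paste(x$config$field_shape_zyx, collapse = "x"), "\n")
  cat("  ", nrow(x$truth), "ground-truth molecule records, seed",
      x$config$seed, "\n")
  invisible(x)
}

# -- mask placement ---------------------------------------------------------

place_cell_masks <- function(config) {
  ny <- config$field_shape_zyx[2]; nx <- config$field_shape_zyx[3]
  cell_labels <- matrix(0L, ny, nx)
  nucleus_labels <- matrix(0L, ny, nx)
  geom <- vector("list", config$n_cells)
  if (config$n_cells == 0)
    return(list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                geom = geom))
  g <- mask_grid(config$n_cells, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (i in seq_len(config$n_cells)) {
    r <- (i - 1) %/% g$gcols; cidx <- (i - 1) %% g$gcols
    cy <- r * g$box_y + g$box_y / 2 + 0.5
    cx <- cidx * g$box_x + g$box_x / 2 + 0.5
    ry <- 0.42 * g$box_y; rx <- 0.42 * g$box_x
    d2 <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2
    cell_labels[d2 <= 1] <- i
    d2n <- ((yy - cy) / (0.5 * ry))^2 + ((xx - cx) / (0.5 * rx))^2
    nucleus_labels[d2n <= 1] <- i
    geom[[i]] <- list(cy = cy, cx = cx, ry = ry, rx = rx)
  }
  if (any(table(cell_labels[cell_labels > 0]) < 50))
    abort("cell masks could not be placed without degenerate overlap",
          class = "lincfish_generation_error")
  list(cell_labels = cell_labels, nucleus_labels = nucleus_labels, geom = geom)
}

# sample n molecule (y, x) positions (0-based, sub-pixel) from a pixel set
sample_xy <- function(pix, n) {
  if (nrow(pix) == 0 || n == 0)
    return(tibble(y = numeric(0), x = numeric(0)))
  idx <- sample.int(nrow(pix), n, replace = TRUE)
  # +/- 0.49 keeps the rounded position on the sampled pixel, so nuclear
  # flags derived from the mask stay consistent with the sampled compartment
  tibble(y = pix[idx, 1] - 1 + runif(n, -0.49, 0.49),
         x = pix[idx, 2] - 1 + runif(n, -0.49, 0.49))
}

# pixels of cell i, eroded by `margin` px, optionally restricted to
# nucleus / cytoplasm
cell_pixels <- function(masks, i,
                        compartment = c("any", "nucleus", "cytoplasm",
                                        "nucleus_core"),
                        margin = 2) {
  compartment <- arg_match(compartment)
  gm <- masks$geom[[i]]
  ny <- nrow(masks$cell_labels); nx <- ncol(masks$cell_labels)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  inner <- ((yy - gm$cy) / (gm$ry - margin))^2 +
    ((xx - gm$cx) / (gm$rx - margin))^2 <= 1
  ok <- inner & masks$cell_labels == i
  if (compartment == "nucleus") ok <- ok & masks$nucleus_labels == i
  if (compartment == "cytoplasm") ok <- ok & masks$nucleus_labels != i
  if (compartment == "nucleus_core") {
    # deep-nuclear pixels: a focus disc (radius 2) plus jitter must stay
    # inside the nucleus mask
    core <- ((yy - gm$cy) / pmax(0.5 * gm$ry - 3.5, 1))^2 +
      ((xx - gm$cx) / pmax(0.5 * gm$rx - 3.5, 1))^2 <= 1
    ok <- ok & core & masks$nucleus_labels == i
  }
  which(ok, arr.ind = TRUE)
}

# -- ground truth -----------------------------------------------------------

generate_truth <- function(config, masks, cells, rna_channels, base_amp) {
  nz <- config$field_shape_zyx[1]
  zmin <- 2; zmax <- nz - 3
  rows <- list()
  counts <- sample_counts(config$count_model, max(config$n_cells, 1))[
    seq_len(config$n_cells)]
  for (i in seq_len(config$n_cells)) {
    pix_nuc <- cell_pixels(masks, i, "nucleus")
    pix_core <- cell_pixels(masks, i, "nucleus_core")
    pix_cyt <- cell_pixels(masks, i, "cytoplasm")
    pix_any <- cell_pixels(masks, i, "any")
    n_i <- counts[i]
    nuc <- runif(n_i) < config$nuclear_fraction
    pos <- dplyr::bind_rows(sample_xy(pix_nuc, sum(nuc)),
                            sample_xy(pix_cyt, sum(!nuc)))
    base <- tibble(cell_id = i, mol_id = seq_len(nrow(pos)), kind = "rna",
                   z = runif(nrow(pos), zmin, zmax), y = pos$y, x = pos$x,
                   focus_id = NA_integer_)
    next_mol <- nrow(pos)
    # bright nuclear foci of co-located molecules (interphase cells only)
    if (!is.null(config$foci_spec) && !cells$mitotic[i] && nrow(pix_core) > 0) {
      fc <- place_foci_centers(pix_core, config$foci_spec$n_foci)
      for (f in seq_len(nrow(fc))) {
        k <- config$foci_spec$molecules
        r <- 2 * sqrt(runif(k)); th <- runif(k, 0, 2 * pi)
        zf <- runif(1, zmin + 1, zmax - 1)
        base <- dplyr::bind_rows(base, tibble(
          cell_id = i, mol_id = next_mol + seq_len(k), kind = "rna",
          z = zf + runif(k, -0.5, 0.5),
          y = fc$y[f] + r * sin(th), x = fc$x[f] + r * cos(th),
          focus_id = f))
        next_mol <- next_mol + k
      }
    }
    # autofluorescent particles, anywhere in the cell
    n_af <- if (config$autofluor_density > 0)
      rpois(1, config$autofluor_density) else 0L
    if (n_af > 0) {
      posf <- sample_xy(pix_any, n_af)
      base <- dplyr::bind_rows(base, tibble(
        cell_id = i, mol_id = next_mol + seq_len(n_af), kind = "autofluor",
        z = runif(n_af, zmin, zmax), y = posf$y, x = posf$x,
        focus_id = NA_integer_))
      next_mol <- next_mol + n_af
    }
    # rogue-oligo off-target foci (dual-label even channel only)
    if (!is.null(config$rogue_signal) && nrow(pix_core) > 0) {
      rs <- config$rogue_signal
      fc <- place_foci_centers(pix_core, rs$n_foci %||% 1)
      for (f in seq_len(nrow(fc))) {
        k <- rs$molecules %||% 10
        r <- 2 * sqrt(runif(k)); th <- runif(k, 0, 2 * pi)
        zf <- runif(1, zmin + 1, zmax - 1)
        base <- dplyr::bind_rows(base, tibble(
          cell_id = i, mol_id = next_mol + seq_len(k), kind = "rogue",
          z = zf + runif(k, -0.5, 0.5),
          y = fc$y[f] + r * sin(th), x = fc$x[f] + r * cos(th),
          focus_id = NA_integer_))
        next_mol <- next_mol + k
      }
    }
    rows[[i]] <- base
  }
  base <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(cell_id = integer(0), mol_id = integer(0), kind = character(0),
           z = numeric(0), y = numeric(0), x = numeric(0),
           focus_id = integer(0))

  expand_truth_channels(base, config, masks, rna_channels, base_amp)
}

# pick focus centers well separated inside the nucleus
place_foci_centers <- function(pix_nuc, n_foci) {
  for (attempt in 1:50) {
    idx <- sample.int(nrow(pix_nuc), n_foci, replace = nrow(pix_nuc) < n_foci)
    ys <- pix_nuc[idx, 1] - 1; xs <- pix_nuc[idx, 2] - 1
    if (n_foci == 1 || min(dist(cbind(ys, xs))) >= 8) break
  }
  tibble(y = ys, x = xs)
}

# replicate base molecule records into rendered channels with per-channel
# jitter / rigid shift / amplitude, and set mask-consistent nuclear flags
expand_truth_channels <- function(base, config, masks, rna_channels, base_amp) {
  out <- list()
  n <- nrow(base)
  amp_scale <- function(kind, factor) {
    a <- base_amp * factor * exp(rnorm(length(kind), 0, 0.2))
    rf <- config$rogue_signal$amp_factor %||% 2
    a * ifelse(kind == "rogue", rf, 1)
  }
  for (ch in rna_channels) {
    rows <- base
    if (config$dual_label && n > 0) {
      keep <- rows$kind != "rogue" | ch == "even"
      rows <- rows[keep, ]
      m <- nrow(rows)
      rows$y <- rows$y + runif(m, -0.5, 0.5)
      rows$x <- rows$x + runif(m, -0.5, 0.5)
      rows$z <- rows$z + runif(m, -0.3, 0.3)
      if (ch == "odd") {
        rows$y <- rows$y + config$channel_shift_px[1]
        rows$x <- rows$x + config$channel_shift_px[2]
      }
      factor <- config$dual_intensity_factor
    } else {
      rows <- rows[rows$kind != "rogue" | identical(ch, rna_channels[1]), ]
      factor <- 1
    }
    rows$channel <- ch
    rows$amplitude <- amp_scale(rows$kind, factor)
    out[[ch]] <- rows
  }
  af <- base[base$kind == "autofluor", ]
  af$channel <- "gfp"
  af$amplitude <- base_amp * exp(rnorm(nrow(af), 0, 0.2))
  out[["gfp"]] <- af
  truth <- dplyr::bind_rows(out)
  truth$in_nucleus <- mask_lookup(masks$nucleus_labels, truth$y, truth$x) ==
    truth$cell_id
  truth[, c("cell_id", "channel", "mol_id", "kind", "z", "y", "x",
            "in_nucleus", "focus_id", "amplitude")]
}

# label value at rounded 0-based (y, x); 0 outside the image
mask_lookup <- function(labels, y, x) {
  iy <- round(y) + 1; ix <- round(x) + 1
  ok <- iy >= 1 & iy <= nrow(labels) & ix >= 1 & ix <= ncol(labels)
  out <- integer(length(y))
  out[ok] <- labels[cbind(iy[ok], ix[ok])]
  out
}

# -- rendering --------------------------------------------------------------

render_background <- function(config, nz, ny, nx) {
  a <- runif(1, -1, 1); b <- runif(1, -1, 1)
  gy <- seq(0, 1, length.out = ny); gx <- seq(0, 1, length.out = nx)
  plane <- outer(gy, gx, function(u, v) a * u + b * v)
  rng <- range(plane)
  if (diff(rng) > 0) plane <- (plane - rng[1]) / diff(rng)
  bg2d <- config$background_offset + config$background_gradient * plane
  st <- array(rep(bg2d, each = nz), dim = c(nz, ny, nx))
  if (config$noise_sd > 0)
    st <- st + array(rnorm(nz * ny * nx, 0, config$noise_sd), dim = c(nz, ny, nx))
  st
}

render_spots <- function(stack, rows, sxy, sz) {
  d <- dim(stack); nz <- d[1]; ny <- d[2]; nx <- d[3]
  rz <- ceiling(3 * sz); rxy <- ceiling(3 * sxy)
  for (i in seq_len(nrow(rows))) {
    z0 <- rows$z[i] + 1; y0 <- rows$y[i] + 1; x0 <- rows$x[i] + 1
    zi <- max(1, floor(z0 - rz)):min(nz, ceiling(z0 + rz))
    yi <- max(1, floor(y0 - rxy)):min(ny, ceiling(y0 + rxy))
    xi <- max(1, floor(x0 - rxy)):min(nx, ceiling(x0 + rxy))
    gz <- exp(-((zi - z0)^2) / (2 * sz^2))
    gy <- exp(-((yi - y0)^2) / (2 * sxy^2))
    gx <- exp(-((xi - x0)^2) / (2 * sxy^2))
    stack[zi, yi, xi] <- stack[zi, yi, xi] +
      rows$amplitude[i] * (gz %o% gy %o% gx)
  }
  stack
}
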