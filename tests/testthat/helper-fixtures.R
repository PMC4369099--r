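# Shared fixture builders. Everything is generated in code at test time.

# small, fast single-cell experiment
tiny_experiment <- function(seed = 1, mean_count = 40, nz = 16, side = 96,
                            ...) {
  generate_experiment(synth_config(
    n_cells = 1, field_shape_zyx = c(nz, side, side),
    count_model = count_model("poisson", mean = mean_count),
    seed = seed, ...))
}

# render an isolated 2-D Gaussian spot on a constant offset, as a 1-slice
# stack: the self-consistency target for the amplitude fit
gaussian_patch_stack <- function(amplitude = 100, offset = 10,
                                 y0 = 10.3, x0 = 11.6, sigma = 1.4,
                                 side = 21, noise_sd = 0, seed = 1) {
  yy <- matrix(0:(side - 1), side, side)
  xx <- t(yy)
  img <- offset + amplitude * exp(-((yy - y0)^2 + (xx - x0)^2) / (2 * sigma^2))
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + rnorm(side * side, 0, noise_sd)
  }
  array(img, dim = c(1, side, side))
}

# spot table with known per-cell nuclear fractions (no imaging involved)
spot_table <- function(fracs, n_spots = 40) {
  purrr::map_dfr(seq_along(fracs), function(i) {
    n_nuc <- round(fracs[i] * n_spots)
    tibble::tibble(cell_id = i, channel = "rna",
                   z = 5, y = runif(n_spots, 0, 99), x = runif(n_spots, 0, 99),
                   is_nuclear = rep(c(TRUE, FALSE), c(n_nuc, n_spots - n_nuc)))
  })
}

# class-conditional generator configs used for the localization cohort
class_config <- function(class, seed) {
  base <- list(n_cells = 6, field_shape_zyx = c(16L, 256L, 256L), seed = seed)
  spec <- switch(class,
    I = list(count_model = count_model("poisson", mean = 2),
             nuclear_fraction = 1, foci_spec = list(n_foci = 2, molecules = 12)),
    II = list(count_model = count_model("poisson", mean = 30),
              nuclear_fraction = 0.95,
              foci_spec = list(n_foci = 2, molecules = 8)),
    III = list(count_model = count_model("poisson", mean = 30),
               nuclear_fraction = 0.9),
    IV = list(count_model = count_model("poisson", mean = 30),
              nuclear_fraction = 0.5),
    V = list(count_model = count_model("poisson", mean = 40),
             nuclear_fraction = 0.15))
  do.call(synth_config, c(base, spec))
}

# ground-truth molecules of one channel as a detected-spot-like table
truth_as_spots <- function(experiment, channel = "rna") {
  tr <- experiment$truth[experiment$truth$channel == channel, ]
  tibble::tibble(cell_id = tr$cell_id, channel = channel,
                 z = tr$z, y = tr$y, x = tr$x,
                 amplitude = tr$amplitude, is_nuclear = tr$in_nucleus,
                 is_autofluorescent = tr$kind == "autofluor")
}
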