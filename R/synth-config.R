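#' Configuration for a synthetic smFISH experiment
#'
#' Bundles every knob of the synthetic-image generator. Defaults emulate the
#' acquisition geometry of a widefield smFISH stack: 25 optical slices at
#' 0.3 um spacing, 0.125 um pixels (100x objective), a diffraction-limited
#' PSF of ~1.3 px laterally, and a smooth nonuniform background with Gaussian
#' read noise. `snr` is the ratio of median spot amplitude to the read-noise
#' standard deviation.
#'
#' @param n_cells Number of cells placed on a non-overlapping grid.
#' @param field_shape_zyx Integer triple `(nz, ny, nx)` in voxels.
#' @param z_step_um Axial slice spacing in micrometres.
#' @param pixel_size_um Lateral pixel size in micrometres.
#' @param count_model A [count_model()] for true molecules per cell.
#' @param nuclear_fraction Probability a scattered molecule is nuclear.
#' @param foci_spec `NULL`, or `list(n_foci =, molecules =)`: each
#'   (non-mitotic) cell receives `n_foci` bright nuclear foci of `molecules`
#'   co-located molecules each, rendered within a 2 px radius disc. Foci are
#'   omitted from mitotic cells: nuclear foci dissolve during mitosis.
#' @param psf_sigma_xy_px,psf_sigma_z_px Gaussian PSF sigmas (pixels, slices).
#' @param snr Median spot amplitude divided by read-noise sd.
#' @param noise_sd Gaussian read-noise standard deviation (fluorescence units).
#' @param background_offset Constant camera/background offset.
#' @param background_gradient Peak-to-trough amplitude of the smooth
#'   polynomial background gradient.
#' @param channel_shift_px Length-2 `(dy, dx)` rigid misregistration applied
#'   to the second ("odd") channel in dual-label mode.
#' @param dual_label If `TRUE`, render every molecule in two channels
#'   (`even`, `odd`) at `dual_intensity_factor` of the single-channel
#'   amplitude, with independent sub-pixel jitter per channel — the even/odd
#'   probe-set validation geometry.
#' @param dual_intensity_factor Amplitude factor for dual-label channels
#'   (half the probe set binds each color).
#' @param rogue_signal `NULL`, or `list(n_foci =, molecules =, amp_factor =)`:
#'   bright off-target foci rendered in the `even` channel only, mimicking a
#'   single rogue oligonucleotide binding an abundant off-target RNA.
#' @param autofluor_density Mean number of autofluorescent particles per cell;
#'   these appear in the GFP channel and are duplicated into every RNA
#'   channel at matching positions.
#' @param mitotic_fraction Probability a cell is flagged mitotic.
#' @param cell_type Label recorded for every cell.
#' @param seed Integer seed driving all randomness in [generate_experiment()].
#'
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_cells = 2, seed = 1)
#' @export
synth_config <- function(n_cells = 10,
                         field_shape_zyx = c(25L, 256L, 256L),
                         z_step_um = 0.3,
                         pixel_size_um = 0.125,
                         count_model = lincfish::count_model("poisson", mean = 40),
                         nuclear_fraction = 0.5,
                         foci_spec = NULL,
                         psf_sigma_xy_px = 1.3,
                         psf_sigma_z_px = 1.2,
                         snr = 10,
                         noise_sd = 10,
                         background_offset = 200,
                         background_gradient = 50,
                         channel_shift_px = c(0, 0),
                         dual_label = FALSE,
                         dual_intensity_factor = 0.7,
                         rogue_signal = NULL,
                         autofluor_density = 0,
                         mitotic_fraction = 0,
                         cell_type = "synthetic",
                         seed = 1L) {
  cfg <- structure(
    list(n_cells = as.integer(n_cells),
         field_shape_zyx = as.integer(field_shape_zyx),
         z_step_um = z_step_um, pixel_size_um = pixel_size_um,
         count_model = count_model, nuclear_fraction = nuclear_fraction,
         foci_spec = foci_spec,
         psf_sigma_xy_px = psf_sigma_xy_px, psf_sigma_z_px = psf_sigma_z_px,
         snr = snr, noise_sd = noise_sd,
         background_offset = background_offset,
         background_gradient = background_gradient,
         channel_shift_px = as.numeric(channel_shift_px),
         dual_label = isTRUE(dual_label),
         dual_intensity_factor = dual_intensity_factor,
         rogue_signal = rogue_signal,
         autofluor_density = autofluor_density,
         mitotic_fraction = mitotic_fraction,
         cell_type = cell_type,
         seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (!inherits(cfg, "synth_config")) abort_config("not a synth_config")
  if (cfg$n_cells < 0) abort_config("n_cells must be >= 0")
  if (length(cfg$field_shape_zyx) != 3 || any(cfg$field_shape_zyx < 1))
    abort_config("field_shape_zyx must be a positive integer triple")
  if (cfg$field_shape_zyx[1] < 7)
    abort_config("need at least 7 z slices to hold a 3-D PSF")
  for (p in c("nuclear_fraction", "mitotic_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort_config(paste(p, "must be in [0, 1]"))
  if (cfg$psf_sigma_xy_px <= 0 || cfg$psf_sigma_z_px <= 0)
    abort_config("PSF sigmas must be > 0")
  if (cfg$snr <= 0 || cfg$noise_sd < 0) abort_config("snr must be > 0 and noise_sd >= 0")
  if (length(cfg$channel_shift_px) != 2) abort_config("channel_shift_px must be length 2")
  validate_count_model(cfg$count_model)
  if (!is.null(cfg$foci_spec) &&
      (is.null(cfg$foci_spec$n_foci) || is.null(cfg$foci_spec$molecules)))
    abort_config("foci_spec needs n_foci and molecules")
  if (cfg$n_cells > 0) {
    g <- mask_grid(cfg$n_cells, cfg$field_shape_zyx[2], cfg$field_shape_zyx[3])
    if (min(g$box_y, g$box_x) < 24)
      abort_config("field too small to place non-overlapping cell masks (need >= 24 px per cell)")
  }
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_cells, "cells, field",
      paste(x$field_shape_zyx, collapse = "x"),
      sprintf("(z %g um, px %g um), snr %g, seed %d\n",
              x$z_step_um, x$pixel_size_um, x$snr, x$seed))
  cat("  counts:", x$count_model$kind,
      "| nuclear fraction", x$nuclear_fraction,
      if (x$dual_label) "| dual-label" else "",
      if (!is.null(x$foci_spec)) sprintf("| foci %dx%d", x$foci_spec$n_foci,
                                         x$foci_spec$molecules) else "", "\n")
  invisible(x)
}

# grid layout used to place non-overlapping cells
mask_grid <- function(n_cells, ny, nx) {
  gcols <- ceiling(sqrt(n_cells))
  grows <- ceiling(n_cells / gcols)
  list(grows = grows, gcols = gcols,
       box_y = floor(ny / grows), box_x = floor(nx / gcols))
}
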