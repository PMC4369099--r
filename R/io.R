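#' Read and write multi-page TIFF image stacks
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFFs, one page per
#' z-slice (page order = z order). `read_stack()` returns a numeric
#' `(z, y, x)` array of integer sample values; `write_stack()` rounds and
#' clips to the 16-bit range, so `read_stack(write_stack(x))` is bit-exact
#' for integer-valued arrays in `[0, 65535]`.
#'
#' @param path TIFF file path.
#' @param stack Numeric `(z, y, x)` array (or a matrix = one slice).
#' @return `read_stack()`: numeric `(z, y, x)` array.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    abort("TIFF pages must be single-channel grayscale",
          class = "lincfish_format_error")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
    abort("TIFF pages differ in size", class = "lincfish_format_error")
  st <- array(0, dim = c(length(pages), d))
  for (z in seq_along(pages)) st[z, , ] <- pages[[z]]
  st
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1, dim(stack)))
  vals <- pmin(pmax(round(stack), 0), 65535)
  pages <- lapply(seq_len(dim(stack)[1]), function(z) vals[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read and write label-image masks
#'
#' Label masks (cell or nucleus segmentations) are 16-bit single-page TIFFs
#' with background 0 and one integer label per cell.
#'
#' @param path TIFF file path.
#' @param labels Integer label matrix.
#' @return `read_mask()`: integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask
#' @export
write_mask <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Write or read a synthetic experiment bundle on disk
#'
#' The on-disk layout mirrors a real acquisition: one multi-page TIFF per
#' channel (`<channel>.tif`), `cell_mask.tif` and `nucleus_mask.tif` label
#' images, `cells.csv`, ground truth as `truth.csv` (one row per molecule)
#' and a JSON `manifest.json` recording the generator configuration
#' including the seed. Stacks are rounded to 16-bit integers on write.
#'
#' @param experiment A `fish_experiment` with rendered stacks.
#' @param dir Output directory (created if missing).
#' @return `write_experiment()`: `dir`, invisibly. `read_experiment()`: a
#'   `fish_experiment` (with `config` restored as a plain list).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(experiment$stacks)) {
    if (is.null(experiment$stacks[[ch]])) next
    write_stack(experiment$stacks[[ch]], file.path(dir, paste0(ch, ".tif")))
  }
  write_mask(experiment$cell_labels, file.path(dir, "cell_mask.tif"))
  write_mask(experiment$nucleus_labels, file.path(dir, "nucleus_mask.tif"))
  readr::write_csv(experiment$cells, file.path(dir, "cells.csv"))
  readr::write_csv(experiment$truth, file.path(dir, "truth.csv"))
  cfg <- experiment$config
  cfg$count_model <- unclass(cfg$count_model)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tifs <- list.files(dir, pattern = "\\.tif$")
  chans <- setdiff(sub("\\.tif$", "", tifs), c("cell_mask", "nucleus_mask"))
  stacks <- setNames(
    lapply(chans, function(ch) read_stack(file.path(dir, paste0(ch, ".tif")))),
    chans)
  structure(list(
    stacks = stacks,
    cell_labels = read_mask(file.path(dir, "cell_mask.tif")),
    nucleus_labels = read_mask(file.path(dir, "nucleus_mask.tif")),
    cells = readr::read_csv(file.path(dir, "cells.csv"),
                            show_col_types = FALSE),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE),
    config = manifest), class = "fish_experiment")
}

#' Read and write spot tables
#'
#' Spots travel between pipeline stages as headered CSV with 0-based voxel
#' coordinates.
#'
#' @param spots Spot tibble as produced by [detect_spots()].
#' @param path CSV path.
#' @return `read_spots()`: spot tibble.
#' @export
write_spots <- function(spots, path) {
  readr::write_csv(spots, path)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
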