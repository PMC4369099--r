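#' Flag spots as nuclear by DAPI-mask membership
#'
#' A spot is nuclear when its (y, x) position, rounded to the nearest pixel,
#' falls inside its cell's nucleus label — the 2-D DAPI heuristic in which
#' the maximal signal across z-slices defines the nuclear outline, so z is
#' collapsed.
#'
#' @param spots Spot tibble with `cell_id`, `y`, `x`.
#' @param nucleus_labels Integer nucleus label matrix (background 0), or a
#'   `fish_experiment`.
#' @return `spots` with `is_nuclear` set.
#' @export
flag_nuclear_spots <- function(spots, nucleus_labels) {
  if (inherits(nucleus_labels, "fish_experiment"))
    nucleus_labels <- nucleus_labels$nucleus_labels
  if (is.null(nucleus_labels)) abort_input("missing nucleus mask")
  spots$is_nuclear <- mask_lookup(nucleus_labels, spots$y, spots$x) ==
    spots$cell_id
  spots
}

#' Population-level nuclear localization metrics
#'
#' Two complementary summaries of how nuclear an RNA is, plus the median
#' per-cell fraction used for classification:
#' * molecule level: total nuclear spots / total spots across all cells;
#' * cell level: fraction of cells in which more than 50% of spots are
#'   nuclear;
#' * median per-cell nuclear fraction.
#' Cells without spots carry no localization information and are excluded.
#'
#' @param spots Spot tibble with `cell_id` and logical `is_nuclear` (rows =
#'   spots; only expressing cells appear).
#' @return One-row tibble: `n_cells`, `n_spots`, `molecule_level`,
#'   `cell_level`, `median_fraction`.
#' @export
nuclear_metrics <- function(spots) {
  if (nrow(spots) == 0)
    abort("no expressing cells: nuclear metrics undefined",
          class = "lincfish_no_expression")
  per_cell <- spots %>%
    group_by(.data$cell_id) %>%
    summarise(n = dplyr::n(), frac = mean(.data$is_nuclear), .groups = "drop")
  tibble(n_cells = nrow(per_cell), n_spots = nrow(spots),
         molecule_level = mean(spots$is_nuclear),
         cell_level = mean(per_cell$frac > 0.5),
         median_fraction = median(per_cell$frac))
}

#' Per-cell nuclear fractions
#' @inheritParams nuclear_metrics
#' @return Tibble `cell_id`, `n_spots`, `nuclear_fraction`.
#' @export
nuclear_fractions <- function(spots) {
  spots %>%
    group_by(.data$cell_id) %>%
    summarise(n_spots = dplyr::n(), nuclear_fraction = mean(.data$is_nuclear),
              .groups = "drop")
}

#' Detect candidate nuclear foci
#'
#' Bright sub-nuclear accumulations of multiple molecules (often the
#' transcription site) are identified as single-linkage clusters of nuclear
#' spots: spots closer than `radius` px (laterally) are linked, and clusters
#' of at least `min_molecules` spots are reported as foci. Intended as a
#' candidate list that a user may confirm visually.
#'
#' @param spots Spot tibble with `cell_id`, `y`, `x` and `is_nuclear`.
#' @param min_molecules Minimum cluster size (default 5).
#' @param radius Single-linkage cut distance in px (default 3).
#' @return Tibble `cell_id`, `focus_id`, `n_molecules`, `y`, `x` (centroid).
#' @export
detect_nuclear_foci <- function(spots, min_molecules = 5, radius = 3) {
  proto <- tibble(cell_id = integer(0), focus_id = integer(0),
                  n_molecules = integer(0), y = numeric(0), x = numeric(0))
  nuc <- spots[!is.na(spots$is_nuclear) & spots$is_nuclear, ]
  if (nrow(nuc) == 0) return(proto)
  out <- purrr::map_dfr(split(nuc, nuc$cell_id), function(cs) {
    if (nrow(cs) == 1) return(NULL)
    cl <- cutree(hclust(dist(cbind(cs$y, cs$x)), method = "single"),
                 h = radius)
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes >= min_molecules])
    if (length(big) == 0) return(NULL)
    purrr::map_dfr(seq_along(big), function(j) {
      m <- cl == big[j]
      tibble(cell_id = cs$cell_id[1], focus_id = j,
             n_molecules = sum(m), y = mean(cs$y[m]), x = mean(cs$x[m]))
    })
  })
  if (nrow(out) == 0) proto else out
}

#' Localization class from summary metrics
#'
#' The five-class nuclear localization taxonomy:
#' * class I-III require a median per-cell nuclear fraction > `nuclear_hi`
#'   (0.65): I when nuclear molecules sit almost exclusively in one or two
#'   large foci (`foci_fraction >= foci_dominant` and typical foci per cell
#'   `<= max_foci_class1`), II when foci coexist with scattered molecules,
#'   III when no foci are present;
#' * class V requires a median fraction < `nuclear_lo` (0.35) *and* mean
#'   count > `min_count_class5` (20) — the count condition keeps the
#'   predominantly-cytoplasmic call conservative;
#' * everything else is class IV (nuclear and cytoplasmic).
#'
#' @param median_fraction Median per-cell nuclear fraction.
#' @param mean_count Mean molecules per cell.
#' @param foci_per_cell Mean number of detected foci per expressing cell.
#' @param foci_fraction Fraction of nuclear molecules inside foci.
#' @param nuclear_hi,nuclear_lo,min_count_class5 Published rule thresholds.
#' @param foci_present Minimum `foci_per_cell` at which foci count as a
#'   feature of the pattern.
#' @param foci_dominant,max_foci_class1 Codification of "one or two large
#'   foci" for class I.
#' @return A single string in `c("I", "II", "III", "IV", "V")`.
#' @examples
#' localization_class(0.9, 30, foci_per_cell = 0)            # "III"
#' localization_class(0.2, 30)                               # "V"
#' localization_class(0.5, 30)                               # "IV"
#' localization_class(0.9, 30, 2, foci_fraction = 0.9)       # "I"
#' @export
localization_class <- function(median_fraction, mean_count,
                               foci_per_cell = 0, foci_fraction = 0,
                               nuclear_hi = 0.65, nuclear_lo = 0.35,
                               min_count_class5 = 20,
                               foci_present = 0.5, foci_dominant = 0.8,
                               max_foci_class1 = 2.5) {
  if (is.na(median_fraction)) abort_input("median_fraction is NA")
  if (median_fraction > nuclear_hi) {
    if (foci_per_cell < foci_present) return("III")
    if (foci_fraction >= foci_dominant && foci_per_cell <= max_foci_class1)
      return("I")
    return("II")
  }
  if (median_fraction < nuclear_lo && mean_count > min_count_class5)
    return("V")
  "IV"
}

#' Summarize nuclear localization for one gene-cell-type pair
#'
#' Computes per-cell nuclear fractions, population metrics, candidate foci
#' and the class I-V assignment from a spot table. Mitotic cells (flagged in
#' `cells`) are excluded from the interphase classification and reported
#' separately: the fraction of mitotic cells retaining foci probes whether
#' nuclear foci persist through mitosis. Autofluorescent spots are dropped
#' first. A `manual_class` override reassigns borderline cases and is
#' recorded.
#'
#' @param spots Spot tibble (one gene, one cell type) with `cell_id`,
#'   `is_nuclear`, optionally `is_autofluorescent`.
#' @param cells Optional cell metadata tibble (`cell_id`, `mitotic`).
#' @param gene,cell_type Identifiers carried into the result.
#' @param min_molecules,radius Foci detection parameters, see
#'   [detect_nuclear_foci()].
#' @param manual_class Optional manual class override ("I".."V").
#' @param ... Further threshold arguments passed to [localization_class()].
#' @return A `localization_summary`: `glance()` gives a one-row tibble with
#'   the metrics, foci statistics and `class`; `tidy()` the per-cell
#'   fractions.
#' @export
summarize_localization <- function(spots, cells = NULL,
                                   gene = NA_character_,
                                   cell_type = NA_character_,
                                   min_molecules = 5, radius = 3,
                                   manual_class = NULL, ...) {
  if (!is.null(spots$is_autofluorescent))
    spots <- spots[!spots$is_autofluorescent, ]
  mitotic_ids <- integer(0)
  if (!is.null(cells) && !is.null(cells$mitotic))
    mitotic_ids <- cells$cell_id[cells$mitotic]
  inter <- spots[!spots$cell_id %in% mitotic_ids, ]
  mito <- spots[spots$cell_id %in% mitotic_ids, ]
  if (nrow(inter) == 0)
    abort("no expressing interphase cells: localization unclassified",
          class = "lincfish_no_expression")
  met <- nuclear_metrics(inter)
  fracs <- nuclear_fractions(inter)
  foci <- detect_nuclear_foci(inter, min_molecules, radius)
  n_cells <- nrow(fracs)
  n_nuclear <- sum(inter$is_nuclear)
  foci_per_cell <- nrow(foci) / n_cells
  foci_fraction <- if (n_nuclear > 0) sum(foci$n_molecules) / n_nuclear else 0
  mean_count <- nrow(inter) / n_cells
  auto_class <- localization_class(met$median_fraction, mean_count,
                                   foci_per_cell, foci_fraction, ...)
  cls <- manual_class %||% auto_class
  mito_foci <- detect_nuclear_foci(mito, min_molecules, radius)
  n_mito <- length(unique(mito$cell_id))
  structure(list(gene = gene, cell_type = cell_type,
                 metrics = met, per_cell = fracs, foci = foci,
                 mean_count = mean_count,
                 foci_per_cell = foci_per_cell,
                 foci_fraction = foci_fraction,
                 class = cls, auto_class = auto_class,
                 manual_reassignment = if (is.null(manual_class)) NA_character_
                   else paste("manual override:", manual_class),
                 n_mitotic_cells = n_mito,
                 mitotic_cells_with_foci =
                   length(unique(mito_foci$cell_id))),
            class = "localization_summary")
}

#' @export
print.localization_summary <- function(x, ...) {
  cat("<localization_summary>",
      if (!is.na(x$gene)) paste0(x$gene, " / ", x$cell_type) else "", "\n")
  cat(sprintf("  class %s | median nuclear fraction %.2f | mean count %.1f | %.2f foci/cell (%.0f%% of nuclear molecules)\n",
              x$class, x$metrics$median_fraction, x$mean_count,
              x$foci_per_cell, 100 * x$foci_fraction))
  if (x$n_mitotic_cells > 0)
    cat("  mitotic cells:", x$n_mitotic_cells, "| with foci:",
        x$mitotic_cells_with_foci, "\n")
  invisible(x)
}

#' @export
glance.localization_summary <- function(x, ...) {
  dplyr::bind_cols(
    tibble(gene = x$gene, cell_type = x$cell_type),
    x$metrics,
    tibble(mean_count = x$mean_count, n_foci = nrow(x$foci),
           foci_per_cell = x$foci_per_cell, foci_fraction = x$foci_fraction,
           class = x$class, auto_class = x$auto_class,
           manual_reassignment = x$manual_reassignment,
           n_mitotic_cells = x$n_mitotic_cells,
           mitotic_cells_with_foci = x$mitotic_cells_with_foci))
}

#' @export
tidy.localization_summary <- function(x, ...) x$per_cell
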