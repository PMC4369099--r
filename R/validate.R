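#' Spot selection count for two-color validation
#'
#' Number of brightest particles taken from each color channel when counting
#' co-localized spots: `x = max(50, round(5 * m))`, where `m` is the mean
#' per-cell particle count measured with the full single-colored probe set.
#' The floor of 50 keeps the selection meaningful for lowly expressed RNAs;
#' the factor 5 keeps it generous relative to true abundance so that the
#' co-localized count does not depend on an intensity threshold.
#'
#' @param m_single Mean per-cell count from the single-colored probe set
#'   (>= 0); vectorized.
#' @return Integer selection count(s).
#' @examples
#' selection_count(c(4, 10, 30))  # 50, 50, 150
#' @export
selection_count <- function(m_single) {
  if (any(m_single < 0)) abort_input("mean count must be >= 0")
  as.integer(pmax(50, round(5 * m_single)))
}

#' Co-localized particle count for one cell
#'
#' Takes the `x_select` highest-signal spots of each of the even- and
#' odd-labeled channels (all spots if fewer) and counts how many co-localize
#' under the two-stage matching of [colocalize_two_stage()]. Deliberately
#' threshold-free: it does not rely on the plateau method, which is often
#' unusable with half probe sets.
#'
#' @param even_spots,odd_spots Spot tibbles for one cell with an intensity
#'   column (`amplitude`, falling back to `raw_intensity`).
#' @param x_select Number of brightest spots to keep per channel (>= 1).
#' @param coarse,fine,z_window Matching parameters, see
#'   [colocalize_two_stage()].
#' @return Integer number of co-localized spots.
#' @export
count_colocalized <- function(even_spots, odd_spots, x_select,
                              coarse = 4, fine = 2, z_window = 1) {
  if (x_select < 1) abort_input("x_select must be >= 1")
  top <- function(sp) {
    if (nrow(sp) <= x_select) return(sp)
    key <- if (!is.null(sp$amplitude) && !all(is.na(sp$amplitude)))
      sp$amplitude else sp$raw_intensity
    sp[order(-key)[seq_len(x_select)], ]
  }
  res <- colocalize_two_stage(top(even_spots), top(odd_spots),
                              coarse = coarse, fine = fine,
                              z_window = z_window)
  res$n_matched
}

#' Per-cell co-localized counts across an experiment
#'
#' Applies [count_colocalized()] to every cell present in either channel.
#'
#' @param even_spots,odd_spots Spot tibbles with a `cell_id` column.
#' @inheritParams count_colocalized
#' @return Tibble `cell_id`, `n_even`, `n_odd`, `n_coloc`.
#' @export
colocalized_counts <- function(even_spots, odd_spots, x_select,
                               coarse = 4, fine = 2, z_window = 1) {
  ids <- sort(union(unique(even_spots$cell_id), unique(odd_spots$cell_id)))
  purrr::map_dfr(ids, function(id) {
    e <- even_spots[even_spots$cell_id == id, ]
    o <- odd_spots[odd_spots$cell_id == id, ]
    tibble(cell_id = id, n_even = nrow(e), n_odd = nrow(o),
           n_coloc = count_colocalized(e, o, x_select, coarse, fine, z_window))
  })
}

#' Validate a probe set from its count distributions
#'
#' The quantitative validation criterion: a probe set is invalid in a cell
#' type when the per-cell distribution of co-localized (even/odd) particle
#' counts differs significantly from the distribution of single-color
#' (full probe set) particle counts — two-sided Mann-Whitney U rank-sum test
#' at `alpha` (default 0.05). A genuine probe set yields co-localized counts
#' statistically indistinguishable from the single-color counts; a rogue
#' oligonucleotide inflates one channel only, deflating the co-localized
#' distribution. A near-zero single-color mean gives verdict `no_signal`;
#' an externally supplied qualitative-mismatch flag (pattern difference
#' between the two colors, judged by eye) forces
#' `invalid_qualitative_flagged`.
#'
#' @param single_counts Per-cell counts from the full single-colored probe
#'   set (>= 3 cells).
#' @param coloc_counts Per-cell co-localized counts from the two-color assay
#'   (>= 3 cells).
#' @param alpha Significance level.
#' @param qualitative_flag `TRUE` if the two color channels show visibly
#'   different localization patterns (manual judgement).
#' @param probe_set,cell_type Optional identifiers carried into the result.
#' @return A `probe_validation` object; `glance()` gives a one-row tibble
#'   (`probe_set`, `cell_type`, `m_single`, `x_select`, `u_statistic`,
#'   `p_value`, `verdict`), `tidy()` the per-cell counts in long form.
#' @export
validate_probe_set <- function(single_counts, coloc_counts, alpha = 0.05,
                               qualitative_flag = FALSE,
                               probe_set = NA_character_,
                               cell_type = NA_character_) {
  if (length(single_counts) < 3 || length(coloc_counts) < 3)
    abort("need at least 3 cells in each count distribution",
          class = "lincfish_insufficient_data")
  m_single <- mean(single_counts)
  wt <- suppressWarnings(
    wilcox.test(single_counts, coloc_counts, alternative = "two.sided",
                exact = FALSE, correct = TRUE))
  verdict <- if (m_single < 0.5) "no_signal"
  else if (qualitative_flag) "invalid_qualitative_flagged"
  else if (wt$p.value < alpha) "invalid_quantitative"
  else "valid"
  structure(list(probe_set = probe_set, cell_type = cell_type,
                 single_counts = single_counts, coloc_counts = coloc_counts,
                 m_single = m_single,
                 x_select = selection_count(m_single),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value, alpha = alpha,
                 qualitative_flag = qualitative_flag, verdict = verdict),
            class = "probe_validation")
}

#' @export
print.probe_validation <- function(x, ...) {
  cat("<probe_validation>",
      if (!is.na(x$probe_set)) paste0(x$probe_set, " / ", x$cell_type) else "",
      "\n  single-color mean", format(x$m_single, digits = 4),
      "| x_select", x$x_select,
      "| Mann-Whitney U", format(x$u_statistic, digits = 4),
      "| p", format(x$p_value, digits = 3), "\n  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
glance.probe_validation <- function(x, ...) {
  tibble(probe_set = x$probe_set, cell_type = x$cell_type,
         n_cells_single = length(x$single_counts),
         n_cells_coloc = length(x$coloc_counts),
         m_single = x$m_single, x_select = x$x_select,
         u_statistic = x$u_statistic, p_value = x$p_value,
         verdict = x$verdict)
}

#' @export
tidy.probe_validation <- function(x, ...) {
  dplyr::bind_rows(
    tibble(assay = "single_color", cell = seq_along(x$single_counts),
           count = as.numeric(x$single_counts)),
    tibble(assay = "colocalized", cell = seq_along(x$coloc_counts),
           count = as.numeric(x$coloc_counts)))
}
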