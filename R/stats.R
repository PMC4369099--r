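#' Histogram bins for molecule-count distributions
#'
#' The binning used for count-distribution heatmaps: width 3 from 0 to 50
#' molecules, width 10 from 50 to 300; counts above 300 fall in the last bin.
#'
#' @param counts Non-negative integer counts per cell.
#' @return Tibble `bin_lo`, `bin_hi` (right-open except the last bin),
#'   `n`, `density`.
#' @export
count_histogram <- function(counts) {
  if (any(counts < 0)) abort_input("counts must be >= 0")
  breaks <- c(seq(0, 48, by = 3), seq(50, 300, by = 10))
  lo <- breaks
  hi <- c(breaks[-1], Inf)
  n <- vapply(seq_along(lo), function(i)
    sum(counts >= lo[i] & counts < hi[i]), integer(1))
  tibble(bin_lo = lo, bin_hi = hi, n = n, density = n / length(counts))
}

#' Summarize a single-cell molecule-count distribution
#'
#' Exact mean, median, standard deviation and coefficient of variation
#' (sd/mean) of per-cell counts, over all imaged cells including zeros, plus
#' the binned histogram of [count_histogram()]. The CV uses the population
#' standard deviation (n denominator) by default.
#'
#' @param counts Non-negative counts per cell (>= 1 cell).
#' @param gene,cell_type Optional identifiers.
#' @param sd_type `"population"` (n) or `"sample"` (n - 1) denominator.
#' @return One-row tibble: `gene`, `cell_type`, `n_cells`, `mean`, `median`,
#'   `sd`, `cv`, and a `histogram` list-column.
#' @examples
#' summarize_counts(c(0, 0, 0, 40))  # mean 10, median 0
#' @export
summarize_counts <- function(counts, gene = NA_character_,
                             cell_type = NA_character_,
                             sd_type = c("population", "sample")) {
  sd_type <- arg_match(sd_type)
  if (length(counts) < 1) abort_input("need at least one cell")
  if (any(counts < 0)) abort_input("counts must be >= 0")
  n <- length(counts)
  s <- if (sd_type == "population")
    sqrt(mean((counts - mean(counts))^2)) else sd(counts)
  mu <- mean(counts)
  tibble(gene = gene, cell_type = cell_type, n_cells = n,
         mean = mu, median = median(counts), sd = s,
         cv = if (mu > 0) s / mu else NA_real_,
         histogram = list(count_histogram(counts)))
}

#' Poisson reference CV
#'
#' Coefficient of variation of a Poisson count distribution with the given
#' mean, `1 / sqrt(mean)` — the reference curve against which single-cell
#' variability is judged.
#'
#' @param mean Mean molecules per cell (> 0); vectorized.
#' @return Numeric CV value(s).
#' @export
poisson_reference <- function(mean) {
  if (any(mean <= 0)) abort_input("mean must be > 0")
  1 / sqrt(mean)
}

#' Median-versus-mean regression across genes
#'
#' Ordinary least squares of the per-gene median molecule count on the mean.
#' For unimodal single-cell distributions the two track each other closely
#' (slope near 1, high Pearson r); heterogeneous (e.g. bimodal) genes fall
#' below the line because rare high-expressing cells inflate the mean but
#' not the median.
#'
#' @param summaries Tibble with `mean` and `median` columns (one row per
#'   gene-cell-type pair; >= 3 rows).
#' @return One-row tibble: `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `n`. The fitted `lm` object is attached as attribute `model`.
#' @export
mean_median_regression <- function(summaries) {
  if (nrow(summaries) < 3) abort_input("need >= 3 gene-cell pairs")
  if (sd(summaries$mean) == 0)
    abort("all means equal: regression slope undefined",
          class = "lincfish_degenerate")
  fit <- lm(median ~ mean, data = summaries)
  ct <- cor.test(summaries$mean, summaries$median)
  out <- tibble(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                pearson_r = unname(ct$estimate),
                p_value = ct$p.value, n = nrow(summaries))
  attr(out, "model") <- fit
  out
}

#' Upper bound on an undetected high-expressing subpopulation
#'
#' If a fraction `f` of cells were high-expressing "jackpot" cells, the
#' probability of seeing at least one among `n` sampled cells is
#' `1 - (1 - f)^n`. The smallest fraction detectable with the given power is
#' therefore `f = 1 - (1 - power)^(1/n)`: observing none in `n` cells bounds
#' the jackpot fraction below `f` at that power. With n = 500 and power
#' 0.95 the bound is ~0.6% of cells.
#'
#' @param n_cells Number of cells imaged (>= 1).
#' @param power Detection power, in (0, 1).
#' @return Minimal detectable fraction (probability scale).
#' @examples
#' jackpot_bound(500, 0.95)  # ~0.006
#' @export
jackpot_bound <- function(n_cells, power = 0.95) {
  if (any(n_cells < 1)) abort_input("n_cells must be >= 1")
  if (any(power <= 0 | power >= 1)) abort_input("power must be in (0, 1)")
  1 - (1 - power)^(1 / n_cells)
}

#' Correlate a gene's single-cell counts with a marker's
#'
#' Pearson correlation of per-cell molecule counts between a gene and a
#' co-stained marker (e.g. the cell-cycle reporter CCNA2, or a divergent
#' neighbor gene), after symmetric outlier removal: cells in which either
#' count exceeds its gene's `median + mad_mult * MAD` are dropped and the
#' number removed is reported. MAD is the scaled median absolute deviation
#' (consistent with the normal sd).
#'
#' @param counts_gene,counts_marker Paired per-cell counts (>= 10 cells).
#' @param mad_mult Outlier multiplier (default 5).
#' @param gene,marker Optional identifiers.
#' @return One-row tibble: `gene`, `marker`, `n_cells`,
#'   `n_outliers_removed`, `pearson_r`, `p_value`.
#' @export
correlate_with_marker <- function(counts_gene, counts_marker, mad_mult = 5,
                                  gene = NA_character_,
                                  marker = NA_character_) {
  if (length(counts_gene) != length(counts_marker))
    abort_input("count vectors must be paired (equal length)")
  if (length(counts_gene) < 10) abort_input("need >= 10 cells")
  hi_g <- median(counts_gene) + mad_mult * mad(counts_gene)
  hi_m <- median(counts_marker) + mad_mult * mad(counts_marker)
  keep <- counts_gene <= hi_g & counts_marker <= hi_m
  if (sum(keep) < 10)
    abort("fewer than 10 cells remain after outlier removal",
          class = "lincfish_insufficient_data")
  ct <- suppressWarnings(cor.test(counts_gene[keep], counts_marker[keep]))
  tibble(gene = gene, marker = marker, n_cells = sum(keep),
         n_outliers_removed = sum(!keep),
         pearson_r = unname(ct$estimate), p_value = ct$p.value)
}

#' Marker correlations across a gene panel with FDR control
#'
#' Runs [correlate_with_marker()] for every gene against the marker and
#' assigns a sign label (`positive` / `negative` / `none`) where the
#' Benjamini-Hochberg adjusted p-value falls below `alpha`.
#'
#' @param counts Long tibble: `gene`, `cell_id`, `count`.
#' @param marker Name (in `gene`) of the marker to correlate against.
#' @param alpha FDR level for sign labels.
#' @param mad_mult Outlier multiplier, see [correlate_with_marker()].
#' @return Tibble, one row per non-marker gene, with `p_adjusted` and
#'   `sign` columns added.
#' @export
correlate_panel <- function(counts, marker, alpha = 0.05, mad_mult = 5) {
  if (!marker %in% counts$gene)
    abort_input(paste0("marker '", marker, "' not found in counts"))
  mk <- counts[counts$gene == marker, c("cell_id", "count")]
  names(mk)[2] <- "marker_count"
  genes <- setdiff(unique(counts$gene), marker)
  res <- purrr::map_dfr(genes, function(g) {
    gg <- dplyr::inner_join(counts[counts$gene == g, c("cell_id", "count")],
                            mk, by = "cell_id")
    correlate_with_marker(gg$count, gg$marker_count, mad_mult = mad_mult,
                          gene = g, marker = marker)
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$sign <- ifelse(res$p_adjusted < alpha,
                     ifelse(res$pearson_r > 0, "positive", "negative"),
                     "none")
  res
}

#' Per-cell spot counts from a spot table
#'
#' Counts non-autofluorescent spots per cell and channel, including
#' zero-count rows for cells listed in `cells` that have no spots — cells
#' with zero molecules are real observations for abundance statistics.
#'
#' @param spots Spot tibble (`cell_id`, `channel`, optionally
#'   `is_autofluorescent`).
#' @param cells Optional cell metadata (`cell_id`) forcing zero rows.
#' @return Tibble `cell_id`, `channel`, `count`.
#' @export
spot_counts <- function(spots, cells = NULL) {
  if (!is.null(spots$is_autofluorescent))
    spots <- spots[!spots$is_autofluorescent, ]
  channels <- unique(spots$channel)
  if (length(channels) == 0) channels <- NA_character_
  ids <- if (!is.null(cells)) cells$cell_id else unique(spots$cell_id)
  grid <- tidyr::expand_grid(cell_id = ids, channel = channels)
  tallied <- spots %>%
    group_by(.data$cell_id, .data$channel) %>%
    summarise(count = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(grid, tallied, by = c("cell_id", "channel"))
  out$count[is.na(out$count)] <- 0L
  out
}
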