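#' Pipeline configuration
#'
#' Collects every stage's parameters for [run_pipeline()]. Accepts either
#' explicit arguments or a YAML file via [read_pipeline_config()].
#'
#' @param input_dir Directory holding an experiment bundle
#'   (see [write_experiment()]); alternatively pass a `fish_experiment` to
#'   [run_pipeline()] directly.
#' @param out_dir Output directory for stage CSVs and the run manifest.
#' @param channels RNA channels to quantify (`NULL` = all non-DAPI/GFP).
#' @param detect A [detect_params()] list.
#' @param coloc `list(coarse =, fine =, z_window =)` matching windows.
#' @param localization `list(min_molecules =, radius =)` foci parameters and
#'   optional class-rule overrides (`nuclear_hi`, `nuclear_lo`,
#'   `min_count_class5`).
#' @param alpha Significance level for the validation stage.
#' @param seed Seed recorded in the run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            channels = NULL,
                            detect = detect_params(),
                            coloc = list(coarse = 4, fine = 2, z_window = 1),
                            localization = list(min_molecules = 5, radius = 3),
                            alpha = 0.05, seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 channels = channels, detect = detect, coloc = coloc,
                 localization = localization, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), c("input_dir", "out_dir", "channels",
                                   "alpha", "seed")))
    cfg[[nm]] <- y[[nm]]
  if (!is.null(y$detect))
    cfg$detect <- do.call(detect_params, y$detect)
  for (nm in c("coloc", "localization"))
    if (!is.null(y[[nm]])) cfg[[nm]] <- modifyList(cfg[[nm]], y[[nm]])
  cfg
}

#' Run the full quantification pipeline
#'
#' detect -> localize -> stats on one experiment: spot detection with
#' plateau thresholds and autofluorescence exclusion, per-gene-cell-type
#' localization summary (class I-V), and per-cell count statistics. When the
#' experiment carries a dual-label (`even`/`odd`) channel pair, the two-color
#' probe-set validation stage runs as well. Results are returned as a bundle
#' and, when `config$out_dir` is set, written as CSVs together with a JSON
#' run manifest (config, seed, package version), so a rerun on identical
#' inputs reproduces identical files.
#'
#' @param experiment A `fish_experiment`, or `NULL` to load
#'   `config$input_dir`.
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `spots`, `counts`, `status`,
#'   `localization` (glance tibble per channel), `summaries` (count
#'   statistics per channel), `validation` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(experiment = NULL, config = pipeline_config()) {
  if (is.null(experiment)) {
    if (is.null(config$input_dir)) abort_input("no experiment and no input_dir")
    experiment <- read_experiment(config$input_dir)
  }
  if (is.null(experiment$stacks$dapi) && is.null(experiment$nucleus_labels))
    abort_input("localization stage requires a DAPI-derived nucleus mask")

  spots <- detect_spots(experiment, channels = config$channels,
                        params = config$detect)
  status <- attr(spots, "status")
  counts <- spot_counts(spots, experiment$cells)

  channels <- unique(counts$channel)
  localization <- purrr::map_dfr(channels, function(ch) {
    sp <- spots[spots$channel == ch, ]
    res <- tryCatch(
      summarize_localization(
        sp, cells = experiment$cells, gene = ch,
        cell_type = unique(experiment$cells$cell_type)[1] %||% NA_character_,
        min_molecules = config$localization$min_molecules,
        radius = config$localization$radius),
      lincfish_no_expression = function(e) NULL)
    if (is.null(res)) return(NULL)
    glance(res)
  })

  summaries <- counts %>%
    group_by(.data$channel) %>%
    summarise(res = list(summarize_counts(.data$count, gene = .data$channel[1])),
              .groups = "drop") %>%
    tidyr::unnest("res") %>%
    select(-"gene")

  validation <- NULL
  if (all(c("even", "odd") %in% channels)) {
    wide <- tidyr::pivot_wider(counts, names_from = "channel",
                               values_from = "count")
    m <- mean(wide$even + wide$odd) / 2
    cc <- colocalized_counts(spots[spots$channel == "even", ],
                             spots[spots$channel == "odd", ],
                             x_select = selection_count(m),
                             coarse = config$coloc$coarse,
                             fine = config$coloc$fine,
                             z_window = config$coloc$z_window)
    validation <- list(per_cell = cc,
                       m_single_proxy = m,
                       x_select = selection_count(m))
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lincfish")),
    channels = channels,
    detect = unclass(config$detect),
    coloc = config$coloc,
    localization = config$localization,
    alpha = config$alpha)

  result <- structure(list(spots = spots, counts = counts, status = status,
                           localization = localization,
                           summaries = summaries, validation = validation,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- result$spots
  attr(sp, "threshold_curves") <- NULL
  attr(sp, "status") <- NULL
  attr(sp, "gfp_spots") <- NULL
  readr::write_csv(sp, file.path(out_dir, "spots.csv"))
  readr::write_csv(result$counts, file.path(out_dir, "counts.csv"))
  readr::write_csv(result$status, file.path(out_dir, "detect_status.csv"))
  if (nrow(result$localization) > 0)
    readr::write_csv(result$localization,
                     file.path(out_dir, "localization.csv"))
  readr::write_csv(select(result$summaries, -"histogram"),
                   file.path(out_dir, "count_summaries.csv"))
  curves <- attr(result$spots, "threshold_curves")
  curves <- purrr::imap(purrr::keep(curves, ~ !is.null(.x)),
                        ~ mutate(tidy(.x), channel = .y))
  if (length(curves) > 0)
    readr::write_csv(dplyr::bind_rows(curves),
                     file.path(out_dir, "threshold_curves.csv"))
  if (!is.null(result$validation))
    readr::write_csv(result$validation$per_cell,
                     file.path(out_dir, "validation_counts.csv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$spots), "spots in",
      paste(unique(x$counts$channel), collapse = ", "), "\n")
  print(x$summaries[, setdiff(names(x$summaries), "histogram")])
  invisible(x)
}
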