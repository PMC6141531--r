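## End-to-end orchestration: simulate a cohort to disk, quantify slides,
## classify the cohort. One JSON-serializable config, one seed.

#' Pipeline configuration
#'
#' @param seed Integer master seed; every random draw flows from it.
#' @param markers Which stains to simulate/quantify (subset of
#'   `c("pdl1", "cd8")`).
#' @param n_per_subtype Cases per subtype (order EBVpos, MSIH, MSS).
#' @param corr_mrna Fraction-mRNA coupling for [sample_cohort()].
#' @param slide A [slide_spec()].
#' @param seg A [seg_params()].
#' @param gates A [gating_thresholds()]; default calibrated from the
#'   slide spec via [calibrate_gates()].
#' @param cutoff_mode `"maxstat"` (select cutoffs from survival) or
#'   `"fixed"` (use `cutoffs`); exactly one mode is active.
#' @param cutoffs A [tme_cutoffs()]; required when
#'   `cutoff_mode = "fixed"`, forbidden otherwise.
#' @param maxstat_eps Quantile margin for cutpoint candidates.
#' @param maxstat_endpoint `"OS"` or `"DFS"`: outcome driving maxstat.
#' @param image_format `"png"` or `"tiff"` for simulated slides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            markers = c("pdl1", "cd8"),
                            n_per_subtype = c(40, 76, 125),
                            corr_mrna = 0.7,
                            slide = slide_spec(),
                            seg = seg_params(),
                            gates = NULL,
                            cutoff_mode = c("maxstat", "fixed"),
                            cutoffs = NULL,
                            maxstat_eps = 0.1,
                            maxstat_endpoint = c("OS", "DFS"),
                            image_format = c("png", "tiff")) {
  cutoff_mode <- match.arg(cutoff_mode)
  maxstat_endpoint <- match.arg(maxstat_endpoint)
  image_format <- match.arg(image_format)
  markers <- match.arg(markers, several.ok = TRUE)
  if (cutoff_mode == "fixed" && is.null(cutoffs))
    stop("fixed cutoff mode requires `cutoffs`")
  if (cutoff_mode == "maxstat" && !is.null(cutoffs))
    stop("`cutoffs` given but cutoff_mode is 'maxstat'; choose one mode")
  if (is.null(gates)) gates <- calibrate_gates(slide, seg)
  structure(list(
    seed = as.integer(seed), markers = markers,
    n_per_subtype = n_per_subtype, corr_mrna = corr_mrna,
    slide = slide, seg = seg, gates = gates,
    cutoff_mode = cutoff_mode, cutoffs = cutoffs,
    maxstat_eps = maxstat_eps, maxstat_endpoint = maxstat_endpoint,
    image_format = image_format
  ), class = "pipeline_config")
}

.config_json <- function(config) {
  x <- lapply(config, function(el) if (is.list(el)) unclass(el) else el)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

## Derive a per-case, per-marker sub-seed from the master seed (kept
## inside 32-bit integer range).
.case_seed <- function(seed, i, marker) {
  (as.integer(seed) * 1009L + i * 7L +
     if (marker == "pdl1") 0L else 3L) %% 2147483587L + 1L
}

#' Simulate a synthetic cohort to a directory
#'
#' Writes one slide image per case and marker, a 16-bit truth label map,
#' a per-nucleus truth table, the cohort table and a manifest JSON
#' recording the full configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the cohort data.frame.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("simulate: cannot create output directory")
  basis <- stain_basis()
  cohort <- sample_cohort(n_per_subtype = config$n_per_subtype,
                          corr_mrna = config$corr_mrna, seed = config$seed)
  ext <- if (config$image_format == "png") "png" else "tif"
  for (i in seq_len(nrow(cohort))) {
    for (marker in config$markers) {
      sl <- render_slide(cohort[i, ], config$slide, basis, marker = marker,
                         seed = .case_seed(config$seed, i, marker))
      stem <- file.path(out_dir, sprintf("%s_%s", cohort$case_id[i], marker))
      write_rgb(sl$rgb, sprintf("%s.%s", stem, ext))
      write_label_map(sl$labels, sprintf("%s_truth.tif", stem))
      utils::write.csv(sl$cells, sprintf("%s_truth_cells.csv", stem),
                       row.names = FALSE)
    }
  }
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  writeLines(.config_json(config), file.path(out_dir, "manifest.json"))
  invisible(cohort)
}

#' Quantify simulated or real slides
#'
#' Runs the measurement chain of [measure_slide()] on every
#' `<case>_<marker>` image under `sim_dir` and writes one summary CSV
#' per marker (`quant_<marker>.csv`: `case_id`, `n_total`, `n_positive`,
#' `ratio`).
#'
#' @param config A [pipeline_config()].
#' @param sim_dir Directory produced by [run_simulate()] (or following
#'   its naming scheme).
#' @param out_dir Where to write the quantification CSVs; default
#'   `sim_dir`.
#' @return Invisibly, a named list of per-marker quantification
#'   data.frames.
#' @export
run_quantify <- function(config, sim_dir, out_dir = sim_dir) {
  basis <- stain_basis()
  cohort <- utils::read.csv(file.path(sim_dir, "cohort.csv"))
  ext <- if (config$image_format == "png") "png" else "tif"
  out <- list()
  n_failed <- 0L
  for (marker in config$markers) {
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      path <- file.path(sim_dir, sprintf("%s_%s.%s", cohort$case_id[i],
                                         marker, ext))
      rows[[i]] <- tryCatch(
        measure_slide(read_rgb(path), basis, config$seg, config$gates,
                      case_id = cohort$case_id[i])$quant,
        error = function(e) {
          message(sprintf("quantify: skipping %s (%s)", path,
                          conditionMessage(e)))
          n_failed <<- n_failed + 1L
          NULL
        })
    }
    q <- do.call(rbind, rows)
    utils::write.csv(q, file.path(out_dir, sprintf("quant_%s.csv", marker)),
                     row.names = FALSE)
    out[[marker]] <- q
  }
  if (n_failed > 0)
    stop(sprintf("quantify: %d slides could not be processed", n_failed))
  invisible(out)
}

#' Classify a quantified cohort and compute cohort statistics
#'
#' Joins the per-marker ratios onto the cohort table, selects cutoffs
#' (maxstat on the configured endpoint, or the fixed override), assigns
#' TME types and writes the statistics bundle: typed cohort CSV, quadrant
#' counts/percentages JSON, ratio-mRNA correlations and the type I vs IV
#' Kaplan-Meier comparison.
#'
#' @param config A [pipeline_config()].
#' @param sim_dir Directory holding `cohort.csv` and `quant_<marker>.csv`.
#' @param out_dir Where to write outputs; default `sim_dir`.
#' @return Invisibly, a list: `cutoffs`, `classification` (see
#'   [classify_cohort()]), `correlations`, `km` (or `NULL` when a type
#'   is unrepresented).
#' @export
run_classify <- function(config, sim_dir, out_dir = sim_dir) {
  cohort <- utils::read.csv(file.path(sim_dir, "cohort.csv"))
  for (marker in config$markers) {
    q <- utils::read.csv(file.path(sim_dir, sprintf("quant_%s.csv", marker)))
    cohort[[paste0(marker, "_ratio")]] <-
      q$ratio[match(cohort$case_id, q$case_id)]
  }
  if (!all(c("pdl1_ratio", "cd8_ratio") %in% names(cohort)))
    stop("classification needs both pdl1 and cd8 ratios")
  cutoffs <- if (config$cutoff_mode == "fixed") {
    config$cutoffs
  } else {
    if (!all(c("os_time", "os_event", "dfs_time", "dfs_event") %in%
             names(cohort)))
      stop("maxstat mode requires survival columns in the cohort table")
    tcol <- if (config$maxstat_endpoint == "OS") "os_time" else "dfs_time"
    ecol <- if (config$maxstat_endpoint == "OS") "os_event" else "dfs_event"
    tme_cutoffs(
      maxstat_cutpoint(cohort$pdl1_ratio, cohort[[tcol]], cohort[[ecol]],
                       eps = config$maxstat_eps)$cutoff,
      maxstat_cutpoint(cohort$cd8_ratio, cohort[[tcol]], cohort[[ecol]],
                       eps = config$maxstat_eps)$cutoff
    )
  }
  cls <- classify_cohort(cohort, cutoffs)
  utils::write.csv(cls$cases, file.path(out_dir, "typed_cohort.csv"),
                   row.names = FALSE)
  correlations <- lapply(
    stats::setNames(nm = intersect(config$markers, c("pdl1", "cd8"))),
    function(m) {
      if (!paste0("mrna_", m) %in% names(cohort)) return(NULL)
      ratio_mrna_correlation(cls$cases, m)
    })
  km <- if (all(c("I", "IV") %in% cls$cases$tme_type) &&
            "os_time" %in% names(cohort)) {
    km_logrank_by_type(cls$cases, "OS", "I", "IV")
  } else NULL
  summary <- list(
    cutoff_mode = config$cutoff_mode,
    cutoffs = unclass(cutoffs),
    counts = as.list(cls$counts),
    percentages = as.list(cls$percentages),
    pdl1_high = cls$pdl1_high,
    cd8_high = cls$cd8_high,
    correlations = lapply(correlations, function(x)
      if (is.null(x)) NULL else x[c("r", "n_used")]),
    km_I_vs_IV_p = if (is.null(km)) NULL else km$p_value
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "classification.json"))
  if (!is.null(km))
    utils::write.csv(km$curves, file.path(out_dir, "km_I_vs_IV.csv"),
                     row.names = FALSE)
  invisible(list(cutoffs = cutoffs, classification = cls,
                 correlations = correlations, km = km))
}
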