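## Per-cell feature extraction, bivariate (area, DAB-OD) gating and the
## positive-cell ratio: positive cells per total segmented cells.

#' Gating thresholds for positive-cell calls
#'
#' A cell is positive iff its mean DAB OD strictly exceeds `dab_od_min`
#' and its area lies inside `[area_min, area_max]` (inclusive). One fixed
#' set of thresholds is applied across all samples.
#'
#' @param dab_od_min Minimum mean DAB OD (exclusive), OD units.
#' @param area_min,area_max Inclusive area window, px^2.
#' @return A `gating_thresholds` list.
#' @export
gating_thresholds <- function(dab_od_min = 0.3, area_min = 4,
                              area_max = 400) {
  if (dab_od_min < 0) stop("dab_od_min must be >= 0")
  if (area_min >= area_max) stop("need area_min < area_max")
  structure(list(dab_od_min = dab_od_min, area_min = area_min,
                 area_max = area_max), class = "gating_thresholds")
}

#' Calibrate default gates from the slide forward model
#'
#' The DAB cut sits at the midpoint between the background DAB OD (zero)
#' and the deposited per-nucleus DAB level; the area window spans from
#' the segmentation minimum to a generous multiple of the mean nucleus
#' area, so merged doublets stay gateable.
#'
#' @param spec A [slide_spec()].
#' @param seg A [seg_params()].
#' @return A [gating_thresholds()].
#' @export
calibrate_gates <- function(spec = slide_spec(), seg = seg_params()) {
  mean_area <- pi * spec$nucleus_radius_mean^2
  gating_thresholds(
    dab_od_min = spec$dab_od_level / 2,
    area_min = seg$min_area,
    area_max = max(seg$max_area, ceiling(8 * mean_area))
  )
}

#' Extract per-cell features from a label map and stain channels
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param dab,hema Stain concentration matrices (OD units), same
#'   dimensions as `labels`.
#' @return data.frame with one row per label: `cell_id`, `area` (px^2),
#'   `mean_dab_od`, `mean_hema_od` (arithmetic means over the region),
#'   `centroid_row`, `centroid_col` (0-based pixel coordinates),
#'   `is_positive` (NA until gated).
#' @export
extract_cells <- function(labels, dab, hema) {
  if (!all(dim(labels) == dim(dab)) || !all(dim(labels) == dim(hema)))
    stop("label map and stain channels must share dimensions")
  n <- max(labels)
  if (n == 0L)
    return(data.frame(cell_id = integer(0), area = numeric(0),
                      mean_dab_od = numeric(0), mean_hema_od = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      is_positive = logical(0)))
  nz <- labels > 0L
  id <- labels[nz]
  area <- tabulate(id, nbins = n)
  rows0 <- (row(labels) - 1L)[nz]
  cols0 <- (col(labels) - 1L)[nz]
  sum_by <- function(x) as.numeric(rowsum(x, id, reorder = TRUE))
  data.frame(
    cell_id = seq_len(n),
    area = area,
    mean_dab_od = sum_by(dab[nz]) / area,
    mean_hema_od = sum_by(hema[nz]) / area,
    centroid_row = sum_by(rows0) / area,
    centroid_col = sum_by(cols0) / area,
    is_positive = NA
  )
}

#' Gate cells as positive or negative
#'
#' @param cells data.frame from [extract_cells()].
#' @param thresholds A [gating_thresholds()].
#' @return `cells` with `is_positive` set for every row (strict `>` on
#'   intensity, inclusive area window).
#' @export
gate_cells <- function(cells, thresholds = gating_thresholds()) {
  if (!inherits(thresholds, "gating_thresholds"))
    stop("`thresholds` must come from gating_thresholds()")
  cells$is_positive <- cells$mean_dab_od > thresholds$dab_od_min &
    cells$area >= thresholds$area_min & cells$area <= thresholds$area_max
  cells
}

#' Scatter export of gated cells
#'
#' @param cells Gated cell table.
#' @return data.frame `(area, mean_dab_od, is_positive)` suitable for a
#'   bivariate flow-cytometry-like scatter plot.
#' @export
cell_scatter <- function(cells) {
  cells[, c("area", "mean_dab_od", "is_positive")]
}

#' Positive-cell ratio for one case
#'
#' The ratio is the absolute number of positive cells divided by the
#' total number of segmented cells.
#'
#' @param cells Gated cell table (every `is_positive` set).
#' @param case_id Optional case identifier carried into the result.
#' @return data.frame row: `case_id`, `n_total`, `n_positive`, `ratio`
#'   (`NA` with `undefined = TRUE` when no cells were segmented).
#' @export
case_ratio <- function(cells, case_id = NA_character_) {
  if (nrow(cells) > 0 && anyNA(cells$is_positive))
    stop("ungated cells present; run gate_cells() first")
  n_total <- nrow(cells)
  n_positive <- sum(cells$is_positive)
  data.frame(
    case_id = case_id,
    n_total = n_total,
    n_positive = n_positive,
    ratio = if (n_total > 0) n_positive / n_total else NA_real_,
    undefined = n_total == 0
  )
}

#' Measure one RGB slide end to end
#'
#' Convenience chain used by the pipeline: RGB -> optical density ->
#' stain unmixing -> nuclei segmentation on the hematoxylin channel ->
#' per-cell features -> gating -> positive-cell ratio.
#'
#' @param rgb RGB array `h x w x 3` in \[0, 255\].
#' @param basis A [stain_basis()].
#' @param seg A [seg_params()].
#' @param gates A [gating_thresholds()].
#' @param case_id Case identifier for the summary row.
#' @return List with `cells` (gated table), `labels` (label matrix) and
#'   `quant` (the [case_ratio()] row).
#' @export
measure_slide <- function(rgb, basis = stain_basis(), seg = seg_params(),
                          gates = gating_thresholds(),
                          case_id = NA_character_) {
  conc <- unmix(rgb_to_od(rgb), basis)
  labels <- segment_nuclei(conc[, , "hema"], seg)
  cells <- gate_cells(extract_cells(labels, conc[, , "dab"],
                                    conc[, , "hema"]), gates)
  list(cells = cells, labels = labels,
       quant = case_ratio(cells, case_id = case_id))
}
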