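## Nuclei segmentation on the hematoxylin concentration channel:
## Gaussian smoothing -> threshold (Otsu or fixed) -> hole filling ->
## area filtering -> optional distance-transform watershed split.
## Image morphology is delegated to EBImage.

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing SD in pixels (0 disables).
#' @param threshold_method `"otsu"` (on the smoothed channel) or `"fixed"`.
#' @param fixed_threshold OD threshold used when `threshold_method = "fixed"`.
#' @param min_area,max_area Retained region area bounds in px^2.
#' @param fill_holes Fill enclosed background holes before filtering.
#' @param split_touching Split touching regions by a watershed on the
#'   distance transform.
#' @param peak_min_distance Minimum separation (px) between watershed
#'   seed maxima; maps to the watershed neighborhood radius.
#' @return A `seg_params` list.
#' @export
seg_params <- function(smooth_sigma = 1, threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 0.3, min_area = 4, max_area = 400,
                       fill_holes = TRUE, split_touching = TRUE,
                       peak_min_distance = 3) {
  threshold_method <- match.arg(threshold_method)
  if (min_area <= 0 || min_area >= max_area)
    stop("need 0 < min_area < max_area")
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (peak_min_distance < 1) stop("peak_min_distance must be >= 1")
  structure(list(
    smooth_sigma = smooth_sigma, threshold_method = threshold_method,
    fixed_threshold = fixed_threshold, min_area = min_area,
    max_area = max_area, fill_holes = fill_holes,
    split_touching = split_touching, peak_min_distance = peak_min_distance
  ), class = "seg_params")
}

## Relabel a label matrix to consecutive 1..N in row-major order of each
## region's first pixel, for deterministic, convention-stable output.
.relabel <- function(lab) {
  v <- as.integer(t(lab))
  ids <- unique(v[v > 0L])
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- lut[as.integer(lab[nz])]
  out
}

.area_filter <- function(lab, min_area, max_area) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop <- which(areas < min_area | areas > max_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Segment nuclei from a hematoxylin OD channel
#'
#' @param hema Nonnegative single-channel matrix (hematoxylin
#'   concentration, OD units).
#' @param params A [seg_params()].
#' @return Integer label matrix, background 0, labels consecutive 1..N
#'   (8-connected regions); an all-background channel yields N = 0.
#' @export
segment_nuclei <- function(hema, params = seg_params()) {
  if (!is.matrix(hema)) {
    if (length(dim(hema)) == 3L) stop("expected a single-channel matrix")
    hema <- as.matrix(hema)
  }
  if (any(hema < 0)) stop("hematoxylin channel must be nonnegative")
  img <- hema
  if (params$smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = params$smooth_sigma))
  thr <- if (params$threshold_method == "fixed") {
    params$fixed_threshold
  } else {
    if (max(img) <= 0) Inf else
      EBImage::otsu(EBImage::Image(img / max(img)), levels = 256L) * max(img)
  }
  mask <- img > thr
  if (!any(mask)) return(matrix(0L, nrow(hema), ncol(hema)))
  if (params$fill_holes)
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(as.matrix(lab)), nrow(hema))
  lab <- .area_filter(lab, params$min_area, params$max_area)
  if (params$split_touching && max(lab) > 0L) {
    m <- lab > 0L
    dm <- EBImage::distmap(EBImage::Image(m))
    ws <- EBImage::watershed(dm, tolerance = 1,
                             ext = as.integer(params$peak_min_distance))
    lab <- matrix(as.integer(as.matrix(ws)), nrow(hema))
  }
  .relabel(lab)
}

#' Match a predicted label map against ground truth
#'
#' Each predicted region is assigned to the truth region of maximal pixel
#' overlap and vice versa. A mutual-best pair is a true positive; a truth
#' region claimed by two or more predictions is a split; a prediction
#' claimed by two or more truth regions is a merge; a truth region to
#' which no prediction is assigned is a miss; a prediction whose only
#' overlap is background is spurious.
#'
#' @param pred,truth Integer label matrices of identical dimensions.
#' @return List with counts `n_pred`, `n_truth`, `tp`, `splits`,
#'   `merges`, `misses`, `spurious` and the pairwise `assignment`
#'   data.frame (`pred`, `truth`, `overlap`).
#' @export
match_to_truth <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("predicted and truth label maps must share dimensions")
  n_pred <- max(pred); n_truth <- max(truth)
  nz <- pred > 0L | truth > 0L
  ov <- table(pred = factor(pred[nz], levels = 0:n_pred),
              truth = factor(truth[nz], levels = 0:n_truth))
  ov <- unclass(ov)  # (n_pred+1) x (n_truth+1), row/col 1 = background
  pred_best <- truth_best <- integer(0)
  if (n_pred > 0) {
    pm <- ov[-1, , drop = FALSE]
    pm[, 1] <- 0  # ignore background when looking for a partner
    pred_best <- apply(pm, 1, function(r) if (max(r) == 0) 0L else
      which.max(r) - 1L)  # truth id (0 = none)
  }
  if (n_truth > 0) {
    tm <- ov[, -1, drop = FALSE]
    tm[1, ] <- 0
    truth_best <- apply(tm, 2, function(col) if (max(col) == 0) 0L else
      which.max(col) - 1L)  # pred id (0 = none)
  }
  claimed <- tabulate(pred_best[pred_best > 0], nbins = max(n_truth, 1))
  claimed_by_truth <- tabulate(truth_best[truth_best > 0],
                               nbins = max(n_pred, 1))
  tp <- sum(vapply(seq_len(n_pred), function(p) {
    t <- pred_best[p]
    t > 0 && truth_best[t] == p
  }, logical(1)))
  assignment <- if (n_pred > 0) data.frame(
    pred = seq_len(n_pred), truth = pred_best,
    overlap = vapply(seq_len(n_pred), function(p)
      if (pred_best[p] > 0) ov[p + 1L, pred_best[p] + 1L] else 0L,
      numeric(1))
  ) else data.frame(pred = integer(0), truth = integer(0),
                    overlap = numeric(0))
  list(
    n_pred = n_pred, n_truth = n_truth,
    tp = tp,
    splits = if (n_truth > 0) sum(claimed >= 2) else 0L,
    merges = if (n_pred > 0) sum(claimed_by_truth >= 2) else 0L,
    misses = if (n_truth > 0) sum(claimed == 0) else 0L,
    spurious = if (n_pred > 0) sum(pred_best == 0) else 0L,
    assignment = assignment
  )
}
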