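#' Asymmetry index of a label between the two SPBs of a spindle
#'
#' `|a - b| / (a + b)`: 0 for perfect symmetry, 1 when one pole carries all
#' the label. The inputs are the (optionally reference-normalized) label
#' intensities at each spindle pole body.
#'
#' @param a,b non-negative intensities, `a + b > 0`. Vectorized.
#' @return numeric in `[0, 1]`.
#' @export
asymmetry_index <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("intensities must be non-negative")
  if (any(a + b == 0)) stop("asymmetry index undefined when a + b == 0")
  abs(a - b) / (a + b)
}

#' Inner:outer plaque intensity ratio
#'
#' @param ip,op non-negative plaque intensities. `op` must be positive; a
#'   zero outer-plaque intensity has no finite ratio and is flagged by the
#'   caller instead.
#' @return `ip / op`.
#' @export
ip_op_ratio <- function(ip, op) {
  if (any(ip < 0) || any(op < 0)) stop("intensities must be non-negative")
  if (any(op == 0))
    stop("outer-plaque intensity is zero: ratio undefined (one-sided label)")
  ip / op
}

#' Classify the asymmetry mode of a spindle
#'
#' Fold-change classes over the outer-plaque label intensities of the two
#' SPBs: `one_pole` when the dimmer pole is below the detection floor;
#' otherwise, with `r = max/min`: `strongly_asymmetric` for at least an
#' 8-fold difference, `symmetric` for less than a 1.3-fold difference,
#' `asymmetric` in between. Boundaries are applied as `r >= 8` and
#' `r < 1.3` so the classes are exhaustive and disjoint.
#'
#' @param i_old,i_new label intensities at the two poles (>= 0).
#' @param detect_floor detection floor; both intensities below it is an
#'   error (no label to classify).
#' @return one of `"one_pole"`, `"strongly_asymmetric"`, `"asymmetric"`,
#'   `"symmetric"`.
#' @export
classify_mode <- function(i_old, i_new, detect_floor = 0) {
  stopifnot(i_old >= 0, i_new >= 0, detect_floor >= 0)
  lo <- min(i_old, i_new); hi <- max(i_old, i_new)
  if (hi < detect_floor)
    stop("no label detected at either pole (both below the floor)")
  if (lo < detect_floor) return("one_pole")
  r <- hi / lo
  if (r >= 8) "strongly_asymmetric"
  else if (r < 1.3) "symmetric"
  else "asymmetric"
}

#' Spindle-pathway stage from the SPB inter-distance
#'
#' Fixed boundaries along the spindle pathway: `< 0.35` um unseparated SPBs,
#' `0.35 <= d < 1` um short spindles, `1 <= d <= 2.5` um spindles, `> 2.5`
#' um elongated spindles. Interior boundaries are lower-inclusive so every
#' distance receives exactly one label.
#'
#' @param d inter-distance, micrometres (>= 0). Vectorized.
#' @return character: `"unseparated"`, `"spindle_lt_1um"`,
#'   `"spindle_1_2p5um"` or `"elongated_gt_2p5um"`.
#' @export
stage_by_distance <- function(d) {
  if (any(d < 0)) stop("inter-distance must be non-negative")
  ifelse(d < 0.35, "unseparated",
  ifelse(d < 1,    "spindle_lt_1um",
  ifelse(d <= 2.5, "spindle_1_2p5um", "elongated_gt_2p5um")))
}

#' Flag a top-view SPB
#'
#' An SPB presented in top view has its plaque axis along the optical axis,
#' so inner- and outer-plaque signals overlap laterally and cannot be
#' resolved; such SPBs are excluded from plaque-resolved analysis. The flag
#' is raised when the lateral (xy) distance between the two plaque-
#' associated fits is below `overlap_threshold` while the axial separation
#' dominates.
#'
#' @param fit_inner,fit_outer `spot_fit`s of the inner- and outer-plaque
#'   signals in a common coordinate frame.
#' @param overlap_threshold lateral overlap threshold, nm; defaults to twice
#'   the mean fitted lateral sigma.
#' @return logical.
#' @export
is_top_view <- function(fit_inner, fit_outer, overlap_threshold = NULL) {
  d <- fit_outer$center - fit_inner$center
  lateral <- sqrt(d[1]^2 + d[2]^2)
  axial <- abs(d[3])
  if (is.null(overlap_threshold))
    overlap_threshold <- 2 * mean(c(fit_inner$sigma_xy, fit_outer$sigma_xy))
  lateral < overlap_threshold && axial > lateral
}

#' Descriptive centile summary with median notch
#'
#' The five boxplot centiles (5th, 25th, 50th, 75th, 95th; linear
#' interpolation of order statistics) plus the 95% confidence notch of the
#' median, `median +/- 1.58 * IQR / sqrt(n)`.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `centiles` (named length-5 vector), `notch_low`,
#'   `notch_high`, `n`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize")
  cts <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         type = 7, names = FALSE)
  names(cts) <- c("p5", "p25", "p50", "p75", "p95")
  iqr <- cts["p75"] - cts["p25"]
  half <- 1.58 * iqr / sqrt(length(values))
  list(centiles = cts,
       notch_low = unname(cts["p50"] - half),
       notch_high = unname(cts["p50"] + half),
       n = length(values))
}
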