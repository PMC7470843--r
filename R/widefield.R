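#' Maximum-intensity projection of a wide-field z-stack
#'
#' Per-pixel, per-channel maximum over z of a short wide-field stack
#' (typically five planes 0.8 um apart, 2x2 binned), the projection on
#' which wide-field quantitation is performed.
#'
#' @param stack5 an `image_stack` with >= 1 z-plane.
#' @return a `projection_2d`.
#' @export
project_stack <- function(stack5) max_project(stack5)

#' Integrated window intensity with background subtraction
#'
#' Sums a `side x side` pixel window centred on an SPB and subtracts
#' `side^2 * background_per_px` (cell background per pixel, per channel).
#'
#' @param image2d matrix (one channel of a projection).
#' @param center_px length-2 integer pixel coordinates of the window centre.
#' @param side odd window side, pixels (default 7).
#' @param background_per_px cell background level per pixel.
#' @return a `window_measurement`: `center_px`, `window_side`, `raw_sum`,
#'   `background_per_px`, `corrected`.
#' @export
window_intensity <- function(image2d, center_px, side = 7,
                             background_per_px = 0) {
  if (side %% 2 == 0) stop("window side must be odd")
  h <- (side - 1) / 2
  d <- dim(image2d)
  xs <- (center_px[1] - h):(center_px[1] + h)
  ys <- (center_px[2] - h):(center_px[2] + h)
  if (min(xs) < 1 || max(xs) > d[1] || min(ys) < 1 || max(ys) > d[2])
    stop("window clipped by the image border")
  raw <- sum(image2d[xs, ys])
  structure(list(center_px = as.integer(center_px),
                 window_side = as.integer(side), raw_sum = raw,
                 background_per_px = background_per_px,
                 corrected = raw - side^2 * background_per_px),
            class = "window_measurement")
}

#' Cell background from an annulus around the measurement window
#'
#' Median of the pixels in a square annulus starting just outside the
#' window and extending `annulus_width` pixels; the automatic fallback when
#' no cytoplasmic ROI is drawn by hand.
#'
#' @param image2d matrix.
#' @param center_px window centre, pixels.
#' @param side window side, pixels.
#' @param annulus_width annulus thickness, pixels.
#' @return median background per pixel.
#' @export
estimate_background_annulus <- function(image2d, center_px, side = 7,
                                        annulus_width = 15) {
  h_in <- (side - 1) / 2
  h_out <- h_in + annulus_width
  d <- dim(image2d)
  xs <- max(1, center_px[1] - h_out):min(d[1], center_px[1] + h_out)
  ys <- max(1, center_px[2] - h_out):min(d[2], center_px[2] + h_out)
  inside_win <- outer(abs(xs - center_px[1]) <= h_in,
                      abs(ys - center_px[2]) <= h_in, `&`)
  ring <- image2d[xs, ys][!inside_win]
  if (length(ring) == 0) stop("no annulus pixels available")
  stats::median(ring)
}

#' Locate an SPB centre in 2D near a seed
#'
#' Maximum of the reference channel within a square neighbourhood of the
#' seed, emulating manual ROI placement on the projection.
#'
#' @param image2d reference-channel matrix.
#' @param seed_px approximate pixel position.
#' @param search_radius half-side of the search square, pixels.
#' @return integer pixel coordinates of the local maximum.
#' @export
locate_spb_2d <- function(image2d, seed_px, search_radius = 5) {
  d <- dim(image2d)
  xs <- max(1, seed_px[1] - search_radius):min(d[1], seed_px[1] + search_radius)
  ys <- max(1, seed_px[2] - search_radius):min(d[2], seed_px[2] + search_radius)
  sub <- image2d[xs, ys, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  c(xs[k[1]], ys[k[2]])
}

#' Reference-normalized label level at one SPB
#'
#' Query label (e.g. Spc72) divided by reference label (e.g. Spc42), both
#' background-corrected; the relative value feeding the wide-field
#' asymmetry index. Normalizing by the reference cancels multiplicative
#' illumination and focus differences between cells.
#'
#' @param query,reference `window_measurement`s for the two channels at the
#'   same SPB.
#' @return dimensionless ratio.
#' @export
relative_label <- function(query, reference) {
  if (reference$corrected <= 0)
    stop("non-positive reference intensity: cannot normalize")
  query$corrected / reference$corrected
}
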