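#' Intensity profile along an axis of a 2D projection
#'
#' Samples each channel along the segment from `axis_start` to `axis_end`
#' (nm, image-local) at one-pixel pitch. The value at each sample is the
#' mean over `width_px` parallel lines offset perpendicular to the axis by
#' whole pixel pitches, matching a linescan drawn at 1-, 3- or 5-px width.
#' In-plane sampling is bilinear.
#'
#' @param image a `projection_2d` (see [max_project()]) or a single matrix
#'   (then `voxel_xy` must be given).
#' @param axis_start,axis_end length-2 nm positions inside the image.
#' @param width_px odd linescan width in pixels (1, 3 or 5).
#' @param voxel_xy pixel pitch, nm (taken from the projection if absent).
#' @return a `line_profile`: `positions` (nm from `axis_start`), `values`
#'   (matrix, samples x channels), `width_px`, `normalization = "none"`.
#' @export
profile_line <- function(image, axis_start, axis_end, width_px = 3,
                         voxel_xy = NULL) {
  if (width_px %% 2 == 0 || !width_px %in% c(1, 3, 5))
    stop("width_px must be odd: 1, 3 or 5")
  if (is.matrix(image)) {
    if (is.null(voxel_xy)) stop("voxel_xy required for a bare matrix")
    mats <- list(ch1 = image)
  } else {
    mats <- image$pixels
    voxel_xy <- image$voxel_xy
  }
  d <- dim(mats[[1]])
  u <- axis_end - axis_start
  len <- sqrt(sum(u^2))
  if (len == 0) stop("zero-length linescan axis")
  u <- u / len
  perp <- c(-u[2], u[1])
  ends <- rbind(axis_start, axis_end)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * voxel_xy
  for (o in offs) {
    pts <- sweep(ends, 2, o * perp, `+`)
    idx <- pts / voxel_xy + 0.5
    if (any(idx < 1) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]))
      stop("linescan segment (with width offsets) outside image bounds")
  }
  positions <- seq(0, len, by = voxel_xy)
  values <- matrix(0, length(positions), length(mats),
                   dimnames = list(NULL, names(mats)))
  for (o in offs) {
    px <- axis_start[1] + positions * u[1] + o * perp[1]
    py <- axis_start[2] + positions * u[2] + o * perp[2]
    ix <- nm_to_index(px, voxel_xy)
    iy <- nm_to_index(py, voxel_xy)
    for (j in seq_along(mats))
      values[, j] <- values[, j] + bilinear(mats[[j]], ix, iy)
  }
  values <- values / width_px
  structure(list(positions = positions, values = values,
                 width_px = as.integer(width_px), normalization = "none"),
            class = "line_profile")
}

#' Normalize a line profile
#'
#' `internal`: per channel, map the minimum to 0 and the maximum to 1.
#' `reference`: divide by the per-channel maximum of a reference profile
#' (the convention used to express profiles relative to, e.g., the old-SPB
#' maximum of elongated spindles).
#'
#' @param profile a `line_profile`.
#' @param mode `"internal"` or `"reference"`.
#' @param reference_profile required for `mode = "reference"`.
#' @return the normalized `line_profile`.
#' @export
normalize_profile <- function(profile, mode = c("internal", "reference"),
                              reference_profile = NULL) {
  mode <- match.arg(mode)
  v <- profile$values
  if (mode == "internal") {
    for (j in seq_len(ncol(v))) {
      rng <- range(v[, j])
      if (diff(rng) == 0)
        stop("degenerate profile: constant intensity, cannot normalize")
      v[, j] <- (v[, j] - rng[1]) / (rng[2] - rng[1])
    }
  } else {
    if (is.null(reference_profile))
      stop("reference profile required for reference normalization")
    for (j in seq_len(ncol(v))) {
      jr <- if (ncol(reference_profile$values) == ncol(v)) j else 1L
      mx <- max(reference_profile$values[, jr])
      if (mx <= 0) stop("non-positive reference maximum")
      v[, j] <- v[, j] / mx
    }
  }
  profile$values <- v
  profile$normalization <- mode
  profile
}

# local maxima of a vector (plateaus count once, at their left edge)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

#' Detect and annotate plaque peaks in a line profile
#'
#' Local maxima above a robust noise floor (median + 3 MAD by default) are
#' assigned structural roles by their order along the axis, relative to the
#' axis midpoint (`center`):
#' \describe{
#'   \item{`single_spb`}{inner, outer (left to right on an IP-OP axis).}
#'   \item{`spindle`}{outer_old, inner_old | inner_new, outer_new; on each
#'     side of the midpoint the peak nearer the midpoint is the inner
#'     plaque. A side with one peak keeps its inner plaque and flags the
#'     outer as missing (the incompletely assembled new outer plaque).}
#'   \item{`spindle_poles`}{outer_old, outer_new; one peak per pole for an
#'     outer-plaque-only label.}
#'   \item{`side_by_side_bridge`}{outer_old (leftmost), bridge (nearest the
#'     midpoint), plus unassigned extra peaks.}
#' }
#' Peak height is the profile value at the maximum (no sub-sample fit).
#'
#' @param profile a `line_profile`.
#' @param expected_layout one of the layouts above.
#' @param channel column of the profile to analyze.
#' @param floor noise floor; default `median + 3 * mad`.
#' @param center axis position (nm) of the spindle midpoint; default the
#'   middle of the profile.
#' @return a `peak_set`: [tibble::tibble] with `role`, `position`, `height`,
#'   `found`; missing layout roles appear with `found = FALSE`.
#' @export
find_plaque_peaks <- function(profile,
                              expected_layout = c("spindle", "single_spb",
                                                  "spindle_poles",
                                                  "side_by_side_bridge"),
                              channel = 1, floor = NULL, center = NULL) {
  expected_layout <- match.arg(expected_layout)
  v <- profile$values[, channel]
  pos <- profile$positions
  if (is.null(floor))
    floor <- stats::median(v) + 3 * stats::mad(v)
  if (is.null(center)) center <- mean(range(pos))
  idx <- .local_maxima(v)
  idx <- idx[v[idx] > floor]
  p <- pos[idx]; h <- v[idx]
  res <- function(role, position, height, found = TRUE)
    data.frame(role = role, position = position, height = height,
               found = found, stringsAsFactors = FALSE)
  miss <- function(role) res(role, NA_real_, NA_real_, FALSE)
  out <- switch(expected_layout,
    single_spb = {
      roles <- c("inner", "outer")
      if (length(p) >= 2) {
        o <- order(p)[c(1, length(p))]
        rbind(res(roles[1], p[o[1]], h[o[1]]), res(roles[2], p[o[2]], h[o[2]]))
      } else if (length(p) == 1) {
        rbind(res("inner", p, h), miss("outer"))
      } else rbind(miss("inner"), miss("outer"))
    },
    spindle_poles = {
      if (length(p) >= 2) {
        o <- order(p)[c(1, length(p))]
        rbind(res("outer_old", p[o[1]], h[o[1]]),
              res("outer_new", p[o[2]], h[o[2]]))
      } else if (length(p) == 1) {
        if (p <= center) rbind(res("outer_old", p, h), miss("outer_new"))
        else rbind(miss("outer_old"), res("outer_new", p, h))
      } else rbind(miss("outer_old"), miss("outer_new"))
    },
    spindle = {
      side <- function(pp, hh, inner_role, outer_role, inner_nearest) {
        if (length(pp) >= 2) {
          o <- order(abs(pp - center))
          i_in <- o[1]
          i_out <- if (inner_nearest) o[length(o)] else o[2]
          rbind(res(outer_role, pp[i_out], hh[i_out]),
                res(inner_role, pp[i_in], hh[i_in]))
        } else if (length(pp) == 1) {
          rbind(miss(outer_role), res(inner_role, pp, hh))
        } else rbind(miss(outer_role), miss(inner_role))
      }
      left <- p <= center
      rbind(side(p[left], h[left], "inner_old", "outer_old", TRUE),
            side(p[!left], h[!left], "inner_new", "outer_new", TRUE))
    },
    side_by_side_bridge = {
      if (length(p) == 0) {
        rbind(miss("outer_old"), miss("bridge"))
      } else {
        i_br <- which.min(abs(p - center))   # central peak = bridge
        rest <- setdiff(seq_along(p), i_br)
        rows <- res("bridge", p[i_br], h[i_br])
        rows <- rbind(rows,
                      if (length(rest)) {
                        i_old <- rest[which.min(p[rest])]
                        rest <- setdiff(rest, i_old)
                        res("outer_old", p[i_old], h[i_old])
                      } else miss("outer_old"))
        if (length(rest))
          rows <- rbind(rows, res(rep("unassigned", length(rest)),
                                  p[rest], h[rest]))
        rows
      }
    })
  out <- out[order(out$position, na.last = TRUE), , drop = FALSE]
  structure(tibble::as_tibble(out), class = c("peak_set",
                                              class(tibble::tibble())))
}
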