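#' Rectangular region of interest in voxel indices
#'
#' @param stack an `image_stack`.
#' @param center_nm length-3 position, stack-local nm.
#' @param halfwidth_xy,halfwidth_z half-widths, nm.
#' @return list of index vectors `x`, `y`, `z` (clipped to the stack).
#' @export
roi_around <- function(stack, center_nm, halfwidth_xy, halfwidth_z) {
  d <- dim(stack$pixels[[1]])
  ir <- function(c0, hw, pitch, n) {
    i0 <- max(1L, floor((c0 - hw) / pitch) + 1L)
    i1 <- min(n, ceiling((c0 + hw) / pitch))
    if (i0 > i1) stop("ROI outside stack bounds")
    i0:i1
  }
  list(x = ir(center_nm[1], halfwidth_xy, stack$voxel_xy, d[1]),
       y = ir(center_nm[2], halfwidth_xy, stack$voxel_xy, d[2]),
       z = ir(center_nm[3], halfwidth_z, stack$voxel_z, d[3]))
}

#' ROI containing two seeded spots
#'
#' Per dimension the ROI spans the seed extent plus 3 PSF sigmas, with a
#' minimum half-width of 4 sigmas, so a double fit always contains both
#' spots with margin.
#'
#' @param stack an `image_stack`.
#' @param seed_a,seed_b stack-local nm seed positions.
#' @param sigma_xy,sigma_z PSF sigma presets, nm.
#' @export
roi_for_pair <- function(stack, seed_a, seed_b, sigma_xy = 50, sigma_z = 140) {
  mid <- (seed_a + seed_b) / 2
  span <- abs(seed_a - seed_b) / 2
  hw_x <- max(4 * sigma_xy, span[1] + 3 * sigma_xy)
  hw_y <- max(4 * sigma_xy, span[2] + 3 * sigma_xy)
  hw_z <- max(4 * sigma_z, span[3] + 3 * sigma_z)
  d <- dim(stack$pixels[[1]])
  ir <- function(c0, hw, pitch, n) {
    i0 <- max(1L, floor((c0 - hw) / pitch) + 1L)
    i1 <- min(n, ceiling((c0 + hw) / pitch))
    if (i0 > i1) stop("ROI outside stack bounds")
    i0:i1
  }
  list(x = ir(mid[1], hw_x, stack$voxel_xy, d[1]),
       y = ir(mid[2], hw_y, stack$voxel_xy, d[2]),
       z = ir(mid[3], hw_z, stack$voxel_z, d[3]))
}

# voxel-edge coordinates (nm) of an ROI along each axis
.roi_edges <- function(roi, voxel_xy, voxel_z) {
  list(x = c(roi$x[1] - 1, roi$x) * voxel_xy,
       y = c(roi$y[1] - 1, roi$y) * voxel_xy,
       z = c(roi$z[1] - 1, roi$z) * voxel_z)
}

# predicted contribution of one integrated 3D Gaussian over the ROI grid;
# amplitude is the total photon count of the spot
.spot_pred <- function(edges, cx, cy, cz, sxy, sz, amp) {
  fx <- diff(stats::pnorm(edges$x, cx, sxy))
  fy <- diff(stats::pnorm(edges$y, cy, sxy))
  fz <- diff(stats::pnorm(edges$z, cz, sz))
  amp * outer(outer(fx, fy), fz)
}

.new_spot_fit <- function(p, rss, converged) {
  structure(list(center = as.numeric(p[1:3]), sigma_xy = p[4], sigma_z = p[5],
                 amplitude = p[6], background = p[7], rss = rss,
                 converged = converged),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf(paste0("<spot_fit> center (%.1f, %.1f, %.1f) nm, ",
                     "sigma %.1f/%.1f nm, amp %.1f, bg %.2f, rss %.3g%s\n"),
              x$center[1], x$center[2], x$center[3], x$sigma_xy, x$sigma_z,
              x$amplitude, x$background, x$rss,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

.fit_bounds <- function(edges, sigma_xy0, sigma_z0) {
  list(lo = c(min(edges$x), min(edges$y), min(edges$z),
              sigma_xy0 / 5, sigma_z0 / 5, 0, 0),
       hi = c(max(edges$x), max(edges$y), max(edges$z),
              sigma_xy0 * 5, sigma_z0 * 5, Inf, Inf))
}

.init_defaults <- function(vals, edges, init) {
  med <- stats::median(vals)
  if (is.null(init$background)) init$background <- med
  if (is.null(init$amplitude)) {
    vx <- diff(edges$x)[1]; vz <- diff(edges$z)[1]
    f <- (2 * stats::pnorm(vx / 2, 0, init$sigma_xy) - 1)^2 *
         (2 * stats::pnorm(vz / 2, 0, init$sigma_z) - 1)
    init$amplitude <- max(max(vals) - med, 1e-6) / f
  }
  init
}

#' Fit a single 3D Gaussian to a spot
#'
#' Bounded nonlinear least squares of
#' `amplitude * G3(center, sigma_xy, sigma_z) + background` to the ROI
#' voxels, where `G3` is an axially anisotropic, laterally isotropic
#' Gaussian integrated over each voxel (amplitude is thus the spot's total
#' photon count). Centers are reported in stack-local nm.
#'
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @param roi ROI from [roi_around()].
#' @param init list with `center` (stack-local nm, inside the ROI) and
#'   optionally `sigma_xy`, `sigma_z`, `amplitude`, `background`.
#' @return a `spot_fit`; `converged = FALSE` carries best-effort parameters.
#' @export
fit_single <- function(stack, channel, roi,
                       init = list(sigma_xy = 50, sigma_z = 140)) {
  arr <- stack_channel(stack, channel)
  vals <- arr[roi$x, roi$y, roi$z]
  if (diff(range(vals)) == 0)
    stop("degenerate ROI: constant intensity, nothing to fit")
  if (is.null(init$center)) stop("init$center is required")
  edges <- .roi_edges(roi, stack$voxel_xy, stack$voxel_z)
  if (init$center[1] < min(edges$x) || init$center[1] > max(edges$x) ||
      init$center[2] < min(edges$y) || init$center[2] > max(edges$y) ||
      init$center[3] < min(edges$z) || init$center[3] > max(edges$z))
    stop("init center outside the ROI")
  if (is.null(init$sigma_xy)) init$sigma_xy <- 50
  if (is.null(init$sigma_z)) init$sigma_z <- 140
  init <- .init_defaults(vals, edges, init)
  b <- .fit_bounds(edges, init$sigma_xy, init$sigma_z)
  p0 <- c(init$center, init$sigma_xy, init$sigma_z,
          init$amplitude, init$background)
  resid <- function(p)
    as.vector(.spot_pred(edges, p[1], p[2], p[3], p[4], p[5], p[6]) +
              p[7] - vals)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = b$lo, upper = b$hi, fn = resid,
    control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                         maxiter = 500))
  .new_spot_fit(fit$par, sum(fit$fvec^2), fit$info %in% 1:4)
}

#' Jointly fit two 3D Gaussians with a shared background
#'
#' Both spots have independent centers, widths and amplitudes; the ROI
#' background is shared. Spots are returned in input order (old/new
#' assignment happens downstream). Centers closer than a quarter of the
#' mean lateral sigma are flagged unresolved.
#'
#' @inheritParams fit_single
#' @param init_a,init_b init lists as in [fit_single()], distinct centers.
#' @return list with `a`, `b` (`spot_fit`s, shared background),
#'   `unresolved` flag and `converged`.
#' @export
fit_double <- function(stack, channel, roi,
                       init_a, init_b) {
  if (is.null(init_a$center) || is.null(init_b$center))
    stop("both init centers are required")
  if (isTRUE(all.equal(init_a$center, init_b$center)))
    stop("init centers must be distinct")
  arr <- stack_channel(stack, channel)
  vals <- arr[roi$x, roi$y, roi$z]
  if (diff(range(vals)) == 0)
    stop("degenerate ROI: constant intensity, nothing to fit")
  edges <- .roi_edges(roi, stack$voxel_xy, stack$voxel_z)
  for (nm in c("sigma_xy", "sigma_z")) {
    if (is.null(init_a[[nm]])) init_a[[nm]] <- c(sigma_xy = 50, sigma_z = 140)[[nm]]
    if (is.null(init_b[[nm]])) init_b[[nm]] <- c(sigma_xy = 50, sigma_z = 140)[[nm]]
  }
  init_a <- .init_defaults(vals, edges, init_a)
  init_b <- .init_defaults(vals, edges, init_b)
  init_a$amplitude <- init_a$amplitude / 2
  init_b$amplitude <- init_b$amplitude / 2
  ba <- .fit_bounds(edges, init_a$sigma_xy, init_a$sigma_z)
  # parameters: xa ya za xb yb zb sxya sza sxyb szb Aa Ab bg
  p0 <- c(init_a$center, init_b$center,
          init_a$sigma_xy, init_a$sigma_z, init_b$sigma_xy, init_b$sigma_z,
          init_a$amplitude, init_b$amplitude, init_a$background)
  lo <- c(ba$lo[1:3], ba$lo[1:3], ba$lo[4:5], ba$lo[4:5], 0, 0, 0)
  hi <- c(ba$hi[1:3], ba$hi[1:3], ba$hi[4:5], ba$hi[4:5], Inf, Inf, Inf)
  resid <- function(p)
    as.vector(.spot_pred(edges, p[1], p[2], p[3], p[7],  p[8],  p[11]) +
              .spot_pred(edges, p[4], p[5], p[6], p[9],  p[10], p[12]) +
              p[13] - vals)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lo, upper = hi, fn = resid,
    control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                         maxiter = 500))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  conv <- fit$info %in% 1:4
  a <- .new_spot_fit(c(p[1:3], p[7], p[8], p[11], p[13]), rss, conv)
  b2 <- .new_spot_fit(c(p[4:6], p[9], p[10], p[12], p[13]), rss, conv)
  sep <- sqrt(sum((a$center - b2$center)^2))
  list(a = a, b = b2,
       unresolved = sep < 0.25 * mean(c(a$sigma_xy, b2$sigma_xy)),
       converged = conv)
}

#' Construct an SPB pair record
#'
#' Orders the two reference fits by amplitude (brighter = old SPB) and
#' records their Euclidean inter-distance.
#'
#' @param fit_a,fit_b reference-channel `spot_fit`s.
#' @return list of class `spb_pair` with `fit_old`, `fit_new`,
#'   `inter_distance` (nm), `tie`, `excluded`, `exclusion_reason`.
#' @export
spb_pair <- function(fit_a, fit_b) {
  ord <- assign_old_new(fit_a, fit_b)
  structure(list(fit_old = ord$old, fit_new = ord$new,
                 inter_distance = sqrt(sum((fit_a$center - fit_b$center)^2)),
                 tie = ord$tie, excluded = FALSE,
                 exclusion_reason = NA_character_),
            class = "spb_pair")
}

#' Exclude SPBs whose focal maximum sits in the first or last z-slice
#'
#' An SPB whose maximum intensity over its ROI falls in z-slice 1 or Nz in
#' either the query or the reference channel is axially clipped and is
#' excluded from further analysis.
#'
#' @param stack the `image_stack`.
#' @param channels channel names to check (reference and query).
#' @param pair an `spb_pair`.
#' @param roi optional ROI (defaults to a 3-sigma box around both fits).
#' @param sigma_xy,sigma_z margins used for the default ROI, nm.
#' @return the pair, with `excluded`/`exclusion_reason` updated.
#' @export
edge_slice_exclusion <- function(stack, channels, pair, roi = NULL,
                                 sigma_xy = 50, sigma_z = 140) {
  if (is.null(roi))
    roi <- roi_for_pair(stack, pair$fit_old$center, pair$fit_new$center,
                        sigma_xy, sigma_z)
  nz <- dim(stack$pixels[[1]])[3]
  for (ch in channels) {
    sub <- stack_channel(stack, ch)[roi$x, roi$y, roi$z, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))[3]
    zmax <- roi$z[k]
    if (zmax == 1L || zmax == nz) {
      pair$excluded <- TRUE
      pair$exclusion_reason <- "edge_slice"
      return(pair)
    }
  }
  pair
}
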