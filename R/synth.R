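#' Optics model for the image forward model
#'
#' Describes the effective point-spread function (anisotropic 3D Gaussian),
#' voxel sizes and constant background used to render synthetic stacks.
#' Two presets cover the resolution regimes of the pipeline: a
#' SIM-reconstruction-like regime resolving the ~150 nm inner/outer plaque
#' separation, and a wide-field regime that does not.
#'
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigma, nm; axial >= lateral.
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param background constant background, photons per voxel.
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(psf_sigma_xy = 50, psf_sigma_z = 140,
                         voxel_xy = 40, voxel_z = 125, background = 10) {
  stopifnot(psf_sigma_xy > 0, psf_sigma_z > 0, voxel_xy > 0, voxel_z > 0,
            background >= 0)
  if (psf_sigma_z < psf_sigma_xy)
    stop("axial PSF sigma must be >= lateral sigma (anisotropic axial blur)")
  structure(list(psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 background = background),
            class = "optics_model")
}

#' @rdname optics_model
#' @export
optics_sim <- function() optics_model(50, 140, 40, 125, 10)

#' @rdname optics_model
#' @details The wide-field preset uses the 0.8 um plane spacing and 2x2
#'   binned camera pixels of a conventional epifluorescence acquisition.
#' @export
optics_widefield <- function() optics_model(110, 300, 129, 800, 10)

#' Noise configuration for rendering
#'
#' Standard camera model: Poisson shot noise on the expected photon count
#' plus additive Gaussian read noise; each can be switched off.
#'
#' @param poisson apply Poisson shot noise?
#' @param read_sd Gaussian read-noise sigma, photons (0 disables).
#' @export
noise_config <- function(poisson = TRUE, read_sd = 2) {
  stopifnot(read_sd >= 0)
  structure(list(poisson = poisson, read_sd = read_sd), class = "noise_config")
}

#' @rdname noise_config
#' @export
noise_none <- function() noise_config(poisson = FALSE, read_sd = 0)

#' Point emitter
#'
#' One fluorescent structure of the scene. `amplitude` is the expected total
#' photon count of the emitter (integrated over the whole PSF).
#'
#' @param position length-3 numeric, nm (scene frame).
#' @param amplitude expected photons, >= 0.
#' @param channel channel name.
#' @param role one of `"core"` (central-plaque reference label),
#'   `"inner_plaque"`, `"outer_plaque"`, `"bridge"`, `"satellite"`.
#' @export
emitter <- function(position, amplitude, channel, role) {
  role <- match.arg(role, c("core", "inner_plaque", "outer_plaque",
                            "bridge", "satellite"))
  stopifnot(length(position) == 3L, amplitude >= 0)
  list(position = as.numeric(position), amplitude = amplitude,
       channel = channel, role = role)
}

#' Intensity configuration of a synthetic scene
#'
#' Amplitudes are free parameters of the simulator (no absolute photon
#' budget is implied by SIM reconstructions); defaults give a bright-pixel
#' SNR above 10 under the SIM optics preset.
#'
#' @param ref_amp reference-channel (core plaque) amplitude, photons.
#' @param ref_fold old:new fold-ratio of the reference label (>= 1; the old
#'   SPB retains slightly more core-plaque label).
#' @param op_amp outer-plaque query amplitude at the old SPB, photons.
#' @param op_fold old:new fold-ratio of the outer-plaque query label (>= 1;
#'   `Inf` means no label at the new outer plaque).
#' @param ip_op_ratio inner:outer plaque query amplitude ratio per SPB
#'   (0 means the query label is outer-plaque-only, e.g. Spc72-like).
#' @param bridge_amp bridge-emitter amplitude (0 disables the bridge).
#' @param ploidy 1 or 2; ploidy 2 doubles every amplitude (twice the gene
#'   dose of each fusion).
#' @export
asymmetry_config <- function(ref_amp = 5000, ref_fold = 1.25,
                             op_amp = 3000, op_fold = 1,
                             ip_op_ratio = 2.5, bridge_amp = 0,
                             ploidy = 1) {
  stopifnot(ref_amp > 0, ref_fold >= 1, op_amp >= 0, op_fold >= 1,
            ip_op_ratio >= 0, bridge_amp >= 0, ploidy %in% c(1, 2))
  structure(list(ref_amp = ref_amp, ref_fold = ref_fold, op_amp = op_amp,
                 op_fold = op_fold, ip_op_ratio = ip_op_ratio,
                 bridge_amp = bridge_amp, ploidy = ploidy),
            class = "asymmetry_config")
}

#' Geometry configuration of a synthetic scene
#'
#' @param ip_op_sep inner-to-outer plaque separation along the plaque axis,
#'   nm (default 150, consistent with plaques resolved at the ~200 nm scale).
#' @param distance_ranges named list of inter-SPB distance intervals (nm) per
#'   separated stage; each interval must sit inside the corresponding
#'   spindle-staging boundary interval (see [stage_by_distance()]).
#' @param tilt_inplane_deg range of plaque-axis elevation from the image
#'   plane, degrees, for ordinary (non-top-view) scenes.
#' @param tilt_topview_deg range of plaque-axis deviation from the optical
#'   axis, degrees, for top-view scenes.
#' @export
geometry_config <- function(ip_op_sep = 150,
                            distance_ranges = list(
                              side_by_side     = c(150, 330),
                              short_spindle_lt1 = c(400, 950),
                              spindle_1_2p5    = c(1050, 2450),
                              elongated        = c(2600, 3400)),
                            tilt_inplane_deg = c(0, 25),
                            tilt_topview_deg = c(0, 25)) {
  stopifnot(ip_op_sep > 0)
  structure(list(ip_op_sep = ip_op_sep, distance_ranges = distance_ranges,
                 tilt_inplane_deg = tilt_inplane_deg,
                 tilt_topview_deg = tilt_topview_deg),
            class = "geometry_config")
}

synth_stages <- c("unduplicated", "side_by_side", "short_spindle_lt1",
                  "spindle_1_2p5", "elongated")

# unit vector at a given elevation above the xy-plane, random azimuth
.axis_at_elevation <- function(elev_deg) {
  az <- stats::runif(1, 0, 2 * pi)
  el <- elev_deg * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

# a unit vector perpendicular to u staying within max_elev_deg of the image
# plane (SPB pairs sit in the nuclear envelope roughly parallel to the
# coverslip; large out-of-plane inter-SPB axes are not generated)
.perp_axis <- function(u, max_elev_deg = 25) {
  cz <- c(u[2], -u[1], 0)                 # horizontal direction ⊥ u
  if (sqrt(sum(cz^2)) < 1e-9) cz <- c(1, 0, 0)   # u along z: any horizontal
  b1 <- cz / sqrt(sum(cz^2))
  b2 <- c(u[2] * b1[3] - u[3] * b1[2],
          u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  psi <- stats::runif(1, -max_elev_deg, max_elev_deg) * pi / 180
  sgn <- sample(c(-1, 1), 1)
  sgn * (cos(psi) * b1) + sin(psi) * b2
}

#' Build the ground truth of one synthetic SPB scene
#'
#' Places the point emitters of a spindle pole body (SPB) scene at one of
#' five cell-cycle stages. Each SPB carries a core reference emitter at its
#' centre and, in the query channel, an inner-plaque and an outer-plaque
#' emitter offset by half the plaque separation on either side along the
#' plaque axis. For separated spindles the plaque axes of the two SPBs are
#' antiparallel along the spindle axis (inner plaques face each other); for
#' side-by-side SPBs the plaque axes are parallel and perpendicular to the
#' inter-SPB segment, with an optional bridge emitter at the midpoint. The
#' new SPB's outer-plaque amplitude is scaled by `1/op_fold` (incomplete
#' outer-plaque assembly at early stages is emulated by large folds), and
#' the new SPB's reference amplitude by `1/ref_fold`.
#'
#' @param stage_label one of `r paste(synth_stages, collapse=", ")`.
#' @param asymmetry an [asymmetry_config()].
#' @param geometry a [geometry_config()].
#' @param seed integer; the scene's RNG seed (reproducibility).
#' @param top_view orient the plaque axis near the optical axis?
#' @return an object of class `ground_truth`: list of emitters, `spb_axis`
#'   (inter-SPB unit vector, NA for single SPBs), `plaque_axis`,
#'   `inter_distance` (nm, 0 for a single SPB), `old_new_fold`,
#'   `stage_label`, `ploidy`, `top_view`, `seed`.
#' @export
build_scene <- function(stage_label,
                        asymmetry = asymmetry_config(),
                        geometry = geometry_config(),
                        seed = 1L, top_view = FALSE) {
  if (!stage_label %in% synth_stages)
    stop("unknown stage label '", stage_label, "'")
  set.seed(seed)
  ac <- asymmetry; gc <- geometry

  # plaque axis orientation: near the optical axis for top views, near the
  # image plane otherwise
  paxis <- if (top_view) {
    dev <- stats::runif(1, gc$tilt_topview_deg[1], gc$tilt_topview_deg[2])
    .axis_at_elevation(90 - dev)
  } else {
    .axis_at_elevation(stats::runif(1, gc$tilt_inplane_deg[1],
                                    gc$tilt_inplane_deg[2]))
  }

  sep <- gc$ip_op_sep
  amp <- function(a) a * ac$ploidy
  op_new <- if (is.infinite(ac$op_fold)) 0 else ac$op_amp / ac$op_fold
  ip_amp <- ac$ip_op_ratio * ac$op_amp

  em <- list()
  add <- function(pos, a, ch, role) {
    if (a > 0 || role == "core")
      em[[length(em) + 1L]] <<- emitter(pos, amp(a), ch, role)
  }

  if (stage_label == "unduplicated") {
    d <- 0; axis <- c(NA_real_, NA_real_, NA_real_)
    c0 <- c(0, 0, 0)
    add(c0, ac$ref_amp, "ref", "core")
    add(c0 - sep / 2 * paxis, ip_amp, "query", "inner_plaque")
    add(c0 + sep / 2 * paxis, ac$op_amp, "query", "outer_plaque")
  } else {
    rng <- gc$distance_ranges[[stage_label]]
    if (is.null(rng)) stop("no distance range configured for ", stage_label)
    d <- stats::runif(1, rng[1], rng[2])
    if (d < 0) stop("geometry produced a negative inter-SPB distance")
    if (stage_label == "side_by_side") {
      axis <- .perp_axis(paxis, gc$tilt_inplane_deg[2])
      c_old <- -d / 2 * axis; c_new <- d / 2 * axis
      add(c_old, ac$ref_amp, "ref", "core")
      add(c_new, ac$ref_amp / ac$ref_fold, "ref", "core")
      add(c_old - sep / 2 * paxis, ip_amp, "query", "inner_plaque")
      add(c_new - sep / 2 * paxis, ip_amp, "query", "inner_plaque")
      add(c_old + sep / 2 * paxis, ac$op_amp, "query", "outer_plaque")
      add(c_new + sep / 2 * paxis, op_new, "query", "outer_plaque")
      add(c(0, 0, 0), ac$bridge_amp, "query", "bridge")
    } else {
      axis <- paxis                   # spindle axis == plaque axis
      c_old <- -d / 2 * axis; c_new <- d / 2 * axis
      add(c_old, ac$ref_amp, "ref", "core")
      add(c_new, ac$ref_amp / ac$ref_fold, "ref", "core")
      # inner plaques face each other across the spindle
      add(c_old + sep / 2 * axis, ip_amp, "query", "inner_plaque")
      add(c_new - sep / 2 * axis, ip_amp, "query", "inner_plaque")
      add(c_old - sep / 2 * axis, ac$op_amp, "query", "outer_plaque")
      add(c_new + sep / 2 * axis, op_new, "query", "outer_plaque")
    }
  }

  truth <- structure(
    list(emitters = em, spb_axis = axis, plaque_axis = paxis,
         inter_distance = d, old_new_fold = ac$op_fold,
         stage_label = stage_label, ploidy = ac$ploidy,
         top_view = top_view, seed = as.integer(seed),
         asymmetry = ac, geometry = gc),
    class = "ground_truth")
  .check_stage_consistency(truth)
  truth
}

# every generated stage must obey the spindle-staging boundaries applied to
# its own inter-distance
.check_stage_consistency <- function(truth) {
  expected <- switch(truth$stage_label,
    unduplicated = "unseparated", side_by_side = "unseparated",
    short_spindle_lt1 = "spindle_lt_1um",
    spindle_1_2p5 = "spindle_1_2p5um",
    elongated = "elongated_gt_2p5um")
  got <- stage_by_distance(truth$inter_distance / 1000)
  if (got != expected)
    stop("stage '", truth$stage_label, "' generated inter-distance ",
         truth$inter_distance, " nm outside its staging interval")
  invisible(TRUE)
}

#' Scene-frame emitter positions mapped into a stack's local frame
#' @param truth a `ground_truth`.
#' @param stack the `image_stack` rendered from it.
#' @return matrix (n x 3) of local nm positions.
#' @export
truth_local_positions <- function(truth, stack) {
  p <- t(vapply(truth$emitters, `[[`, numeric(3), "position"))
  sweep(p, 2, stack$origin)
}

# separable integrated-Gaussian line factors: fraction of a unit Gaussian at
# `center` falling into each voxel along an axis of n voxels of size `pitch`
.gauss_frac <- function(n, pitch, center, sigma) {
  edges <- (0:n) * pitch
  diff(stats::pnorm(edges, mean = center, sd = sigma))
}

#' Render a ground truth into a noisy image stack
#'
#' Forward model: each emitter contributes its amplitude multiplied by the
#' fraction of an anisotropic 3D Gaussian (sigma from `optics`) integrated
#' over each voxel, so that the noiseless stack total equals background x
#' voxels + the summed amplitudes up to boundary truncation. Poisson shot
#' noise and Gaussian read noise are then applied per `noise`.
#'
#' @param truth a `ground_truth` from [build_scene()].
#' @param optics an [optics_model()].
#' @param noise a [noise_config()].
#' @param seed RNG seed for the noise draw.
#' @param margin_sigma half-margin around the emitter bounding box, in PSF
#'   sigmas (>= 3 keeps boundary truncation below 0.1%).
#' @param dims optional integer c(nx, ny, nz) to force stack dimensions.
#' @return an `image_stack` with channels `ref` and `query`; its `origin`
#'   records the scene-frame position of the stack corner.
#' @export
render <- function(truth, optics = optics_sim(), noise = noise_config(),
                   seed = 1L, margin_sigma = 4, dims = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optics, "optics_model"))
  if (margin_sigma < 3)
    warning("margins below 3 sigma truncate > 0.1% of emitter photons")
  pos <- t(vapply(truth$emitters, `[[`, numeric(3), "position"))
  mx <- margin_sigma * optics$psf_sigma_xy
  mz <- margin_sigma * optics$psf_sigma_z
  lo <- c(min(pos[, 1]) - mx, min(pos[, 2]) - mx, min(pos[, 3]) - mz)
  hi <- c(max(pos[, 1]) + mx, max(pos[, 2]) + mx, max(pos[, 3]) + mz)
  if (is.null(dims)) {
    dims <- c(ceiling((hi[1] - lo[1]) / optics$voxel_xy),
              ceiling((hi[2] - lo[2]) / optics$voxel_xy),
              ceiling((hi[3] - lo[3]) / optics$voxel_z))
    dims <- pmax(dims, 5L)
  }
  pitch <- c(optics$voxel_xy, optics$voxel_xy, optics$voxel_z)
  # centre the grid on the emitter bounding box
  origin <- (lo + hi) / 2 - dims * pitch / 2
  chans <- unique(vapply(truth$emitters, `[[`, "", "channel"))
  pix <- stats::setNames(
    lapply(chans, function(ch) array(optics$background, dim = dims)), chans)
  sig <- c(optics$psf_sigma_xy, optics$psf_sigma_xy, optics$psf_sigma_z)
  for (e in truth$emitters) {
    p <- e$position - origin
    if (any(p < -mx - 1e-9) || any(p > dims * pitch + mx + 1e-9) ||
        any(p < -3 * sig) || any(p > dims * pitch + 3 * sig))
      stop("emitter outside the renderable volume")
    if (e$amplitude == 0) next
    fx <- .gauss_frac(dims[1], pitch[1], p[1], sig[1])
    fy <- .gauss_frac(dims[2], pitch[2], p[2], sig[2])
    fz <- .gauss_frac(dims[3], pitch[3], p[3], sig[3])
    pix[[e$channel]] <- pix[[e$channel]] +
      e$amplitude * outer(outer(fx, fy), fz)
  }
  set.seed(seed)
  for (ch in names(pix)) {
    v <- pix[[ch]]
    if (noise$poisson) v[] <- stats::rpois(length(v), pmax(v, 0))
    if (noise$read_sd > 0) v <- v + stats::rnorm(length(v), 0, noise$read_sd)
    pix[[ch]] <- v
  }
  image_stack(pix, optics$voxel_xy, optics$voxel_z,
              source_id = sprintf("%s_seed%d", truth$stage_label, truth$seed),
              origin = origin)
}

#' Sample a synthetic asynchronous SPB population
#'
#' Draws scene stages from `stage_mix`, marks a configured fraction as top
#' views (plaque axis along the optical axis), and renders each scene with a
#' per-scene seed derived from the global seed by counter, so populations
#' are reproducible scene by scene.
#'
#' @param stage_mix named numeric vector of stage proportions (sums to 1).
#' @param n number of scenes (>= 1).
#' @param asymmetry,geometry,optics,noise scene and rendering configuration.
#' @param seed global integer seed.
#' @param top_view_fraction fraction of scenes oriented as top views.
#' @return list of `n` elements, each `list(stack =, truth =)`.
#' @export
sample_population <- function(stage_mix, n,
                              asymmetry = asymmetry_config(),
                              geometry = geometry_config(),
                              optics = optics_sim(),
                              noise = noise_config(),
                              seed = 1L, top_view_fraction = 0) {
  if (length(stage_mix) == 0) stop("empty stage mix")
  if (abs(sum(stage_mix) - 1) > 1e-8)
    stop("stage-mix proportions must sum to 1")
  if (!all(names(stage_mix) %in% synth_stages))
    stop("unknown stage in mix: ",
         paste(setdiff(names(stage_mix), synth_stages), collapse = ", "))
  stopifnot(n >= 1, top_view_fraction >= 0, top_view_fraction <= 1)
  set.seed(seed)
  stages <- sample(names(stage_mix), n, replace = TRUE, prob = stage_mix)
  tops <- stats::runif(n) < top_view_fraction
  scene_seed <- (as.integer(seed) %% 20000L) * 100000L + seq_len(n)
  lapply(seq_len(n), function(i) {
    truth <- build_scene(stages[i], asymmetry, geometry,
                         seed = scene_seed[i], top_view = tops[i])
    stack <- render(truth, optics, noise, seed = scene_seed[i] + 50000000L)
    stack$source_id <- sprintf("scene%04d", i)
    list(stack = stack, truth = truth)
  })
}
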