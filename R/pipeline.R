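#' Configuration of a full synthetic pipeline run
#'
#' @param n number of scenes.
#' @param stage_mix named stage proportions (see [sample_population()]).
#' @param asymmetry,geometry,optics,noise generator configuration.
#' @param seed global integer seed (scenes, noise and seed jitter all
#'   derive from it).
#' @param top_view_fraction fraction of top-view scenes.
#' @param detect_floor amplitude floor (photons) below which a pole counts
#'   as unlabeled for mode classification.
#' @param seed_jitter_sd sd (nm) of the jitter applied to ground-truth
#'   positions to emulate manual spot identification.
#' @param linescan_width linescan width in pixels (1, 3 or 5).
#' @param keep_images keep realigned images (needed for averaging).
#' @return a `run_config` list.
#' @export
run_config <- function(n = 50,
                       stage_mix = c(unduplicated = 0.2, side_by_side = 0.2,
                                     short_spindle_lt1 = 0.3,
                                     spindle_1_2p5 = 0.2, elongated = 0.1),
                       asymmetry = asymmetry_config(),
                       geometry = geometry_config(),
                       optics = optics_sim(),
                       noise = noise_config(),
                       seed = 1L, top_view_fraction = 0,
                       detect_floor = 50, seed_jitter_sd = 30,
                       linescan_width = 3, keep_images = FALSE) {
  stopifnot(n >= 1, detect_floor >= 0, seed_jitter_sd >= 0)
  structure(list(n = n, stage_mix = stage_mix, asymmetry = asymmetry,
                 geometry = geometry, optics = optics, noise = noise,
                 seed = as.integer(seed),
                 top_view_fraction = top_view_fraction,
                 detect_floor = detect_floor,
                 seed_jitter_sd = seed_jitter_sd,
                 linescan_width = linescan_width,
                 keep_images = keep_images),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments (`n_scenes`
#' maps to `n`; a bare `n` key is reserved by YAML 1.1 for booleans);
#' `stage_mix`, `asymmetry`, `geometry`, `optics` and `noise` are nested
#' maps passed to their constructors (which validate them).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_scenes)) args$n <- y$n_scenes
  for (f in c("seed", "top_view_fraction", "detect_floor",
              "seed_jitter_sd", "linescan_width", "keep_images"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$stage_mix)) args$stage_mix <- unlist(y$stage_mix)
  if (!is.null(y$asymmetry)) args$asymmetry <- do.call(asymmetry_config, y$asymmetry)
  if (!is.null(y$geometry)) {
    g <- y$geometry
    if (!is.null(g$distance_ranges))
      g$distance_ranges <- lapply(g$distance_ranges, unlist)
    args$geometry <- do.call(geometry_config, g)
  }
  if (!is.null(y$optics)) args$optics <- do.call(optics_model, y$optics)
  if (!is.null(y$noise)) args$noise <- do.call(noise_config, y$noise)
  do.call(run_config, args)
}

# per-stage realignment field (nm) so grids match within a stage class
.stage_field_xy <- c(unseparated = 1600, spindle_lt_1um = 2000,
                     spindle_1_2p5um = 3500, elongated_gt_2p5um = 4500)

# is the channel maximum around `center` in the first or last z slice?
.edge_max <- function(stack, channels, center, sigma_xy, sigma_z) {
  roi <- roi_around(stack, center, 4 * sigma_xy, 4 * sigma_z)
  nz <- dim(stack$pixels[[1]])[3]
  for (ch in channels) {
    sub <- stack_channel(stack, ch)[roi$x, roi$y, roi$z, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))[3]
    if (roi$z[k] %in% c(1L, nz)) return(TRUE)
  }
  FALSE
}

.na_row <- function(source_id, stage_true, reason) {
  tibble::tibble(source_id = source_id, spb_pair_id = "p1",
                 stage_true = stage_true, stage = NA_character_,
                 inter_distance_nm = NA_real_,
                 i_old = NA_real_, i_new = NA_real_,
                 asymmetry_index = NA_real_, mode = NA_character_,
                 ip_intensity = NA_real_, op_intensity = NA_real_,
                 ip_op_ratio = NA_real_, tie = NA,
                 excluded = TRUE, exclusion_reason = reason)
}

#' Run the full synthetic pipeline
#'
#' simulate -> fit -> exclude -> realign -> linescan -> metrics -> report,
#' deterministic under the config seed. Each scene is processed as the
#' microscope data would be: reference spots are seeded from jittered
#' ground-truth positions (standing in for manual identification), fitted
#' with one or two 3D Gaussians, screened by the edge-slice rule, realigned
#' with the old SPB (or inner plaque) left, and quantified. Separated pairs
#' yield per-SPB query intensities (fitted amplitudes), the asymmetry index
#' and the fold-change mode; single SPBs yield inner/outer plaque fits, the
#' top-view screen and the IP:OP ratio.
#'
#' @param config a [run_config()].
#' @return list with `results` (tibble, one row per SPB pair; excluded
#'   pairs carry a reason and no metrics), `averages` (per-stage
#'   [average_class()] outputs when `keep_images`), `profiles` (per-scene
#'   [line_profile]s for retained pairs), and `report` (per-stage counts,
#'   exclusion tallies, mode distributions, centile summaries).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pop <- sample_population(config$stage_mix, config$n,
                           asymmetry = config$asymmetry,
                           geometry = config$geometry,
                           optics = config$optics, noise = config$noise,
                           seed = config$seed,
                           top_view_fraction = config$top_view_fraction)
  opt <- config$optics
  set.seed(config$seed + 777L)
  jit <- function() stats::rnorm(3, 0, config$seed_jitter_sd)
  rows <- vector("list", length(pop))
  profiles <- list()
  realigned <- list()
  for (i in seq_along(pop)) {
    sc <- pop[[i]]
    stack <- sc$stack; truth <- sc$truth
    sid <- stack$source_id
    pos <- truth_local_positions(truth, stack)
    roles <- vapply(truth$emitters, `[[`, "", "role")
    chans <- vapply(truth$emitters, `[[`, "", "channel")
    ref_idx <- which(chans == "ref" & roles == "core")
    row <- tryCatch({
      if (length(ref_idx) == 2) {
        seeds <- list(pos[ref_idx[1], ] + jit(), pos[ref_idx[2], ] + jit())
        roi <- roi_for_pair(stack, seeds[[1]], seeds[[2]],
                            opt$psf_sigma_xy, opt$psf_sigma_z)
        dbl <- fit_double(stack, "ref", roi,
                          init_a = list(center = seeds[[1]],
                                        sigma_xy = opt$psf_sigma_xy,
                                        sigma_z = opt$psf_sigma_z),
                          init_b = list(center = seeds[[2]],
                                        sigma_xy = opt$psf_sigma_xy,
                                        sigma_z = opt$psf_sigma_z))
        pair <- spb_pair(dbl$a, dbl$b)
        pair <- edge_slice_exclusion(stack, c("ref", "query"), pair,
                                     sigma_xy = opt$psf_sigma_xy,
                                     sigma_z = opt$psf_sigma_z)
        if (pair$excluded) {
          .na_row(sid, truth$stage_label, pair$exclusion_reason)
        } else {
          stage <- stage_by_distance(pair$inter_distance / 1000)
          qroi <- roi_for_pair(stack, pair$fit_old$center,
                               pair$fit_new$center,
                               opt$psf_sigma_xy, opt$psf_sigma_z)
          qd <- fit_double(stack, "query", qroi,
                           init_a = list(center = pair$fit_old$center,
                                         sigma_xy = opt$psf_sigma_xy,
                                         sigma_z = opt$psf_sigma_z),
                           init_b = list(center = pair$fit_new$center,
                                         sigma_xy = opt$psf_sigma_xy,
                                         sigma_z = opt$psf_sigma_z))
          i_old <- qd$a$amplitude; i_new <- qd$b$amplitude
          mode <- if (max(i_old, i_new) >= config$detect_floor)
            classify_mode(i_old, i_new, config$detect_floor)
          else NA_character_
          ri <- realign_stack(stack, pair$fit_old, pair$fit_new,
                              field_xy = .stage_field_xy[[stage]],
                              field_z = 1200)
          if (config$keep_images)
            realigned[[length(realigned) + 1L]] <-
              list(stage = stage, image = ri)
          proj <- max_project(ri)
          half <- pair$inter_distance / 2 + 400
          p0 <- ri$center_local[1:2] - c(half, 0)
          p1 <- ri$center_local[1:2] + c(half, 0)
          prof <- profile_line(proj, p0, p1,
                               width_px = config$linescan_width)
          profiles[[sid]] <- prof
          tibble::tibble(source_id = sid, spb_pair_id = "p1",
                         stage_true = truth$stage_label, stage = stage,
                         inter_distance_nm = pair$inter_distance,
                         i_old = i_old, i_new = i_new,
                         asymmetry_index = if (i_old + i_new > 0)
                           asymmetry_index(i_old, i_new) else NA_real_,
                         mode = mode,
                         ip_intensity = NA_real_, op_intensity = NA_real_,
                         ip_op_ratio = NA_real_, tie = pair$tie,
                         excluded = FALSE,
                         exclusion_reason = NA_character_)
        }
      } else {
        # single SPB: inner/outer plaque analysis in the query channel
        ref_seed <- pos[ref_idx[1], ] + jit()
        rroi <- roi_around(stack, ref_seed, 4 * opt$psf_sigma_xy,
                           4 * opt$psf_sigma_z)
        rfit <- fit_single(stack, "ref", rroi,
                           init = list(center = ref_seed,
                                       sigma_xy = opt$psf_sigma_xy,
                                       sigma_z = opt$psf_sigma_z))
        if (.edge_max(stack, c("ref", "query"), rfit$center,
                      opt$psf_sigma_xy, opt$psf_sigma_z)) {
          .na_row(sid, truth$stage_label, "edge_slice")
        } else {
          q_idx <- which(chans == "query" &
                         roles %in% c("inner_plaque", "outer_plaque"))
          sa <- pos[q_idx[1], ] + jit(); sb <- pos[q_idx[2], ] + jit()
          qroi <- roi_for_pair(stack, sa, sb,
                               opt$psf_sigma_xy, opt$psf_sigma_z)
          qd <- fit_double(stack, "query", qroi,
                           init_a = list(center = sa,
                                         sigma_xy = opt$psf_sigma_xy,
                                         sigma_z = opt$psf_sigma_z),
                           init_b = list(center = sb,
                                         sigma_xy = opt$psf_sigma_xy,
                                         sigma_z = opt$psf_sigma_z))
          ord <- assign_old_new(qd$a, qd$b)   # stronger signal = inner plaque
          ip <- ord$old; op <- ord$new
          if (is_top_view(ip, op, 2 * opt$psf_sigma_xy)) {
            .na_row(sid, truth$stage_label, "top_view")
          } else {
            ri <- realign_stack(stack, ip, op,
                                field_xy = .stage_field_xy[["unseparated"]],
                                field_z = 1200)
            if (config$keep_images)
              realigned[[length(realigned) + 1L]] <-
                list(stage = "unseparated", image = ri)
            ratio <- if (op$amplitude > 0) ip$amplitude / op$amplitude
                     else NA_real_
            tibble::tibble(source_id = sid, spb_pair_id = "p1",
                           stage_true = truth$stage_label,
                           stage = "unseparated",
                           inter_distance_nm = 0,
                           i_old = NA_real_, i_new = NA_real_,
                           asymmetry_index = NA_real_, mode = NA_character_,
                           ip_intensity = ip$amplitude,
                           op_intensity = op$amplitude,
                           ip_op_ratio = ratio, tie = FALSE,
                           excluded = FALSE,
                           exclusion_reason = NA_character_)
          }
        }
      }
    }, error = function(e)
      .na_row(sid, truth$stage_label, paste0("fit_error: ",
                                             conditionMessage(e))))
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)

  averages <- list()
  if (config$keep_images && length(realigned)) {
    stages <- vapply(realigned, `[[`, "", "stage")
    for (st in unique(stages)) {
      imgs <- lapply(realigned[stages == st], `[[`, "image")
      averages[[st]] <- average_class(imgs, class_key = st)
    }
  }

  kept <- results[!results$excluded, ]
  report <- list(
    n_scenes = nrow(results),
    n_excluded = sum(results$excluded),
    exclusion_tally = table(results$exclusion_reason[results$excluded]),
    stage_counts = table(kept$stage),
    stage_counts_true = table(results$stage_true),
    mode_by_stage = if (any(!is.na(kept$mode)))
      table(kept$stage[!is.na(kept$mode)], kept$mode[!is.na(kept$mode)])
    else NULL,
    asymmetry_summary = if (any(!is.na(kept$asymmetry_index)))
      summarize_distribution(kept$asymmetry_index) else NULL,
    ip_op_summary = if (any(!is.na(kept$ip_op_ratio)))
      summarize_distribution(kept$ip_op_ratio) else NULL)

  list(results = results, averages = averages, profiles = profiles,
       report = report)
}
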