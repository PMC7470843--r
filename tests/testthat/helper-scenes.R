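# shared builders for synthetic test scenes

scene_stack <- function(stage = "short_spindle_lt1", seed = 1,
                        noise = noise_config(),
                        asym = asymmetry_config(),
                        geom = geometry_config(),
                        optics = optics_sim(), top_view = FALSE) {
  truth <- build_scene(stage, asym, geom, seed = seed, top_view = top_view)
  stack <- render(truth, optics, noise, seed = seed + 500000L)
  list(truth = truth, stack = stack)
}

emitter_table <- function(truth, stack = NULL) {
  pos <- t(vapply(truth$emitters, `[[`, numeric(3), "position"))
  if (!is.null(stack)) pos <- truth_local_positions(truth, stack)
  data.frame(channel = vapply(truth$emitters, `[[`, "", "channel"),
             role = vapply(truth$emitters, `[[`, "", "role"),
             amplitude = vapply(truth$emitters, `[[`, 1, "amplitude"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

# fit the two reference spots of a rendered pair scene, seeded near truth
fit_ref_pair <- function(sc, jitter = c(20, -15, 30)) {
  et <- emitter_table(sc$truth, sc$stack)
  rp <- as.matrix(et[et$channel == "ref", c("x", "y", "z")])
  roi <- roi_for_pair(sc$stack, rp[1, ], rp[2, ])
  fit_double(sc$stack, "ref", roi,
             init_a = list(center = rp[1, ] + jitter),
             init_b = list(center = rp[2, ] - jitter))
}

# single-emitter stack: one bright spot, optional noise
single_spot_stack <- function(amplitude = 5000, seed = 1,
                              noise = noise_none(),
                              optics = optics_sim()) {
  truth <- structure(
    list(emitters = list(emitter(c(0, 0, 0), amplitude, "ref", "core")),
         spb_axis = c(NA, NA, NA), plaque_axis = c(1, 0, 0),
         inter_distance = 0, old_new_fold = 1,
         stage_label = "unduplicated", ploidy = 1, top_view = FALSE,
         seed = seed),
    class = "ground_truth")
  list(truth = truth, stack = render(truth, optics, noise, seed = seed))
}
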