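test_that("a noiseless single emitter is recovered to nm / percent accuracy", {
  sc <- single_spot_stack(amplitude = 5000, seed = 1)
  p <- truth_local_positions(sc$truth, sc$stack)[1, ]
  roi <- roi_around(sc$stack, p, 200, 560)
  fit <- fit_single(sc$stack, "ref", roi,
                    init = list(center = p + c(25, -18, 40)))
  expect_true(fit$converged)
  expect_lt(sqrt(sum((fit$center - p)^2)), 1)
  expect_lt(abs(fit$amplitude - 5000) / 5000, 0.01)
  expect_lt(abs(fit$background - 10), 0.1)
})

test_that("degenerate flat ROIs and bad inits are rejected", {
  arr <- array(7, c(12, 12, 8))
  st <- image_stack(list(ref = arr), 40, 125)
  roi <- list(x = 2:11, y = 2:11, z = 2:7)
  expect_error(fit_single(st, "ref", roi, init = list(center = c(200, 200, 400))),
               "degenerate")
  sc <- single_spot_stack()
  p <- truth_local_positions(sc$truth, sc$stack)[1, ]
  roi2 <- roi_around(sc$stack, p, 200, 560)
  expect_error(fit_single(sc$stack, "ref", roi2,
                          init = list(center = p + c(5000, 0, 0))),
               "outside the ROI")
  expect_error(fit_double(sc$stack, "ref", roi2,
                          init_a = list(center = p), init_b = list(center = p)),
               "distinct")
})

test_that("an emitter matching the init is a fixed point of the optimizer", {
  opt <- optics_sim()
  truth <- structure(
    list(emitters = list(emitter(c(0, 0, 0), 4000, "ref", "core")),
         stage_label = "unduplicated", seed = 1),
    class = "ground_truth")
  st <- render(truth, opt, noise_none(), seed = 1)
  p <- truth_local_positions(truth, st)[1, ]
  # place the init exactly at the truth with true widths and amplitude
  roi <- roi_around(st, p, 200, 560)
  fit <- fit_single(st, "ref", roi,
                    init = list(center = p, sigma_xy = 50, sigma_z = 140,
                                amplitude = 4000, background = 10))
  expect_lt(max(abs(fit$center - p)), 1e-3)
  expect_lt(abs(fit$sigma_xy - 50), 1e-2)
  expect_lt(abs(fit$sigma_z - 140), 1e-2)
})

test_that("a noiseless double fit recovers both centers and the inter-distance", {
  geom <- geometry_config(distance_ranges = list(
    side_by_side = c(300, 300.0001),
    short_spindle_lt1 = c(400, 950), spindle_1_2p5 = c(1050, 2450),
    elongated = c(2600, 3400)))
  sc <- scene_stack("side_by_side", seed = 21, noise = noise_none(),
                    geom = geom)
  et <- emitter_table(sc$truth, sc$stack)
  rp <- as.matrix(et[et$channel == "ref", c("x", "y", "z")])
  fd <- fit_ref_pair(sc)
  expect_lt(sqrt(sum((fd$a$center - rp[1, ])^2)), 2)
  expect_lt(sqrt(sum((fd$b$center - rp[2, ])^2)), 2)
  d_fit <- sqrt(sum((fd$a$center - fd$b$center)^2))
  expect_lt(abs(d_fit - sc$truth$inter_distance), 3)
  expect_false(fd$unresolved)
})

test_that("a 3:1 amplitude ratio is recovered within 2% at zero noise", {
  sc <- scene_stack("short_spindle_lt1", seed = 22, noise = noise_none(),
                    asym = asymmetry_config(ref_amp = 6000, ref_fold = 3))
  fd <- fit_ref_pair(sc)
  expect_equal(max(fd$a$amplitude, fd$b$amplitude) /
                 min(fd$a$amplitude, fd$b$amplitude), 3, tolerance = 0.02)
})

test_that("the double fit never fits worse than the best single fit", {
  sc <- scene_stack("short_spindle_lt1", seed = 23)
  et <- emitter_table(sc$truth, sc$stack)
  rp <- as.matrix(et[et$channel == "ref", c("x", "y", "z")])
  roi <- roi_for_pair(sc$stack, rp[1, ], rp[2, ])
  fd <- fit_double(sc$stack, "ref", roi,
                   init_a = list(center = rp[1, ]),
                   init_b = list(center = rp[2, ]))
  fs1 <- fit_single(sc$stack, "ref", roi, init = list(center = rp[1, ]))
  fs2 <- fit_single(sc$stack, "ref", roi, init = list(center = rp[2, ]))
  expect_lte(fd$a$rss, min(fs1$rss, fs2$rss) + 1e-6)
})

test_that("fitted centers are equivariant under integer-voxel translation", {
  tr <- structure(
    list(emitters = list(emitter(c(0, 0, 0), 5000, "ref", "core")),
         stage_label = "unduplicated", seed = 31),
    class = "ground_truth")
  st <- render(tr, optics_sim(), noise_config(), seed = 31, margin_sigma = 8)
  p <- truth_local_positions(tr, st)[1, ]
  shift <- c(2L, 1L, 1L)
  d <- dim(st)
  arr <- st$pixels[[1]]
  arr2 <- array(10, d)
  arr2[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
    arr[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
  st2 <- image_stack(list(ref = arr2), st$voxel_xy, st$voxel_z)
  off <- shift * c(st$voxel_xy, st$voxel_xy, st$voxel_z)
  roi1 <- roi_around(st, p, 160, 500)
  roi2 <- list(x = roi1$x + shift[1], y = roi1$y + shift[2],
               z = roi1$z + shift[3])
  f1 <- fit_single(st, "ref", roi1, init = list(center = p))
  f2 <- fit_single(st2, "ref", roi2, init = list(center = p + off))
  expect_equal(f2$center, f1$center + off, tolerance = 1e-6)
})

test_that("parameter recovery holds across many noisy pairs at SNR >= 10", {
  center_err <- c(); amp_err <- c()
  for (i in 1:40) {
    sc <- scene_stack("short_spindle_lt1", seed = 4000 + i)
    et <- emitter_table(sc$truth, sc$stack)
    ref <- et[et$channel == "ref", ]
    fd <- fit_ref_pair(sc)
    center_err <- c(center_err,
                    sqrt(sum((fd$a$center - as.numeric(ref[1, c("x", "y", "z")]))^2)),
                    sqrt(sum((fd$b$center - as.numeric(ref[2, c("x", "y", "z")]))^2)))
    amp_err <- c(amp_err,
                 abs(fd$a$amplitude - ref$amplitude[1]) / ref$amplitude[1],
                 abs(fd$b$amplitude - ref$amplitude[2]) / ref$amplitude[2])
  }
  expect_lt(median(center_err), optics_sim()$voxel_xy / 4)
  expect_lt(median(amp_err), 0.05)
})

test_that("SPBs peaking in the first or last slice are excluded, from either channel", {
  sc <- scene_stack("side_by_side", seed = 41, noise = noise_none())
  fd <- fit_ref_pair(sc)
  pair <- spb_pair(fd$a, fd$b)

  # mid-stack in both channels: retained
  keep <- edge_slice_exclusion(sc$stack, c("ref", "query"), pair)
  expect_false(keep$excluded)

  # crop the stack so the focal plane becomes the first slice
  zc <- round(mean(c(pair$fit_old$center[3], pair$fit_new$center[3])) /
                sc$stack$voxel_z)
  cropped <- sc$stack
  cropped$pixels <- lapply(cropped$pixels, function(a)
    a[, , zc:dim(a)[3], drop = FALSE])
  pair2 <- pair
  pair2$fit_old$center[3] <- pair$fit_old$center[3] - (zc - 1) * sc$stack$voxel_z
  pair2$fit_new$center[3] <- pair$fit_new$center[3] - (zc - 1) * sc$stack$voxel_z
  out <- edge_slice_exclusion(cropped, c("ref", "query"), pair2)
  expect_true(out$excluded)
  expect_identical(out$exclusion_reason, "edge_slice")

  # reference mid-stack but the query maximum in the last slice: excluded
  mixed <- sc$stack
  nz <- dim(mixed)[3]
  kx <- round(pair$fit_old$center[1] / mixed$voxel_xy)
  ky <- round(pair$fit_old$center[2] / mixed$voxel_xy)
  mixed$pixels$query[kx, ky, nz] <- 10 * max(mixed$pixels$query)
  roi_fullz <- roi_for_pair(mixed, pair$fit_old$center, pair$fit_new$center)
  roi_fullz$z <- seq_len(nz)
  out3 <- edge_slice_exclusion(mixed, c("ref", "query"), pair, roi = roi_fullz)
  expect_true(out3$excluded)
  # the reference channel alone would have kept it
  out4 <- edge_slice_exclusion(mixed, "ref", pair, roi = roi_fullz)
  expect_false(out4$excluded)
})
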