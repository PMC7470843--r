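# a projection with two Gaussian peaks on the x axis, analytic ground truth
two_peak_projection <- function(x1 = 600, x2 = 1400, h1 = 100, h2 = 40,
                                sigma = 50, voxel = 40, ny = 25, nx = 50,
                                bg = 2) {
  xs <- (seq_len(nx) - 0.5) * voxel
  ys <- (seq_len(ny) - 0.5) * voxel
  yc <- ys[ceiling(ny / 2)]
  m <- outer(xs, ys, function(x, y)
    bg + h1 * exp(-((x - x1)^2 + (y - yc)^2) / (2 * sigma^2)) +
         h2 * exp(-((x - x2)^2 + (y - yc)^2) / (2 * sigma^2)))
  structure(list(pixels = list(query = m), voxel_xy = voxel,
                 source_id = "synthetic"),
            class = "projection_2d")
}

test_that("profiles are constant on constant images and decompose by width", {
  flat <- structure(list(pixels = list(q = matrix(4, 30, 30)),
                         voxel_xy = 40, source_id = ""),
                    class = "projection_2d")
  p <- profile_line(flat, c(200, 600), c(1000, 600), width_px = 5)
  expect_true(all(abs(p$values - 4) < 1e-12))

  pj <- two_peak_projection()
  yc <- (ceiling(25 / 2) - 0.5) * 40
  a0 <- c(200, yc); a1 <- c(1800, yc)
  w3 <- profile_line(pj, a0, a1, width_px = 3)
  w1_mid <- profile_line(pj, a0, a1, width_px = 1)
  # offsets perpendicular to a +x axis are along -y and +y
  w1_lo <- profile_line(pj, a0 - c(0, 40), a1 - c(0, 40), width_px = 1)
  w1_hi <- profile_line(pj, a0 + c(0, 40), a1 + c(0, 40), width_px = 1)
  expect_equal(w3$values,
               (w1_lo$values + w1_mid$values + w1_hi$values) / 3,
               tolerance = 1e-12)
  expect_error(profile_line(pj, a0, a1, width_px = 2), "odd")
  expect_error(profile_line(pj, c(-500, yc), a1), "outside image")
})

test_that("profile maxima sit at the emitter positions", {
  pj <- two_peak_projection(x1 = 600, x2 = 1400)
  yc <- (ceiling(25 / 2) - 0.5) * 40
  p <- profile_line(pj, c(200, yc), c(1800, yc), width_px = 1)
  pk <- find_plaque_peaks(p, "spindle_poles", center = 800)
  expect_true(all(pk$found))
  # positions are relative to the scan start at x = 200 nm
  expect_lt(abs(pk$position[pk$role == "outer_old"] + 200 - 600), 41)
  expect_lt(abs(pk$position[pk$role == "outer_new"] + 200 - 1400), 41)
})

test_that("normalization follows the internal and reference conventions", {
  prof <- structure(list(positions = c(0, 40, 80),
                         values = matrix(c(2, 4, 6), ncol = 1,
                                         dimnames = list(NULL, "q")),
                         width_px = 1L, normalization = "none"),
                    class = "line_profile")
  ni <- normalize_profile(prof, "internal")
  expect_equal(as.numeric(ni$values), c(0, 0.5, 1))

  flat <- prof; flat$values[] <- 3
  expect_error(normalize_profile(flat, "internal"), "degenerate")
  expect_error(normalize_profile(prof, "reference"), "reference")

  # reference normalization: divide by the reference profile's maximum,
  # e.g. the old-SPB maximum of an elongated-spindle profile
  ref <- prof; ref$values[] <- c(1, 8, 2)
  nr <- normalize_profile(prof, "reference", reference_profile = ref)
  expect_equal(as.numeric(nr$values), c(2, 4, 6) / 8)
  # a profile equal to the reference peaks at exactly 1
  nr2 <- normalize_profile(ref, "reference", reference_profile = ref)
  expect_equal(max(nr2$values), 1)
})

test_that("profiles are offset-invariant after internal normalization", {
  pj <- two_peak_projection()
  yc <- (ceiling(25 / 2) - 0.5) * 40
  p1 <- profile_line(pj, c(200, yc), c(1800, yc))
  pj2 <- pj; pj2$pixels$query <- pj$pixels$query + 57
  p2 <- profile_line(pj2, c(200, yc), c(1800, yc))
  expect_equal(normalize_profile(p1, "internal")$values,
               normalize_profile(p2, "internal")$values, tolerance = 1e-9)
})

test_that("spindle-layout peaks get role order outer_old, inner_old, inner_new, outer_new", {
  # a 250 nm plaque separation keeps the dimmer outer-plaque peak a distinct
  # local maximum next to the 2.5x brighter inner plaque
  sc <- scene_stack("spindle_1_2p5", seed = 81, noise = noise_none(),
                    asym = asymmetry_config(op_fold = 2),
                    geom = geometry_config(ip_op_sep = 250))
  fd <- fit_ref_pair(sc)
  pr <- spb_pair(fd$a, fd$b)
  ri <- realign_stack(sc$stack, pr$fit_old, pr$fit_new, field_xy = 3500)
  proj <- max_project(ri)
  half <- pr$inter_distance / 2 + 400
  p <- profile_line(proj, ri$center_local[1:2] - c(half, 0),
                    ri$center_local[1:2] + c(half, 0), width_px = 3)
  pk <- find_plaque_peaks(p, "spindle", channel = "query",
                          center = half)
  expect_identical(pk$role[order(pk$position)],
                   c("outer_old", "inner_old", "inner_new", "outer_new"))
  expect_true(all(pk$found))
  # outer peaks flank the inner peaks
  expect_lt(pk$position[pk$role == "outer_old"],
            pk$position[pk$role == "inner_old"])
  expect_gt(pk$position[pk$role == "outer_new"],
            pk$position[pk$role == "inner_new"])
})

test_that("an absent new outer plaque is reported as missing", {
  sc <- scene_stack("spindle_1_2p5", seed = 82, noise = noise_none(),
                    asym = asymmetry_config(op_fold = Inf),
                    geom = geometry_config(ip_op_sep = 250))
  fd <- fit_ref_pair(sc)
  pr <- spb_pair(fd$a, fd$b)
  ri <- realign_stack(sc$stack, pr$fit_old, pr$fit_new, field_xy = 3500)
  proj <- max_project(ri)
  half <- pr$inter_distance / 2 + 400
  p <- profile_line(proj, ri$center_local[1:2] - c(half, 0),
                    ri$center_local[1:2] + c(half, 0), width_px = 3)
  pk <- find_plaque_peaks(p, "spindle", channel = "query", center = half)
  expect_false(pk$found[pk$role == "outer_new"])
  expect_true(pk$found[pk$role == "inner_new"])
})

test_that("the central side-by-side peak is annotated as the bridge", {
  # old SPB plaques at 600, bridge at the inter-SPB midpoint 900, new
  # inner plaque at 1200 nm: the query profile of a side-by-side pair
  xs <- (seq_len(50) - 0.5) * 40
  ys <- (seq_len(25) - 0.5) * 40
  yc <- ys[13]
  m <- outer(xs, ys, function(x, y) {
    r2 <- (y - yc)^2
    2 + 80 * exp(-((x - 600)^2 + r2) / 5000) +
        60 * exp(-((x - 900)^2 + r2) / 5000) +
        30 * exp(-((x - 1200)^2 + r2) / 5000)
  })
  pj <- structure(list(pixels = list(query = m), voxel_xy = 40,
                       source_id = ""), class = "projection_2d")
  p <- profile_line(pj, c(300, yc), c(1500, yc), width_px = 3)
  pk <- find_plaque_peaks(p, "side_by_side_bridge", channel = "query",
                          center = 600)   # midpoint at 900 nm = 600 from start
  br <- pk[pk$role == "bridge", ]
  expect_true(br$found)
  expect_lt(abs(br$position - 600), 41)
  oo <- pk[pk$role == "outer_old", ]
  expect_true(oo$found)
  expect_lt(oo$position, br$position)
})

test_that("peak positions track a rigid shift of the emitters", {
  pj1 <- two_peak_projection(x1 = 600, x2 = 1400)
  pj2 <- two_peak_projection(x1 = 720, x2 = 1520)
  yc <- (ceiling(25 / 2) - 0.5) * 40
  p1 <- profile_line(pj1, c(80, yc), c(1920, yc))
  p2 <- profile_line(pj2, c(80, yc), c(1920, yc))
  k1 <- find_plaque_peaks(p1, "spindle_poles", center = 920)
  k2 <- find_plaque_peaks(p2, "spindle_poles", center = 920)
  expect_equal(k2$position, k1$position + 120, tolerance = 1e-9)
})
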