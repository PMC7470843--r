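make_fit <- function(center, amplitude, sigma_xy = 50, sigma_z = 140,
                     background = 10) {
  structure(list(center = center, sigma_xy = sigma_xy, sigma_z = sigma_z,
                 amplitude = amplitude, background = background,
                 rss = 0, converged = TRUE), class = "spot_fit")
}

test_that("the brighter spot is the old SPB, with a declared tie rule", {
  a <- make_fit(c(100, 0, 0), 100); b <- make_fit(c(400, 0, 0), 40)
  o <- assign_old_new(a, b)
  expect_identical(o$old$amplitude, 100)
  expect_false(o$tie)
  o2 <- assign_old_new(b, a)
  expect_identical(o2$old$amplitude, 100)
  b$amplitude <- 100
  o3 <- assign_old_new(b, a)   # equal amplitudes: smaller x is old
  expect_true(o3$tie)
  expect_identical(o3$old$center[1], 100)
})

test_that("a pair already on +x with old left is unchanged up to interpolation", {
  # two emitters on the x axis, old (brighter) on the left
  tr <- structure(
    list(emitters = list(emitter(c(-300, 0, 0), 6000, "ref", "core"),
                         emitter(c(300, 0, 0), 3000, "ref", "core")),
         stage_label = "side_by_side", seed = 1),
    class = "ground_truth")
  st <- render(tr, optics_sim(), noise_none(), seed = 1, margin_sigma = 8)
  pos <- truth_local_positions(tr, st)
  old <- make_fit(pos[1, ], 6000); new <- make_fit(pos[2, ], 3000)
  ri <- realign_stack(st, old, new)
  # sample the input at the output voxel centres: identity rotation
  ctr_in <- (pos[1, ] + pos[2, ]) / 2
  d <- dim(ri$pixels$ref)
  gx <- ((seq_len(d[1]) - 0.5) * st$voxel_xy) - ri$center_local[1] + ctr_in[1]
  gy <- ((seq_len(d[2]) - 0.5) * st$voxel_xy) - ri$center_local[2] + ctr_in[2]
  gz <- ((seq_len(d[3]) - 0.5) * st$voxel_z) - ri$center_local[3] + ctr_in[3]
  g <- expand.grid(x = gx, y = gy, z = gz)
  direct <- array(spbquant:::lanczos3(st$pixels$ref,
                                      g$x / st$voxel_xy + 0.5,
                                      g$y / st$voxel_xy + 0.5,
                                      g$z / st$voxel_z + 0.5, fill = 10), d)
  rng <- diff(range(st$pixels$ref))
  expect_lt(max(abs(ri$pixels$ref - direct)) / rng, 1e-6)
})

test_that("a pair along +y realigns onto the x axis with distance preserved", {
  tr <- structure(
    list(emitters = list(emitter(c(0, -350, 0), 6000, "ref", "core"),
                         emitter(c(0, 350, 0), 3000, "ref", "core")),
         stage_label = "short_spindle_lt1", seed = 1),
    class = "ground_truth")
  st <- render(tr, optics_sim(), noise_none(), seed = 1, margin_sigma = 6)
  pos <- truth_local_positions(tr, st)
  old <- make_fit(pos[1, ], 6000); new <- make_fit(pos[2, ], 3000)
  ri <- realign_stack(st, old, new)
  exp_old <- ri$center_local - c(350, 0, 0)
  exp_new <- ri$center_local + c(350, 0, 0)
  roi <- roi_for_pair(ri, exp_old, exp_new)
  fd <- fit_double(ri, "ref", roi, init_a = list(center = exp_old),
                   init_b = list(center = exp_new))
  o <- assign_old_new(fd$a, fd$b)
  expect_lt(abs(o$old$center[2] - ri$center_local[2]), 1)
  expect_lt(abs(o$old$center[3] - ri$center_local[3]), 1)
  expect_lt(o$old$center[1], o$new$center[1])   # old SPB on the left
  d_fit <- sqrt(sum((o$old$center - o$new$center)^2))
  expect_lt(abs(d_fit - 700), 2)
})

test_that("realignment conserves total intensity and is idempotent", {
  sc <- scene_stack("short_spindle_lt1", seed = 61, noise = noise_none())
  fd <- fit_ref_pair(sc)
  pr <- spb_pair(fd$a, fd$b)
  ri <- realign_stack(sc$stack, pr$fit_old, pr$fit_new, field_xy = 2400,
                      field_z = 2000)
  # compare background-subtracted totals over the emitter neighbourhood
  tot_in <- sum(sc$stack$pixels$ref - 10)
  tot_out <- sum(ri$pixels$ref - pr$fit_old$background)
  expect_lt(abs(tot_out - tot_in) / tot_in, 0.01)

  # refit on the realigned image and realign again: centres move < 1 nm
  exp_old <- ri$center_local - c(pr$inter_distance / 2, 0, 0)
  exp_new <- ri$center_local + c(pr$inter_distance / 2, 0, 0)
  roi <- roi_for_pair(ri, exp_old, exp_new)
  fd2 <- fit_double(ri, "ref", roi, init_a = list(center = exp_old),
                    init_b = list(center = exp_new))
  o2 <- assign_old_new(fd2$a, fd2$b)
  ri2 <- realign_stack(ri, o2$old, o2$new, field_xy = 2400, field_z = 2000)
  roi2 <- roi_for_pair(ri2, exp_old, exp_new)
  fd3 <- fit_double(ri2, "ref", roi2, init_a = list(center = exp_old),
                    init_b = list(center = exp_new))
  o3 <- assign_old_new(fd3$a, fd3$b)
  expect_lt(max(abs(o3$old$center - o2$old$center)), 1)
  expect_lt(max(abs(o3$new$center - o2$new$center)), 1)
})

test_that("coincident centers cannot define a realignment axis", {
  sc <- single_spot_stack()
  f <- make_fit(c(200, 200, 400), 100)
  expect_error(realign_stack(sc$stack, f, f), "coincident")
})

test_that("max projection selects per-pixel maxima over the requested slices", {
  arr <- array(0, c(4, 4, 3))
  arr[2, 3, 1] <- 5; arr[2, 3, 3] <- 9; arr[1, 1, 2] <- 2
  st <- image_stack(list(q = arr), 40, 125)
  pr <- max_project(st)
  expect_identical(pr$pixels$q[2, 3], 9)
  expect_identical(pr$pixels$q[1, 1], 2)
  one <- max_project(st, z_range = 1)
  expect_identical(one$pixels$q, arr[, , 1])
  const <- image_stack(list(q = array(3, c(4, 4, 3))), 40, 125)
  expect_true(all(max_project(const)$pixels$q == 3))
  expect_error(max_project(st, z_range = integer(0)), "empty")

  # projection of a two-emitter render peaks at the lateral emitter positions
  sc <- scene_stack("side_by_side", seed = 62, noise = noise_none())
  et <- emitter_table(sc$truth, sc$stack)
  ref <- et[et$channel == "ref", ]
  prj <- max_project(sc$stack)
  m <- prj$pixels$ref
  for (i in 1:2) {
    k <- c(ceiling(ref$x[i] / sc$stack$voxel_xy),
           ceiling(ref$y[i] / sc$stack$voxel_xy))
    win <- m[max(1, k[1] - 1):min(nrow(m), k[1] + 1),
             max(1, k[2] - 1):min(ncol(m), k[2] + 1)]
    # the voxel at the emitter is a local neighbourhood maximum
    expect_identical(max(win), win[min(2, nrow(win)), min(2, ncol(win))])
  }
})

test_that("asymmetry metrics agree before and after realignment", {
  sc <- scene_stack("short_spindle_lt1", seed = 63, noise = noise_none(),
                    asym = asymmetry_config(op_fold = 3, ip_op_ratio = 0))
  fd <- fit_ref_pair(sc)
  pr <- spb_pair(fd$a, fd$b)
  qroi <- roi_for_pair(sc$stack, pr$fit_old$center, pr$fit_new$center)
  qd <- fit_double(sc$stack, "query", qroi,
                   init_a = list(center = pr$fit_old$center),
                   init_b = list(center = pr$fit_new$center))
  idx_raw <- asymmetry_index(qd$a$amplitude, qd$b$amplitude)

  ri <- realign_stack(sc$stack, pr$fit_old, pr$fit_new, field_xy = 2400)
  exp_old <- ri$center_local - c(pr$inter_distance / 2, 0, 0)
  exp_new <- ri$center_local + c(pr$inter_distance / 2, 0, 0)
  roi2 <- roi_for_pair(ri, exp_old, exp_new)
  qd2 <- fit_double(ri, "query", roi2, init_a = list(center = exp_old),
                    init_b = list(center = exp_new))
  idx_rot <- asymmetry_index(qd2$a$amplitude, qd2$b$amplitude)
  expect_equal(idx_rot, idx_raw, tolerance = 0.02)
})
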