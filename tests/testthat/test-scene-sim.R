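# Synthetic conveyor-scene simulator.

test_that("class-conditional profile dimensions match their presets", {
  lens <- vapply(1:1000, function(i)
    make_fillet_profile("normal", seed = i)$length_px, numeric(1))
  # mean length within 3 standard errors of the normal-class preset (319 +/- 12)
  expect_lt(abs(mean(lens) - 319), 3 * 12 / sqrt(1000) + 0.5)
  hts <- vapply(1:1000, function(i)
    make_fillet_profile("severe", seed = i)$max_thickness_px, numeric(1))
  expect_lt(abs(mean(hts) - 85), 3 * 7 / sqrt(1000) + 0.5)
  # rigidity presets are ordered normal < moderate < severe
  rig <- vapply(c("normal", "moderate", "severe"), function(cl)
    mean(vapply(1:50, function(i)
      make_fillet_profile(cl, seed = i)$rigidity, numeric(1))), numeric(1))
  expect_true(all(diff(rig) > 0))
})

test_that("profile construction is deterministic and validates input", {
  p1 <- make_fillet_profile("moderate", seed = 42)
  p2 <- make_fillet_profile("moderate", seed = 42)
  expect_identical(p1$heights, p2$heights)
  expect_identical(p1$outline, p2$outline)
  expect_error_class(make_fillet_profile("mild", seed = 1),
                     "fb_invalid_argument")
  expect_error_class(fillet_profile(100, 30, taper = 2), "fb_invalid_argument")
})

test_that("zero taper gives a symmetric profile", {
  p <- fillet_profile(120, 30, taper = 0)
  expect_identical(p$heights, rev(p$heights))
  expect_identical(p$heights[1], p$heights[120])
})

test_that("rasterized profiles respect their invariants", {
  for (seed in 1:20) {
    p <- make_fillet_profile(sample(c("normal", "moderate", "severe"), 1),
                             seed = seed)
    expect_lte(max(p$heights), p$max_thickness_px)
    expect_identical(length(p$heights), p$length_px)
    expect_true(all(p$heights >= 1))
  }
})

test_that("simulated passes are bit-identical given the same seed", {
  p1 <- simulate_pass(small_profile(), small_geom(), seed = 3, noise_sd = 4)
  p2 <- simulate_pass(small_profile(), small_geom(), seed = 3, noise_sd = 4)
  expect_identical(p1$frames$frames, p2$frames$frames)
  expect_identical(p1$truth_masks, p2$truth_masks)
})

test_that("an infinitely rigid fillet moves as a rigid body", {
  pass <- simulate_pass(small_profile(rigidity = Inf), small_geom(),
                        seed = 1, noise_sd = 0)
  crop <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    m[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  }
  ref <- crop(pass$truth_masks[[1]])
  # belt phase: every mask is an exact translation of the first
  for (i in seq_len(pass$detach_frame)) {
    expect_identical(crop(pass$truth_masks[[i]]), ref)
  }
  # tipping phase: rigid rotation preserves area to rasterization accuracy
  # (frames clipped by the field of view are excluded)
  H <- nrow(pass$truth_masks[[1]]); W <- ncol(pass$truth_masks[[1]])
  for (i in seq(pass$detach_frame + 1L, length(pass$truth_masks))) {
    m <- pass$truth_masks[[i]]
    clipped <- any(m[1, ]) || any(m[H, ]) || any(m[, 1]) || any(m[, W])
    if (clipped) next
    expect_lt(abs(sum(m) / sum(ref) - 1), 0.04)
  }
})

test_that("oversized profiles and blocked scenes are rejected", {
  geom <- small_geom()
  expect_error_class(
    simulate_pass(fillet_profile(500, 30), geom),
    "fb_invalid_argument")
  expect_error_class(
    simulate_pass(fillet_profile(100, 110), geom),  # taller than belt space
    "fb_invalid_argument")
})

test_that("a floppier fillet brings its centroid closer to the axle", {
  geom <- small_geom()
  dmin <- function(pass) {
    min(vapply(pass$truth_masks, function(m)
      distance_i(region_properties(m)$centroid, geom$reference_point),
      numeric(1)))
  }
  lo <- simulate_pass(small_profile(rigidity = 25), geom, seed = 2, noise_sd = 0)
  hi <- simulate_pass(small_profile(rigidity = 400), geom, seed = 2, noise_sd = 0)
  expect_lt(dmin(lo), dmin(hi))
})

test_that("rigidity sweep orders minimum distance and bending energy", {
  geom <- small_geom()
  ks <- c(20, 80, 200)  # range where bending dominates shape curvature
  dmins <- mbes <- numeric(length(ks))
  for (i in seq_along(ks)) {
    pass <- simulate_pass(small_profile(rigidity = ks[i]), geom,
                          seed = 4, noise_sd = 0)
    win <- delimit_window(pass$frames, as_trigger_config(geom))
    segs <- lapply(pass$truth_masks[win$start_frame:win$end_frame],
                   region_properties)
    dmins[i] <- run_distance_trace(segs, geom)$MDM
    mbes[i] <- suppressWarnings(max_bending_energy(segs))$MBE
  }
  expect_true(all(diff(dmins) > 0))   # stiffer => larger minimum distance
  expect_true(all(diff(mbes) < 0))    # stiffer => smaller peak bending energy
})

test_that("noise-free frames threshold back to the exact truth mask", {
  pass <- cached_small_pass()
  mid <- (200 + 10) / 2
  for (i in seq(1, length(pass$frames$frames), by = 5)) {
    got <- pass$frames$frames[[i]] > mid
    tm <- pass$truth_masks[[i]]
    expect_gte(sum(got & tm) / sum(got | tm), 0.98)
  }
})

test_that("bending deforms but does not destroy the fillet", {
  pass <- cached_small_pass()
  a0 <- sum(pass$truth_masks[[1]])
  pre_detach <- seq_len(pass$detach_frame)
  areas <- vapply(pass$truth_masks[pre_detach], sum, numeric(1))
  expect_true(all(abs(areas / a0 - 1) < 0.05))
})

test_that("cohorts are balanced, labeled and reproducible", {
  geom <- small_geom()
  co <- generate_cohort(1, geom, master_seed = 9,
                        profile_fun = small_profile_fun, noise_sd = 0)
  expect_length(co, 3L)
  expect_setequal(vapply(co, `[[`, character(1), "label"),
                  c("normal", "moderate", "severe"))
  co2 <- generate_cohort(1, geom, master_seed = 9,
                         profile_fun = small_profile_fun, noise_sd = 0)
  expect_identical(co[[1]]$frames$frames, co2[[1]]$frames$frames)
  expect_error_class(generate_cohort(0, geom, 1), "fb_invalid_argument")
})

test_that("a 15-per-class cohort yields 45 passes, 15 per label", {
  geom <- scene_geometry(image_w = 200, image_h = 130, belt_row = 56,
                         edge_col = 130, roller_radius = 10,
                         arrival_col = 80, departure_row = 104,
                         line_speed = 5)
  pf <- function(class_label, seed, ...) {
    rig <- c(normal = 15, moderate = 60, severe = 90)[[class_label]]
    fillet_profile(56, 15, rigidity = rig)
  }
  co <- generate_cohort(15, geom, master_seed = 1, profile_fun = pf,
                        noise_sd = 0)
  expect_length(co, 45L)
  expect_equal(as.integer(table(vapply(co, `[[`, character(1), "label"))),
               c(15L, 15L, 15L))
})
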