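# Bending energy: rotation, skeletonization, quadratic fit, energy assembly.

test_that("an already-horizontal rectangle survives rotation unchanged", {
  m <- mk_rect()
  out <- rotate_to_major_axis(region_properties(m))
  crop <- function(x) {
    idx <- which(x, arr.ind = TRUE)
    x[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  }
  a <- crop(m); b <- crop(out)
  expect_identical(dim(a), dim(b))
  expect_gte(sum(a & b) / sum(a | b), 0.98)
})

test_that("rotation brings the major axis within a degree of horizontal", {
  for (deg in c(10, 25, 40)) {
    seg <- region_properties(mk_rot_rect(deg * pi / 180))
    out <- rotate_to_major_axis(seg)
    expect_lt(abs(region_properties(out)$major_axis_angle) * 180 / pi, 1)
    expect_lt(abs(sum(out) / seg$area - 1), 0.02)  # area preserved
  }
})

test_that("degenerate masks cannot be oriented", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  expect_error_class(rotate_to_major_axis(m), "fb_invalid_argument")
})

test_that("skeleton of a straight rectangle is flat", {
  sk <- skeletonize_and_fit(mk_rect())
  expect_lt(abs(sk$fit_coeffs[["a"]]), 1e-3)
  expect_gte(sk$n_samples, 3L)
})

test_that("skeleton fit recovers the generating polynomial of a thick band", {
  sk <- skeletonize_and_fit(mk_parabola_band(a = 0.001, ht = 20, ncol = 320))
  expect_lt(abs(sk$fit_coeffs[["a"]] - 0.001) / 0.001, 0.15)
})

test_that("quadratic fit never beats its own nested linear fit", {
  sk <- skeletonize_and_fit(mk_parabola_band(a = 0.0008, ht = 15))
  x <- sk$raw_points[, 2] - 0.5
  y <- sk$raw_points[, 1] - 0.5
  rms_quad <- sqrt(mean(stats::lm.fit(cbind(1, x, x^2), y)$residuals^2))
  rms_line <- sqrt(mean(stats::lm.fit(cbind(1, x), y)$residuals^2))
  expect_lte(rms_quad, rms_line + 1e-12)
})

test_that("skeletons need at least three usable points", {
  m <- matrix(FALSE, 10, 10); m[5, 4:5] <- TRUE
  expect_error_class(skeletonize_and_fit(m), "fb_degenerate_shape")
})

test_that("a straight shape carries essentially no bending energy", {
  expect_lt(compute_bending_energy(mk_rect())$BE, 1e-3)
})

test_that("bending energy is scale invariant on a smooth bent phantom", {
  mk <- function(s) mk_parabola_band(a = 0.002 / s, ht = 14 * s,
                                     ncol = round(360 * s),
                                     nrow = round(260 * s),
                                     y0 = 40 * s, margin = 8 * s)
  be1 <- compute_bending_energy(mk(1))$BE
  for (s in c(0.5, 1.5, 2)) {
    expect_lt(abs(compute_bending_energy(mk(s))$BE / be1 - 1), 0.05)
  }
})

test_that("bending energy matches the closed form on a constant-curvature arc", {
  arc <- mk_arc_band(R0 = 400, phi = 0.5, ht = 12)
  be <- compute_bending_energy(arc)
  # analytic band perimeter: outer arc + inner arc + two radial ends
  P_true <- 2 * 0.5 * (400 + 12) + 2 * 0.5 * (400 - 12) + 4 * 12
  closed <- P_true^2 * (1 / 400)^2
  expect_lt(abs(be$BE - closed) / closed, 0.15)
  # assembly identity: BE re-composes exactly from its own fields
  expect_equal(be$BE, (be$P^2 / be$L) * sum(be$curvature_samples^2))
})

test_that("bending energy is invariant to the input pose", {
  base <- mk_parabola_band(a = 0.0015, ht = 14, ncol = 340, nrow = 260, y0 = 50)
  be0 <- compute_bending_energy(base)$BE
  for (deg in c(12, 20)) {
    th <- deg * pi / 180
    n <- 520
    rowm <- matrix(seq_len(n) - 0.5, n, n); colm <- t(rowm)
    # exact rasterization of the same band pre-rotated by `th`
    xr <- (colm - n / 2) * cos(th) + (rowm - n / 2) * sin(th) + 170
    yr <- -(colm - n / 2) * sin(th) + (rowm - n / 2) * cos(th) + 130
    yc <- 50 + 0.0015 * (xr - 170)^2
    rot <- abs(yr - yc) <= 14 & xr >= 10 & xr <= 330
    expect_lt(abs(compute_bending_energy(rot)$BE / be0 - 1), 0.05)
  }
})

test_that("the trace maximum obeys max semantics", {
  flat <- region_properties(mk_rect())
  bent <- region_properties(mk_parabola_band(a = 0.002, ht = 14))
  same <- max_bending_energy(rep(list(flat), 4))
  expect_equal(same$MBE, compute_bending_energy(flat)$BE)
  mixed <- max_bending_energy(list(flat, bent, flat))
  expect_equal(mixed$MBE, compute_bending_energy(bent)$BE)
  expect_identical(mixed$argmax_frame, 2L)
  # injecting a higher-curvature frame raises the maximum to that frame's BE
  expect_gt(mixed$MBE, same$MBE)
})

test_that("degenerate frames are skipped with a warning, empty traces error", {
  flat <- region_properties(mk_rect())
  tiny <- region_properties({m <- matrix(FALSE, 8, 8); m[4, 4:5] <- TRUE; m})
  expect_warning(bt <- max_bending_energy(list(flat, tiny, NULL)), "skipped")
  expect_equal(bt$MBE, compute_bending_energy(flat)$BE)
  expect_error_class(suppressWarnings(max_bending_energy(list(tiny))),
                     "fb_no_object")
})

test_that("a floppy pass shows a larger peak bending energy than a stiff one", {
  geom <- small_geom()
  mbe <- function(rig) {
    pass <- simulate_pass(small_profile(rigidity = rig), geom,
                          seed = 6, noise_sd = 0)
    win <- delimit_window(pass$frames, as_trigger_config(geom))
    segs <- lapply(win$start_frame:win$end_frame, function(i)
      tryCatch(segment_fillet(pass$frames$frames[[i]], small_seg_params()),
               fb_no_object = function(e) NULL))
    suppressWarnings(max_bending_energy(segs))$MBE
  }
  expect_gt(mbe(25), mbe(350))
})
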