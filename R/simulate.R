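# Synthetic conveyor-scene simulator: renders frame sequences of a fillet
# traveling along the belt, bending over the discharge edge, detaching and
# falling, with exact per-frame ground-truth masks.
#
# Deflection law: the portion of the fillet overhanging the roller edge is
# bent along a cantilever-like curve whose tangent angle at overhang
# arc-length s is phi(s) = atan(s / rigidity); for small deflections this
# reduces to the quadratic sag s^2 / (2 * rigidity) consistent with the
# quadratic skeleton model of the bending-energy descriptor, while for a
# floppy fillet the tip rolls toward vertical and hangs down past the
# roller, as real low-rigidity fillets do. After the mask centroid passes
# the edge column the fillet detaches: its bent shape is frozen and it tips
# forward about the roller edge corner with a constant angular acceleration
# (the rigid-body motion of a slab tipping off a ledge), sliding straight
# down once the swing reaches `tip_max` radians.

#' Simulate one fillet pass over the conveyor discharge edge
#'
#' Renders an 8-bit grayscale frame sequence (dark background, bright fillet,
#' optional additive Gaussian pixel noise) of `profile` translating along the
#' belt, deflecting over the roller edge in proportion to `1/rigidity`,
#' detaching, and falling out of view. Exact ground-truth masks and the
#' ground-truth arrival/departure trigger frames are returned alongside.
#'
#' @param profile a [fillet_profile()].
#' @param geom a [scene_geometry()].
#' @param seed integer seed controlling the pixel noise; frames are
#'   bit-identical across calls with equal arguments.
#' @param noise_sd SD of additive Gaussian pixel noise on the 0-255 scale
#'   (0 disables noise).
#' @param tip_accel angular acceleration of the post-detachment tipping
#'   rotation about the roller edge, in radians per frame squared.
#' @param tip_max maximum tipping angle in radians; past it the fillet
#'   translates straight down (slides off the roller).
#' @param gravity constant downward acceleration of the post-swing slide, in
#'   pixels per frame squared.
#' @param label optional severity label carried through to downstream tables
#'   (`"normal"`, `"moderate"` or `"severe"`).
#' @param max_frames hard cap on the number of rendered frames.
#' @param tail_frames number of frames rendered after the ground-truth
#'   departure trigger before the simulation stops.
#' @return an object of class `simulated_pass`: `frames` (a
#'   [frame_sequence()]), `truth_masks` (list of logical matrices),
#'   `truth_arrival_frame`, `truth_departure_frame`, `detach_frame`, `label`,
#'   `rigidity_used`, `seed` and `geom`.
#' @examples
#' geom <- scene_geometry(image_w = 320, image_h = 240, belt_row = 120,
#'                        edge_col = 200, roller_radius = 20,
#'                        arrival_col = 150, departure_row = 170,
#'                        line_speed = 5)
#' pass <- simulate_pass(fillet_profile(100, 30, rigidity = 40), geom,
#'                       seed = 1, noise_sd = 0)
#' length(pass$frames$frames)
#' @export
simulate_pass <- function(profile, geom, seed = 0, noise_sd = 4,
                          tip_accel = 0.05, tip_max = 1.5,
                          gravity = 3,
                          label = NA_character_,
                          max_frames = 400L, tail_frames = 4L) {
  stopifnot(inherits(profile, "fillet_profile"), inherits(geom, "scene_geometry"))
  if (profile$length_px > geom$image_w) {
    stop_invalid("fillet profile is wider than the image")
  }
  if (profile$max_thickness_px >= geom$belt_row) {
    stop_invalid("fillet profile does not fit above the belt surface")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (!is_number(tip_accel) || tip_accel <= 0) stop_invalid("`tip_accel` must be > 0")
  if (!is_number(gravity) || gravity <= 0) stop_invalid("`gravity` must be > 0")
  L <- profile$length_px
  hcol <- rev(profile$heights)   # tail-end first: thin tail leads on the right
  speed <- geom$line_speed
  lead0 <- geom$arrival_col - ceiling(2 * speed) - 2L  # leading edge, frame 1
  offset0 <- lead0 - L + 1L
  if (offset0 < 1L) {
    stop_invalid("fillet does not fit upstream of the arrival trigger line")
  }
  W <- geom$image_w; H <- geom$image_h
  belt <- geom$belt_row; edge <- geom$edge_col
  rigidity <- profile$rigidity
  min_trig <- 5L  # ground-truth trigger definition mirrors the default sensor

  frames <- vector("list", max_frames)
  masks <- vector("list", max_frames)
  arrival <- NA_integer_; departure <- NA_integer_
  detach_frame <- NA_integer_
  det_crop <- NULL; det_origin <- NULL  # frozen shape at detachment

  with_seed(seed, {
    f <- 0L
    repeat {
      f <- f + 1L
      if (f > max_frames) { f <- f - 1L; break }
      shift <- as.integer(round((f - 1L) * speed))
      mask <- matrix(FALSE, H, W)
      if (is.na(detach_frame)) {
        gcols <- offset0 + shift + 0:(L - 1L)
        over <- gcols - edge           # overhang arc position, px
        omax <- max(over)
        phi_tip <- if (omax > 0) atan(omax / rigidity) else 0
        # supported columns (and the whole fillet when effectively straight)
        # render as exact vertical pixel columns resting on the belt
        straight <- omax <= 0L || phi_tip < 0.02
        vsel <- if (straight) rep(TRUE, L) else gcols <= edge
        vcols <- gcols[vsel]; vh <- hcol[vsel]
        vis <- vcols >= 1L & vcols <= W
        gc2 <- vcols[vis]; h2 <- vh[vis]
        if (length(gc2)) {
          idxm <- cbind(sequence(h2, from = belt - h2 + 1L), rep(gc2, h2))
          keep <- idxm[, 1] >= 1L & idxm[, 1] <= H
          mask[idxm[keep, , drop = FALSE]] <- TRUE
        }
        if (!straight) {
          # overhang: extrude the thickness profile about the midline of the
          # tangent-integrated cantilever curve; the area Jacobian (1 + t*k)
          # is odd in the midline offset t, so bending preserves area
          ds <- 0.25
          sg <- seq(ds, omax, by = ds)
          phis <- atan((sg - ds / 2) / rigidity)
          hs <- stats::approx(over, hcol, xout = sg, rule = 2)$y
          h0 <- stats::approx(over, hcol, xout = 0, rule = 2)$y
          mx <- edge + cumsum(cos(phis)) * ds
          my <- belt - h0 / 2 + cumsum(sin(phis)) * ds
          nxt <- sin(phis); nyt <- -cos(phis)   # up-normal of the curve
          counts <- pmax(1L, as.integer(ceiling(hs / 0.4)))
          tfrac <- (sequence(counts) - 0.5) / rep(counts, counts) - 0.5
          px <- rep(mx, counts) + tfrac * rep(hs * nxt, counts)
          py <- rep(my, counts) + tfrac * rep(hs * nyt, counts)
          pr <- floor(py) + 1L; pc <- floor(px) + 1L
          okp <- pr >= 1L & pr <= H & pc >= 1L & pc <= W
          mask[cbind(pr[okp], pc[okp])] <- TRUE
        }
        if (!any(mask)) { f <- f - 1L; break }
        idx <- which(mask)
        mcols <- ((idx - 1L) %/% H) + 1L
        ccol <- mean(mcols) - 0.5
        if (ccol > edge) {
          # detach: freeze the bent shape as a cropped raster
          detach_frame <- f
          mrows <- ((idx - 1L) %% H) + 1L
          rmin <- min(mrows); rmax <- max(mrows)
          cmin <- min(mcols); cmax <- max(mcols)
          det_crop <- mask[rmin:rmax, cmin:cmax, drop = FALSE]
          det_origin <- c(rmin, cmin)
        }
      } else {
        # tipping about the roller edge corner, then a straight-down slide
        n <- f - detach_frame
        phi_raw <- tip_accel * n * (n + 1) / 2
        phi <- min(phi_raw, tip_max)
        drop <- 0; sideways <- 0
        if (phi_raw > tip_max) {
          # frames spent past the swing cap slide off: the fillet keeps the
          # belt's horizontal momentum and accelerates downward
          m <- n - ceiling((sqrt(1 + 8 * tip_max / tip_accel) - 1) / 2)
          m <- max(m, 1L)
          drop <- gravity * m * (m + 1) / 2
          sideways <- speed * m
        }
        hc2 <- nrow(det_crop); wc2 <- ncol(det_crop)
        # forward-rotate the crop corners about the pivot to bound the output
        py <- belt; px <- edge
        cy <- c(det_origin[1] - 1, det_origin[1] - 1,
                det_origin[1] + hc2 - 1, det_origin[1] + hc2 - 1)
        cx <- c(det_origin[2] - 1, det_origin[2] + wc2 - 1,
                det_origin[2] - 1, det_origin[2] + wc2 - 1)
        ry <- py + sin(phi) * (cx - px) + cos(phi) * (cy - py) + drop
        rx <- px + cos(phi) * (cx - px) - sin(phi) * (cy - py) + sideways
        r1 <- max(1L, floor(min(ry)) - 1L); r2 <- min(H, ceiling(max(ry)) + 1L)
        c1 <- max(1L, floor(min(rx)) - 1L); c2 <- min(W, ceiling(max(rx)) + 1L)
        if (r1 > r2 || c1 > c2) { f <- f - 1L; break }
        oy <- matrix((r1:r2) - 0.5 - py - drop, r2 - r1 + 1L, c2 - c1 + 1L)
        ox <- matrix(rep((c1:c2) - 0.5 - px - sideways, each = r2 - r1 + 1L),
                     r2 - r1 + 1L, c2 - c1 + 1L)
        sy <- -sin(phi) * ox + cos(phi) * oy + py
        sx <- cos(phi) * ox + sin(phi) * oy + px
        sr <- floor(sy) + 1L - det_origin[1] + 1L
        sc <- floor(sx) + 1L - det_origin[2] + 1L
        valid <- sr >= 1L & sr <= hc2 & sc >= 1L & sc <= wc2
        sub <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
        sub[valid] <- det_crop[cbind(sr[valid], sc[valid])]
        if (!any(sub)) { f <- f - 1L; break }
        mask[r1:r2, c1:c2] <- sub
        idx <- which(mask)
      }
      img <- matrix(10, H, W)
      img[idx] <- 200
      if (noise_sd > 0) img <- img + stats::rnorm(H * W, 0, noise_sd)
      img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)
      frames[[f]] <- img
      masks[[f]] <- mask
      if (is.na(arrival) && sum(mask[, geom$arrival_col]) >= min_trig) {
        arrival <- f
      }
      if (is.na(departure) && sum(mask[geom$departure_row, ]) >= min_trig) {
        departure <- f
      }
      if (!is.na(departure) && f >= departure + tail_frames) break
    }
    frames <- frames[seq_len(f)]
    masks <- masks[seq_len(f)]
  })

  if (is.na(arrival)) {
    stop_no_object("simulated fillet never reached the arrival trigger line")
  }
  if (is.na(departure)) departure <- length(frames)
  structure(list(
    frames = frame_sequence(frames, frame_rate = geom$frame_rate,
                            source_id = sprintf("sim_seed%d", as.integer(seed))),
    truth_masks = masks,
    truth_arrival_frame = arrival,
    truth_departure_frame = as.integer(departure),
    detach_frame = detach_frame,
    label = label,
    rigidity_used = rigidity,
    seed = as.integer(seed),
    geom = geom
  ), class = "simulated_pass")
}

#' @export
print.simulated_pass <- function(x, ...) {
  cat("Simulated pass:", length(x$frames$frames), "frames,",
      x$frames$frames[[1]] |> dim() |> paste(collapse = " x "), "px\n")
  cat("  label:", x$label, "| rigidity:", signif(x$rigidity_used, 4),
      "| seed:", x$seed, "\n")
  cat("  truth arrival frame", x$truth_arrival_frame,
      ", departure frame", x$truth_departure_frame,
      ", detach frame", x$detach_frame, "\n")
  invisible(x)
}

# Reproducible per-pass seed schedule for a balanced cohort.
cohort_plan <- function(n_per_class, master_seed) {
  if (!is_count(n_per_class)) stop_invalid("`n_per_class` must be >= 1")
  labels <- rep(c("normal", "moderate", "severe"), each = n_per_class)
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max, 2L * length(labels)))
  data.frame(
    id = sprintf("%s_%02d", labels, rep(seq_len(n_per_class), times = 3)),
    label = labels,
    profile_seed = seeds[seq_along(labels)],
    pass_seed = seeds[length(labels) + seq_along(labels)],
    stringsAsFactors = FALSE
  )
}

#' Generate a balanced labeled cohort of simulated passes
#'
#' Draws `n_per_class` fillets per severity class with [make_fillet_profile()]
#' and simulates each pass, deriving all per-pass seeds reproducibly from
#' `master_seed`. Note that full-resolution passes are large in memory; for
#' cohorts at the default scene size prefer [cohort_feature_table()], which
#' streams passes through feature extraction one at a time.
#'
#' @param n_per_class number of fillets per severity class.
#' @param geom a [scene_geometry()].
#' @param master_seed integer master seed.
#' @param profile_fun function `(class_label, seed)` drawing a
#'   [fillet_profile()]; defaults to [make_fillet_profile()]. Override to
#'   simulate cohorts at other scene scales.
#' @param ... further arguments passed to [simulate_pass()] (e.g. `noise_sd`).
#' @return a list of [simulate_pass()] results, in class-blocked order
#'   (all normal, all moderate, all severe).
#' @export
generate_cohort <- function(n_per_class, geom, master_seed,
                            profile_fun = make_fillet_profile, ...) {
  plan <- cohort_plan(n_per_class, master_seed)
  lapply(seq_len(nrow(plan)), function(i) {
    prof <- profile_fun(plan$label[i], seed = plan$profile_seed[i])
    simulate_pass(prof, geom, seed = plan$pass_seed[i],
                  label = plan$label[i], ...)
  })
}
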