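# Per-frame joint angles and their geometric invariances.

test_that("angle_between handles the canonical vector pairs exactly", {
  expect_equal(angle_between(c(0, -1), c(0, -1)), 0)
  expect_equal(angle_between(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_between(c(1, 0), c(-1, 0)), 180)
  # clamp: cosine marginally above 1 from rounding must give 0, not NaN
  u <- c(1, 1e-8)
  expect_false(is.nan(angle_between(u, u * (1 + 1e-12))))
  expect_equal(angle_between(u, u * (1 + 1e-12)), 0, tolerance = 1e-6)
  expect_error(angle_between(c(0, 0), c(1, 0)), "degenerate")
})

test_that("angle_between matches the atan2 oracle on 1000 random pairs", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      u <- rnorm(2); v <- rnorm(2)
      if (sqrt(sum(u^2)) < 1e-6 || sqrt(sum(v^2)) < 1e-6) next
      a <- angle_between(u, v)
      expect_true(a >= 0 && a <= 180)
      expect_equal(a, atan2_angle(u, v), tolerance = 1e-9)
    }
  })
})

test_that("angle_between is symmetric and flips under vector negation", {
  withr::with_seed(7, {
    for (i in 1:50) {
      u <- rnorm(2); v <- rnorm(2)
      expect_equal(angle_between(u, v), angle_between(v, u), tolerance = 1e-12)
      expect_equal(angle_between(u, -v), 180 - angle_between(u, v),
                   tolerance = 1e-9)
    }
  })
})

test_that("hip angle follows the vertical-axis reference in both conventions", {
  # thigh pointing down-image: anti-parallel to (0, -1)
  fr <- make_frame(LEFT_HIP = c(0.5, 0.4), LEFT_KNEE = c(0.5, 0.6))
  expect_equal(hip_angle(fr, "left", "raw_eq1", warn_aspect = FALSE), 180)
  expect_equal(hip_angle(fr, "left", "flexion", warn_aspect = FALSE), 0)
  # horizontal thigh
  fr <- make_frame(LEFT_HIP = c(0.5, 0.5), LEFT_KNEE = c(0.7, 0.5))
  expect_equal(hip_angle(fr, "left", "raw_eq1", warn_aspect = FALSE), 90)
  expect_equal(hip_angle(fr, "left", "flexion", warn_aspect = FALSE), 90)
  # thigh pointing up-image: parallel to (0, -1)
  fr <- make_frame(LEFT_HIP = c(0.5, 0.6), LEFT_KNEE = c(0.5, 0.4))
  expect_equal(hip_angle(fr, "left", "raw_eq1", warn_aspect = FALSE), 0)
  expect_error(hip_angle(make_frame(LEFT_HIP = c(0.5, 0.5)), "left",
                         warn_aspect = FALSE), "missing landmark LEFT_KNEE")
})

test_that("knee angle measures thigh-shank deviation from a straight leg", {
  fr <- make_frame(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.5, 0.5),
                   LEFT_ANKLE = c(0.5, 0.7))
  expect_equal(knee_angle(fr, "left", warn_aspect = FALSE), 0)
  fr <- make_frame(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.5, 0.5),
                   LEFT_ANKLE = c(0.7, 0.5))
  expect_equal(knee_angle(fr, "left", warn_aspect = FALSE), 90)
  fr <- make_frame(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.5, 0.5),
                   LEFT_ANKLE = c(0.5, 0.3))
  expect_equal(knee_angle(fr, "left", warn_aspect = FALSE), 180)
})

test_that("ankle angle measures shank-foot deviation", {
  fr <- make_frame(LEFT_KNEE = c(0.5, 0.3), LEFT_ANKLE = c(0.5, 0.5),
                   LEFT_FOOT_INDEX = c(0.6, 0.5))
  expect_equal(ankle_angle(fr, "left", warn_aspect = FALSE), 90)
  fr <- make_frame(LEFT_KNEE = c(0.5, 0.3), LEFT_ANKLE = c(0.5, 0.5),
                   LEFT_FOOT_INDEX = c(0.5, 0.7))
  expect_equal(ankle_angle(fr, "left", warn_aspect = FALSE), 0)
  # hand-derived: shank (0, 0.2), foot (0.1, -0.1): cos = -1/sqrt(2) -> 135
  fr <- make_frame(LEFT_KNEE = c(0.5, 0.3), LEFT_ANKLE = c(0.5, 0.5),
                   LEFT_FOOT_INDEX = c(0.6, 0.4))
  expect_equal(ankle_angle(fr, "left", warn_aspect = FALSE),
               acos(-1 / sqrt(2)) * 180 / pi, tolerance = 1e-9)
})

test_that("knee and ankle angles are invariant to rotation, translation and scale", {
  rot <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                           sin(th) * p[1] + cos(th) * p[2])
  withr::with_seed(31, {
    for (i in 1:200) {
      pts <- list(LEFT_HIP = runif(2), LEFT_KNEE = runif(2),
                  LEFT_ANKLE = runif(2), LEFT_FOOT_INDEX = runif(2))
      fr <- do.call(make_frame, pts)
      k0 <- tryCatch(knee_angle(fr, "left", warn_aspect = FALSE),
                     error = function(e) NA)
      a0 <- tryCatch(ankle_angle(fr, "left", warn_aspect = FALSE),
                     error = function(e) NA)
      h0 <- tryCatch(hip_angle(fr, "left", warn_aspect = FALSE),
                     error = function(e) NA)
      if (anyNA(c(k0, a0, h0))) next
      th <- runif(1, 0, 2 * pi); shift <- rnorm(2); sc <- runif(1, 0.1, 5)
      fr2 <- do.call(make_frame, lapply(pts, function(p) rot(p, th)))
      expect_equal(knee_angle(fr2, "left", warn_aspect = FALSE), k0,
                   tolerance = 1e-9)
      expect_equal(ankle_angle(fr2, "left", warn_aspect = FALSE), a0,
                   tolerance = 1e-9)
      fr3 <- do.call(make_frame, lapply(pts, function(p) sc * p + shift))
      expect_equal(knee_angle(fr3, "left", warn_aspect = FALSE), k0,
                   tolerance = 1e-9)
      expect_equal(ankle_angle(fr3, "left", warn_aspect = FALSE), a0,
                   tolerance = 1e-9)
      expect_equal(hip_angle(fr3, "left", warn_aspect = FALSE), h0,
                   tolerance = 1e-9)  # translation/scale only; rotation moves it
    }
  })
})

test_that("aspect correction changes angles only for non-square frames", {
  pts <- list(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.6, 0.5),
              LEFT_ANKLE = c(0.55, 0.7))
  fr_sq <- do.call(make_frame, c(pts, list(width_px = 1080, height_px = 1080)))
  fr_no <- do.call(make_frame, pts)
  expect_equal(knee_angle(fr_sq, "left"),
               knee_angle(fr_no, "left", warn_aspect = FALSE), tolerance = 1e-12)
  fr_wide <- do.call(make_frame, c(pts, list(width_px = 1920, height_px = 1080)))
  expect_false(isTRUE(all.equal(knee_angle(fr_wide, "left"),
                                knee_angle(fr_no, "left", warn_aspect = FALSE))))
  expect_warning(knee_angle(fr_no, "left"), "normalized coordinates")
})

test_that("a static pose yields a constant series equal to the frame angle", {
  pts <- list(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.55, 0.5),
              LEFT_ANKLE = c(0.7, 0.6), LEFT_FOOT_INDEX = c(0.78, 0.58))
  seq <- make_static_seq(50, pts, width_px = 1080, height_px = 1080)
  one <- knee_angle(do.call(make_frame,
                            c(pts, list(width_px = 1080, height_px = 1080))),
                    "left")
  out <- compute_angle_series(seq, joints = "knee", side = "left")
  expect_lt(max(abs(out$knee$samples$deg - one)), 1e-6)
  expect_true(all(out$knee$samples$origin == "observed"))
})

test_that("pipeline recovers a noiseless synthetic peak and tolerates dropout", {
  spec <- synthetic_motion_spec(joint = "knee", peak_deg = 90, n_reps = 3,
                                fps_hz = 18, seed = 301)
  sim <- simulate_motion(spec)
  out <- compute_angle_series(sim$sequence, joints = "knee", side = "left")
  expect_lt(abs(peak_flexion(out$knee) - 90), 0.5)

  dropped <- degrade_sequence(sim$sequence, 0, 0.2, seed = 302)
  out2 <- compute_angle_series(dropped, joints = "knee", side = "left")
  expect_lt(abs(peak_flexion(out2$knee) - peak_flexion(out$knee)), 2)
  expect_true(any(out2$knee$samples$origin == "interpolated"))
})

test_that("degenerate frames are skipped with a warning, not zeroed", {
  pts <- list(LEFT_HIP = c(0.5, 0.3), LEFT_KNEE = c(0.55, 0.5),
              LEFT_ANKLE = c(0.7, 0.6))
  seq <- make_static_seq(30, pts, width_px = 1080, height_px = 1080)
  seq$landmarks$LEFT_ANKLE$x[10] <- seq$landmarks$LEFT_KNEE$x[10]
  seq$landmarks$LEFT_ANKLE$y[10] <- seq$landmarks$LEFT_KNEE$y[10]
  expect_warning(
    out <- compute_angle_series(seq, joints = "knee", side = "left",
                                filter = NULL),
    "skipped")
  expect_true(all(is.finite(out$knee$samples$deg)))
})
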