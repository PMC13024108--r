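# Fixture builders shared across test files.

# A pose sequence with the given timestamps and one row per frame for each
# landmark in `pts`: a named list of n x 2 matrices (normalized x, y).
make_seq <- function(t, pts, v = 1, ...) {
  lms <- lapply(pts, function(p) {
    p <- matrix(p, ncol = 2)
    data.frame(x = p[, 1], y = p[, 2], v = rep_len(v, nrow(p)))
  })
  pose_sequence(t, lms, ...)
}

# A single static frame, replicated: landmark named vector of c(x, y).
make_static_seq <- function(n, lm_points, ...) {
  t <- seq_len(n) / 20
  pts <- lapply(lm_points, function(p) {
    cbind(rep(p[1], n), rep(p[2], n))
  })
  make_seq(t, pts, ...)
}

# One frame as consumed by hip_angle()/knee_angle()/ankle_angle().
make_frame <- function(..., width_px = NULL, height_px = NULL) {
  lm <- lapply(list(...), function(p) c(x = p[1], y = p[2], v = 1))
  structure(list(t = 0, lm = lm, width_px = width_px, height_px = height_px),
            class = "pose_frame")
}

# Uniform joint-angle series from raw values.
make_angle_series <- function(deg, fs = 20, joint = "knee", side = "left",
                              filtered = TRUE) {
  joint_angle_series(joint, side, t = (seq_along(deg) - 1) / fs, deg,
                     filtered = filtered)
}

# atan2-based signed-angle magnitude: independent oracle for angle_between.
atan2_angle <- function(u, v) {
  a <- atan2(v[2], v[1]) - atan2(u[2], u[1])
  a <- abs((a + pi) %% (2 * pi) - pi)
  a * 180 / pi
}

# Butterworth magnitude response of the designed digital filter at f_hz:
# |B(e^{-iw}) / A(e^{-iw})|, the closed-form oracle for gain tests.
butter_gain_at <- function(order, cutoff_hz, fs_hz, f_hz) {
  ba <- signal::butter(order, cutoff_hz / (fs_hz / 2), "low")
  w <- 2 * pi * f_hz / fs_hz
  z <- exp(-1i * w * (seq_along(ba$b) - 1))
  Mod(sum(ba$b * z) / sum(ba$a * exp(-1i * w * (seq_along(ba$a) - 1))))
}

# Amplitude of the f_hz component of y by quadrature least squares, using
# samples where keep is TRUE (avoids picket-fence bias of max - min).
sine_amplitude <- function(y, t, f_hz, keep = rep(TRUE, length(y))) {
  s <- sin(2 * pi * f_hz * t)[keep]
  c_ <- cos(2 * pi * f_hz * t)[keep]
  fit <- stats::lm(y[keep] ~ s + c_ - 1)
  sqrt(sum(stats::coef(fit)^2))
}

# ICC(A,1) via stats::aov mean squares: the independent two-way ANOVA route.
icc_a1_aov <- function(clinical, algorithm) {
  n <- length(clinical)
  d <- data.frame(y = c(clinical, algorithm),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(c("c", "a"), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

cohort_path <- function() {
  system.file("extdata", "postarthroplasty_cohort.csv", package = "kinemark")
}
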