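# Synthetic motion and paired-measurement generators with known ground truth.
#
# The generator poses a sagittal-plane lower-limb chain (hip fixed;
# thigh/shank/foot segments) driven by a raised-cosine flexion profile, and
# projects the joints to y-down normalized landmark coordinates. Because the
# driving angle is known analytically, the generated sequences serve as an
# end-to-end oracle for the kinematics pipeline.

#' Specify a simulated flexion-extension motion
#'
#' Parameters of a simulated exercise recording: which joint moves, how high
#' each repetition flexes, how many repetitions, the capture rate and its
#' degradations (landmark noise, visibility dropout, frame-interval jitter).
#'
#' @param joint `"knee"` or `"hip"` (the moving joint; the others are held).
#' @param peak_deg Target peak flexion per repetition, in (0, 180).
#' @param n_reps Number of repetitions (default 3, the clinical protocol).
#' @param rep_period_s Duration of one repetition in seconds (default 4).
#' @param fps_hz Nominal capture rate in Hz (default 18, within the 15-20 Hz
#'   range of mobile capture).
#' @param duration_s Total duration; default `n_reps * rep_period_s`.
#' @param noise_sd_norm Gaussian landmark noise sd, normalized units
#'   (default 0).
#' @param dropout_prob Per-frame per-landmark probability of visibility
#'   dropout, in \[0, 1) (default 0).
#' @param jitter_frac Frame-interval jitter as a fraction of the nominal
#'   interval, in \[0, 1) (default 0.1).
#' @param seed Integer seed; all randomness flows from it.
#' @param segment_lengths Named numeric vector `c(thigh=, shank=, foot=)` in
#'   normalized (frame-height) units; defaults 0.22/0.20/0.07, plausible
#'   on-screen proportions for full-body capture at ~2.5 m.
#' @return Object of class `synthetic_motion_spec`.
#' @export
synthetic_motion_spec <- function(joint = c("knee", "hip"), peak_deg = 90,
                                  n_reps = 3, rep_period_s = 4, fps_hz = 18,
                                  duration_s = NULL, noise_sd_norm = 0,
                                  dropout_prob = 0, jitter_frac = 0.1,
                                  seed = 1L,
                                  segment_lengths = c(thigh = 0.22,
                                                      shank = 0.20,
                                                      foot = 0.07)) {
  joint <- match.arg(joint)
  if (peak_deg <= 0 || peak_deg >= 180) stop("peak_deg must be in (0, 180)", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (rep_period_s <= 0) stop("rep_period_s must be positive", call. = FALSE)
  if (fps_hz <= 0) stop("fps_hz must be positive", call. = FALSE)
  if (noise_sd_norm < 0) stop("noise_sd_norm must be non-negative", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  if (jitter_frac < 0 || jitter_frac >= 1) {
    stop("jitter_frac must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(duration_s)) duration_s <- n_reps * rep_period_s
  structure(list(joint = joint, peak_deg = peak_deg, n_reps = n_reps,
                 rep_period_s = rep_period_s, fps_hz = fps_hz,
                 duration_s = duration_s, noise_sd_norm = noise_sd_norm,
                 dropout_prob = dropout_prob, jitter_frac = jitter_frac,
                 seed = as.integer(seed), segment_lengths = segment_lengths),
            class = "synthetic_motion_spec")
}

# Raised-cosine repetition profile: 0 -> peak -> 0 each period, C1-smooth so
# a 6 Hz low-pass filter passes it essentially unchanged.
raised_cosine_profile <- function(t, peak_deg, period_s) {
  peak_deg * 0.5 * (1 - cos(2 * pi * (t %% period_s) / period_s))
}

# Chain geometry in a "height-unit" plane (1 unit = frame height), converted
# to normalized coordinates by dividing x by the aspect ratio. All angles are
# preserved by that projection because the kinematics aspect-corrects back.
chain_landmarks <- function(spec, phi) {
  L <- spec$segment_lengths
  hip_u <- c(0.80, 0.35)
  if (spec$joint == "knee") {
    thigh_dir <- matrix(c(0, 1), nrow = length(phi), ncol = 2, byrow = TRUE)
    shank_dir <- cbind(sinpi(phi / 180), cospi(phi / 180))
    foot_dir <- cbind(cospi(phi / 180), -sinpi(phi / 180))
  } else {
    thigh_dir <- cbind(sinpi(phi / 180), cospi(phi / 180))
    shank_dir <- thigh_dir
    foot_dir <- cbind(cospi(phi / 180), -sinpi(phi / 180))
  }
  hip <- matrix(hip_u, nrow = length(phi), ncol = 2, byrow = TRUE)
  knee <- hip + L[["thigh"]] * thigh_dir
  ankle <- knee + L[["shank"]] * shank_dir
  toe <- ankle + L[["foot"]] * foot_dir
  list(HIP = hip, KNEE = knee, ANKLE = ankle, FOOT_INDEX = toe)
}

#' Simulate a landmark sequence with known kinematic ground truth
#'
#' Generates a [pose_sequence()] of left-side lower-limb landmarks for the
#' motion described by `spec`, plus the analytic ground truth: the driving
#' joint-angle series at the generated timestamps and the per-repetition
#' peak angles. Landmark noise and visibility dropout (if any) are applied
#' via [degrade_sequence()]; all randomness derives from `spec$seed`.
#'
#' Frame size is 1920 x 1080 px; landmarks are stored y-down normalized, and
#' the geometry is constructed in the aspect-corrected plane so that angles
#' recomputed by the kinematics module equal the driving profile exactly
#' (noiseless case).
#'
#' @param spec A [synthetic_motion_spec()].
#' @return List with `sequence` (a `pose_sequence`) and `truth` (list:
#'   `t`, `angle_deg` — flexion convention —, `rep_peaks_deg`, `spec`).
#' @export
simulate_motion <- function(spec) {
  stopifnot(inherits(spec, "synthetic_motion_spec"))
  width_px <- 1920; height_px <- 1080
  aspect <- width_px / height_px
  withr::with_seed(spec$seed, {
    dt0 <- 1 / spec$fps_hz
    n_nom <- ceiling(spec$duration_s * spec$fps_hz) + 1L
    jit <- if (spec$jitter_frac > 0) {
      runif(n_nom, -spec$jitter_frac, spec$jitter_frac)
    } else rep(0, n_nom)
    t <- cumsum(dt0 * (1 + jit)) - dt0 * (1 + jit[1])
    t <- t[t <= spec$duration_s + 1e-12]
    phi <- raised_cosine_profile(t, spec$peak_deg, spec$rep_period_s)
    pts <- chain_landmarks(spec, phi)
    lms <- lapply(pts, function(p) {
      x <- p[, 1] / aspect; y <- p[, 2]
      if (any(x < 0 | x > 1 | y < 0 | y > 1)) {
        stop("infeasible geometry: a landmark leaves the frame; ",
             "reduce peak_deg or segment lengths", call. = FALSE)
      }
      data.frame(x = x, y = y, v = rep(1, length(x)))
    })
    names(lms) <- paste0("LEFT_", names(pts))
    seq <- pose_sequence(t, lms, width_px = width_px, height_px = height_px,
                         fps = spec$fps_hz,
                         metadata = list(side = "left", generator = "kinemark",
                                         joint = spec$joint))
    if (spec$noise_sd_norm > 0 || spec$dropout_prob > 0) {
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      seq <- degrade_sequence(seq, spec$noise_sd_norm, spec$dropout_prob,
                              seed = sub_seed)
    }
    n_full <- floor(spec$duration_s / spec$rep_period_s + 1e-9)
    truth <- list(t = t, angle_deg = phi,
                  rep_peaks_deg = rep(spec$peak_deg, min(spec$n_reps, n_full)),
                  spec = spec)
    list(sequence = seq, truth = truth)
  })
}

#' Degrade a landmark sequence with noise and dropout
#'
#' Adds independent Gaussian noise (sd `noise_sd_norm`, normalized units) to
#' every landmark coordinate and applies Bernoulli visibility dropout
#' (visibility set to 0) with probability `dropout_prob` per frame and
#' landmark. Timestamps are untouched.
#'
#' @param seq A [pose_sequence()].
#' @param noise_sd_norm Non-negative noise sd in normalized units.
#' @param dropout_prob Dropout probability in \[0, 1).
#' @param seed Integer seed.
#' @return A degraded [pose_sequence()].
#' @export
degrade_sequence <- function(seq, noise_sd_norm = 0, dropout_prob = 0,
                             seed = 1L) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (noise_sd_norm < 0) stop("noise_sd_norm must be non-negative", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    n <- length(seq$t)
    for (nm in names(seq$landmarks)) {
      d <- seq$landmarks[[nm]]
      if (noise_sd_norm > 0) {
        d$x <- d$x + rnorm(n, 0, noise_sd_norm)
        d$y <- d$y + rnorm(n, 0, noise_sd_norm)
      }
      if (dropout_prob > 0) {
        drop <- runif(n) < dropout_prob
        d$v[drop] <- 0
      }
      seq$landmarks[[nm]] <- d
    }
    seq
  })
}

#' Simulate paired measurements from a two-way random-effects model
#'
#' Generates an n-subject table under
#' `value_ij = mu + subject_i + offset_j + e_ij` with
#' `subject_i ~ N(0, subject_sd^2)` and `e_ij ~ N(0, error_sd^2)`; rater 1
#' (clinical) has offset 0 and rater 2 (algorithm) offset `rater_offset`.
#' The population single-measure absolute-agreement ICC of this model,
#' `subject_sd^2 / (subject_sd^2 + rater_offset^2 / 2 + error_sd^2)`
#' (the rater term entering through the k - 1 = 1 denominator of the
#' column variance), is echoed in the result's attributes.
#'
#' @param n_subjects Number of subjects, >= 3.
#' @param mu Grand mean in degrees (default 90).
#' @param subject_sd Between-subject sd (degrees).
#' @param rater_offset Systematic algorithm-minus-clinical offset (degrees).
#' @param error_sd Residual sd per measurement (degrees).
#' @param seed Integer seed.
#' @return A [paired_measurements()] data frame with attribute
#'   `population_icc_a1`.
#' @export
simulate_two_way_table <- function(n_subjects, mu = 90, subject_sd = 9,
                                   rater_offset = 0, error_sd = 3, seed = 1L) {
  if (n_subjects < 3L) stop("n_subjects must be >= 3", call. = FALSE)
  if (subject_sd < 0 || error_sd < 0) stop("sds must be non-negative", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    s <- rnorm(n_subjects, 0, subject_sd)
    clinical <- mu + s + rnorm(n_subjects, 0, error_sd)
    algorithm <- mu + rater_offset + s + rnorm(n_subjects, 0, error_sd)
    out <- paired_measurements(seq_len(n_subjects), clinical, algorithm)
    attr(out, "population_icc_a1") <-
      subject_sd^2 / (subject_sd^2 + rater_offset^2 / 2 + error_sd^2)
    attr(out, "model") <- list(mu = mu, subject_sd = subject_sd,
                               rater_offset = rater_offset, error_sd = error_sd)
    out
  })
}
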