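# Per-frame joint angles from landmark vectors.
#
# Coordinate convention (stated because every sign ambiguity flows from it):
# origin top-left, x rightward, y increasing DOWNWARD — the pose-estimator
# standard for normalized image coordinates. The "vertical axis" (0, -1) used
# as the hip reference therefore points up-image.

DEGENERATE_EPS <- 1e-9

#' Angle between two 2D vectors (degrees)
#'
#' The dot-product formula:
#' `theta = arccos(clamp(u . v / (|u| |v|), -1, 1)) * 180 / pi`,
#' always in \[0, 180\]. The normalized dot product is clamped to \[-1, 1\] so
#' rounding can never produce `NaN` from `arccos`.
#'
#' @param u,v Numeric length-2 vectors `(dx, dy)`; must have norm > 1e-9.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != 2L || length(v) != 2L) {
    stop("u and v must be length-2 vectors", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu <= DEGENERATE_EPS || nv <= DEGENERATE_EPS) {
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  }
  c_ <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, c_))) * 180 / pi
}

# Landmark point for one side, aspect-corrected when frame dimensions are
# known: normalized (x, y) mapped to (x * width, y * height) so angles are
# measured in the true image plane rather than the distorted unit square.
frame_point <- function(frame, base, side, warn_aspect = TRUE) {
  nm <- paste0(toupper(side), "_", base)
  p <- frame$lm[[nm]]
  if (is.null(p) || !is.finite(p[["x"]]) || !is.finite(p[["y"]])) {
    stop(sprintf("missing landmark %s at t = %g s", nm, frame$t), call. = FALSE)
  }
  if (!is.null(frame$width_px) && !is.null(frame$height_px)) {
    c(p[["x"]] * frame$width_px, p[["y"]] * frame$height_px)
  } else {
    if (warn_aspect) {
      warning("frame dimensions unknown; using raw normalized coordinates ",
              "(angles distorted for non-square frames)", call. = FALSE)
    }
    c(p[["x"]], p[["y"]])
  }
}

#' Hip angle from a single frame
#'
#' Angle between the thigh vector (Hip to Knee) and the fixed vertical axis
#' `(0, -1)`. Two conventions are offered because the raw arccos output is
#' referenced to *up-image* in y-down coordinates:
#' * `raw_eq1` — the verbatim arccos value: 180 deg for a thigh pointing
#'   down-image (standing), 0 for a thigh pointing up-image.
#' * `flexion` — `180 - raw`: 0 deg at upright posture, increasing with hip
#'   flexion, the clinically natural reading.
#'
#' @param frame A `pose_frame` from [get_frame()].
#' @param side `"left"` or `"right"`.
#' @param convention `"raw_eq1"` (default) or `"flexion"`.
#' @param warn_aspect Warn when frame dimensions are unknown and raw
#'   normalized coordinates are used.
#' @return Angle in degrees.
#' @export
hip_angle <- function(frame, side = c("left", "right"),
                      convention = c("raw_eq1", "flexion"),
                      warn_aspect = TRUE) {
  side <- match.arg(side); convention <- match.arg(convention)
  hip <- frame_point(frame, "HIP", side, warn_aspect)
  knee <- frame_point(frame, "KNEE", side, warn_aspect = FALSE)
  raw <- angle_between(knee - hip, c(0, -1))
  if (convention == "flexion") 180 - raw else raw
}

#' Knee angle from a single frame
#'
#' Angle between the thigh vector (Hip to Knee) and the shank vector (Knee to
#' Ankle): the flexion/extension of the knee joint. 0 deg is a straight leg.
#'
#' @inheritParams hip_angle
#' @return Angle in degrees in \[0, 180\].
#' @export
knee_angle <- function(frame, side = c("left", "right"), warn_aspect = TRUE) {
  side <- match.arg(side)
  hip <- frame_point(frame, "HIP", side, warn_aspect)
  knee <- frame_point(frame, "KNEE", side, warn_aspect = FALSE)
  ankle <- frame_point(frame, "ANKLE", side, warn_aspect = FALSE)
  angle_between(knee - hip, ankle - knee)
}

#' Ankle angle from a single frame
#'
#' Angle between the shank vector (Knee to Ankle) and the foot vector (Ankle
#' to Toe): dorsiflexion/plantarflexion. 0 deg is a foot collinear with the
#' shank.
#'
#' @inheritParams hip_angle
#' @return Angle in degrees in \[0, 180\].
#' @export
ankle_angle <- function(frame, side = c("left", "right"), warn_aspect = TRUE) {
  side <- match.arg(side)
  knee <- frame_point(frame, "KNEE", side, warn_aspect)
  ankle <- frame_point(frame, "ANKLE", side, warn_aspect = FALSE)
  toe <- frame_point(frame, "FOOT_INDEX", side, warn_aspect = FALSE)
  angle_between(ankle - knee, toe - ankle)
}

joint_required_landmarks <- function(joint, side) {
  base <- switch(joint,
                 hip = c("HIP", "KNEE"),
                 knee = c("HIP", "KNEE", "ANKLE"),
                 ankle = c("KNEE", "ANKLE", "FOOT_INDEX"))
  paste0(toupper(side), "_", base)
}

#' Compute joint-angle series from a pose sequence
#'
#' The full kinematics pipeline: fill landmark gaps by linear interpolation,
#' compute the per-frame joint angle(s), resample onto a uniform grid, and
#' (optionally) apply a Butterworth low-pass filter. Samples whose landmarks
#' were gap-filled carry `origin = "interpolated"`. Frames with degenerate
#' geometry (coincident landmarks) are skipped with a warning rather than
#' emitted as spurious zeros.
#'
#' @param seq A [pose_sequence()].
#' @param joints Character vector from `c("hip", "knee", "ankle")`.
#' @param side `"left"` or `"right"`.
#' @param convention Hip angle convention, `"raw_eq1"` or `"flexion"` (knee
#'   and ankle are unaffected).
#' @param filter `NULL` for no filtering, `TRUE` for the default 4th-order
#'   6 Hz zero-phase Butterworth at the resampling rate, or a [filter_spec()].
#' @param fs_hz Uniform resampling rate; default (`NULL`) is the median
#'   observed frame rate, which minimizes interpolation distortion for
#'   variable 15-20 Hz capture.
#' @param visibility_threshold Landmark missingness cutoff (default 0.5).
#' @return Named list of [joint_angle_series()], one per requested joint.
#' @export
compute_angle_series <- function(seq, joints = c("hip", "knee", "ankle"),
                                 side = c("left", "right"),
                                 convention = c("raw_eq1", "flexion"),
                                 filter = TRUE, fs_hz = NULL,
                                 visibility_threshold = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  joints <- match.arg(joints, several.ok = TRUE)
  side <- match.arg(side)
  convention <- match.arg(convention)
  needed <- unique(unlist(lapply(joints, joint_required_landmarks, side = side)))
  seq <- interpolate_gaps(seq, needed, visibility_threshold)
  if (is.null(fs_hz)) {
    fs_hz <- if (length(seq$t) > 1L) 1 / median(diff(seq$t)) else stop(
      "cannot infer sampling rate from a single frame", call. = FALSE)
  }
  fspec <- NULL
  if (inherits(filter, "filter_spec")) {
    fspec <- filter
  } else if (isTRUE(filter)) {
    fspec <- filter_spec(order = 4, cutoff_hz = 6, fs_hz = fs_hz)
  }
  warn_aspect <- is.null(seq$width_px) || is.null(seq$height_px)
  if (warn_aspect) {
    warning("frame dimensions unknown; angles computed on raw normalized ",
            "coordinates", call. = FALSE)
  }
  # per-frame interpolation provenance: TRUE if any needed landmark was filled
  interp_any <- rep(FALSE, length(seq$t))
  for (nm in needed) {
    ip <- seq$landmarks[[nm]]$interp
    if (!is.null(ip)) interp_any <- interp_any | ip
  }
  out <- list()
  for (joint in joints) {
    fn <- switch(joint, hip = function(fr) hip_angle(fr, side, convention,
                                                     warn_aspect = FALSE),
                 knee = function(fr) knee_angle(fr, side, warn_aspect = FALSE),
                 ankle = function(fr) ankle_angle(fr, side, warn_aspect = FALSE))
    deg <- rep(NA_real_, length(seq$t))
    for (i in seq_along(seq$t)) {
      deg[i] <- tryCatch(fn(get_frame(seq, i)), error = function(e) {
        warning(sprintf("%s %s, frame %d (t = %g s): %s — frame skipped",
                        side, joint, i, seq$t[i], conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
    }
    keep <- !is.na(deg)
    if (sum(keep) < 2L) {
      stop("fewer than 2 computable frames for ", joint, call. = FALSE)
    }
    origin <- ifelse(interp_any[keep], "interpolated", "observed")
    ser <- joint_angle_series(joint, side, seq$t[keep], deg[keep], origin,
                              convention = convention)
    if (!is.null(fspec)) {
      ser <- filter_angle_series(ser, fspec)
    } else {
      rs <- resample_uniform(ser$samples$t, ser$samples$deg, fs_hz)
      ofrac <- approx(ser$samples$t,
                      as.numeric(ser$samples$origin == "interpolated"),
                      xout = rs$t, method = "linear", rule = 2)$y
      ser <- joint_angle_series(joint, side, rs$t, rs$values,
                                ifelse(ofrac > 1e-12, "interpolated", "observed"),
                                convention = convention)
    }
    out[[joint]] <- ser
  }
  out
}
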