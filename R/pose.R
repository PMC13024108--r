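#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom stats approx median sd lm coef pf qf pt cor rnorm runif rbinom
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics abline plot points
## usethis namespace: end
NULL

# Fixed lower-limb landmark vocabulary: the subset of the standard 33-landmark
# pose topology this pipeline consumes (indices 23-28, 31-32).
LOWER_LIMB_LANDMARKS <- c(
  "LEFT_HIP", "RIGHT_HIP",
  "LEFT_KNEE", "RIGHT_KNEE",
  "LEFT_ANKLE", "RIGHT_ANKLE",
  "LEFT_FOOT_INDEX", "RIGHT_FOOT_INDEX"
)

#' Lower-limb landmark vocabulary
#'
#' The eight landmark names this package recognises: `HIP`, `KNEE`, `ANKLE`
#' and `FOOT_INDEX` on each of the `LEFT` and `RIGHT` sides, matching the
#' lower-limb subset of the standard 33-landmark pose topology. Landmarks with
#' other names are tolerated in input files but ignored by the kinematics.
#'
#' @return Character vector of the eight landmark names.
#' @export
landmark_vocabulary <- function() LOWER_LIMB_LANDMARKS

#' Construct a pose-landmark sequence
#'
#' A `pose_sequence` holds an ordered series of video frames, each carrying a
#' timestamp and named 2D landmarks in normalized image coordinates (origin
#' top-left, `x` a fraction of frame width, `y` a fraction of frame height
#' increasing *downward*) together with a per-landmark visibility confidence
#' in \[0, 1\]. It is the raw input to the kinematics pipeline.
#'
#' Landmarks are stored column-wise: `landmarks` is a named list with one
#' entry per landmark name, each a data frame with columns `x`, `y`, `v` and
#' one row per frame. A landmark absent from a frame is represented by an
#' `NA` row (visibility 0).
#'
#' @param t Numeric vector of frame timestamps in seconds, strictly
#'   increasing, non-negative.
#' @param landmarks Named list of data frames (columns `x`, `y`, `v`), one per
#'   landmark, each with `length(t)` rows. Names outside
#'   [landmark_vocabulary()] are moved to `metadata$extra_landmarks` and
#'   ignored downstream.
#' @param width_px,height_px Optional positive integers: source frame size in
#'   pixels, used for aspect correction in angle computation.
#' @param fps Optional nominal capture rate in Hz.
#' @param metadata Free-form named list (subject id, side, exercise, ...).
#'
#' @return An object of class `pose_sequence`.
#' @seealso [read_pose_json()], [validate_sequence()], [compute_angle_series()]
#' @export
pose_sequence <- function(t, landmarks, width_px = NULL, height_px = NULL,
                          fps = NULL, metadata = list()) {
  t <- as.numeric(t)
  if (length(t) < 1L) stop("pose_sequence needs at least one frame", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t))) stop("timestamps must be finite", call. = FALSE)
  if (any(t < 0)) stop("timestamps must be non-negative", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.list(landmarks) || is.null(names(landmarks))) {
    stop("landmarks must be a named list of data frames", call. = FALSE)
  }
  known <- names(landmarks) %in% LOWER_LIMB_LANDMARKS
  extra <- landmarks[!known]
  landmarks <- landmarks[known]
  landmarks <- lapply(landmarks, function(lm) {
    lm <- as.data.frame(lm)
    if (!all(c("x", "y", "v") %in% names(lm))) {
      stop("each landmark table needs columns x, y, v", call. = FALSE)
    }
    if (nrow(lm) != length(t)) {
      stop("landmark table rows must match number of frames", call. = FALSE)
    }
    lm <- lm[c("x", "y", "v")]
    lm$v[is.na(lm$v)] <- 0
    if (any(lm$v < 0 | lm$v > 1)) {
      stop("visibility must lie in [0, 1]", call. = FALSE)
    }
    lm
  })
  for (dim_arg in list(width_px = width_px, height_px = height_px)) {
    if (!is.null(dim_arg) && (!is.numeric(dim_arg) || dim_arg <= 0)) {
      stop("frame dimensions must be positive", call. = FALSE)
    }
  }
  if (length(extra)) metadata$extra_landmarks <- names(extra)
  structure(
    list(t = t, landmarks = landmarks,
         width_px = if (is.null(width_px)) NULL else as.numeric(width_px),
         height_px = if (is.null(height_px)) NULL else as.numeric(height_px),
         fps = if (is.null(fps)) NULL else as.numeric(fps),
         metadata = metadata),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf("<pose_sequence> %d frames over %.2f s (%s landmarks: %s)\n",
              length(x$t), dur, length(x$landmarks),
              paste(names(x$landmarks), collapse = ", ")))
  if (!is.null(x$fps)) cat(sprintf("  nominal fps: %g Hz\n", x$fps))
  if (!is.null(x$width_px)) {
    cat(sprintf("  frame: %g x %g px\n", x$width_px, x$height_px))
  }
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A [pose_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  length(seq$t)
}

#' Extract a single frame from a pose sequence
#'
#' @param seq A [pose_sequence()].
#' @param i Frame index (1-based).
#' @return A `pose_frame`: list with `t` (seconds), `lm` (named list of
#'   `c(x, y, v)` vectors), and the sequence's `width_px`/`height_px`.
#' @export
get_frame <- function(seq, i) {
  stopifnot(inherits(seq, "pose_sequence"))
  i <- as.integer(i)
  if (i < 1L || i > length(seq$t)) stop("frame index out of range", call. = FALSE)
  lm <- lapply(seq$landmarks, function(d) c(x = d$x[i], y = d$y[i], v = d$v[i]))
  structure(list(t = seq$t[i], lm = lm,
                 width_px = seq$width_px, height_px = seq$height_px),
            class = "pose_frame")
}

# Validity mask: TRUE where a landmark is usable in a frame. A landmark is
# missing when its coordinates are absent/non-finite or its visibility falls
# below the threshold; frames filled by interpolation are usable.
landmark_valid <- function(seq, name, visibility_threshold = 0.5) {
  d <- seq$landmarks[[name]]
  if (is.null(d)) return(rep(FALSE, length(seq$t)))
  ok <- is.finite(d$x) & is.finite(d$y) & d$v >= visibility_threshold
  if (!is.null(d$interp)) ok <- ok | (d$interp & is.finite(d$x) & is.finite(d$y))
  ok
}

#' Report missing-frame counts per required landmark
#'
#' Counts, for each required landmark, the frames in which it is absent or its
#' visibility falls below `visibility_threshold`. Reporting only; the input is
#' never modified.
#'
#' @param seq A [pose_sequence()].
#' @param required Character vector of landmark names to check; must be drawn
#'   from [landmark_vocabulary()].
#' @param visibility_threshold Visibility below which a landmark counts as
#'   missing (default 0.5).
#' @return Data frame with columns `landmark`, `missing_frames`, `n_frames`.
#' @export
validate_sequence <- function(seq, required = landmark_vocabulary(),
                              visibility_threshold = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  bad <- setdiff(required, LOWER_LIMB_LANDMARKS)
  if (length(bad)) {
    stop("required landmark(s) not in vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(seq$t)
  miss <- vapply(required, function(nm) {
    sum(!landmark_valid(seq, nm, visibility_threshold))
  }, integer(1))
  data.frame(landmark = required, missing_frames = miss, n_frames = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a joint-angle time series
#'
#' A `joint_angle_series` holds per-frame joint angles in degrees for one
#' joint and side, with a provenance flag per sample (`observed` for angles
#' computed purely from detected landmarks, `interpolated` where gap filling
#' or resampling contributed) and a record of any low-pass filtering applied.
#'
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param side One of `"left"`, `"right"`.
#' @param t Numeric timestamps in seconds, strictly increasing.
#' @param value_deg Angles in degrees, each in \[0, 180\] (the arccos range).
#' @param origin Character vector, each `"observed"` or `"interpolated"`.
#' @param filtered Logical: has a low-pass filter been applied?
#' @param filter_spec Optional [filter_spec()] describing the filter.
#' @param convention Angle convention: `"raw_eq1"` (verbatim arccos output) or
#'   `"flexion"` (180 minus raw; hip only). See [hip_angle()].
#' @return Object of class `joint_angle_series` with a `samples` data frame
#'   (columns `t`, `deg`, `origin`).
#' @export
joint_angle_series <- function(joint, side, t, value_deg,
                               origin = "observed", filtered = FALSE,
                               filter_spec = NULL, convention = "raw_eq1") {
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  side <- match.arg(side, c("left", "right"))
  convention <- match.arg(convention, c("raw_eq1", "flexion"))
  t <- as.numeric(t); value_deg <- as.numeric(value_deg)
  if (length(t) != length(value_deg)) stop("t and value_deg lengths differ", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  origin <- rep_len(as.character(origin), length(t))
  if (!all(origin %in% c("observed", "interpolated"))) {
    stop("origin must be 'observed' or 'interpolated'", call. = FALSE)
  }
  # unfiltered samples are arccos output and must sit in [0, 180]; filtering
  # may overshoot marginally at the boundaries, tolerated to 1e-6
  tol <- if (filtered) 1e-6 else 0
  if (any(value_deg < -tol | value_deg > 180 + tol)) {
    if (!filtered) stop("angle values must lie in [0, 180] degrees", call. = FALSE)
  }
  structure(
    list(joint = joint, side = side,
         samples = data.frame(t = t, deg = value_deg, origin = origin,
                              stringsAsFactors = FALSE),
         filtered = isTRUE(filtered), filter_spec = filter_spec,
         convention = convention),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s %s (%s), %d samples%s\n",
              x$side, x$joint, x$convention, nrow(x$samples),
              if (x$filtered) ", filtered" else ""))
  if (nrow(x$samples)) {
    cat(sprintf("  range: %.2f..%.2f deg over %.2f s\n",
                min(x$samples$deg), max(x$samples$deg),
                diff(range(x$samples$t))))
  }
  invisible(x)
}

# ---- JSON I/O --------------------------------------------------------------
#
# Landmark schema (UTF-8, fixed key order):
#   {"fps": f|null, "width_px": i|null, "height_px": i|null,
#    "metadata": {...},
#    "frames": [{"t": f, "lm": {"LEFT_HIP": {"x": f, "y": f, "v": f}, ...}}]}
# Angle schema: a JSON array of
#   {"joint": s, "side": s, "convention": s, "filtered": b,
#    "samples": [{"t": f, "deg": f, "origin": s}]}

#' Read a pose-landmark JSON file
#'
#' Parses the documented landmark schema into a validated [pose_sequence()].
#' Landmark names outside [landmark_vocabulary()] are recorded in
#' `metadata$extra_landmarks` and ignored downstream. Invariant violations
#' (non-increasing timestamps, visibility outside \[0, 1\], non-finite
#' coordinates on a visible landmark) are rejected with errors naming the
#' offending field.
#'
#' @param path Path to a JSON file in the landmark schema.
#' @return A [pose_sequence()].
#' @export
read_pose_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(obj$frames) || !length(obj$frames)) {
    stop("field 'frames' missing or empty", call. = FALSE)
  }
  frames <- obj$frames
  t <- vapply(frames, function(fr) {
    if (is.null(fr$t) || !is.numeric(fr$t)) {
      stop("frame field 't' missing or non-numeric", call. = FALSE)
    }
    as.numeric(fr$t)
  }, numeric(1))
  all_names <- unique(unlist(lapply(frames, function(fr) names(fr$lm))))
  landmarks <- lapply(all_names, function(nm) {
    xs <- ys <- vs <- rep(NA_real_, length(frames))
    for (i in seq_along(frames)) {
      p <- frames[[i]]$lm[[nm]]
      if (!is.null(p)) {
        xs[i] <- if (is.null(p$x)) NA_real_ else as.numeric(p$x)
        ys[i] <- if (is.null(p$y)) NA_real_ else as.numeric(p$y)
        vs[i] <- if (is.null(p$v)) NA_real_ else as.numeric(p$v)
        if (!is.na(vs[i]) && (vs[i] < 0 || vs[i] > 1)) {
          stop(sprintf("landmark '%s' frame %d: field 'v' = %g outside [0, 1]",
                       nm, i, vs[i]), call. = FALSE)
        }
        if (!is.na(vs[i]) && vs[i] >= 0.5 && (!is.finite(xs[i]) || !is.finite(ys[i]))) {
          stop(sprintf("landmark '%s' frame %d: non-finite coordinates on visible landmark",
                       nm, i), call. = FALSE)
        }
      }
    }
    vs[is.na(vs)] <- 0
    data.frame(x = xs, y = ys, v = vs)
  })
  names(landmarks) <- all_names
  metadata <- if (is.null(obj$metadata)) list() else obj$metadata
  pose_sequence(
    t = t, landmarks = landmarks,
    width_px = obj$width_px, height_px = obj$height_px,
    fps = obj$fps, metadata = metadata
  )
}

#' Write a pose sequence to the landmark JSON schema
#'
#' Deterministic serialization with fixed key order; numeric fields survive a
#' read/write round trip to better than 1e-9.
#'
#' @param seq A [pose_sequence()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pose_json <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  frames <- lapply(seq_along(seq$t), function(i) {
    lm <- list()
    for (nm in sort(names(seq$landmarks))) {
      d <- seq$landmarks[[nm]]
      if (is.finite(d$x[i]) || is.finite(d$y[i]) || d$v[i] > 0) {
        lm[[nm]] <- list(x = d$x[i], y = d$y[i], v = d$v[i])
      }
    }
    list(t = seq$t[i], lm = lm)
  })
  meta <- seq$metadata
  meta$extra_landmarks <- NULL
  obj <- list(fps = seq$fps, width_px = seq$width_px, height_px = seq$height_px,
              metadata = meta, frames = frames)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = FALSE)
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Write joint-angle series to the angle JSON schema
#'
#' Serializes one or more [joint_angle_series()] objects as a JSON array with
#' fixed key order. Read-back with [read_angles_json()] reproduces all numeric
#' fields to better than 1e-9 degrees.
#'
#' @param series A single `joint_angle_series` or a (non-empty) list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_angles_json <- function(series, path) {
  if (inherits(series, "joint_angle_series")) series <- list(series)
  if (!is.list(series) || !length(series)) {
    stop("'series' must be a non-empty list of joint_angle_series", call. = FALSE)
  }
  if (!all(vapply(series, inherits, logical(1), "joint_angle_series"))) {
    stop("all elements must be joint_angle_series objects", call. = FALSE)
  }
  objs <- lapply(series, function(s) {
    samples <- lapply(seq_len(nrow(s$samples)), function(i) {
      list(t = s$samples$t[i], deg = s$samples$deg[i],
           origin = s$samples$origin[i])
    })
    list(joint = s$joint, side = s$side, convention = s$convention,
         filtered = s$filtered, samples = samples)
  })
  json <- jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read joint-angle series from the angle JSON schema
#'
#' @param path Path to a file written by [write_angles_json()].
#' @return A list of [joint_angle_series()] objects, named by
#'   `"<joint>_<side>"`.
#' @export
read_angles_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(objs, function(o) {
    if (is.null(o$joint) || is.null(o$samples)) {
      stop("angle JSON missing 'joint' or 'samples'", call. = FALSE)
    }
    t <- vapply(o$samples, function(s) as.numeric(s$t), numeric(1))
    deg <- vapply(o$samples, function(s) as.numeric(s$deg), numeric(1))
    origin <- vapply(o$samples, function(s) as.character(s$origin), character(1))
    joint_angle_series(o$joint, o$side, t, deg, origin,
                       filtered = isTRUE(o$filtered),
                       convention = o$convention)
  })
  names(out) <- vapply(out, function(s) paste(s$joint, s$side, sep = "_"),
                       character(1))
  out
}
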