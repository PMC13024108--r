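# Gap detection/filling, uniform resampling, Butterworth smoothing.

#' Detect runs of missing frames for a landmark
#'
#' A landmark is missing in a frame when it is absent or its visibility falls
#' below `visibility_threshold`. Maximal runs of missing frames are reported
#' with the indices of the bracketing valid frames where those exist; leading
#' and trailing runs have `NA` on the open side.
#'
#' @param seq A [pose_sequence()].
#' @param landmark A name from [landmark_vocabulary()].
#' @param visibility_threshold Missingness cutoff (default 0.5).
#' @return Data frame with columns `landmark`, `start_index`, `end_index`,
#'   `left_valid`, `right_valid` (frame indices, 1-based; `NA` = unbracketed).
#'   Zero rows when nothing is missing.
#' @export
detect_gaps <- function(seq, landmark, visibility_threshold = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!landmark %in% LOWER_LIMB_LANDMARKS) {
    stop("landmark not in vocabulary: ", landmark, call. = FALSE)
  }
  ok <- landmark_valid(seq, landmark, visibility_threshold)
  r <- rle(!ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  if (!length(gi)) {
    return(data.frame(landmark = character(), start_index = integer(),
                      end_index = integer(), left_valid = integer(),
                      right_valid = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    landmark = landmark,
    start_index = starts[gi],
    end_index = ends[gi],
    left_valid = ifelse(starts[gi] > 1L, starts[gi] - 1L, NA_integer_),
    right_valid = ifelse(ends[gi] < length(ok), ends[gi] + 1L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Fill missing landmark frames by linear interpolation
#'
#' Bracketed gaps are filled per coordinate by straight-line interpolation in
#' timestamp: the last valid coordinate is connected to the next available one
#' and intermediate frames take proportionally distributed values,
#' `v(t) = v0 + (v1 - v0) * (t - t0) / (t1 - t0)`. Unbracketed leading and
#' trailing gaps are filled by holding the nearest valid value constant.
#' Observed frames are never modified; filled frames are flagged so that
#' downstream angle samples inherit `origin = "interpolated"`. The operation
#' is idempotent.
#'
#' @param seq A [pose_sequence()].
#' @param landmarks Landmark names to fill; defaults to every vocabulary
#'   landmark present in `seq`.
#' @param visibility_threshold Missingness cutoff (default 0.5).
#' @return A [pose_sequence()] with gaps filled.
#' @export
interpolate_gaps <- function(seq, landmarks = NULL, visibility_threshold = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (is.null(landmarks)) {
    landmarks <- intersect(names(seq$landmarks), LOWER_LIMB_LANDMARKS)
  }
  for (nm in landmarks) {
    if (is.null(seq$landmarks[[nm]])) {
      stop("unusable landmark '", nm, "': absent from sequence", call. = FALSE)
    }
    d <- seq$landmarks[[nm]]
    ok <- landmark_valid(seq, nm, visibility_threshold)
    if (sum(ok) < 2L) {
      stop("unusable landmark '", nm, "': fewer than 2 valid frames",
           call. = FALSE)
    }
    if (all(ok)) next
    tv <- seq$t[ok]
    # rule = 2: hold nearest valid value across unbracketed leading/trailing runs
    d$x[!ok] <- approx(tv, d$x[ok], xout = seq$t[!ok], method = "linear",
                       rule = 2)$y
    d$y[!ok] <- approx(tv, d$y[ok], xout = seq$t[!ok], method = "linear",
                       rule = 2)$y
    interp <- if (is.null(d$interp)) rep(FALSE, length(ok)) else d$interp
    interp[!ok] <- TRUE
    d$interp <- interp
    seq$landmarks[[nm]] <- d
  }
  seq
}

#' Butterworth filter specification
#'
#' Parameters for the low-pass smoothing applied to joint-angle series:
#' filter order, cutoff frequency, sampling rate, and whether the filter is
#' applied forward-backward (`zero_phase`, no phase lag, squared magnitude
#' response) or single-pass (`causal`, as in a streaming deployment).
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz Low-pass cutoff in Hz (default 6); must be below the
#'   Nyquist frequency `fs_hz / 2`.
#' @param fs_hz Sampling rate of the (uniform) series in Hz.
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 6, fs_hz,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (!is.numeric(order) || order < 1 || order != round(order)) {
    stop("order must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) {
    stop("cutoff_hz must be positive", call. = FALSE)
  }
  if (missing(fs_hz) || !is.numeric(fs_hz) || fs_hz <= 0) {
    stop("fs_hz must be positive", call. = FALSE)
  }
  if (cutoff_hz >= fs_hz / 2) {
    stop("cutoff_hz must be below the Nyquist frequency fs_hz/2", call. = FALSE)
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 fs_hz = fs_hz, mode = mode),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> order-%d Butterworth low-pass, %g Hz cutoff @ %g Hz (%s)\n",
              x$order, x$cutoff_hz, x$fs_hz, x$mode))
  invisible(x)
}

#' Resample a timestamped series onto a uniform grid
#'
#' Linear interpolation of `(t, values)` onto the grid
#' `t0, t0 + 1/fs, ...` spanning `[min(t), max(t)]`. Capture from mobile
#' devices runs at a variable 15-20 Hz; a fixed-cutoff digital filter needs a
#' fixed rate, so angle series are resampled before filtering.
#'
#' @param t Numeric timestamps, strictly increasing, length >= 2.
#' @param values Numeric values, same length as `t`.
#' @param fs_hz Target sampling rate in Hz.
#' @return List with components `t` (uniform grid) and `values`.
#' @export
resample_uniform <- function(t, values, fs_hz) {
  t <- as.numeric(t); values <- as.numeric(values)
  if (length(t) < 2L) stop("resampling needs at least 2 samples", call. = FALSE)
  if (length(values) != length(t)) stop("t and values lengths differ", call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  n_steps <- floor((t[length(t)] - t[1]) * fs_hz + 1e-9)
  grid <- t[1] + seq(0L, n_steps) / fs_hz
  # rule = 2: the last grid point may overshoot t_last by floating-point dust
  list(t = grid, values = approx(t, values, xout = grid, method = "linear",
                                 rule = 2)$y)
}

# Direct-form-II-transposed IIR filter pass with explicit initial state,
# y[n] = b0 x[n] + z1; z_i updated per sample. State vector length
# max(length(b), length(a)) - 1.
lfilter_df2t <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nfilt - 1L) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (nfilt > 2L) {
      for (i in 1:(nfilt - 2L)) {
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
      }
    }
    z[nfilt - 1L] <- b[nfilt] * xm - a[nfilt] * ym
    y[m] <- ym
  }
  y
}

# Steady-state DF2T state for unit step input (scale by x[1] before use);
# removes startup transients so a constant input yields a constant output.
lfilter_zi <- function(b, a) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  # companion matrix of a, transposed
  comp_t <- matrix(0, nfilt - 1L, nfilt - 1L)
  comp_t[, 1L] <- -a[-1L]
  if (nfilt > 2L) comp_t[cbind(1:(nfilt - 2L), 2:(nfilt - 1L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(nfilt - 1L) - comp_t, B)
}

#' Apply a Butterworth low-pass filter to a uniform series
#'
#' Designs an order-`spec$order` Butterworth low-pass filter at
#' `spec$cutoff_hz` for sampling rate `spec$fs_hz` (via [signal::butter()])
#' and applies it to `x`. In `zero_phase` mode the filter runs forward then
#' backward, cancelling phase lag and squaring the magnitude response; edge
#' transients are controlled by odd-reflection padding of length
#' `3 * (order + 1)` with steady-state initial conditions. In `causal` mode a
#' single forward pass is applied (initialised at steady state for `x[1]`), as
#' a real-time deployment would.
#'
#' DC gain is exactly 1: a constant series is returned unchanged (to 1e-9).
#'
#' @param x Numeric series sampled uniformly at `spec$fs_hz`.
#' @param spec A [filter_spec()].
#' @return Filtered numeric series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- as.numeric(x)
  ba <- signal::butter(spec$order, spec$cutoff_hz / (spec$fs_hz / 2), "low")
  b <- ba$b; a <- ba$a
  zi <- lfilter_zi(b, a)
  if (spec$mode == "causal") {
    if (length(x) < 2L) stop("series too short to filter", call. = FALSE)
    return(lfilter_df2t(b, a, x, zi * x[1]))
  }
  padlen <- 3L * (max(length(a), length(b)))
  if (length(x) <= padlen) {
    stop(sprintf("series length %d too short for zero-phase padding (needs > %d)",
                 length(x), padlen), call. = FALSE)
  }
  # odd (point-symmetric) reflection about the end samples
  left <- 2 * x[1] - x[(padlen + 1L):2L]
  right <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)]
  ext <- c(left, x, right)
  fb <- function(e) {
    y <- lfilter_df2t(b, a, e, zi * e[1])
    rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  }
  # run forward-backward and backward-forward and average: the edge
  # transients of the two orderings mirror each other, so the averaged
  # operator is exactly time-reversal symmetric
  y <- (fb(ext) + rev(fb(rev(ext)))) / 2
  y[(padlen + 1L):(padlen + length(x))]
}

#' Low-pass filter a joint-angle series
#'
#' Convenience wrapper: resamples the series onto a uniform grid at
#' `spec$fs_hz` (if not already uniform at that rate) and applies
#' [butterworth_lowpass()]. Origin flags are carried through resampling: a
#' grid sample is `interpolated` when any contributing source sample was.
#'
#' @param series A [joint_angle_series()].
#' @param spec A [filter_spec()].
#' @return A filtered [joint_angle_series()] on the uniform grid.
#' @export
filter_angle_series <- function(series, spec) {
  stopifnot(inherits(series, "joint_angle_series"), inherits(spec, "filter_spec"))
  s <- series$samples
  rs <- resample_uniform(s$t, s$deg, spec$fs_hz)
  ofrac <- approx(s$t, as.numeric(s$origin == "interpolated"),
                  xout = rs$t, method = "linear", rule = 2)$y
  origin <- ifelse(ofrac > 1e-12, "interpolated", "observed")
  deg <- butterworth_lowpass(rs$values, spec)
  joint_angle_series(series$joint, series$side, rs$t, deg, origin,
                     filtered = TRUE, filter_spec = spec,
                     convention = series$convention)
}
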