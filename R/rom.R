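# Repetition segmentation and range-of-motion summaries.

# Topographic prominence of local maxima. For each strict local maximum,
# extend left and right until a higher sample (or the series end) is reached;
# the prominence is the peak height minus the higher of the two interval
# minima. Plateau maxima are represented by their first sample.
local_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # walk across any plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

peak_prominence <- function(x, idx) {
  vapply(idx, function(p) {
    h <- x[p]
    li <- p
    while (li > 1L && x[li - 1L] <= h) li <- li - 1L
    left_min <- min(x[li:p])
    ri <- p
    while (ri < length(x) && x[ri + 1L] <= h) ri <- ri + 1L
    right_min <- min(x[p:ri])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Segment an angle series into exercise repetitions
#'
#' Detects repetitions as local maxima of the angle series with topographic
#' prominence at least `min_prominence_deg` and peak-to-peak separation at
#' least `min_separation_s` (when peaks conflict, higher ones win).
#' Repetition boundaries are placed at the series minima between consecutive
#' retained peaks (and between each outer peak and the series ends).
#' Segmentation is deterministic and invariant to adding a constant to the
#' series.
#'
#' @param series A [joint_angle_series()], expected filtered and uniform.
#' @param min_prominence_deg Minimum peak prominence in degrees (default 10),
#'   chosen to separate physiological repetitions from jitter at 15-20 Hz.
#' @param min_separation_s Minimum separation between peaks in seconds
#'   (default 1).
#' @return Data frame with one row per repetition: `start_t`, `peak_t`,
#'   `end_t` (seconds), `peak_deg` (degrees), ordered in time.
#' @export
segment_repetitions <- function(series, min_prominence_deg = 10,
                                min_separation_s = 1) {
  stopifnot(inherits(series, "joint_angle_series"))
  s <- series$samples
  if (!nrow(s)) stop("empty series", call. = FALSE)
  x <- s$deg; t <- s$t
  cand <- local_peaks(x)
  empty <- data.frame(start_t = numeric(), peak_t = numeric(),
                      end_t = numeric(), peak_deg = numeric())
  if (!length(cand)) return(empty)
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence_deg]
  if (!length(cand)) return(empty)
  # enforce separation, keeping higher peaks first
  ord <- cand[order(-x[cand], t[cand])]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(t[p] - t[kept]) >= min_separation_s)) {
      kept <- c(kept, p)
    }
  }
  kept <- sort(kept)
  # boundaries: minimum between consecutive peaks / toward the series ends
  bounds <- integer(length(kept) + 1L)
  bounds[1L] <- which.min(x[1:kept[1L]])
  if (length(kept) > 1L) {
    for (k in 1:(length(kept) - 1L)) {
      lo <- kept[k]; hi <- kept[k + 1L]
      bounds[k + 1L] <- lo + which.min(x[lo:hi]) - 1L
    }
  }
  bounds[length(kept) + 1L] <- kept[length(kept)] - 1L +
    which.min(x[kept[length(kept)]:length(x)])
  keep <- bounds[-length(bounds)] < kept & kept < bounds[-1L]
  data.frame(start_t = t[bounds[-length(bounds)]][keep],
             peak_t = t[kept][keep],
             end_t = t[bounds[-1L]][keep],
             peak_deg = x[kept][keep])
}

#' Peak flexion of an angle series
#'
#' The maximum sample value, i.e. the maximal range of motion reached
#' anywhere in the recording.
#'
#' @param series A [joint_angle_series()].
#' @return Degrees.
#' @export
peak_flexion <- function(series) {
  stopifnot(inherits(series, "joint_angle_series"))
  if (!nrow(series$samples)) stop("empty series", call. = FALSE)
  max(series$samples$deg)
}

#' Summarize an exercise recording into a range-of-motion value
#'
#' Segments the series into repetitions and reports `rom_deg` as the
#' arithmetic mean of the repetition peak angles — the protocol of averaging
#' three repeated trials to reduce within-subject variability.
#'
#' @inheritParams segment_repetitions
#' @return Object of class `exercise_summary`: list with `joint`, `side`,
#'   `repetitions` (the [segment_repetitions()] table), `n_reps`, `rom_deg`.
#' @export
summarize_exercise <- function(series, min_prominence_deg = 10,
                               min_separation_s = 1) {
  reps <- segment_repetitions(series, min_prominence_deg, min_separation_s)
  if (!nrow(reps)) {
    stop("no repetitions detected; consider peak_flexion() as a fallback",
         call. = FALSE)
  }
  structure(list(joint = series$joint, side = series$side,
                 repetitions = reps, n_reps = nrow(reps),
                 rom_deg = mean(reps$peak_deg)),
            class = "exercise_summary")
}

#' @export
print.exercise_summary <- function(x, ...) {
  cat(sprintf("<exercise_summary> %s %s: %d repetition(s), ROM %.2f deg\n",
              x$side, x$joint, x$n_reps, x$rom_deg))
  cat(sprintf("  repetition peaks: %s deg\n",
              paste(sprintf("%.2f", x$repetitions$peak_deg), collapse = ", ")))
  invisible(x)
}
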