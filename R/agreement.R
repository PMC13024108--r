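# Method-comparison statistics: ICC(A,1), Bland-Altman, proportional bias,
# error-vs-covariate regressions, cohort summaries.
#
# Sign convention used throughout: differences are algorithm - clinical, so a
# NEGATIVE bias means the markerless algorithm under-reads relative to
# goniometry.

#' Assemble paired clinical/algorithm measurements
#'
#' Validates a table of per-subject paired measurements: one clinical
#' goniometry value and one markerless-algorithm value per subject, plus
#' optional covariate columns (e.g. `months_since_surgery`).
#'
#' @param subject_id Identifier vector.
#' @param clinical_deg Reference goniometry values in degrees.
#' @param algorithm_deg Markerless algorithm values in degrees.
#' @param ... Optional covariate vectors, same length (named).
#' @return Data frame of class `paired_measurements`.
#' @export
paired_measurements <- function(subject_id, clinical_deg, algorithm_deg, ...) {
  clinical_deg <- as.numeric(clinical_deg)
  algorithm_deg <- as.numeric(algorithm_deg)
  n <- length(subject_id)
  if (length(clinical_deg) != n || length(algorithm_deg) != n) {
    stop("subject_id, clinical_deg, algorithm_deg must have equal length",
         call. = FALSE)
  }
  if (n < 3L) stop("at least 3 paired measurements are required", call. = FALSE)
  if (anyNA(clinical_deg) || anyNA(algorithm_deg)) {
    stop("missing values in measurement columns are not allowed", call. = FALSE)
  }
  cov <- list(...)
  if (length(cov) && any(vapply(cov, length, integer(1)) != n)) {
    stop("covariate columns must match the number of subjects", call. = FALSE)
  }
  out <- data.frame(subject_id = subject_id, clinical_deg = clinical_deg,
                    algorithm_deg = algorithm_deg, stringsAsFactors = FALSE)
  for (nm in names(cov)) out[[nm]] <- cov[[nm]]
  class(out) <- c("paired_measurements", "data.frame")
  out
}

#' Read paired measurements from CSV
#'
#' Expects a header `subject_id,clinical_deg,algorithm_deg` plus optional
#' covariate columns.
#'
#' @param path CSV file path.
#' @return A [paired_measurements()] data frame.
#' @export
read_paired_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "clinical_deg", "algorithm_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("pairs CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- d[setdiff(names(d), need)]
  do.call(paired_measurements,
          c(list(subject_id = d$subject_id, clinical_deg = d$clinical_deg,
                 algorithm_deg = d$algorithm_deg), as.list(extra)))
}

as_pairs <- function(pairs) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  if (is.data.frame(pairs) &&
      all(c("clinical_deg", "algorithm_deg") %in% names(pairs))) {
    if (!"subject_id" %in% names(pairs)) pairs$subject_id <- seq_len(nrow(pairs))
    return(do.call(paired_measurements, c(
      list(subject_id = pairs$subject_id, clinical_deg = pairs$clinical_deg,
           algorithm_deg = pairs$algorithm_deg),
      as.list(pairs[setdiff(names(pairs),
                            c("subject_id", "clinical_deg", "algorithm_deg"))])
    )))
  }
  stop("expected a paired_measurements object or a data frame with ",
       "clinical_deg and algorithm_deg columns", call. = FALSE)
}

# Two-way crossed ANOVA mean squares for an n-subjects x k-raters matrix,
# computed from row/column/grand means (no model fit).
two_way_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' ICC(A,1): single-measure absolute-agreement intraclass correlation
#'
#' The two-way model intraclass correlation for absolute agreement between
#' single measurements (McGraw & Wong's A,1 form), estimated from the two-way
#' ANOVA mean squares of the n-subjects by 2-raters table
#' (rows = subjects, columns = clinical / algorithm):
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`, `k = 2`.
#'
#' Unlike consistency-type ICCs, absolute agreement penalizes a systematic
#' offset between the raters, not only loss of correlation. The 95%
#' confidence interval follows the F-based procedure with Satterthwaite
#' degrees of freedom; the p-value tests ICC = 0 via `F = MSR / MSE` on
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param pairs A [paired_measurements()] object (or data frame with
#'   `clinical_deg`, `algorithm_deg`), n >= 3 subjects.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `f_value`, `df1`, `df2`, `p_value`, `n_subjects`, `k_raters`,
#'   `model`, and the underlying mean squares `ms`.
#' @export
icc_a1 <- function(pairs, conf_level = 0.95) {
  pairs <- as_pairs(pairs)
  m <- cbind(pairs$clinical_deg, pairs$algorithm_deg)
  ms <- two_way_mean_squares(m)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  if (abs(denom) < 1e-300 || (ms$msr == 0 && ms$msc == 0 && ms$mse == 0)) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  est <- (ms$msr - ms$mse) / denom

  alpha <- 1 - conf_level
  # F-based CI (Satterthwaite df), evaluated at the point estimate
  r <- est
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  if (!is.finite(a) || !is.finite(b)) { # r == 1: degenerate, zero error
    ci <- c(1, 1)
  } else {
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
    ci <- c(max(-1, lo), min(1, hi))
  }
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f0 <- if (ms$mse > 0) ms$msr / ms$mse else Inf
  p <- pf(f0, df1, df2, lower.tail = FALSE)
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 f_value = f0, df1 = df1, df2 = df2, p_value = p,
                 n_subjects = n, k_raters = k,
                 model = "two-way, absolute agreement, single measures (A,1)",
                 conf_level = conf_level, ms = ms),
            class = "icc_result")
}

# Consistency-form single-measure ICC (C,1); internal, kept as a comparison
# oracle: the absolute-agreement form must fall below it whenever the raters
# differ by a systematic offset.
icc_c1 <- function(pairs) {
  pairs <- as_pairs(pairs)
  ms <- two_way_mean_squares(cbind(pairs$clinical_deg, pairs$algorithm_deg))
  (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, %d%% CI [%.3f, %.3f]\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g; n = %d subjects, k = %d raters\n",
              x$df1, x$df2, x$f_value, x$p_value, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Per-subject differences `d = algorithm - clinical` are summarized by their
#' mean (the bias), sample standard deviation (n - 1 denominator), and the
#' 95% limits of agreement `bias +/- 1.96 sd`. A proportional-bias regression
#' of differences on pair means is included (see [proportional_bias()]).
#'
#' @param pairs A [paired_measurements()] object, n >= 3.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96, the
#'   normal 95% span).
#' @return Object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `loa_multiplier`, `prop_slope`, `prop_p`, `n`,
#'   plus the `differences` and `means` vectors for plotting.
#' @export
bland_altman <- function(pairs, loa_multiplier = 1.96) {
  pairs <- as_pairs(pairs)
  d <- pairs$algorithm_deg - pairs$clinical_deg
  m <- (pairs$algorithm_deg + pairs$clinical_deg) / 2
  bias <- mean(d)
  s <- sd(d)
  pb <- if (length(d) >= 4 && sd(m) > 0) proportional_bias(pairs) else
    list(slope = NA_real_, p_value = NA_real_)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - loa_multiplier * s,
                 loa_high = bias + loa_multiplier * s,
                 loa_multiplier = loa_multiplier,
                 prop_slope = pb$slope, prop_p = pb$p_value,
                 n = length(d), differences = d, means = m),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (algorithm - clinical), n = %d\n", x$n))
  cat(sprintf("  bias %.2f deg, sd %.2f deg, LoA [%.2f, %.2f] deg (x %.2f)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$loa_multiplier))
  if (!is.na(x$prop_slope)) {
    cat(sprintf("  proportional bias: slope %.3f deg/deg, p = %.3g\n",
                x$prop_slope, x$prop_p))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with `x` markers; the mean bias and the
#' limits of agreement drawn as dashed horizontal lines.
#'
#' @param x A `bland_altman_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, ...) {
  plot(x$means, x$differences, pch = 4,
       xlab = "Mean of methods (deg)",
       ylab = "Algorithm - clinical (deg)", ...)
  abline(h = x$bias, lty = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Proportional bias test
#'
#' Ordinary least squares of the between-method differences on the pair
#' means. A non-zero slope indicates that the disagreement grows (or shrinks)
#' with the magnitude of the measured angle.
#'
#' @param pairs A [paired_measurements()] object, n >= 4.
#' @return List with `slope` (deg per deg), `p_value` (two-sided),
#'   `intercept`, `n`.
#' @export
proportional_bias <- function(pairs) {
  pairs <- as_pairs(pairs)
  d <- pairs$algorithm_deg - pairs$clinical_deg
  m <- (pairs$algorithm_deg + pairs$clinical_deg) / 2
  if (length(d) < 4L) stop("proportional bias needs n >= 4", call. = FALSE)
  if (sd(m) == 0) stop("pair means are constant: no regressor variance",
                       call. = FALSE)
  fit <- lm(d ~ m)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["m", "Estimate"]),
       p_value = unname(sm["m", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n = length(d))
}

# Spearman rho with midrank ties; p by t-approximation, or exact enumeration
# of all permutations for very small n (<= 7).
spearman_midrank <- function(x, y, exact = FALSE) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (exact && n <= 7L) {
    perms <- permutations_all(n)
    stats_ <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p <- mean(abs(stats_) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[r + pos, ] <- append(sub[i, ], n, after = pos - 1L)
    }
    r <- r + n
  }
  out
}

#' Measurement error versus a covariate
#'
#' Regresses the per-subject measurement error (signed:
#' `algorithm - clinical`; or absolute: `|algorithm - clinical|`) on a
#' covariate such as months since surgery. Reports the OLS slope with its
#' two-sided p-value and R-squared, plus Spearman's rank correlation (midrank
#' ties, t-approximation p-value; exact permutation available for n <= 7).
#'
#' @param pairs A [paired_measurements()] object carrying the covariate
#'   column, n >= 4.
#' @param covariate Name of the covariate column.
#' @param error_kind `"absolute"` or `"signed"`.
#' @param exact_spearman Use exact permutation enumeration for the Spearman
#'   p-value (only honoured for n <= 7).
#' @return Object of class `covariate_error_result`: `beta` (deg per
#'   covariate unit), `beta_p`, `r_squared`, `rho`, `rho_p`, `error_kind`,
#'   `covariate`, `n`.
#' @export
error_vs_covariate <- function(pairs, covariate = "months_since_surgery",
                               error_kind = c("absolute", "signed"),
                               exact_spearman = FALSE) {
  pairs <- as_pairs(pairs)
  error_kind <- match.arg(error_kind)
  if (!covariate %in% names(pairs)) {
    stop("covariate column not found: ", covariate, call. = FALSE)
  }
  z <- as.numeric(pairs[[covariate]])
  if (anyNA(z)) {
    stop("missing covariate values for subject(s): ",
         paste(pairs$subject_id[is.na(z)], collapse = ", "), call. = FALSE)
  }
  if (length(z) < 4L) stop("error_vs_covariate needs n >= 4", call. = FALSE)
  e <- pairs$algorithm_deg - pairs$clinical_deg
  if (error_kind == "absolute") e <- abs(e)
  fit <- lm(e ~ z)
  sm <- summary(fit)
  sp <- spearman_midrank(z, e, exact = exact_spearman)
  structure(list(beta = unname(coef(fit)["z"]),
                 beta_p = unname(sm$coefficients["z", "Pr(>|t|)"]),
                 r_squared = sm$r.squared,
                 rho = sp$rho, rho_p = sp$p_value,
                 error_kind = error_kind, covariate = covariate,
                 n = length(z)),
            class = "covariate_error_result")
}

#' @export
print.covariate_error_result <- function(x, ...) {
  cat(sprintf("%s error vs %s (n = %d)\n", x$error_kind, x$covariate, x$n))
  cat(sprintf("  OLS: beta = %.3f deg/unit, p = %.3g, R^2 = %.3f\n",
              x$beta, x$beta_p, x$r_squared))
  cat(sprintf("  Spearman: rho = %.3f, p = %.3g\n", x$rho, x$rho_p))
  invisible(x)
}
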