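# Cohort table parsing and summaries.

#' Parse a surgery-type label
#'
#' Labels follow the clinical shorthand `"<Side> THA"` / `"<Side> TKA"` with
#' side one of `Left`, `Right`, `Left and Right` (bilateral). Case and extra
#' whitespace are tolerated.
#'
#' @param x Character vector of labels.
#' @return Data frame with columns `procedure` (`"THA"`/`"TKA"`), `side`
#'   (`"left"`, `"right"`, `"bilateral"`), `bilateral` (logical).
#' @export
parse_surgery_type <- function(x) {
  x0 <- x
  x <- tolower(trimws(gsub("\\s+", " ", x)))
  m <- regmatches(x, regexec("^(left and right|right and left|left|right|bilateral) (tha|tka)$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("unparseable surgery_type: \"", x0[which(bad)[1]], "\"", call. = FALSE)
  }
  side_raw <- vapply(m, `[`, character(1), 2L)
  proc <- toupper(vapply(m, `[`, character(1), 3L))
  bilat <- side_raw %in% c("left and right", "right and left", "bilateral")
  side <- ifelse(bilat, "bilateral", side_raw)
  data.frame(procedure = proc, side = side, bilateral = bilat,
             stringsAsFactors = FALSE)
}

#' Read a cohort CSV
#'
#' Expects columns `age_years`, `weight_kg`, `height_m`, `surgery_type`,
#' `months_since_surgery` (a demographics table of post-arthroplasty
#' patients). The packaged pilot cohort is available via
#' `system.file("extdata", "postarthroplasty_cohort.csv", package = "kinemark")`.
#'
#' @param path CSV file path.
#' @return Data frame with validated columns.
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_years", "weight_kg", "height_m", "surgery_type",
            "months_since_surgery")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("age_years", "weight_kg", "height_m", "months_since_surgery")
  for (nm in num) {
    d[[nm]] <- as.numeric(d[[nm]])
    if (anyNA(d[[nm]]) || any(d[[nm]] <= 0)) {
      stop("column ", nm, " must be positive numeric", call. = FALSE)
    }
  }
  parse_surgery_type(d$surgery_type)  # validates
  d
}

#' Summarize a post-arthroplasty cohort
#'
#' Per-column mean (rounded to 2 decimals), minimum and maximum for the
#' numeric demographics, plus patient counts by procedure. A bilateral hip
#' replacement counts as one THA patient.
#'
#' @param cohort Data frame as returned by [read_cohort_csv()].
#' @return Object of class `cohort_summary`: `n`, `numeric_summary` (data
#'   frame: variable, mean, min, max), `n_tha`, `n_tka`, `by_type` (counts of
#'   the raw labels).
#' @export
summarize_cohort <- function(cohort) {
  st <- parse_surgery_type(cohort$surgery_type)
  num <- c("age_years", "weight_kg", "height_m", "months_since_surgery")
  num <- intersect(num, names(cohort))
  ns <- data.frame(
    variable = num,
    mean = vapply(num, function(nm) round(mean(cohort[[nm]]), 2), numeric(1)),
    min = vapply(num, function(nm) min(cohort[[nm]]), numeric(1)),
    max = vapply(num, function(nm) max(cohort[[nm]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(n = nrow(cohort), numeric_summary = ns,
                 n_tha = sum(st$procedure == "THA"),
                 n_tka = sum(st$procedure == "TKA"),
                 by_type = table(cohort$surgery_type)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d (THA %d, TKA %d)\n",
              x$n, x$n_tha, x$n_tka))
  print(x$numeric_summary, row.names = FALSE)
  invisible(x)
}
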