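#' Percent-positive bin score
#'
#' Maps the percentage of immunostained cells to its ordinal score:
#' 0 (0%), 1 (1-10%), 2 (11-50%), 3 (51-80%), 4 (> 80%). Percentages are
#' visually estimated integers; non-integer input is rejected rather than
#' silently binned.
#'
#' @param percent_positive integer percentage(s) in 0-100; vectorized.
#' @param config a `genedose_config` (the bin breaks are configurable).
#' @return Integer score(s) in 0-4.
#' @export
#' @examples
#' percent_score(c(0, 10, 11, 50, 51, 80, 81, 100))
percent_score <- function(percent_positive, config = default_config()) {
  p <- percent_positive
  if (any(!is.finite(p)) || any(p != floor(p)) || any(p < 0) || any(p > 100)) {
    stop("percent_positive must be an integer in [0, 100]")
  }
  b <- config$percent_bin_breaks  # c(0, 10, 50, 80, 100)
  ifelse(p == 0L, 0L,
    ifelse(p <= b[2], 1L,
      ifelse(p <= b[3], 2L,
        ifelse(p <= b[4], 3L, 4L))))
}

#' ImmunoReactive Score (IRS)
#'
#' Combines a staining intensity grade (0 negative, 1+ weak, 2+ moderate,
#' 3+ strong) with the percent-positive bin score into the combined IRS:
#' intensity x percent score, range 0-12. Scores of 0 are "no expression",
#' 1-3 low (negative), 4-8 moderate and 9-12 high (scores >= 4 are
#' designated positive).
#'
#' @param intensity integer grade(s) 0-3; vectorized.
#' @param percent_positive integer percentage(s) 0-100.
#' @param config a `genedose_config`.
#' @return An object of class `irs_result`: data.frame with columns
#'   `intensity`, `percent_positive`, `percent_score`, `combined`,
#'   `category` (`none`/`low`/`moderate`/`high`), `positive`.
#' @export
#' @examples
#' irs(2, 90)   # moderate intensity in 90% of cells -> combined score 8
irs <- function(intensity, percent_positive, config = default_config()) {
  if (any(!is.finite(intensity)) || any(intensity != floor(intensity)) ||
      any(intensity < 0) || any(intensity > 3)) {
    stop("intensity must be an integer grade in 0-3")
  }
  n <- max(length(intensity), length(percent_positive))
  intensity <- as.integer(rep_len(intensity, n))
  percent_positive <- as.integer(rep_len(percent_positive, n))
  if (any(intensity == 0L & percent_positive > 0L)) {
    stop("intensity 0 with positive percent is inconsistent")
  }
  ps <- percent_score(percent_positive, config)
  combined <- intensity * ps
  category <- ifelse(combined == 0L, "none",
    ifelse(combined < config$irs_positive_min, "low",
      ifelse(combined < config$irs_high_min, "moderate", "high")))
  out <- data.frame(
    intensity = intensity, percent_positive = percent_positive,
    percent_score = as.integer(ps), combined = as.integer(combined),
    category = category, positive = combined >= config$irs_positive_min,
    stringsAsFactors = FALSE
  )
  class(out) <- c("irs_result", "data.frame")
  out
}

#' Per-core IRS table
#'
#' Applies `irs()` to every row of an IHC core table.
#'
#' @param cores data.frame in `read_ihc_table()` format.
#' @param config a `genedose_config`.
#' @return The input with the IRS columns appended.
#' @export
irs_table <- function(cores, config = default_config()) {
  res <- irs(cores$intensity, cores$percent_positive, config)
  cbind(cores, res[c("percent_score", "combined", "category", "positive")])
}

#' Cohort-level IHC summary by tissue class
#'
#' Summarizes one cellular compartment across a cohort: per tissue class, the
#' number of cores, the count and fraction of IRS-positive cores (combined
#' score >= 4), and the mean and SD of percent-positive cells.
#'
#' @param cores data.frame in `read_ihc_table()` format.
#' @param compartment `"nuclear"` or `"cytoplasmic"`.
#' @param classes tissue classes to report, in order. The default reports
#'   every class present; comparisons in this package's drivers use the
#'   ordered benign/DCIS/IDC triple, with metastasis carried in summaries
#'   only.
#' @param percent_digits decimals for the reported positivity percentage.
#' @param config a `genedose_config`.
#' @return A data.frame with columns `tissue_class`, `n`, `n_positive`,
#'   `positive_fraction` (e.g. `"17/39"`), `positive_percent`,
#'   `mean_percent_positive`, `sd_percent_positive`.
#' @export
cohort_summary <- function(cores, compartment = c("nuclear", "cytoplasmic"),
                           classes = NULL, percent_digits = 0L,
                           config = default_config()) {
  compartment <- match.arg(compartment)
  stopifnot(all(c("tissue_class", "compartment", "intensity",
                  "percent_positive") %in% names(cores)))
  bad <- setdiff(unique(cores$tissue_class), tissue_classes())
  if (length(bad)) stop("unknown tissue_class: ", paste(bad, collapse = ", "))
  d <- cores[cores$compartment == compartment, , drop = FALSE]
  if (is.null(classes)) {
    classes <- intersect(tissue_classes(), unique(d$tissue_class))
  }
  rows <- lapply(classes, function(cl) {
    s <- d[d$tissue_class == cl, , drop = FALSE]
    if (nrow(s) == 0L) stop("no cores for reported class: ", cl)
    scored <- irs(s$intensity, s$percent_positive, config)
    npos <- sum(scored$positive)
    data.frame(
      tissue_class = cl,
      n = nrow(s),
      n_positive = npos,
      positive_fraction = sprintf("%d/%d", npos, nrow(s)),
      positive_percent = round_half_up(100 * npos / nrow(s), percent_digits),
      mean_percent_positive = round_half_up(mean(s$percent_positive), 2L),
      sd_percent_positive = round_half_up(stats::sd(s$percent_positive), 2L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
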