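#' Default run configuration
#'
#' Returns the configuration list holding every classification threshold used
#' by the pipeline, with defaults frozen to the published cutoffs: gene
#' amplification at a gene-to-centromere ratio >= 2.0 (high-level
#' amplification at >= 5.0), polysomy bands keyed to integer copy number
#' (disomy = 2, low = 3, high >= 4), relative-quantification (RQ) expression
#' bands (high >= 50, moderate 20-50, low 1-20, baseline <= 1), IRS
#' percent-positive bins (0, 1-10, 11-50, 51-80, 81-100) and category cuts
#' (positive >= 4, high >= 9), and reporting precision (1 decimal for FISH
#' summaries, 2 for RQ).
#'
#' @param ... named overrides for individual entries, e.g.
#'   `default_config(amplification_ratio = 2.2)`.
#' @return A named list of class `genedose_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$amplification_ratio
default_config <- function(...) {
  cfg <- list(
    gene_label = "MELK",
    cep_label = "CEP9",
    amplification_ratio = 2.0,
    high_amplification_ratio = 5.0,
    polysomy_low_max = 3L,     # low polysomy: copy number > 2 and <= 3
    polysomy_high_min = 4L,    # high polysomy: copy number >= 4
    rq_high_min = 50,
    rq_moderate_min = 20,
    rq_baseline_max = 1,
    irs_positive_min = 4L,
    irs_high_min = 9L,
    percent_bin_breaks = c(0L, 10L, 50L, 80L, 100L),
    fish_precision = 1L,
    rq_precision = 2L,
    ratio_from_rounded_means = TRUE,
    rq_sd_estimator = "replicate",  # or "propagated"
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "genedose_config")
}

#' Read a configuration file
#'
#' Reads a flat key-value YAML file of threshold overrides and merges it onto
#' the defaults. Unknown keys are an error so typos never silently fall back
#' to defaults.
#'
#' @param path path to a YAML file with a flat mapping of config entries.
#' @return A `genedose_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  do.call(default_config, overrides)
}

validate_config <- function(cfg) {
  num <- c(
    "amplification_ratio", "high_amplification_ratio", "polysomy_low_max",
    "polysomy_high_min", "rq_high_min", "rq_moderate_min", "rq_baseline_max",
    "irs_positive_min", "irs_high_min"
  )
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      stop("config entry '", k, "' must be a single positive number")
    }
  }
  # bands must be non-overlapping and exhaustive over their domains
  if (!(cfg$rq_baseline_max < cfg$rq_moderate_min &&
        cfg$rq_moderate_min < cfg$rq_high_min)) {
    stop("RQ band cutoffs must satisfy baseline < moderate < high")
  }
  if (!(cfg$polysomy_low_max < cfg$polysomy_high_min)) {
    stop("polysomy band cutoffs must satisfy low < high")
  }
  if (!(cfg$irs_positive_min <= cfg$irs_high_min)) {
    stop("IRS cutoffs must satisfy positive <= high")
  }
  breaks <- cfg$percent_bin_breaks
  if (length(breaks) != 5L || is.unsorted(breaks, strictly = TRUE) ||
      breaks[1] != 0L || breaks[5] != 100L) {
    stop("percent_bin_breaks must be 5 strictly increasing integers from 0 to 100")
  }
  invisible(cfg)
}

#' @export
print.genedose_config <- function(x, ...) {
  cat("genedose run configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

# Round half away from zero (half-up for positives) at `digits` decimals.
# base::round() rounds half to even; reported ratios and RQ values follow the
# half-up convention of the source tables.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a deterministic stage-salted seed, restoring the caller's
# RNG state afterwards. Salting with the stage name gives every generator an
# independent substream of one global seed, so adding a stage never perturbs
# another stage's draws.
with_stage_seed <- function(seed, stage, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  s <- (abs(as.integer(seed)) %% 1000003L) * 2011L + (salt %% 1000003L)
  s <- s %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(s)
  expr
}
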