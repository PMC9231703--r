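#' Simulate a clonal FISH cell population
#'
#' Draws per-nucleus integer probe counts from a mixture of clones. Each clone
#' is a `(gene_copies, cep_copies, fraction)` pattern; each scored cell is
#' assigned to a clone by its fraction and, with probability `miscount_rate`
#' per probe, its count is perturbed by +/-1 (floored at 0) to emulate signal
#' scoring error. The miscount model is the minimal symmetric perturbation
#' that exercises the robustness of major-clone calling.
#'
#' @param clones list of clones; each a list or vector with `gene_copies`,
#'   `cep_copies`, `fraction`. Fractions must sum to 1 (within 1e-9).
#' @param n_cells number of nuclei to score.
#' @param miscount_rate per-probe perturbation probability in \[0, 0.5).
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param sample_id sample label attached to the output.
#' @return A data.frame with columns `sample_id`, `cell_id`, `gene_signals`,
#'   `cep_signals` — the format `read_cell_counts()` produces.
#' @export
#' @examples
#' pop <- simulate_fish_population(
#'   clones = list(c(gene_copies = 3, cep_copies = 4, fraction = 0.8),
#'                 c(gene_copies = 2, cep_copies = 2, fraction = 0.2)),
#'   n_cells = 200, miscount_rate = 0.02, seed = 1
#' )
#' table(pop$gene_signals, pop$cep_signals)
simulate_fish_population <- function(clones, n_cells, miscount_rate = 0,
                                     seed = 1L, sample_id = "S1") {
  if (length(clones) == 0L) stop("empty clone list")
  cl <- do.call(rbind, lapply(clones, function(x) {
    x <- as.list(x)
    stopifnot(all(c("gene_copies", "cep_copies", "fraction") %in% names(x)))
    data.frame(gene_copies = as.integer(x$gene_copies),
               cep_copies = as.integer(x$cep_copies),
               fraction = as.numeric(x$fraction))
  }))
  if (any(cl$gene_copies < 0L) || any(cl$cep_copies < 0L)) {
    stop("clone copy numbers must be nonnegative integers")
  }
  if (abs(sum(cl$fraction) - 1) > 1e-9) {
    stop("clone fractions must sum to 1 (got ", sum(cl$fraction), ")")
  }
  stopifnot(n_cells >= 1, miscount_rate >= 0, miscount_rate < 0.5)
  with_stage_seed(seed, "fish_population", {
    idx <- sample.int(nrow(cl), n_cells, replace = TRUE, prob = cl$fraction)
    g <- cl$gene_copies[idx]
    c9 <- cl$cep_copies[idx]
    if (miscount_rate > 0) {
      g <- perturb_counts(g, miscount_rate)
      c9 <- perturb_counts(c9, miscount_rate)
    }
    data.frame(
      sample_id = sample_id,
      cell_id = sprintf("c%d", seq_len(n_cells)),
      gene_signals = g,
      cep_signals = c9,
      stringsAsFactors = FALSE
    )
  })
}

perturb_counts <- function(x, rate) {
  hit <- stats::runif(length(x)) < rate
  delta <- ifelse(stats::runif(length(x)) < 0.5, -1L, 1L)
  pmax(0L, x + ifelse(hit, delta, 0L))
}

#' Simulate a qPCR Ct replicate table
#'
#' Generates replicate cycle-threshold values for the four cells of a
#' relative-quantification design (sample/calibrator x target/reference).
#' Reference Cts are Normal(`base_ct`, `replicate_sd`) in both conditions;
#' the sample-condition target Cts are shifted by `-log2(true_fold_change)`
#' relative to the calibrator target Cts, so the delta-delta-Ct estimate
#' downstream recovers `true_fold_change` (exactly when `replicate_sd = 0`).
#'
#' @param true_fold_change the fold change the design encodes (> 0).
#' @param base_ct mean cycle threshold of the reference assays.
#' @param replicate_sd replicate noise SD in cycles (>= 0).
#' @param n_reps replicates per design cell (>= 2; assays are typically run
#'   in quadruplicate).
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return A data.frame in `read_ct_table()` format.
#' @export
simulate_qpcr <- function(true_fold_change, base_ct = 20, replicate_sd = 0.1,
                          n_reps = 4L, seed = 1L, sample_id = "S1") {
  if (!is.numeric(true_fold_change) || true_fold_change <= 0) {
    stop("true_fold_change must be positive")
  }
  if (replicate_sd < 0) stop("replicate_sd must be nonnegative")
  if (n_reps < 2L) stop("n_reps must be >= 2")
  with_stage_seed(seed, "qpcr", {
    grid <- expand.grid(
      condition = c("sample", "calibrator"),
      role = c("target", "reference"),
      replicate = seq_len(n_reps),
      stringsAsFactors = FALSE
    )
    mu <- ifelse(grid$role == "reference", base_ct,
                 ifelse(grid$condition == "calibrator", base_ct,
                        base_ct - log2(true_fold_change)))
    grid$ct <- stats::rnorm(nrow(grid), mean = mu, sd = replicate_sd)
    data.frame(sample_id = sample_id, grid, stringsAsFactors = FALSE)
  })
}

#' Simulate an IHC scoring cohort
#'
#' Draws per-core intensity grades and percent-positive values per cellular
#' compartment from tissue-class models, under the biological constraints the
#' scoring assumes: a grade-0 compartment has 0% positivity, and cytoplasmic
#' staining occurs only in cores with nuclear staining.
#'
#' @param models list of group models; each a list with `tissue_class` and,
#'   per compartment (`nuclear`, `cytoplasmic`), a list with
#'   `intensity_probs` (4 probabilities over grades 0-3, summing to 1),
#'   `percent_min`, `percent_max` (integer percent range used when the grade
#'   is positive).
#' @param n_per_group cores per tissue class (>= 1).
#' @param seed integer seed.
#' @return A data.frame in `read_ihc_table()` format (two rows per core, one
#'   per compartment).
#' @export
#' @examples
#' benign <- ihc_group_model("benign",
#'   nuclear = list(intensity_probs = c(0.2, 0.3, 0.4, 0.1),
#'                  percent_min = 20, percent_max = 100),
#'   cytoplasmic = list(intensity_probs = c(32/33, 1/33, 0, 0),
#'                      percent_min = 80, percent_max = 100))
#' head(simulate_ihc_cohort(list(benign), n_per_group = 5, seed = 2))
simulate_ihc_cohort <- function(models, n_per_group, seed = 1L) {
  if (length(models) == 0L) stop("empty model list")
  stopifnot(n_per_group >= 1)
  lapply(models, validate_ihc_model)
  with_stage_seed(seed, "ihc_cohort", {
    out <- lapply(models, function(m) {
      rows <- lapply(seq_len(n_per_group), function(i) {
        core <- sprintf("%s_%03d", m$tissue_class, i)
        nuc <- draw_compartment(m$nuclear)
        cyt <- draw_compartment(m$cytoplasmic)
        if (nuc$percent == 0L) {
          # cytoplasmic staining occurs only in cores with nuclear staining
          cyt <- list(intensity = 0L, percent = 0L)
        }
        data.frame(
          core_id = core,
          tissue_class = m$tissue_class,
          compartment = c("nuclear", "cytoplasmic"),
          intensity = c(nuc$intensity, cyt$intensity),
          percent_positive = c(nuc$percent, cyt$percent),
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, rows)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Build an IHC tissue-class model
#'
#' Convenience constructor for the group models `simulate_ihc_cohort()`
#' consumes.
#'
#' @param tissue_class one of `benign`, `DCIS`, `IDC`, `metastasis`.
#' @param nuclear,cytoplasmic per-compartment model: list with
#'   `intensity_probs`, `percent_min`, `percent_max`.
#' @return A validated model list.
#' @export
ihc_group_model <- function(tissue_class, nuclear, cytoplasmic) {
  m <- list(tissue_class = tissue_class, nuclear = nuclear,
            cytoplasmic = cytoplasmic)
  validate_ihc_model(m)
  m
}

validate_ihc_model <- function(m) {
  stopifnot(is.list(m), all(c("tissue_class", "nuclear", "cytoplasmic") %in% names(m)))
  if (!m$tissue_class %in% tissue_classes()) {
    stop("unknown tissue_class: ", m$tissue_class)
  }
  for (comp in c("nuclear", "cytoplasmic")) {
    cm <- m[[comp]]
    p <- cm$intensity_probs
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(comp, " intensity_probs must be 4 nonnegative values summing to 1")
    }
    lo <- cm$percent_min; hi <- cm$percent_max
    if (lo < 0 || hi > 100 || lo > hi) stop(comp, " percent range must be within [0,100]")
  }
  invisible(m)
}

draw_compartment <- function(cm) {
  intensity <- sample(0:3, 1L, prob = cm$intensity_probs)
  if (intensity == 0L) {
    list(intensity = 0L, percent = 0L)
  } else {
    lo <- max(1L, as.integer(cm$percent_min))
    hi <- as.integer(cm$percent_max)
    list(intensity = as.integer(intensity),
         percent = sample(seq.int(lo, hi), 1L))
  }
}

#' Simulate a piecewise-constant signal track
#'
#' Tiles a genomic region with non-overlapping constant segments of width at
#' most `bin_width`, cut at peak boundaries. Inside a peak the segment value
#' is the peak height plus noise; outside it is noise alone; all values are
#' truncated at 0 (signal tracks are nonnegative).
#'
#' @param region one-row region data.frame from `genomic_region()`.
#' @param peaks list of peaks; each a list/vector with `start`, `end`
#'   (0-based half-open, inside `region`, mutually non-overlapping) and
#'   `height` (>= 0).
#' @param bin_width maximum segment width in bp (positive integer).
#' @param noise_sd SD of the additive Gaussian noise (>= 0).
#' @param seed integer seed.
#' @return A segment data.frame (`chrom`, `start`, `end`, `value`) sorted by
#'   start — the format `read_bedgraph()` produces.
#' @export
simulate_signal_track <- function(region, peaks = list(), bin_width = 25L,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(nrow(region) == 1L, bin_width >= 1, noise_sd >= 0)
  pk <- if (length(peaks)) {
    do.call(rbind, lapply(peaks, function(p) {
      p <- as.list(p)
      data.frame(start = as.numeric(p$start), end = as.numeric(p$end),
                 height = as.numeric(p$height))
    }))
  } else {
    data.frame(start = numeric(), end = numeric(), height = numeric())
  }
  if (nrow(pk)) {
    if (any(pk$end <= pk$start) || any(pk$height < 0)) stop("invalid peak")
    if (any(pk$start < region$start) || any(pk$end > region$end)) {
      stop("peak outside region")
    }
    pk <- pk[order(pk$start), , drop = FALSE]
    if (nrow(pk) > 1L && any(pk$start[-1L] < pk$end[-nrow(pk)])) {
      stop("overlapping peak intervals")
    }
  }
  # breakpoints: region ends, peak edges, and the bin grid
  cuts <- sort(unique(c(region$start, region$end, pk$start, pk$end,
                        seq(region$start, region$end, by = bin_width))))
  cuts <- cuts[cuts >= region$start & cuts <= region$end]
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1L]
  height <- numeric(length(starts))
  for (i in seq_len(nrow(pk))) {
    inside <- starts >= pk$start[i] & ends <= pk$end[i]
    height[inside] <- pk$height[i]
  }
  with_stage_seed(seed, "signal_track", {
    noise <- if (noise_sd > 0) stats::rnorm(length(starts), 0, noise_sd) else 0
    data.frame(
      chrom = region$chrom,
      start = starts,
      end = ends,
      value = pmax(0, height + noise),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate paired copy-number/expression samples by subtype
#'
#' Draws (log2 copy number, log2 expression) pairs from a bivariate normal
#' with within-subtype correlation `target_r`, then adds subtype-specific
#' location shifts — emulating cohorts where a basal-like shift in both
#' variables coexists with a within-subtype dosage effect.
#'
#' @param n number of samples (>= 10).
#' @param target_r within-subtype Pearson correlation, in (-1, 1).
#' @param subtype_effects named list mapping subtype to `c(cn, expr)` shifts
#'   (log2 units).
#' @param proportions named numeric vector of subtype proportions (same
#'   names; sums to 1).
#' @param seed integer seed.
#' @param sd marginal SD of each variable before shifts (default 1).
#' @return A data.frame in `read_sample_table()` format.
#' @export
#' @examples
#' d <- simulate_cn_expression(
#'   n = 500, target_r = 0.5,
#'   subtype_effects = list(basal = c(0.4, 1.5), luminal_A = c(0, 0)),
#'   proportions = c(basal = 0.3, luminal_A = 0.7), seed = 3
#' )
#' cor(d$log2_cn, d$log2_expr)
simulate_cn_expression <- function(n, target_r,
                                   subtype_effects = list(other = c(0, 0)),
                                   proportions = c(other = 1),
                                   seed = 1L, sd = 1) {
  if (abs(target_r) >= 1) stop("target_r must be in (-1, 1)")
  stopifnot(n >= 10)
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  labs <- names(proportions)
  if (is.null(labs) || !all(labs %in% subtypes())) {
    stop("proportions must be named with known subtypes")
  }
  if (!all(labs %in% names(subtype_effects))) {
    stop("every subtype in proportions needs an entry in subtype_effects")
  }
  with_stage_seed(seed, "cn_expression", {
    subtype <- sample(labs, n, replace = TRUE, prob = proportions)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    cn <- sd * z1
    expr <- sd * (target_r * z1 + sqrt(1 - target_r^2) * z2)
    shift <- t(vapply(subtype, function(s) as.numeric(subtype_effects[[s]]),
                      numeric(2)))
    data.frame(
      sample_id = sprintf("s%05d", seq_len(n)),
      subtype = subtype,
      log2_cn = cn + shift[, 1],
      log2_expr = expr + shift[, 2],
      stringsAsFactors = FALSE
    )
  })
}
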