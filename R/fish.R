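#' Summarize a dual-probe FISH cell population
#'
#' Aggregates per-nucleus gene-probe and centromere-probe counts into the
#' sample-level summary used for copy-number interpretation: mean copies per
#' cell of each probe, the gene-to-centromere ratio, and the ranked major
#' clones (distinct count patterns by observed frequency).
#'
#' Reported means are rounded half-up to `precision` decimals, and by default
#' the ratio is the quotient of the *rounded* means (again rounded), matching
#' how such tables are printed; set `from_rounded = FALSE` in
#' `classify_fish()`-independent use to get the unrounded quotient. Unrounded
#' values are retained in the returned object.
#'
#' @param cells data.frame with columns `gene_signals`, `cep_signals` (one
#'   row per nucleus), as from `read_cell_counts()` or
#'   `simulate_fish_population()`.
#' @param precision reported decimals (default 1).
#' @param from_rounded compute the ratio from the rounded means (default
#'   `TRUE`).
#' @return An object of class `fish_summary`: list with `n_cells`,
#'   `mean_gene`, `mean_cep`, `ratio` (reported, rounded), their `raw_*`
#'   counterparts, and `major_clones` (data.frame `gene`, `cep`, `count`,
#'   `fraction`, ranked by descending frequency, ties broken by ascending
#'   (gene, cep)).
#' @export
#' @examples
#' cells <- simulate_fish_population(
#'   list(c(gene_copies = 4, cep_copies = 4, fraction = 1)), 50, seed = 1)
#' summarize_cells(cells)
summarize_cells <- function(cells, precision = 1L, from_rounded = TRUE) {
  stopifnot(is.data.frame(cells),
            all(c("gene_signals", "cep_signals") %in% names(cells)))
  if (nrow(cells) == 0L) stop("empty cell collection")
  g <- cells$gene_signals
  c9 <- cells$cep_signals
  if (any(g < 0) || any(c9 < 0) || any(g != floor(g)) || any(c9 != floor(c9))) {
    stop("signal counts must be nonnegative integers")
  }
  raw_mean_gene <- mean(g)
  raw_mean_cep <- mean(c9)
  if (all(c9 == 0)) stop("all centromere counts are zero: ratio undefined")
  mean_gene <- round_half_up(raw_mean_gene, precision)
  mean_cep <- round_half_up(raw_mean_cep, precision)
  raw_ratio <- raw_mean_gene / raw_mean_cep
  ratio <- if (from_rounded) {
    round_half_up(mean_gene / mean_cep, precision)
  } else {
    round_half_up(raw_ratio, precision)
  }
  tab <- as.data.frame(table(gene = g, cep = c9), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab$gene <- as.integer(tab$gene)
  tab$cep <- as.integer(tab$cep)
  tab <- tab[order(-tab$Freq, tab$gene, tab$cep), , drop = FALSE]
  clones <- data.frame(
    gene = tab$gene, cep = tab$cep, count = tab$Freq,
    fraction = tab$Freq / length(g)
  )
  rownames(clones) <- NULL
  structure(
    list(
      n_cells = length(g),
      mean_gene = mean_gene, mean_cep = mean_cep, ratio = ratio,
      raw_mean_gene = raw_mean_gene, raw_mean_cep = raw_mean_cep,
      raw_ratio = raw_ratio,
      precision = as.integer(precision),
      major_clones = clones
    ),
    class = "fish_summary"
  )
}

#' Construct a FISH summary from reported values
#'
#' Builds a `fish_summary` directly from sample-level numbers — mean copies
#' per cell of each probe and the major clone — as printed in a score table,
#' so published rows can be classified without the underlying per-cell
#' counts. The ratio defaults to the quotient of the (already rounded)
#' reported means, rounded half-up to `precision`; with `mean_cep = 0` the
#' ratio is `Inf` (gene signals with no centromere signal).
#'
#' @param mean_gene,mean_cep reported mean copies per cell.
#' @param clone_gene,clone_cep integer counts of the top major clone.
#' @param clone_fraction observed fraction of the major clone.
#' @param n_cells number of scored nuclei, if known.
#' @param ratio override for the reported ratio (default computed from the
#'   means).
#' @param precision reported decimals.
#' @return A `fish_summary` object.
#' @export
#' @examples
#' fish_summary(8.9, 10.6, clone_gene = 9, clone_cep = 10,
#'              clone_fraction = 0.55)
fish_summary <- function(mean_gene, mean_cep, clone_gene, clone_cep,
                         clone_fraction = NA_real_, n_cells = NA_integer_,
                         ratio = NULL, precision = 1L) {
  stopifnot(mean_gene >= 0, mean_cep >= 0)
  if (is.null(ratio)) {
    ratio <- if (mean_cep > 0) {
      round_half_up(mean_gene / mean_cep, precision)
    } else if (mean_gene > 0) Inf else NaN
  }
  clones <- data.frame(
    gene = as.integer(clone_gene), cep = as.integer(clone_cep),
    count = NA_integer_, fraction = clone_fraction
  )
  structure(
    list(
      n_cells = n_cells,
      mean_gene = mean_gene, mean_cep = mean_cep, ratio = ratio,
      raw_mean_gene = mean_gene, raw_mean_cep = mean_cep,
      raw_ratio = if (mean_cep > 0) mean_gene / mean_cep else Inf,
      precision = as.integer(precision),
      major_clones = clones
    ),
    class = "fish_summary"
  )
}

#' Classify a FISH summary into a copy-number call
#'
#' Applies the dual-probe interpretation rules. Amplification is a
#' gene-to-centromere ratio at or above the cutoff (default 2.0); the
#' centromere probe distinguishes true gene amplification from copy gain due
#' to whole-chromosome polysomy. For non-amplified samples the polysomy call
#' is made from the top major clone's integer counts `(g, c)` (real-valued
#' means cannot separate a 4:4 clone at 3.8 mean copies from a 3:3 clone at
#' 3.2):
#' \itemize{
#'   \item level keyed to the gene count: disomy at g = 2, low polysomy at
#'     g = 3, high at g >= 4, none below 2;
#'   \item balanced iff g = c (equal copy gain of both signals);
#'   \item centromere hemizygous deletion when c = 1 with g >= 2.
#' }
#' When amplified, the centromere status is still reported, from the major
#' clone's centromere count (or the rounded mean when no clone is available).
#' A high-level amplification qualifier is added at ratio >=
#' `high_amplification_ratio` (default 5.0).
#'
#' The rendered label follows the conventions of published dual-probe score
#' tables, e.g. `"High unbalanced polysomy"`, `"Disomy balanced"`,
#' `"SA, unbalanced disomy"`, `"SA, CEP9 hemizygous deletion"`,
#' `"High ampl; CEP9 high polysomy"`. When the two probes' counts fall in
#' different polysomy bands and differ by two or more copies, no single level
#' describes both signals and the qualifier is omitted (`"Unbalanced
#' polysomy"`).
#'
#' @param summary a `fish_summary`.
#' @param structural_alteration logical; cytogenetically annotated chromosome
#'   rearrangement involving the gene locus. This is an input annotation (SA
#'   is identified on metaphases, not inferrable from counts); it prefixes
#'   the label with `"SA, "`.
#' @param config a `genedose_config`.
#' @return An object of class `fish_call`: list with `amplified`,
#'   `high_level`, `polysomy_level` (`none`, `disomy`, `low`, `high`),
#'   `balance` (`balanced`, `unbalanced`, `not_applicable`),
#'   `cep_hemizygous_deletion`, `structural_alteration`, `ratio`, `label`.
#' @export
classify_fish <- function(summary, structural_alteration = FALSE,
                          config = default_config()) {
  stopifnot(inherits(summary, "fish_summary"))
  clones <- summary$major_clones
  if (is.null(clones) || nrow(clones) == 0L) stop("no major clones in summary")
  top <- clones[1L, ]
  g <- top$gene
  c9 <- top$cep
  if (g == 0L && c9 == 0L) stop("uninterpretable: major clone has zero signals for both probes")
  if (is.na(summary$ratio)) stop("summary has no defined ratio")
  ratio <- summary$ratio

  amplified <- ratio >= config$amplification_ratio
  high_level <- amplified && ratio >= config$high_amplification_ratio

  level_of <- function(k) {
    if (k >= config$polysomy_high_min) "high"
    else if (k > 2L && k <= config$polysomy_low_max) "low"
    else if (k == 2L) "disomy"
    else "none"
  }

  if (amplified) {
    # the gene side is amplified; report CEP status on its own
    cep_count <- if (!is.na(c9)) c9 else as.integer(round_half_up(summary$mean_cep, 0))
    cep_level <- level_of(cep_count)
    call <- list(
      amplified = TRUE, high_level = high_level,
      polysomy_level = cep_level, balance = "not_applicable",
      cep_hemizygous_deletion = cep_count == 1L,
      structural_alteration = isTRUE(structural_alteration),
      ratio = ratio, gene = g, cep = c9
    )
    call$label <- render_fish_label(call, config)
    return(structure(call, class = "fish_call"))
  }

  hemi <- (c9 == 1L && g >= 2L)
  level <- level_of(g)
  balance <- if (hemi) "not_applicable" else if (g == c9) "balanced" else "unbalanced"
  call <- list(
    amplified = FALSE, high_level = FALSE,
    polysomy_level = level, balance = balance,
    cep_hemizygous_deletion = hemi,
    structural_alteration = isTRUE(structural_alteration),
    ratio = ratio, gene = g, cep = c9
  )
  call$label <- render_fish_label(call, config)
  structure(call, class = "fish_call")
}

render_fish_label <- function(call, config = default_config()) {
  gene_lab <- config$gene_label
  cep_lab <- config$cep_label
  base <- if (call$amplified) {
    qual <- if (call$high_level) "High ampl" else "Ampl"
    cep_part <- switch(call$polysomy_level,
      high = sprintf("%s high polysomy", cep_lab),
      low = sprintf("%s low polysomy", cep_lab),
      disomy = sprintf("%s disomy", cep_lab),
      none = if (call$cep_hemizygous_deletion) {
        sprintf("%s hemizygous deletion", cep_lab)
      } else sprintf("%s loss", cep_lab)
    )
    sprintf("%s; %s", qual, cep_part)
  } else if (call$cep_hemizygous_deletion) {
    sprintf("%s hemizygous deletion", cep_lab)
  } else if (call$polysomy_level == "disomy") {
    if (call$balance == "balanced") "Disomy balanced" else "Unbalanced disomy"
  } else if (call$polysomy_level == "none") {
    if (call$gene == 1L) sprintf("%s hemizygous deletion", gene_lab)
    else sprintf("%s nullisomy", gene_lab)
  } else {
    lev <- level_qualifier(call$gene, call$cep, config)
    bal <- if (call$balance == "balanced") "balanced" else "unbalanced"
    if (is.na(lev)) {
      paste0(toupper(substr(bal, 1, 1)), substr(bal, 2, nchar(bal)), " polysomy")
    } else {
      sprintf("%s %s polysomy", lev, bal)
    }
  }
  if (call$structural_alteration) {
    first <- sub("[ ,;].*$", "", base)
    if (!first %in% c(gene_lab, cep_lab)) {
      base <- paste0(tolower(substr(base, 1, 1)), substr(base, 2, nchar(base)))
    }
    base <- paste0("SA, ", base)
  }
  base
}

# Level qualifier for a polysomy label. Keyed to the gene count; omitted
# (NA) when the two signals sit in different bands and differ by >= 2
# copies, in which case neither "low" nor "high" describes both probes.
level_qualifier <- function(g, c9, config) {
  band <- function(k) {
    if (k >= config$polysomy_high_min) 2L
    else if (k > 2L && k <= config$polysomy_low_max) 1L
    else 0L
  }
  if (band(g) != band(c9) && abs(g - c9) >= 2L) return(NA_character_)
  if (g >= config$polysomy_high_min) "High" else "Low"
}

#' Score one FISH sample end to end
#'
#' Composes `summarize_cells()` and `classify_fish()`.
#'
#' @inheritParams summarize_cells
#' @param sa_flag structural-alteration annotation for the sample.
#' @param config a `genedose_config`.
#' @return A list with elements `summary` (`fish_summary`) and `call`
#'   (`fish_call`).
#' @export
score_sample <- function(cells, sa_flag = FALSE, config = default_config()) {
  s <- summarize_cells(cells, precision = config$fish_precision,
                       from_rounded = config$ratio_from_rounded_means)
  list(summary = s, call = classify_fish(s, sa_flag, config))
}

#' Score a multi-sample FISH cell table
#'
#' Splits a cell count table by `sample_id`, scores each sample, and returns
#' one row per sample in the layout of a published score table.
#'
#' @param cells data.frame from `read_cell_counts()` (columns `sample_id`,
#'   `cell_id`, `gene_signals`, `cep_signals`).
#' @param sa_flags optional data.frame (`sample_id`, `structural_alteration`)
#'   or named logical vector of per-sample annotations; samples absent
#'   default to `FALSE`.
#' @param config a `genedose_config`.
#' @return A data.frame with columns `sample_id`, `n_cells`, `mean_gene`,
#'   `mean_cep`, `ratio`, `major_clone` (`"g:c"`), `percent` (clone
#'   percentage, rounded to integer), `interpretation`.
#' @export
score_samples <- function(cells, sa_flags = NULL, config = default_config()) {
  stopifnot("sample_id" %in% names(cells))
  flags <- normalize_sa_flags(sa_flags)
  ids <- unique(cells$sample_id)  # preserve input order
  rows <- lapply(ids, function(id) {
    res <- score_sample(cells[cells$sample_id == id, , drop = FALSE],
                        sa_flag = isTRUE(flags[[id]]), config = config)
    top <- res$summary$major_clones[1L, ]
    data.frame(
      sample_id = id,
      n_cells = res$summary$n_cells,
      mean_gene = res$summary$mean_gene,
      mean_cep = res$summary$mean_cep,
      ratio = res$summary$ratio,
      major_clone = sprintf("%d:%d", top$gene, top$cep),
      percent = as.integer(round_half_up(100 * top$fraction, 0)),
      interpretation = res$call$label,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

normalize_sa_flags <- function(sa_flags) {
  if (is.null(sa_flags)) return(list())
  if (is.data.frame(sa_flags)) {
    stopifnot(all(c("sample_id", "structural_alteration") %in% names(sa_flags)))
    out <- as.list(as.logical(sa_flags$structural_alteration))
    names(out) <- sa_flags$sample_id
    return(out)
  }
  as.list(sa_flags)
}

#' @export
print.fish_summary <- function(x, ...) {
  cat(sprintf("FISH summary: %d cells\n", x$n_cells))
  cat(sprintf("  mean gene/cell: %.*f   mean CEP/cell: %.*f   ratio: %.*f\n",
              x$precision, x$mean_gene, x$precision, x$mean_cep,
              x$precision, x$ratio))
  top <- utils::head(x$major_clones, 3L)
  cat("  major clones: ",
      paste(sprintf("%d:%d (%.0f%%)", top$gene, top$cep, 100 * top$fraction),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.fish_call <- function(x, ...) {
  cat("FISH call:", x$label, "\n")
  cat(sprintf("  amplified: %s (ratio %.1f)   polysomy: %s   balance: %s\n",
              x$amplified, x$ratio, x$polysomy_level, x$balance))
  invisible(x)
}
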