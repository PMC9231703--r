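#' Read a per-cell dual-probe FISH count table
#'
#' Reads a TSV with columns `sample_id`, `cell_id`, `gene_signals`,
#' `cep_signals`: one row per scored nucleus, with the number of gene-probe
#' and centromere-probe spots counted in that nucleus. Counts must be
#' nonnegative integers; malformed rows are rejected with their row number.
#'
#' @param path path to the TSV file.
#' @return A data.frame with the four columns, input order preserved;
#'   `sample_id` defines the grouping used downstream.
#' @export
read_cell_counts <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "cell_id", "gene_signals", "cep_signals"))
  for (col in c("gene_signals", "cep_signals")) {
    v <- df[[col]]
    bad <- which(!is_nonneg_int(v))
    if (length(bad)) {
      stop(sprintf(
        "%s: column '%s' must be a nonnegative integer; first bad data row: %d (value '%s')",
        path, col, bad[1], as.character(v[bad[1]])
      ))
    }
    df[[col]] <- as.integer(v)
  }
  df$sample_id <- as.character(df$sample_id)
  df$cell_id <- as.character(df$cell_id)
  df
}

#' Read a bedGraph signal track
#'
#' Imports a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' track, skipping track-definition and comment lines, and returns signal
#' segments sorted by (chrom, start). Negative values and segments that
#' overlap on one chromosome are format errors: a signal track is a partial
#' step function, so overlap would make the region area ill-defined.
#'
#' @param path path to the bedGraph file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value`, sorted by (chrom, start).
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  seg <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  validate_segments(seg, path)
  seg
}

#' Read regions from a BED file
#'
#' @param path path to a BED file (0-based half-open, BED native).
#' @return A data.frame of `genomic_region()` rows: `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Construct a genomic region
#'
#' Regions are held 0-based half-open internally (bedGraph/BED native). A
#' region given in genome-browser style (1-based, fully closed, e.g. the
#' coordinates printed next to a browser screenshot) is converted on input
#' with `browser = TRUE`; requiring the explicit flag avoids a silent
#' off-by-one.
#'
#' @param chrom chromosome name.
#' @param start,end interval coordinates.
#' @param browser if `TRUE`, `start`/`end` are 1-based inclusive browser
#'   coordinates and are converted; if `FALSE` (default) they are already
#'   0-based half-open.
#' @return A one-row data.frame with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' # the promoter window chr9:36,571,990-36,574,891 as printed by a browser
#' genomic_region("chr9", 36571990, 36574891, browser = TRUE)
genomic_region <- function(chrom, start, end, browser = FALSE) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (browser) {
    start <- start - 1  # 1-based inclusive -> 0-based half-open
  }
  if (!(end > start) || start < 0) {
    stop("invalid region: need 0 <= start < end")
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Parse a region string
#'
#' Accepts `"chr9:100-200"` (with optional thousands separators). By default
#' the string is treated as browser style (1-based inclusive), which is how
#' such strings are written.
#'
#' @param spec region string `"chrom:start-end"`.
#' @param browser interpret coordinates as 1-based inclusive (default TRUE).
#' @return A one-row region data.frame.
#' @export
parse_region <- function(spec, browser = TRUE) {
  spec <- gsub(",", "", spec)
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", spec)
  genomic_region(m[2], as.numeric(m[3]), as.numeric(m[4]), browser = browser)
}

#' Read a qPCR Ct replicate table
#'
#' TSV columns: `sample_id`, `condition` (`sample` or `calibrator`), `role`
#' (`target` or `reference`), `replicate`, `ct`. Ct values must be finite and
#' positive.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "condition", "role", "replicate", "ct"))
  df$condition <- match_level(df$condition, c("sample", "calibrator"), path, "condition")
  df$role <- match_level(df$role, c("target", "reference"), path, "role")
  df$ct <- as.numeric(df$ct)
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad)) {
    stop(sprintf("%s: non-finite or nonpositive Ct at data row %d", path, bad[1]))
  }
  df
}

#' Read an IHC core score table
#'
#' TSV columns: `core_id`, `tissue_class` (`benign`, `DCIS`, `IDC`,
#' `metastasis`), `compartment` (`nuclear`, `cytoplasmic`), `intensity`
#' (grade 0-3), `percent_positive` (integer 0-100). Percent positivity is a
#' visually estimated integer, so non-integer input is rejected rather than
#' silently binned.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
read_ihc_table <- function(path) {
  df <- read_tsv_checked(
    path,
    c("core_id", "tissue_class", "compartment", "intensity", "percent_positive")
  )
  df$tissue_class <- match_level(df$tissue_class, tissue_classes(), path, "tissue_class")
  df$compartment <- match_level(df$compartment, c("nuclear", "cytoplasmic"), path, "compartment")
  for (col in c("intensity", "percent_positive")) {
    bad <- which(!is_nonneg_int(df[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be integer; first bad data row: %d", path, col, bad[1]))
    }
    df[[col]] <- as.integer(df[[col]])
  }
  if (any(df$intensity > 3L)) stop(path, ": intensity grade must be 0-3")
  if (any(df$percent_positive > 100L)) stop(path, ": percent_positive must be 0-100")
  bad <- which(df$intensity == 0L & df$percent_positive > 0L)
  if (length(bad)) {
    stop(sprintf("%s: intensity 0 with positive percent at data row %d", path, bad[1]))
  }
  df
}

#' Read a per-sample copy-number/expression table
#'
#' TSV columns: `sample_id`, `subtype`, `log2_cn`, `log2_expr`.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "subtype", "log2_cn", "log2_expr"))
  df$subtype <- match_level(df$subtype, subtypes(), path, "subtype")
  for (col in c("log2_cn", "log2_expr")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]))) stop(path, ": non-finite value in ", col)
  }
  df
}

#' Read a methylation beta-value table
#'
#' TSV columns: `sample_id`, `probe_id`, `beta` (in \[0,1\]), `subtype`.
#'
#' @param path path to the TSV file.
#' @return A validated data.frame.
#' @export
read_beta_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "probe_id", "beta", "subtype"))
  df$beta <- as.numeric(df$beta)
  bad <- which(!is.finite(df$beta) | df$beta < 0 | df$beta > 1)
  if (length(bad)) {
    stop(sprintf("%s: beta outside [0,1] at data row %d", path, bad[1]))
  }
  df
}

#' Write a table as TSV
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tissue_classes <- function() c("benign", "DCIS", "IDC", "metastasis")

subtypes <- function() {
  c("basal", "luminal_A", "luminal_B", "HER2", "normal_like", "other")
}

read_tsv_checked <- function(path, required) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  df
}

match_level <- function(x, levels, path, col) {
  x <- as.character(x)
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop(sprintf("%s: column '%s' has unknown value '%s' at data row %d (allowed: %s)",
                 path, col, x[bad[1]], bad[1], paste(levels, collapse = ", ")))
  }
  x
}

is_nonneg_int <- function(v) {
  suppressWarnings(num <- as.numeric(v))
  !is.na(num) & is.finite(num) & num >= 0 & num == floor(num)
}

validate_segments <- function(seg, what = "track") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(seg)))
  if (any(seg$end <= seg$start)) stop(what, ": segment with end <= start")
  if (any(seg$start < 0)) stop(what, ": negative coordinate")
  if (any(seg$value < 0)) stop(what, ": negative signal value")
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop(what, ": overlapping segments on ", chr)
    }
  }
  invisible(seg)
}

#' Write a signal track as bedGraph
#'
#' @param seg segment data.frame (`chrom`, `start`, `end`, `value`), 0-based
#'   half-open.
#' @param path output path.
#' @param name optional track name for the track-definition line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(seg, path, name = NULL) {
  validate_segments(seg)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  }
  utils::write.table(seg[, c("chrom", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
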