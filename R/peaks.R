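#' Total peak area of a signal track within a region
#'
#' The region-level signal statistic: a track is a piecewise-constant step
#' function (each segment a rectangle of width = genomic span and height =
#' signal value), and the total peak area is the sum of rectangle areas over
#' all segments within the region. Segments partially overlapping the region
#' contribute only their clipped width — the only convention under which the
#' area is independent of how the track was binned.
#'
#' @param track segment data.frame (`chrom`, `start`, `end`, `value`;
#'   0-based half-open) as from `read_bedgraph()` or
#'   `simulate_signal_track()`; segments of one chromosome must not overlap.
#' @param region one-row region data.frame (`genomic_region()` /
#'   `parse_region()`).
#' @return Numeric area in coordinate-units x signal; 0 for an empty track
#'   or a region the track does not touch.
#' @export
#' @examples
#' reg <- genomic_region("chr9", 100, 200)
#' trk <- data.frame(chrom = "chr9", start = 0, end = 150, value = 2)
#' peak_area(trk, reg)  # clipped width 50 -> area 100
peak_area <- function(track, region) {
  stopifnot(is.data.frame(region), nrow(region) == 1L,
            region$end > region$start)
  if (nrow(track) == 0L) return(0)
  validate_segments(track)
  s <- track[track$chrom == region$chrom, , drop = FALSE]
  if (nrow(s) == 0L) return(0)
  w <- pmin(s$end, region$end) - pmax(s$start, region$start)
  sum(pmax(w, 0) * s$value)
}

#' Peak areas for a set of sample tracks
#'
#' @param tracks named list of segment data.frames, one per sample.
#' @param region one-row region data.frame.
#' @return A data.frame with columns `sample_id`, `area`.
#' @export
peak_area_table <- function(tracks, region) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  data.frame(
    sample_id = names(tracks),
    area = vapply(tracks, peak_area, numeric(1), region = region),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Compare per-sample peak areas across groups
#'
#' Kruskal-Wallis rank test of region peak areas across molecular subtypes
#' (or any grouping).
#'
#' @param areas named numeric vector of per-sample areas, or the data.frame
#'   from `peak_area_table()`.
#' @param groups named character vector (or data.frame with `sample_id`,
#'   `subtype`) mapping each sample to its group.
#' @return A `genedose_test` / `htest` object from `kruskal_wallis()`.
#' @export
compare_area_by_group <- function(areas, groups) {
  if (is.data.frame(areas)) {
    a <- stats::setNames(areas$area, areas$sample_id)
  } else a <- areas
  if (is.data.frame(groups)) {
    g <- stats::setNames(groups$subtype, groups$sample_id)
  } else g <- groups
  if (is.null(names(a)) || any(!names(a) %in% names(g))) {
    stop("every sample with an area needs a group label")
  }
  g <- g[names(a)]
  if (length(unique(g)) < 2L) stop("need >= 2 groups to compare")
  kruskal_wallis(split(unname(a), g))
}

#' Compare methylation beta values across groups, per probe
#'
#' For each probe in `probes`, runs a Kruskal-Wallis test of beta values
#' across subtypes, then adjusts the per-probe p-values by Holm's step-down
#' method.
#'
#' @param betas data.frame in `read_beta_table()` format (`sample_id`,
#'   `probe_id`, `beta`, `subtype`).
#' @param probes character vector of probe ids to test (default: promoter
#'   CpG probes closest to the transcription start site used by the region
#'   default). An empty subset returns an empty result.
#' @return A data.frame with columns `probe_id`, `n`, `statistic`, `df`,
#'   `p_value`, `p_holm`.
#' @export
compare_beta_by_group <- function(betas, probes = default_beta_probes()) {
  stopifnot(all(c("probe_id", "beta", "subtype") %in% names(betas)))
  if (any(betas$beta < 0 | betas$beta > 1)) stop("beta outside [0,1]")
  probes <- probes[probes %in% betas$probe_id]
  if (length(probes) == 0L) {
    return(data.frame(probe_id = character(), n = integer(),
                      statistic = numeric(), df = integer(),
                      p_value = numeric(), p_holm = numeric()))
  }
  rows <- lapply(probes, function(pr) {
    d <- betas[betas$probe_id == pr, , drop = FALSE]
    if (length(unique(d$subtype)) < 2L) {
      stop("probe ", pr, " has fewer than 2 groups")
    }
    ht <- kruskal_wallis(split(d$beta, d$subtype))
    data.frame(probe_id = pr, n = nrow(d),
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Default promoter methylation probes
#'
#' The CpG probes nearest the transcription start site of the promoter
#' region the package defaults to. Any probe list can be supplied instead.
#'
#' @return Character vector of probe ids.
#' @export
default_beta_probes <- function() {
  c("cg14552260", "cg14339556", "cg13912011")
}

#' Default promoter analysis region
#'
#' The chr9 promoter window used as the default region for peak-area
#' quantification, stored 0-based half-open (converted from the 1-based
#' browser coordinates chr9:36,571,990-36,574,891).
#'
#' @return A one-row region data.frame.
#' @export
default_region <- function() {
  genomic_region("chr9", 36571990, 36574891, browser = TRUE)
}
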