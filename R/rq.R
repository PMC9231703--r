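#' Relative quantification by the delta-delta-Ct method
#'
#' Computes the relative quantification (RQ, fold change) of a target gene in
#' a sample versus a calibrator, each normalized to an endogenous reference:
#' \deqn{\Delta Ct_{cond} = \overline{Ct}_{target} - \overline{Ct}_{reference}}
#' \deqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator},
#'       \quad RQ = 2^{-\Delta\Delta Ct}}
#' The RQ spread is estimated, by default, as the standard deviation of the
#' per-replicate RQ values formed by pairing replicate i across the four
#' design cells (replicates beyond the shortest list are ignored); set
#' `config$rq_sd_estimator = "propagated"` for the delta-Ct
#' variance-propagation alternative.
#'
#' @param ct data.frame in `read_ct_table()` format: columns `condition`
#'   (`sample`/`calibrator`), `role` (`target`/`reference`), `replicate`,
#'   `ct`; at least 2 replicates in each of the four design cells.
#' @param config a `genedose_config`.
#' @return An object of class `rq_result`: list with `rq`, `sd`,
#'   `delta_delta_ct`, `band` (unset, `NA`; see `classify_rq()`), `n_reps`.
#' @export
#' @examples
#' tab <- simulate_qpcr(true_fold_change = 50, replicate_sd = 0, seed = 1)
#' delta_delta_ct(tab)
delta_delta_ct <- function(ct, config = default_config()) {
  stopifnot(is.data.frame(ct),
            all(c("condition", "role", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct value")
  cells <- list(
    st = ct$ct[ct$condition == "sample" & ct$role == "target"],
    sr = ct$ct[ct$condition == "sample" & ct$role == "reference"],
    ct_ = ct$ct[ct$condition == "calibrator" & ct$role == "target"],
    cr = ct$ct[ct$condition == "calibrator" & ct$role == "reference"]
  )
  n <- vapply(cells, length, integer(1))
  if (any(n < 2L)) {
    stop("each condition x role design cell needs >= 2 replicates")
  }
  dct_sample <- mean(cells$st) - mean(cells$sr)
  dct_calib <- mean(cells$ct_) - mean(cells$cr)
  ddct <- dct_sample - dct_calib
  rq <- 2^(-ddct)

  m <- min(n)
  rep_rq <- 2^(-((cells$st[seq_len(m)] - cells$sr[seq_len(m)]) -
                 (cells$ct_[seq_len(m)] - cells$cr[seq_len(m)])))
  sd_out <- if (identical(config$rq_sd_estimator, "propagated")) {
    # SD of ddCt propagated from the four cells, on the RQ scale
    v <- stats::var(cells$st) / n[1] + stats::var(cells$sr) / n[2] +
      stats::var(cells$ct_) / n[3] + stats::var(cells$cr) / n[4]
    rq * log(2) * sqrt(v)
  } else {
    stats::sd(rep_rq)
  }
  structure(
    list(rq = rq, sd = sd_out, delta_delta_ct = ddct, band = NA_character_,
         n_reps = m),
    class = "rq_result"
  )
}

#' Band a relative-quantification value
#'
#' Assigns an RQ fold change to an expression band: `high` (RQ >= 50),
#' `moderate` (20 <= RQ < 50), `low` (1 < RQ < 20) or `baseline` (RQ <= 1;
#' the calibrator itself sits at exactly 1). Cutoffs come from the
#' configuration.
#'
#' @param rq positive fold change(s); vectorized.
#' @param config a `genedose_config`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' classify_rq(c(381.55, 27.43, 5.09, 1.0))
classify_rq <- function(rq, config = default_config()) {
  if (any(!is.finite(rq)) || any(rq <= 0)) stop("rq must be positive")
  ifelse(rq >= config$rq_high_min, "high",
    ifelse(rq >= config$rq_moderate_min, "moderate",
      ifelse(rq > config$rq_baseline_max, "low", "baseline")))
}

#' Quantify and band every sample of a Ct table
#'
#' @param ct data.frame in `read_ct_table()` format, with a `sample_id`
#'   column; each sample must contain its own calibrator rows.
#' @param config a `genedose_config`.
#' @return A data.frame with columns `sample_id`, `rq`, `sd` (both rounded
#'   half-up to the configured precision), `band`.
#' @export
rq_table <- function(ct, config = default_config()) {
  stopifnot("sample_id" %in% names(ct))
  ids <- unique(ct$sample_id)
  rows <- lapply(ids, function(id) {
    r <- delta_delta_ct(ct[ct$sample_id == id, , drop = FALSE], config)
    data.frame(
      sample_id = id,
      rq = round_half_up(r$rq, config$rq_precision),
      sd = round_half_up(r$sd, config$rq_precision),
      band = classify_rq(r$rq, config),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("RQ = %.2f (ddCt = %.3f, sd = %.2f, %d paired replicates)",
              x$rq, x$delta_delta_ct, x$sd, x$n_reps))
  if (!is.na(x$band)) cat(" band:", x$band)
  cat("\n")
  invisible(x)
}
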