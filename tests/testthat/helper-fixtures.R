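# Published cell-line score table used as fixtures: reported mean gene and
# centromere copies per cell, the top major clone, structural-alteration
# annotation, and the printed ratio and interpretation. SKBR3's printed
# ratio (1.1) is inconsistent with its printed means (3.1/3.0 -> 1.0) and is
# flagged with ratio NA here; its interpretation is still asserted.
cell_line_table <- function() {
  rows <- list(
    list("HCC70",    8.9, 10.6, 9, 10, FALSE, 0.8, "High unbalanced polysomy"),
    list("BT549",    6.4,  7.7, 6,  8, FALSE, 0.8, "High unbalanced polysomy"),
    list("UACC3199", 4.0,  4.0, 4,  4, FALSE, 1.0, "High balanced polysomy"),
    list("HCC1187",  3.0,  2.9, 3,  3, FALSE, 1.0, "Low balanced polysomy"),
    list("MDAMB231", 3.2,  3.1, 3,  3, FALSE, 1.0, "Low balanced polysomy"),
    list("HCC1954",  3.1,  3.8, 3,  4, FALSE, 0.8, "Low unbalanced polysomy"),
    list("BT20",     2.0,  3.0, 2,  3, TRUE,  0.7, "SA, unbalanced disomy"),
    list("HCC1937",  3.8,  3.8, 4,  4, FALSE, 1.0, "High balanced polysomy"),
    list("HCC1500",  2.0,  2.1, 2,  2, FALSE, 1.0, "Disomy balanced"),
    list("HCC1428",  3.8,  3.8, 4,  4, FALSE, 1.0, "High balanced polysomy"),
    list("T47D",     2.0,  1.2, 2,  1, TRUE,  1.7, "SA, CEP9 hemizygous deletion"),
    list("MCF7",     3.0,  3.0, 3,  3, FALSE, 1.0, "Low balanced polysomy"),
    list("ZR7530",   3.0,  3.0, 3,  3, FALSE, 1.0, "Low balanced polysomy"),
    list("HCC2185", 29.1,  5.3, 29, 5, FALSE, 5.5, "High ampl; CEP9 high polysomy"),
    list("HCC202",   3.0,  5.1, 3,  5, FALSE, 0.6, "Unbalanced polysomy"),
    list("SKBR3",    3.1,  3.0, 3,  3, FALSE, NA,  "Low balanced polysomy")
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], mean_gene = r[[2]], mean_cep = r[[3]],
               clone_gene = r[[4]], clone_cep = r[[5]], sa = r[[6]],
               ratio = r[[7]], interpretation = r[[8]],
               stringsAsFactors = FALSE)
  })
  )
  df
}

# Published RQ column: value and printed band.
rq_fixture <- function() {
  data.frame(
    sample_id = c("HCC70", "UACC3199", "HCC1187", "MDAMB231", "HCC1954",
                  "BT20", "HCC1937", "HCC1500", "HCC1428", "T47D", "MCF7",
                  "ZR7530", "HCC2185", "HCC202", "SKBR3", "HMEC"),
    rq = c(381.55, 86.04, 57.38, 44.18, 41.29, 38.36, 34.51, 29.11, 50.78,
           27.43, 12.90, 19.05, 265.44, 28.07, 5.09, 1.00),
    band = c("high", "high", "high", "moderate", "moderate", "moderate",
             "moderate", "moderate", "high", "moderate", "low", "low",
             "high", "moderate", "low", "baseline"),
    stringsAsFactors = FALSE
  )
}

# Build a 10-cell population whose exact means equal the reported
# one-decimal means and whose modal pattern is the reported major clone:
# 6 cells at the clone pattern, the remainder of each probe's total spread
# near-evenly over the other 4 cells (any leftover pattern has frequency
# <= 4 < 6, so the intended clone stays modal).
cells_from_summary <- function(mean_gene, mean_cep, clone_gene, clone_cep,
                               sample_id = "S") {
  n <- 10L
  k <- 6L
  total_g <- round(mean_gene * n)
  total_c <- round(mean_cep * n)
  stopifnot(abs(total_g - mean_gene * n) < 1e-6,
            abs(total_c - mean_cep * n) < 1e-6)
  rest_g <- total_g - k * clone_gene
  rest_c <- total_c - k * clone_cep
  m <- n - k
  stopifnot(rest_g >= 0, rest_c >= 0)
  spread <- function(total, m) {
    base <- total %/% m
    extra <- total %% m
    base + (seq_len(m) <= extra)
  }
  data.frame(
    sample_id = sample_id,
    cell_id = sprintf("c%02d", seq_len(n)),
    gene_signals = as.integer(c(rep(clone_gene, k), spread(rest_g, m))),
    cep_signals = as.integer(c(rep(clone_cep, k), spread(rest_c, m))),
    stringsAsFactors = FALSE
  )
}

# Uniform-clone population shortcut.
uniform_cells <- function(g, c9, n = 20L, sample_id = "S") {
  data.frame(sample_id = sample_id, cell_id = sprintf("c%03d", seq_len(n)),
             gene_signals = as.integer(g), cep_signals = as.integer(c9),
             stringsAsFactors = FALSE)
}

# Independent rule table for single-clone populations (g, c): a direct
# transcription of the written classification rules, kept separate from the
# package's implementation.
rule_table_call <- function(g, c9) {
  if (g == 0 && c9 == 0) return(NA_character_)
  ratio <- if (c9 > 0) round(floor((g / c9) * 10 + 0.5) / 10, 10) else Inf
  if (ratio >= 2) {
    lev <- if (c9 >= 4) "high polysomy" else if (c9 == 3) "low polysomy"
      else if (c9 == 2) "disomy" else if (c9 == 1) "hemizygous deletion" else "loss"
    qual <- if (ratio >= 5) "High ampl" else "Ampl"
    return(paste0(qual, "; CEP9 ", lev))
  }
  if (c9 == 1 && g >= 2) return("CEP9 hemizygous deletion")
  if (g == 0) return("MELK nullisomy")
  if (g == 1) return("MELK hemizygous deletion")
  if (g == 2) return(if (g == c9) "Disomy balanced" else "Unbalanced disomy")
  lev <- if (g >= 4) "High" else "Low"
  band <- function(k) if (k >= 4) 2 else if (k == 3) 1 else 0
  if (band(g) != band(c9) && abs(g - c9) >= 2) lev <- NA
  bal <- if (g == c9) "balanced" else "unbalanced"
  if (is.na(lev)) {
    paste0(toupper(substr(bal, 1, 1)), substr(bal, 2, nchar(bal)), " polysomy")
  } else {
    paste(lev, bal, "polysomy")
  }
}
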