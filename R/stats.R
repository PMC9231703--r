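#' Pearson correlation with t-test p-value
#'
#' Sample Pearson correlation of two numeric vectors, with the two-sided
#' p-value from the exact t transform `t = r sqrt((n-2)/(1-r^2))` on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return An object of classes `genedose_test` and `htest` with `estimate`
#'   (r), `statistic` (t), `parameter` (df) and `p.value`.
#' @export
#' @examples
#' d <- simulate_cn_expression(200, target_r = 0.5, seed = 1)
#' pearson_r(d$log2_cn, d$log2_expr)
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0) stop("x has zero variance")
  if (sy == 0) stop("y has zero variance")
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  t <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  new_test(
    statistic = c(t = t), parameter = c(df = df), p.value = min(1, p),
    estimate = c(r = r), method = "Pearson product-moment correlation",
    n = n, ties_corrected = FALSE
  )
}

#' Kendall's tau-b with tie correction
#'
#' Rank correlation for ordinal variables with tied ranks:
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' with C/D the concordant/discordant pair counts, `n0 = n(n-1)/2` and
#' `n1`, `n2` the tie terms `sum t_i (t_i - 1) / 2` for x and y. The p-value
#' uses the normal approximation for S = C - D with the tie-adjusted
#' variance, two-sided.
#'
#' @param x,y equal-length vectors (numeric or ordered values coercible to
#'   numeric ranks), n >= 2; not all tied in either variable.
#' @return A `genedose_test` / `htest` object with `estimate` (tau_b),
#'   `statistic` (z) and `p.value`.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need n >= 2")
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod_ <- dx[up] * dy[up]
  S <- sum(prod_)                       # C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  if (n1 == n0) stop("all x values tied: tau-b undefined")
  if (n2 == n0) stop("all y values tied: tau-b undefined")
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  # tie-adjusted variance of S (Kendall)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (var_s > 0) S / sqrt(var_s) else 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test(
    statistic = c(z = z), parameter = NULL, p.value = p,
    estimate = c(tau_b = tau),
    method = "Kendall's tau-b (tie-adjusted normal approximation)",
    n = n, ties_corrected = TRUE
  )
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H across two or more groups, with the
#' chi-square approximation on k-1 degrees of freedom. With every
#' observation tied the tie-correction denominator vanishes; by convention
#' H = 0 and p = 1 (no evidence of any group difference).
#'
#' @param groups list of numeric vectors, one per group (>= 2 nonempty
#'   groups, total n >= 3).
#' @return A `genedose_test` / `htest` object with `statistic` (H),
#'   `parameter` (df) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need >= 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite input")
  N <- length(x)
  if (N < 3L) stop("need total n >= 3")
  r <- rank(x)
  grp <- rep(seq_along(groups), sizes)
  Rsum <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  new_test(
    statistic = c(H = H), parameter = c(df = length(groups) - 1L),
    p.value = p, estimate = NULL,
    method = "Kruskal-Wallis rank sum test (tie-corrected)",
    n = N, ties_corrected = TRUE
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with the tie-corrected normal approximation and
#' continuity correction, two-sided. The statistic reported is W, the number
#' of (a, b) pairs with a > b counting ties as 1/2 (the Mann-Whitney form).
#'
#' @param a,b nonempty numeric vectors.
#' @return A `genedose_test` / `htest` object.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  x <- c(a, b)
  if (any(!is.finite(x))) stop("non-finite input")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(x)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for a
  mu <- n1 * n2 / 2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    cc <- sign(W - mu) * 0.5  # continuity correction toward the mean
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_test(
    statistic = c(W = W), parameter = NULL, p.value = p, estimate = NULL,
    method = "Wilcoxon rank sum test (tie-corrected normal approximation)",
    n = N, ties_corrected = TRUE
  )
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with the Welch (unequal-variance) statistic and
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric vectors, n >= 2 each; at least one with nonzero
#'   variance.
#' @return A `genedose_test` / `htest` object.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per sample")
  if (any(!is.finite(c(a, b)))) stop("non-finite input")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both samples")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- min(1, 2 * stats::pt(-abs(t), df))
  new_test(
    statistic = c(t = t), parameter = c(df = df), p.value = p,
    estimate = c(mean_difference = mean(a) - mean(b)),
    method = "Welch two-sample t-test", n = na + nb, ties_corrected = FALSE
  )
}

#' Holm step-down p-value adjustment
#'
#' Sorts the m p-values ascending, multiplies the i-th by (m - i + 1),
#' enforces monotone nondecrease, caps at 1, and returns the adjusted values
#' in the original input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  adj <- pmin(1, p[o] * (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Copy-number / expression integration report
#'
#' The integration driver: pooled Pearson correlation of log2 copy number
#' with log2 expression; Kruskal-Wallis comparison of each variable across
#' molecular subtypes; and pairwise basal-versus-each-other-subtype Wilcoxon
#' rank-sum tests, Holm-adjusted within each variable. Pairwise comparisons
#' use rank-sum tests with Holm adjustment in place of cumulative link mixed
#' models; the report notes this substitution.
#'
#' @param records data.frame in `read_sample_table()` format (`sample_id`,
#'   `subtype`, `log2_cn`, `log2_expr`) with >= 2 subtypes present.
#' @param reference_subtype subtype each other subtype is compared against
#'   (default `"basal"`; must be present in the data).
#' @return An object of class `cn_expression_report`: list with
#'   `correlation` (`genedose_test`), `group_tests` (named list of
#'   Kruskal-Wallis results for `log2_cn` and `log2_expr`), `pairwise`
#'   (data.frame: variable, subtype, statistic, p_value, p_holm), `note`.
#' @export
cn_expression_report <- function(records, reference_subtype = "basal") {
  stopifnot(all(c("subtype", "log2_cn", "log2_expr") %in% names(records)))
  subs <- unique(records$subtype)
  if (length(subs) < 2L) stop("need >= 2 subtypes")
  if (!reference_subtype %in% subs) {
    stop("reference subtype '", reference_subtype, "' not present")
  }
  correlation <- pearson_r(records$log2_cn, records$log2_expr)
  vars <- c("log2_cn", "log2_expr")
  group_tests <- lapply(vars, function(v) {
    kruskal_wallis(split(records[[v]], records$subtype))
  })
  names(group_tests) <- vars
  others <- setdiff(subs, reference_subtype)
  pw <- do.call(rbind, lapply(vars, function(v) {
    ref <- records[[v]][records$subtype == reference_subtype]
    rows <- lapply(others, function(s) {
      ht <- wilcoxon_rank_sum(ref, records[[v]][records$subtype == s])
      data.frame(variable = v, subtype = s,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$p_holm <- holm_adjust(d$p_value)
    d
  }))
  rownames(pw) <- NULL
  structure(
    list(
      correlation = correlation,
      group_tests = group_tests,
      pairwise = pw,
      n = nrow(records),
      reference_subtype = reference_subtype,
      note = paste("Pairwise comparisons: Wilcoxon rank-sum with Holm",
                   "adjustment (substitute for cumulative link mixed models).")
    ),
    class = "cn_expression_report"
  )
}

#' @export
print.cn_expression_report <- function(x, digits = 4, ...) {
  cat("Copy-number / expression integration report\n")
  cat(sprintf("  n = %d samples; reference subtype: %s\n", x$n,
              x$reference_subtype))
  cat(sprintf("  pooled Pearson r = %.3f (p = %.3g)\n",
              x$correlation$estimate[["r"]], x$correlation$p.value))
  for (v in names(x$group_tests)) {
    gt <- x$group_tests[[v]]
    cat(sprintf("  %s across subtypes: H = %.3f, p = %.3g\n", v,
                gt$statistic[["H"]], gt$p.value))
  }
  cat("  pairwise (", x$reference_subtype, " vs other), Holm-adjusted:\n",
      sep = "")
  print(x$pairwise, digits = digits)
  cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

# Minimal htest-compatible constructor so results print via stats.
new_test <- function(statistic, parameter, p.value, estimate, method, n,
                     ties_corrected) {
  structure(
    list(statistic = statistic, parameter = parameter, p.value = p.value,
         estimate = estimate, method = method,
         data.name = "x", n = n, ties_corrected = ties_corrected),
    class = c("genedose_test", "htest")
  )
}
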