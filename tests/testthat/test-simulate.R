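test_that("FISH population generator is deterministic and respects the mixture", {
  clones <- list(c(gene_copies = 3, cep_copies = 4, fraction = 0.8),
                 c(gene_copies = 2, cep_copies = 2, fraction = 0.2))
  a <- simulate_fish_population(clones, 500, miscount_rate = 0.05, seed = 42)
  b <- simulate_fish_population(clones, 500, miscount_rate = 0.05, seed = 42)
  expect_identical(a, b)

  one <- simulate_fish_population(
    list(c(gene_copies = 2, cep_copies = 2, fraction = 1)), 100, seed = 1)
  expect_true(all(one$gene_signals == 2L & one$cep_signals == 2L))

  big <- simulate_fish_population(clones, 10000, miscount_rate = 0, seed = 7)
  frac34 <- mean(big$gene_signals == 3L & big$cep_signals == 4L)
  expect_lt(abs(frac34 - 0.8), 0.02)

  expect_error(simulate_fish_population(list(), 10), "empty clone")
  expect_error(simulate_fish_population(
    list(c(gene_copies = 2, cep_copies = 2, fraction = 0.9)), 10),
    "sum to 1")
})

test_that("miscount perturbation is bounded to one signal and floored at zero", {
  pop <- simulate_fish_population(
    list(c(gene_copies = 1, cep_copies = 0, fraction = 1)),
    5000, miscount_rate = 0.4, seed = 11)
  expect_true(all(pop$gene_signals %in% 0:2))
  expect_true(all(pop$cep_signals %in% 0:1))  # 0 can only move up
  expect_gt(mean(pop$gene_signals != 1L), 0.2)  # perturbation actually occurs
})

test_that("qPCR generator encodes the fold change exactly at zero noise", {
  tab <- simulate_qpcr(true_fold_change = 1, replicate_sd = 0, seed = 3)
  r <- delta_delta_ct(tab)
  expect_identical(r$rq, 1)
  expect_identical(r$delta_delta_ct, 0)

  tab50 <- simulate_qpcr(50, replicate_sd = 0.05, n_reps = 4, seed = 8)
  expect_true(delta_delta_ct(tab50)$rq > 45 && delta_delta_ct(tab50)$rq < 55)

  # a reported fold change recovered to printed precision at zero noise
  tabhi <- simulate_qpcr(381.55, replicate_sd = 0, seed = 1)
  expect_equal(round(delta_delta_ct(tabhi)$rq, 2), 381.55)

  expect_error(simulate_qpcr(-2), "positive")
  expect_error(simulate_qpcr(2, n_reps = 1), "n_reps")
})

test_that("IHC cohort generator honors the scoring constraints", {
  strong <- list(intensity_probs = c(0, 0, 0, 1), percent_min = 50, percent_max = 100)
  absent <- list(intensity_probs = c(1, 0, 0, 0), percent_min = 0, percent_max = 0)
  m0 <- ihc_group_model("benign", nuclear = absent, cytoplasmic = strong)
  coh <- simulate_ihc_cohort(list(m0), 50, seed = 4)
  # nuclear percent 0 forces cytoplasmic staining to 0
  expect_true(all(coh$intensity == 0L & coh$percent_positive == 0L))
  expect_true(all(irs(coh$intensity, coh$percent_positive)$combined == 0L))

  m1 <- ihc_group_model("IDC", nuclear = strong, cytoplasmic = strong)
  coh1 <- simulate_ihc_cohort(list(m1), 40, seed = 4)
  expect_true(all(coh1$percent_positive[coh1$intensity == 0L] == 0L))
  expect_true(all(coh1$percent_positive[coh1$intensity > 0L] > 0L))

  expect_identical(simulate_ihc_cohort(list(m1), 10, seed = 5),
                   simulate_ihc_cohort(list(m1), 10, seed = 5))
  expect_error(simulate_ihc_cohort(list(), 10), "empty model")
})

test_that("IHC generator reproduces group positivity rates at large n", {
  # cytoplasmic positivity by class, matching reported cohort rates:
  # benign 1/33, IDC 17/39 (strong staining when present, so any positive
  # draw scores IRS-positive)
  mk <- function(class, p_pos) {
    ihc_group_model(
      class,
      nuclear = list(intensity_probs = c(0, 0, 0, 1),
                     percent_min = 60, percent_max = 100),
      cytoplasmic = list(intensity_probs = c(1 - p_pos, 0, p_pos, 0),
                         percent_min = 81, percent_max = 100)
    )
  }
  coh <- simulate_ihc_cohort(list(mk("benign", 1 / 33), mk("IDC", 17 / 39)),
                             n_per_group = 10000, seed = 6)
  s <- cohort_summary(coh, "cytoplasmic")
  p_emp <- s$n_positive / s$n
  expect_lt(abs(p_emp[s$tissue_class == "benign"] - 1 / 33), 0.02)
  expect_lt(abs(p_emp[s$tissue_class == "IDC"] - 17 / 39), 0.02)
})

test_that("signal-track generator tiles exactly and areas are additive", {
  reg <- genomic_region("chr9", 0, 1000)
  trk <- simulate_signal_track(reg, list(c(start = 200, end = 500, height = 3)),
                               bin_width = 40, noise_sd = 0, seed = 1)
  expect_true(all(trk$end - trk$start <= 40))
  expect_equal(trk$start[1], 0)
  expect_equal(trk$end[nrow(trk)], 1000)
  expect_true(all(trk$start[-1] == trk$end[-nrow(trk)]))  # gapless tiling
  expect_equal(peak_area(trk, reg), 3 * 300)

  flat <- simulate_signal_track(reg, list(), bin_width = 100, noise_sd = 0, seed = 1)
  expect_equal(peak_area(flat, reg), 0)

  two <- simulate_signal_track(reg, list(c(start = 0, end = 100, height = 2),
                                         c(start = 600, end = 650, height = 7)),
                               bin_width = 30, noise_sd = 0, seed = 1)
  expect_equal(peak_area(two, reg), 2 * 100 + 7 * 50)

  expect_error(simulate_signal_track(
    reg, list(c(start = 0, end = 300, height = 1),
              c(start = 200, end = 400, height = 1))), "overlapping peak")
  expect_error(simulate_signal_track(
    reg, list(c(start = 900, end = 1100, height = 1))), "outside region")
})

test_that("cn/expression generator hits the target correlation and shifts", {
  d0 <- simulate_cn_expression(10000, target_r = 0, seed = 12)
  expect_lt(abs(cor(d0$log2_cn, d0$log2_expr)), 0.05)

  d5 <- simulate_cn_expression(2000, target_r = 0.5, seed = 12)
  expect_true(cor(d5$log2_cn, d5$log2_expr) > 0.45 &&
              cor(d5$log2_cn, d5$log2_expr) < 0.55)

  d1 <- simulate_cn_expression(5000, target_r = 0.3,
                               subtype_effects = list(other = c(0, 0)),
                               proportions = c(other = 1), seed = 2)
  expect_lt(abs(mean(d1$log2_cn)), 0.05)
  expect_lt(abs(mean(d1$log2_expr)), 0.05)

  ds <- simulate_cn_expression(
    4000, target_r = 0.3,
    subtype_effects = list(basal = c(0.4, 1.5), luminal_A = c(0, 0)),
    proportions = c(basal = 0.5, luminal_A = 0.5), seed = 2)
  shift <- mean(ds$log2_expr[ds$subtype == "basal"]) -
    mean(ds$log2_expr[ds$subtype == "luminal_A"])
  expect_lt(abs(shift - 1.5), 0.1)

  expect_error(simulate_cn_expression(100, target_r = 1), "target_r")
  expect_error(simulate_cn_expression(100, 0.2, proportions = c(other = 0.5)),
               "sum to 1")
})

test_that("generators draw independent substreams of one global seed", {
  fish1 <- simulate_fish_population(
    list(c(gene_copies = 3, cep_copies = 3, fraction = 1)),
    50, miscount_rate = 0.2, seed = 99)
  # interleave another stage's generator; same-stage draws must not change
  invisible(simulate_qpcr(5, seed = 99))
  fish2 <- simulate_fish_population(
    list(c(gene_copies = 3, cep_copies = 3, fraction = 1)),
    50, miscount_rate = 0.2, seed = 99)
  expect_identical(fish1, fish2)
  # and the generators leave the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_cn_expression(100, 0.2, seed = 1))
  expect_identical(.Random.seed, before)
})
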