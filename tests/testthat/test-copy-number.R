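test_that("standard-curve efficiency follows the dilution slope", {
  ld <- c(0, -1, -2, -3)
  # perfect doubling chemistry: slope -1/log10(2)
  ct <- 20 - ld / log10(2)
  cv <- efficiency_from_curve(ld, ct)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(cv$efficiency, 2, tolerance = 1e-10)
  expect_equal(cv$r2, 1, tolerance = 1e-9)
  # oracle: direct evaluation of 10^(1/3.5)
  cv2 <- efficiency_from_curve(ld, 20 - 3.5 * ld)
  expect_equal(cv2$efficiency, 10^(1 / 3.5), tolerance = 1e-10)
  expect_equal(cv2$efficiency, 1.93, tolerance = 0.005)
  expect_error(efficiency_from_curve(c(0, -1), c(20, 23)), "at least 3")
  expect_error(efficiency_from_curve(ld, 20 + 2 * ld), "invalid")
})

test_that("relative concentrations are efficiency powers of delta-Ct", {
  expect_equal(relative_concentration(25, 25, 2), 1)
  expect_equal(relative_concentration(23, 25, 2), 4)  # 2 cycles earlier
  # Dover-like worked case: delta-Ct of log2(4.5) means 4.5-fold, 9 total copies
  expect_equal(relative_concentration(25 - log2(4.5), 25, 2), 4.5,
               tolerance = 1e-12)
  expect_error(relative_concentration(20, 21, 1), "\\(1, 2.2\\]")
})

test_that("a wild-type sample referenced to itself carries exactly two copies", {
  g <- gen_qpcr(c(wt1 = 2, wt2 = 2), ct_noise_sd = 0, loading_factors = 1,
                seed = 1)
  r <- copy_number(g$wells, g$primers, wt_samples = c("wt1", "wt2"))
  expect_equal(r$total_copies, c(2, 2), tolerance = 1e-12)
  expect_equal(r$transgenic_copies, c(0, 0), tolerance = 1e-12)
})

test_that("a hand-built Dover-like table yields 7 transgenic copies", {
  # deltaD wells 4.5-fold the WT amount (delta-Ct = log2(4.5)); deltaC equal
  wells <- rbind(
    data.frame(sample_id = "wt", primer_id = c("dD_1", "dD_1", "dC_1", "dC_1"),
               replicate = c(1, 2, 1, 2), ct = c(25, 25, 26, 26)),
    data.frame(sample_id = "dover", primer_id = c("dD_1", "dD_1", "dC_1", "dC_1"),
               replicate = c(1, 2, 1, 2), ct = c(25 - log2(4.5), 25 - log2(4.5), 26, 26)))
  primers <- data.frame(primer_id = c("dD_1", "dC_1"),
                        target = c("deltaD", "deltaC"), efficiency = 2)
  r <- copy_number(wells, primers, wt_samples = "wt")
  expect_equal(r$total_copies[r$sample_id == "dover"], 9, tolerance = 1e-9)
  expect_equal(round(r$transgenic_copies[r$sample_id == "dover"]), 7)
})

test_that("loading errors cancel exactly in the calibrated estimate", {
  base <- gen_qpcr(c(wt1 = 2, wt2 = 2, tg = 9), ct_noise_sd = 0,
                   loading_factors = 1, seed = 2)
  skew <- gen_qpcr(c(wt1 = 2, wt2 = 2, tg = 9), ct_noise_sd = 0,
                   loading_factors = stats::setNames(c(1, 2.7, 0.4),
                                                     c("wt1", "wt2", "tg")),
                   seed = 2)
  r1 <- copy_number(base$wells, base$primers, wt_samples = c("wt1", "wt2"))
  r2 <- copy_number(skew$wells, skew$primers, wt_samples = c("wt1", "wt2"))
  expect_equal(r2$total_copies, r1$total_copies, tolerance = 1e-9)
})

test_that("the qPCR inverse model recovers copy numbers across the genotype range", {
  # genotypes span the study's range: wild type through the ~100-copy line;
  # trial counts keep the Monte-Carlo error on the bias well below the
  # 0.2-copy band (per-trial spread scales with the copy number)
  for (copies in c(2, 3, 4, 9, 102)) {
    n_trials <- if (copies > 50) 600L else 150L
    est <- vapply(seq_len(n_trials), function(k) {
      g <- gen_qpcr(c(wt1 = 2, wt2 = 2, s = copies), ct_noise_sd = 0.05,
                    seed = 1000 * copies + k)
      r <- copy_number(g$wells, g$primers, wt_samples = c("wt1", "wt2"))
      r$total_copies[r$sample_id == "s"]
    }, numeric(1))
    # bias band of 0.2 copies, verified up to the Monte-Carlo error of the
    # bias estimate (which matters only for the ~100-copy genotype)
    expect_lt(abs(mean(est) - copies), 0.2 + 2 * sd(est) / sqrt(n_trials))
    # spread scales with the copy number (multiplicative Ct noise)
    if (copies == 2) sd2 <- sd(est)
    if (copies == 102) expect_equal(sd(est) / 102, sd2 / 2, tolerance = 0.5)
  }
})

test_that("one functional-copy difference separates cleanly at assay noise", {
  est <- function(copies, seeds) {
    vapply(seeds, function(k) {
      g <- gen_qpcr(c(wt1 = 2, wt2 = 2, s = copies), ct_noise_sd = 0.05,
                    seed = k)
      r <- copy_number(g$wells, g$primers, wt_samples = c("wt1", "wt2"))
      r$total_copies[r$sample_id == "s"]
    }, numeric(1))
  }
  one <- est(1, 1:3)
  two <- est(2, 4:6)
  ci <- function(x) mean(x) + c(-1, 1) * qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
  expect_lt(ci(one)[2], ci(two)[1])  # non-overlapping 95% intervals
})

test_that("trial aggregation averages and flags low replication", {
  mk <- function(tg) data.frame(sample_id = "s", rel_deltaD = NA, rel_deltaC = NA,
                                calibrated = (tg + 2) / 2, total_copies = tg + 2,
                                transgenic_copies = tg)
  agg <- aggregate_trials(list(mk(6.8), mk(7.1), mk(7.1)))
  expect_equal(agg$transgenic_copies, 7)
  expect_false(agg$low_n)
  one <- aggregate_trials(list(mk(6.8)))
  expect_equal(one$transgenic_copies, 6.8)
  expect_true(one$low_n)
  # permutation invariance
  agg2 <- aggregate_trials(list(mk(7.1), mk(6.8), mk(7.1)))
  expect_equal(agg2$transgenic_copies, agg$transgenic_copies)
  expect_equal(agg2$transgenic_sd, agg$transgenic_sd)
})

test_that("venus primers merge through the anchor's deltaD estimate", {
  g <- gen_qpcr(c(wt1 = 2, anchor = 9, s = 9), ct_noise_sd = 0,
                loading_factors = 1, seed = 3)
  venus <- rbind(
    data.frame(sample_id = "anchor", primer_id = "v_1", replicate = 1:2, ct = 24),
    data.frame(sample_id = "s", primer_id = "v_1", replicate = 1:2, ct = 24))
  wells <- rbind(g$wells, venus)
  primers <- rbind(g$primers,
                   data.frame(primer_id = "v_1", target = "venus", efficiency = 2))
  r <- copy_number(wells, primers, wt_samples = "wt1", venus_anchor = "anchor")
  expect_equal(r$transgenic_copies[r$sample_id == "s"], 7, tolerance = 1e-9)
})
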