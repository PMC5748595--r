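make_pairs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ff <- rnorm(n, 0, 0.4)
    data.frame(sample_id = sprintf("P%03d", seq_len(n)),
               ff_score = ff, ffpe_score = ff + rnorm(n, 0, 0.1),
               stringsAsFactors = FALSE)
  })
}

test_that("exclusion bookkeeping matches planted defects, tumor first", {
  pairs <- make_pairs(201)
  ann <- data.frame(sample_id = pairs$sample_id,
                    braf_status = "unknown",
                    tumor_pct = 60, signal_intensity = 10,
                    stringsAsFactors = FALSE)
  ann$tumor_pct[1:25] <- 12              # low tumor
  ann$signal_intensity[26:31] <- 2       # low signal
  ann$signal_intensity[3] <- 1           # fails both -> counted as low tumor
  res <- apply_exclusions(pairs, ann, min_tumor_pct = 30, min_signal = 8)
  expect_equal(res$n_excluded_low_tumor, 25)
  expect_equal(res$n_excluded_low_signal, 6)
  expect_equal(nrow(res$kept), 170)
  expect_equal(sum(res$excluded$reason == "low_tumor_pct"), 25)
  expect_true("P003" %in%
                res$excluded$sample_id[res$excluded$reason == "low_tumor_pct"])

  # cutoffs of zero exclude nothing, even with missing annotations
  ann_na <- ann
  ann_na$tumor_pct <- NA
  res0 <- apply_exclusions(pairs, ann_na, min_tumor_pct = 0, min_signal = 0)
  expect_equal(nrow(res0$kept), 201)
  expect_equal(nrow(res0$excluded), 0)

  expect_error(apply_exclusions(pairs, ann[-7, ], 30, 8), "P007")
  expect_error(apply_exclusions(pairs, ann_na, 30, 0), "tumor_pct missing")
})

test_that("random planted exclusions are tallied exactly", {
  withr::local_seed(61)
  for (k in 1:10) {
    n <- sample(50:120, 1)
    pairs <- make_pairs(n, seed = k)
    tumor <- runif(n, 40, 90)
    signal <- runif(n, 9, 11)
    plant_t <- sample(n, sample(0:8, 1))
    plant_s <- sample(setdiff(seq_len(n), plant_t), sample(0:5, 1))
    tumor[plant_t] <- runif(length(plant_t), 0, 29)
    signal[plant_s] <- runif(length(plant_s), 0, 7)
    ann <- data.frame(sample_id = pairs$sample_id, braf_status = "unknown",
                      tumor_pct = tumor, signal_intensity = signal)
    res <- apply_exclusions(pairs, ann, 30, 8)
    expect_equal(res$n_excluded_low_tumor, length(plant_t))
    expect_equal(res$n_excluded_low_signal, length(plant_s))
    expect_equal(nrow(res$kept), n - length(plant_t) - length(plant_s))
  }
})

test_that("concordance counts switches outside the borderline region", {
  # identical paired scores: full agreement, r = 1
  pairs <- make_pairs(50)
  pairs$ffpe_score <- pairs$ff_score
  region <- borderline_region(0, 0.02)
  rpt <- concordance_report(pairs, 0, 0, region)
  expect_equal(rpt$n_switched, 0)
  expect_equal(rpt$agreement, 1)
  expect_equal(rpt$pearson_r, 1)
  expect_equal(rpt$agreement + rpt$n_switched / rpt$n_outside_borderline, 1)

  # random pairs vs a brute-force tally
  withr::local_seed(62)
  for (k in 1:10) {
    p <- make_pairs(80, seed = 100 + k)
    reg <- borderline_region(0, runif(1, 0.01, 0.15))
    rpt <- concordance_report(p, 0, 0, reg)
    n_sw <- 0; n_out <- 0
    for (i in seq_len(nrow(p))) {
      inside <- p$ffpe_score[i] >= reg$low && p$ffpe_score[i] <= reg$high
      if (!inside) {
        n_out <- n_out + 1
        if ((p$ff_score[i] > 0) != (p$ffpe_score[i] > 0)) n_sw <- n_sw + 1
      }
    }
    expect_equal(rpt$n_outside_borderline, n_out)
    expect_equal(rpt$n_switched, n_sw)
    expect_equal(rpt$agreement, 1 - n_sw / n_out)
  }

  # a pair exactly on the region edge counts as borderline
  edge <- data.frame(sample_id = c("A", "B", "C"),
                     ff_score = c(1, -1, 0.5),
                     ffpe_score = c(region$high, -1, 0.5))
  e <- concordance_report(edge, 0, 0, region)
  expect_true(e$pairs$in_borderline[1])
  expect_equal(e$n_outside_borderline, 2)
})

test_that("widening the borderline region never increases switch count", {
  withr::local_seed(63)
  p <- make_pairs(120, seed = 9)
  widths <- seq(0, 0.25, by = 0.05)
  switches <- vapply(widths, function(w) {
    concordance_report(p, 0, 0, borderline_region(0, w))$n_switched
  }, numeric(1))
  expect_true(all(diff(switches) <= 0))
})

test_that("calibrated paired cohorts rarely switch outside the region", {
  frac <- vapply(1:20, function(s) {
    fx <- scored_fixture(n = 170, seed = 900 + s)
    sp <- ffpe_noise_spec(seed = 900 + s)
    ffpe <- degrade_to_ffpe(fx$aligned, sp, fx$cohort$signature)
    ffpe_sc <- score_cohort(ffpe, fx$templates, 0)$score
    pairs <- data.frame(sample_id = colnames(fx$aligned),
                        ff_score = fx$ff_scores, ffpe_score = ffpe_sc)
    labs <- fx$cohort$annotations$braf_status
    th <- optimize_threshold(fx$ff_scores, labs)
    ctrl_sd <- sd(score_cohort(
      generate_control_replicates(fx$templates$mut_template, 40,
                                  ffpe_noise_spec(seed = 5000 + s),
                                  fx$cohort$signature),
      fx$templates, th)$score)
    rpt <- concordance_report(pairs, th, th,
                              borderline_region(th, ctrl_sd))
    if (rpt$n_outside_borderline == 0) return(0)
    rpt$n_switched / rpt$n_outside_borderline
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("an all-borderline comparison is flagged as undefined", {
  p <- data.frame(sample_id = c("A", "B"), ff_score = c(0.01, -0.01),
                  ffpe_score = c(0.01, -0.01))
  expect_warning(rpt <- concordance_report(p, 0, 0,
                                           borderline_region(0, 1)),
                 "undefined")
  expect_false(rpt$agreement_defined)
  expect_true(is.na(rpt$agreement))
})
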