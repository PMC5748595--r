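test_that("LOOCV scores equal an explicit leave-one-out fold loop", {
  m <- rand_matrix(12, 6, seed = 30)
  labs <- rep(c("mutated", "wildtype"), each = 3)
  got <- loocv_scores(m, labs)
  oracle <- vapply(1:6, function(i) {
    tpl <- build_templates(m[, -i, drop = FALSE], labs[-i])
    score_sample(m[, i], tpl)
  }, numeric(1))
  expect_equal(unname(got), oracle)

  expect_error(loocv_scores(m, rep(c("mutated", "wildtype"), c(2, 4))),
               "at least 3")
  flat <- matrix(1, 12, 6, dimnames = dimnames(m))
  expect_error(loocv_scores(flat, labs), "zero-variance")
})

test_that("a duplicated sample's LOOCV score matches the original's full-template score", {
  ch <- generate_cohort(cohort_spec(300, n_background_genes = 0, seed = 31))
  al <- align_to_signature(ch$matrix, ch$signature)
  labs <- ch$annotations$braf_status
  dup <- cbind(al, DUP = al[, 17])
  s_dup <- loocv_scores(dup, c(labs, labs[17]))
  tpl <- build_templates(al, labs)
  expect_equal(unname(s_dup["DUP"]), score_sample(al[, 17], tpl),
               tolerance = 1e-6)
})

test_that("optimize_threshold matches exhaustive search and breaks ties low", {
  # separable toy case: accuracy 1 at the gap midpoint
  expect_equal(optimize_threshold(c(1, -1), c("mutated", "wildtype")), 0)
  sc <- c(-0.3, -0.1, 0.2, 0.5)
  labs <- c("wildtype", "wildtype", "mutated", "mutated")
  th <- optimize_threshold(sc, labs)
  expect_equal(th, (-0.1 + 0.2) / 2)
  expect_equal(mean(classify_scores(sc, th) ==
                      ifelse(labs == "mutated", "mutation_like",
                             "wildtype_like")), 1)

  # random instances: every candidate threshold checked by brute force
  withr::local_seed(32)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    scores <- round(rnorm(n), 2)  # duplicates likely
    labels <- sample(c("mutated", "wildtype"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("mutated", "wildtype")
    th <- optimize_threshold(scores, labels)
    acc <- function(t) mean((scores > t) == (labels == "mutated"))
    cand <- sort(c(sort(unique(scores)) - 1e-9, max(scores) + 1))
    best <- max(vapply(cand, acc, numeric(1)))
    expect_equal(acc(th), best)
    # no strictly lower candidate achieves the same accuracy
    lower <- cand[cand < th - 1e-12]
    if (length(lower))
      expect_true(all(vapply(lower, acc, numeric(1)) < best))
  }
})

test_that("confusion metrics match a hand-tallied oracle", {
  withr::local_seed(33)
  calls <- sample(c("mutation_like", "wildtype_like"), 50, replace = TRUE)
  labels <- sample(c("mutated", "wildtype"), 50, replace = TRUE)
  cm <- confusion_metrics(calls, labels)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in 1:50) {
    if (calls[i] == "mutation_like" && labels[i] == "mutated") tp <- tp + 1
    if (calls[i] == "mutation_like" && labels[i] == "wildtype") fp <- fp + 1
    if (calls[i] == "wildtype_like" && labels[i] == "mutated") fn <- fn + 1
    if (calls[i] == "wildtype_like" && labels[i] == "wildtype") tn <- tn + 1
  }
  expect_equal(cm$tp, tp); expect_equal(cm$fp, fp)
  expect_equal(cm$fn, fn); expect_equal(cm$tn, tn)
  expect_equal(cm$sensitivity, tp / (tp + fn))
  expect_equal(cm$specificity, tn / (tn + fp))
  expect_equal(cm$accuracy, (tp + tn) / 50)
  expect_equal(cm$fraction_called_positive, (tp + fp) / 50)

  all_right <- confusion_metrics(
    ifelse(labels == "mutated", "mutation_like", "wildtype_like"), labels)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_error(confusion_metrics(calls, rep("odd", 50)), "odd")
})

test_that("expected specificity encodes the enrichment-bias estimate", {
  expect_equal(expected_specificity(0, 245), 1)
  expect_equal(expected_specificity(245, 245), 0)
  expect_error(expected_specificity(5, 0), "positive")
})

test_that("prescreen selection takes the top block plus a seeded random draw", {
  withr::local_seed(34)
  scores <- setNames(rnorm(602), sprintf("S%03d", 1:602))
  sel <- prescreen_select(scores, 96, 206, seed = 2)
  expect_length(sel, 302)
  expect_length(unique(sel), 302)
  # the first block is exactly the top scorers
  expect_setequal(sel[1:96], names(sort(scores, decreasing = TRUE))[1:96])
  expect_identical(sel, prescreen_select(scores, 96, 206, seed = 2))
  expect_false(identical(sel, prescreen_select(scores, 96, 206, seed = 3)))
  # identity selection
  expect_setequal(prescreen_select(scores, length(scores), 0), names(scores))
  expect_error(prescreen_select(scores, 500, 200), "exceeds")
})

test_that("prescreening by score enriches the selected set for mutants", {
  hits <- vapply(1:20, function(s) {
    ch <- generate_cohort(cohort_spec(400, n_background_genes = 0,
                                      seed = 500 + s))
    al <- align_to_signature(ch$matrix, ch$signature)
    tpl <- build_templates(al, ch$annotations$braf_status)
    sc <- setNames(score_cohort(al, tpl, 0)$score, colnames(al))
    sel <- prescreen_select(sc, 60, 140, seed = s)
    mut <- ch$annotations$braf_status == "mutated"
    names(mut) <- ch$annotations$sample_id
    mean(mut[sel]) > mean(mut)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cohort composition tallies mutants per cohort block", {
  ann <- prescreen_annotation(n_top = 10, mut_top = 4,
                              n_random = 20, mut_random = 3)
  comp <- cohort_composition(ann)
  pre <- comp[comp$cohort_tag == "prescreen", ]
  expect_equal(pre$n, 10); expect_equal(pre$n_mutated, 4)
  expect_equal(pre$frac_mutated, 0.4)
  all_row <- comp[comp$cohort_tag == "all", ]
  expect_equal(all_row$n, 30); expect_equal(all_row$n_mutated, 7)
})

test_that("LOOCV recovers the subtype when mutants dominate the subtype", {
  # with nearly all subtype tumors sequenced mutant, the accuracy-optimal
  # threshold sits in the score gap and performance approaches perfection
  ch <- generate_cohort(cohort_spec(302, n_background_genes = 0,
                                    p_mutated_given_subtype = 0.95,
                                    p_discordant = 0, effect_size = 3,
                                    noise_sd = 0.5, seed = 40))
  al <- align_to_signature(ch$matrix, ch$signature)
  labs <- ch$annotations$braf_status
  sc <- loocv_scores(al, labs)
  th <- optimize_threshold(sc, labs)
  cm <- confusion_metrics(classify_scores(sc, th), labs)
  expect_equal(cm$sensitivity, 1)
  expect_gte(cm$specificity, 0.95)
  # calls recover the latent subtype exactly in this strong-signal regime
  expect_identical(unname(sc > th), ch$subtype)
})
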