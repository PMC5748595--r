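# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

tiny_matrix <- function() {
  matrix(c(1.5, -0.25, 3, 2.125, 0.5, -1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
}

rand_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    matrix(round(rnorm(n_genes * n_samples), 6), n_genes, n_samples,
           dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                           sprintf("S%03d", seq_len(n_samples))))
  })
}

# turn confusion counts into call/label vectors
expand_confusion <- function(tp, fp, fn, tn) {
  list(calls = c(rep("mutation_like", tp + fp), rep("wildtype_like", fn + tn)),
       labels = c(rep("mutated", tp), rep("wildtype", fp),
                  rep("mutated", fn), rep("wildtype", tn)))
}

# annotation table encoding a pre-screened sequencing cohort: a top-ranked
# block and a random block with given sizes and mutant counts
prescreen_annotation <- function(n_top = 96, mut_top = 34,
                                 n_random = 206, mut_random = 23) {
  n <- n_top + n_random
  data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    braf_status = c(rep("mutated", mut_top), rep("wildtype", n_top - mut_top),
                    rep("mutated", mut_random),
                    rep("wildtype", n_random - mut_random)),
    cohort_tag = c(rep("prescreen", n_top), rep("random", n_random)),
    stringsAsFactors = FALSE)
}

# independent Pearson correlation oracle from the covariance definition
cor_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# a small scored cohort with templates, for stability/concordance tests
scored_fixture <- function(n = 170, seed = 7, noise_sd = 1) {
  ch <- generate_cohort(cohort_spec(n, noise_sd = noise_sd, seed = seed))
  al <- align_to_signature(ch$matrix, ch$signature)
  tpl <- build_templates(al, ch$annotations$braf_status)
  list(cohort = ch, aligned = al, templates = tpl,
       ff_scores = score_cohort(al, tpl, threshold = 0)$score)
}
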