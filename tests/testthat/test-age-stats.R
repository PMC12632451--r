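test_that("weighted mean age counts each mutation once", {
  coh <- toy_cohort(c(40, 60), list(c("G", "G"), "G"))
  res <- weighted_mean_age(coh, "G")
  expect_equal(res$mean_age, (40 * 2 + 60) / 3, tolerance = 1e-12)
  expect_equal(res$n_mutations, 3)
  # all mutations at one age: zero-width CI
  coh2 <- toy_cohort(c(50, 50), list("G", "G"))
  res2 <- weighted_mean_age(coh2, "G")
  expect_equal(res2$ci_low, 50)
  expect_equal(res2$ci_high, 50)
  # no data: explicit empty result, not NaN
  none <- weighted_mean_age(coh, "ABSENT")
  expect_equal(none$n_mutations, 0)
  expect_true(is.na(none$mean_age))
})

test_that("weighted mean age matches an independent recomputation", {
  set.seed(19)
  ages <- runif(25, 10, 90)
  kmut <- sample(0:4, 25, replace = TRUE)
  coh <- toy_cohort(ages, lapply(kmut, function(k) rep("G", k)))
  res <- weighted_mean_age(coh, "G")
  expect_equal(res$mean_age, sum(ages * kmut) / sum(kmut),
               tolerance = 1e-12)
  flat <- rep(ages, kmut)
  se <- sd(flat) / sqrt(length(flat))
  expect_equal(res$ci_low, mean(flat) - qnorm(0.975) * se,
               tolerance = 1e-12)
})

test_that("age divergence ratio matches brute force and is translation invariant", {
  coh <- toy_cohort(c(1, 1, 3, 3), list("A", "A", "B", "B"))
  res <- age_divergence(coh, c("A", "B"))
  expect_equal(res$ratio, 1)
  # genes share one mean age (cohort ages still vary): ratio 0
  coh0 <- toy_cohort(c(5, 9, 5, 9), list("A", "A", "B", "B"))
  expect_equal(age_divergence(coh0, c("A", "B"))$ratio, 0)
  # translation invariance
  shift <- toy_cohort(c(1, 1, 3, 3) + 17, list("A", "A", "B", "B"))
  expect_equal(age_divergence(shift, c("A", "B"))$ratio, res$ratio)
  expect_error(age_divergence(coh, "A"), class = "carceff_domain_error")
})

test_that("age difference vs synonymous follows the class definitions", {
  smp <- tibble::tibble(sample_id = paste0("s", 1:4),
                        donor_id = paste0("s", 1:4),
                        age = c(20, 40, 60, 80), sex = "female",
                        tissue_state = "cancer", cohort_label = "t")
  muts <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    gene = c("G", "BG", "BG", "BG", "BG"),
    mclass = c("nonsynonymous_snv", rep("synonymous", 4)),
    chrom = "1", pos = 1:5
  )
  coh <- as_cohort(smp, muts)
  expect_equal(age_difference_vs_synonymous(coh, "G"), 20 - 50)
  expect_true(is.na(age_difference_vs_synonymous(coh, "ABSENT")))
  # same age sets in both classes: zero
  muts2 <- tibble::tibble(sample_id = c("s1", "s1"), gene = c("G", "BG"),
                          mclass = c("nonsynonymous_snv", "synonymous"),
                          chrom = "1", pos = 1:2)
  expect_equal(age_difference_vs_synonymous(as_cohort(smp, muts2), "G"), 0)
})

test_that("permutation test pins planted young-bias genes to the floor", {
  coh <- synth_age_cohort(n_samples = 600, mode = "young_bias", effect = 4,
                          base_p = 0.15, seed = 12)
  pt <- permutation_test(coh, paste0("G", 1:20), n_perm = 300, seed = 13)
  expect_true(all(pt$delta_age < 0, na.rm = TRUE))
  expect_gt(mean(pt$q_value < 0.05, na.rm = TRUE), 0.9)
  expect_equal(min(pt$perm_quantile, na.rm = TRUE), 1 / 301)
  # determinism
  pt2 <- permutation_test(coh, paste0("G", 1:20), n_perm = 300, seed = 13)
  expect_identical(pt, pt2)
  expect_error(permutation_test(coh, "G1", n_perm = 10),
               class = "carceff_domain_error")
})

test_that("permutation quantiles are uniform under the exchangeable null", {
  qs <- unlist(lapply(1:60, function(i) {
    coh <- synth_age_cohort(n_samples = 250, mode = "null",
                            syn_rate = c(3, 0), seed = 900 + i)
    permutation_test(coh, paste0("G", 1:20), n_perm = 150,
                     seed = i)$perm_quantile
  }))
  ks <- suppressWarnings(stats::ks.test(qs, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(qs < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(qs)) + 0.01)
})

test_that("rank biserial equals brute-force pair enumeration", {
  expect_equal(rank_biserial_age_bias(c(30, 35), c(60, 70))$r, -1)
  expect_equal(rank_biserial_age_bias(c(1, 2), c(1, 2))$r, 0)
  expect_equal(rank_biserial_age_bias(c(1, 3), c(2))$r, 0)
  set.seed(23)
  for (i in 1:200) {
    n1 <- sample(1:30, 1)
    n2 <- sample(1:30, 1)
    x <- sample(1:40, n1, replace = TRUE) # ties likely
    y <- sample(1:40, n2, replace = TRUE)
    expect_equal(rank_biserial_age_bias(x, y)$r, rb_brute(x, y))
  }
  expect_error(rank_biserial_age_bias(numeric(0), 1:3),
               class = "carceff_domain_error")
})

test_that("SCNA/SNV bias table recovers planted concordance and applies rules", {
  genes <- tibble::tibble(gene = paste0("T", 1:14),
                          role = rep(c("tsg", "oncogene"), 7))
  st <- synth_scna_table(genes, n_samples = 700, concordant = TRUE,
                         seed = 41)
  bt <- scna_snv_bias_table(st$cohort, genes, min_freq = 0.05)
  expect_gt(nrow(bt), 8)
  expect_gt(cor(bt$r_snv, bt$r_scna, method = "spearman"), 0.5)
  # frequency threshold removes rare genes
  bt_hi <- scna_snv_bias_table(st$cohort, genes, min_freq = 0.9)
  expect_equal(nrow(bt_hi), 0)
})

test_that("co-occurring samples are excluded from both bias computations", {
  # deterministic micro-fixture: sample s1 has both SNV and deletion in G
  smp <- tibble::tibble(sample_id = paste0("s", 1:6),
                        donor_id = paste0("s", 1:6),
                        age = c(30, 40, 50, 60, 70, 80), sex = "female",
                        tissue_state = "cancer", cohort_label = "t")
  muts <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3"),
    gene = "G",
    mclass = c("nonsynonymous_snv", "scna_del", "nonsynonymous_snv",
               "scna_del"),
    chrom = "1", pos = 1:4
  )
  coh <- as_cohort(smp, muts)
  bt <- scna_snv_bias_table(coh, tibble::tibble(gene = "G", role = "tsg"),
                            min_freq = 0)
  # SNV bias: among samples without any SCNA in G (s2, s4, s5, s6):
  # carrier s2 (40) vs s4, s5, s6 (60, 70, 80) -> r = -1
  expect_equal(bt$r_snv, -1)
  # deletion bias: among samples without SNV in G (s3..s6): carrier s3 (50)
  # vs 60, 70, 80 -> r = -1
  expect_equal(bt$r_scna, -1)
})
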