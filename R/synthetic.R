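#' Synthetic matched cancer/normal cohorts with known carcinogenic effects
#'
#' Generates a matched pair of cohorts from planted per-gene truths: each
#' normal-tissue sample carries, for every gene, a mutant cell fraction drawn
#' from a Beta distribution with mean `x` and the given precision (the
#' over-dispersion the estimators must tolerate, and the law the hybrid Beta
#' model assumes); each cancer sample carries the gene's mutation with
#' probability \eqn{y = w x / (1 - x + w x)}, the inverse of the
#' carcinogenic-effect odds ratio. Normal fractions are emitted as autosomal
#' VAFs (`vaf = fraction / 2`). Ages are uniform on `age_range` (default
#' 36-90, an adult-blood-like span).
#'
#' @param genes Data frame with columns `gene`, `x` (true mutant cell
#'   fraction in (0, 1)), `w` (true carcinogenic effect > 0), and optionally
#'   `coding_length`.
#' @param n_cancer,n_normal Sample counts.
#' @param age_range Length-2 numeric.
#' @param precision Beta precision (shape1 + shape2) of the normal-tissue
#'   fraction noise.
#' @param seed RNG seed.
#' @return A list: `cancer` and `normal` (`carceff_cohort`s), `truth`
#'   (tibble of `gene`, `x`, `y`, `w`).
#' @export
synth_matched_cohort <- function(genes, n_cancer, n_normal,
                                 age_range = c(36, 90), precision = 50,
                                 seed = NULL) {
  genes <- as_tibble(genes)
  stopifnot(all(genes$x > 0), all(genes$x < 1), all(genes$w > 0))
  with_seed(seed, {
    y <- genes$w * genes$x / (1 - genes$x + genes$w * genes$x)
    truth <- tibble(gene = genes$gene, x = genes$x, y = y, w = genes$w)

    c_samp <- tibble(
      sample_id = sprintf("C%04d", seq_len(n_cancer)),
      donor_id = sprintf("CD%04d", seq_len(n_cancer)),
      age = runif(n_cancer, age_range[1], age_range[2]),
      sex = "female", tissue_state = "cancer", cohort_label = "synthetic"
    )
    pres <- matrix(rbinom(n_cancer * nrow(genes), 1,
                          rep(y, each = n_cancer)) == 1,
                   nrow = n_cancer)
    hit <- which(pres, arr.ind = TRUE)
    c_mut <- tibble(
      sample_id = c_samp$sample_id[hit[, 1]],
      gene = genes$gene[hit[, 2]],
      mclass = "nonsynonymous_snv",
      chrom = "1", vaf = NA_real_
    )

    n_samp <- tibble(
      sample_id = sprintf("N%04d", seq_len(n_normal)),
      donor_id = sprintf("ND%04d", seq_len(n_normal)),
      age = runif(n_normal, age_range[1], age_range[2]),
      sex = "female", tissue_state = "normal", cohort_label = "synthetic"
    )
    fr <- matrix(rbeta(n_normal * nrow(genes),
                       rep(genes$x * precision, each = n_normal),
                       rep((1 - genes$x) * precision, each = n_normal)),
                 nrow = n_normal)
    nz <- which(fr > 0, arr.ind = TRUE)
    n_mut <- tibble(
      sample_id = n_samp$sample_id[nz[, 1]],
      gene = genes$gene[nz[, 2]],
      mclass = "nonsynonymous_snv",
      chrom = "1", vaf = fr[nz] / 2
    )
    list(
      cancer = as_cohort(c_samp, c_mut,
                         provenance = "synth_matched_cohort cancer arm"),
      normal = as_cohort(n_samp, n_mut,
                         provenance = "synth_matched_cohort normal arm"),
      truth = truth
    )
  })
}

#' Synthetic normal-tissue VAF table with read noise and a detection floor
#'
#' True mutant cell fractions are drawn as in [synth_matched_cohort()], then
#' observed through binomial read sampling at the given depth (autosomal:
#' expected VAF is fraction/2) and censored below the detection floor `x0`
#' (applied on the cell-fraction scale, i.e. records with `2 * vaf < x0` are
#' dropped, emulating the invisibility of small clones in bulk sequencing).
#'
#' @inheritParams synth_matched_cohort
#' @param n_samples Number of normal samples.
#' @param depth Sequencing depth (reads); `Inf` for noiseless VAFs.
#' @param x0 Detection floor on the cell-fraction scale (0 disables).
#' @return A list: `normal` (`carceff_cohort`), `truth`.
#' @export
synth_vaf_table <- function(genes, n_samples, depth = 1000, x0 = 0.001,
                            age_range = c(36, 90), precision = 50,
                            seed = NULL) {
  genes <- as_tibble(genes)
  with_seed(seed, {
    smp <- tibble(
      sample_id = sprintf("N%04d", seq_len(n_samples)),
      donor_id = sprintf("ND%04d", seq_len(n_samples)),
      age = runif(n_samples, age_range[1], age_range[2]),
      sex = "female", tissue_state = "normal", cohort_label = "synthetic"
    )
    fr <- matrix(rbeta(n_samples * nrow(genes),
                       rep(genes$x * precision, each = n_samples),
                       rep((1 - genes$x) * precision, each = n_samples)),
                 nrow = n_samples)
    true_vaf <- fr / 2
    obs_vaf <- if (is.finite(depth)) {
      matrix(rbinom(length(true_vaf), depth, true_vaf) / depth,
             nrow = n_samples)
    } else {
      true_vaf
    }
    keep <- which(2 * obs_vaf >= x0 & obs_vaf > 0, arr.ind = TRUE)
    muts <- tibble(
      sample_id = smp$sample_id[keep[, 1]],
      gene = genes$gene[keep[, 2]],
      mclass = "nonsynonymous_snv",
      chrom = "1", vaf = obs_vaf[keep]
    )
    list(
      normal = as_cohort(smp, muts, provenance = "synth_vaf_table"),
      truth = tibble(gene = genes$gene, x = genes$x,
                     w = if ("w" %in% names(genes)) genes$w else NA_real_)
    )
  })
}

#' Synthetic cancer cohort for age-statistic calibration
#'
#' Builds a cancer cohort in which synonymous background mutations accrue as
#' a Poisson count per sample with rate increasing linearly in age (neutral
#' mutations accumulate with age). Under `mode = "null"` each planted gene's
#' mutations are likewise neutral: per-sample counts are Poisson with the
#' same linear-in-age rate profile as the synonymous background (scaled to
#' expected frequency `base_p`), which is the null hypothesis the
#' permutation test embodies — a gene whose mutations did *not* accumulate
#' with age would be genuinely young-biased relative to neutral mutations.
#' The bias modes tilt the per-gene mutation probability by a
#' logistic-in-age factor towards young (`"young_bias"`) or old
#' (`"old_bias"`) patients with the given effect size (log-odds per age
#' standard deviation).
#'
#' @param n_samples Number of cancer samples.
#' @param genes Character vector of planted gene names.
#' @param mode `"null"`, `"young_bias"` or `"old_bias"`.
#' @param effect Log-odds tilt per standard deviation of age.
#' @param base_p Baseline per-gene mutation probability.
#' @param syn_rate Length-2: synonymous Poisson rate intercept and slope per
#'   year of age.
#' @param age_range Length-2 numeric.
#' @param seed RNG seed.
#' @return A `carceff_cohort` (cancer tissue state).
#' @export
synth_age_cohort <- function(n_samples = 500, genes = paste0("G", 1:20),
                             mode = c("null", "young_bias", "old_bias"),
                             effect = 2, base_p = 0.1,
                             syn_rate = c(1, 0.05), age_range = c(0, 90),
                             seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    smp <- tibble(
      sample_id = sprintf("S%05d", seq_len(n_samples)),
      donor_id = sprintf("D%05d", seq_len(n_samples)),
      age = runif(n_samples, age_range[1], age_range[2]),
      sex = "female", tissue_state = "cancer", cohort_label = "synthetic"
    )
    zage <- as.numeric(scale(smp$age))
    if (mode == "null") {
      # neutral gene mutations: same relative age profile as synonymous
      rel <- syn_rate[1] + syn_rate[2] * smp$age
      lam <- base_p * rel / mean(rel)
      counts <- matrix(rpois(n_samples * length(genes), lam),
                       nrow = n_samples)
    } else {
      tilt <- if (mode == "young_bias") -effect else effect
      p <- plogis(qlogis(base_p) + tilt * zage)
      counts <- matrix(rbinom(n_samples * length(genes), 1, p),
                       nrow = n_samples)
    }
    hit <- which(counts > 0, arr.ind = TRUE)
    ns_mut <- tibble(
      sample_id = rep(smp$sample_id[hit[, 1]], counts[hit]),
      gene = rep(genes[hit[, 2]], counts[hit]),
      mclass = "nonsynonymous_snv", chrom = "1", vaf = NA_real_
    )
    syn_n <- rpois(n_samples, syn_rate[1] + syn_rate[2] * smp$age)
    syn_mut <- tibble(
      sample_id = rep(smp$sample_id, syn_n),
      gene = "BG", mclass = "synonymous", chrom = "2", vaf = NA_real_
    )
    # distinct() must not collapse same-sample same-gene records: tag pos
    muts <- dplyr::bind_rows(ns_mut, syn_mut)
    muts$pos <- seq_len(nrow(muts))
    as_cohort(smp, muts,
              provenance = sprintf("synth_age_cohort mode=%s", mode))
  })
}

#' Synthetic cohort with copy-number and point alterations
#'
#' Plants per-gene SCNA (deletion for tumour suppressors, amplification for
#' oncogenes) and non-synonymous SNV carrier sets with age-tilted carrier
#' probabilities. `concordant = TRUE` gives both alteration types of a gene
#' the same age tilt (drawn once per gene on `bias_range`);
#' `concordant = FALSE` draws independent tilts. `cooccurrence` adds the
#' given fraction of samples carrying both alteration types in the same
#' gene, to exercise the co-occurrence exclusion.
#'
#' @param genes Data frame with columns `gene` and `role` (`"tsg"` /
#'   `"oncogene"`).
#' @param n_samples Number of cancer samples.
#' @param concordant Shared or independent age tilts for the two alteration
#'   types.
#' @param bias_range Range of the per-gene age tilt (log-odds per age SD).
#' @param base_p Baseline carrier probability per alteration type.
#' @param cooccurrence Fraction of samples with both types planted.
#' @param age_range Length-2 numeric.
#' @param seed RNG seed.
#' @return A list: `cohort` (`carceff_cohort`), `truth` (tibble of `gene`,
#'   `role`, `tilt_snv`, `tilt_scna`).
#' @export
synth_scna_table <- function(genes, n_samples = 500, concordant = TRUE,
                             bias_range = c(-2, 2), base_p = 0.15,
                             cooccurrence = 0, age_range = c(20, 90),
                             seed = NULL) {
  genes <- as_tibble(genes)
  with_seed(seed, {
    smp <- tibble(
      sample_id = sprintf("S%05d", seq_len(n_samples)),
      donor_id = sprintf("D%05d", seq_len(n_samples)),
      age = runif(n_samples, age_range[1], age_range[2]),
      sex = "female", tissue_state = "cancer", cohort_label = "synthetic"
    )
    zage <- as.numeric(scale(smp$age))
    rows <- list()
    truth <- list()
    for (g in seq_len(nrow(genes))) {
      tilt_snv <- runif(1, bias_range[1], bias_range[2])
      tilt_scna <- if (concordant) tilt_snv else runif(1, bias_range[1],
                                                       bias_range[2])
      scna_class <- if (genes$role[g] == "tsg") "scna_del" else "scna_amp"
      p_snv <- plogis(qlogis(base_p) + tilt_snv * zage)
      p_scna <- plogis(qlogis(base_p) + tilt_scna * zage)
      snv <- rbinom(n_samples, 1, p_snv) == 1
      scna <- rbinom(n_samples, 1, p_scna) == 1
      if (cooccurrence > 0) {
        both <- runif(n_samples) < cooccurrence
        snv <- snv | both
        scna <- scna | both
      } else {
        # by default keep types disjoint so exclusions are well-defined
        scna <- scna & !snv
      }
      rows[[length(rows) + 1]] <- tibble(
        sample_id = smp$sample_id[snv], gene = genes$gene[g],
        mclass = "nonsynonymous_snv", chrom = "1", vaf = NA_real_
      )
      rows[[length(rows) + 1]] <- tibble(
        sample_id = smp$sample_id[scna], gene = genes$gene[g],
        mclass = scna_class, chrom = "1", vaf = NA_real_
      )
      truth[[g]] <- tibble(gene = genes$gene[g], role = genes$role[g],
                           tilt_snv = tilt_snv, tilt_scna = tilt_scna)
    }
    list(
      cohort = as_cohort(smp, dplyr::bind_rows(rows),
                         provenance = "synth_scna_table"),
      truth = dplyr::bind_rows(truth)
    )
  })
}
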