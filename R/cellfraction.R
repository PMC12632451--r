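#' Convert variant allele frequencies to mutant cell fractions
#'
#' For an autosomal site (or the X chromosome in a female) under the
#' diploid-heterozygous assumption the mutant cell fraction is twice the VAF;
#' when twice the VAF exceeds one (possible loss of heterozygosity) the cell
#' fraction is set to the VAF itself, and for the X chromosome in males
#' (hemizygous) the cell fraction equals the VAF. Donors of unknown sex are
#' treated as female (diploid X), a conservative factor-of-two choice, with a
#' warning when X-chromosome records are affected.
#'
#' @param vaf Numeric vector of VAFs in \[0, 1\].
#' @param chrom Chromosome labels (`"X"`/`"chrX"` recognised as X); recycled.
#' @param sex `"male"`, `"female"` or `"unknown"`; recycled.
#' @return Numeric vector of cell fractions in \[0, 1\].
#' @examples
#' vaf_to_cell_fraction(c(0.10, 0.60), "7", "female") # 0.20, 0.60
#' vaf_to_cell_fraction(0.30, "X", "male") # 0.30
#' @export
vaf_to_cell_fraction <- function(vaf, chrom, sex) {
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) {
    abort("vaf outside [0, 1]", class = "carceff_domain_error")
  }
  n <- length(vaf)
  chrom <- rep_len(as.character(chrom), n)
  sex <- rep_len(as.character(sex), n)
  is_x <- chrom %in% c("X", "chrX", "x", "chrx")
  if (any(is_x & sex == "unknown")) {
    warn("X-chromosome records with unknown sex treated as female (diploid X)")
  }
  male_x <- is_x & sex == "male"
  ifelse(male_x | 2 * vaf > 1, vaf, 2 * vaf)
}

#' Aggregate a gene's per-mutation cell fractions within one sample
#'
#' Multiple mutations of one gene in one sample are summed (assuming they sit
#' in distinct cells) unless the sum exceeds one, in which case the maximum is
#' taken (assuming they share cells). An empty input gives 0. The result is
#' permutation-invariant and monotone in each element.
#'
#' @param fractions Numeric vector of per-mutation cell fractions in \[0, 1\].
#' @return A single fraction in \[0, 1\].
#' @examples
#' gene_sample_fraction(c(0.2, 0.3)) # 0.5
#' gene_sample_fraction(c(0.7, 0.8)) # 0.8
#' @export
gene_sample_fraction <- function(fractions) {
  if (length(fractions) == 0) return(0)
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE)) {
    abort("fractions outside [0, 1]", class = "carceff_domain_error")
  }
  s <- sum(fractions)
  if (s <= 1) s else max(fractions)
}

# Per-sample mutant cell fraction of `gene` for every sample in the cohort
# (0 where the gene is unmutated). Returns tibble(sample_id, donor_id,
# fraction).
sample_gene_fractions <- function(cohort, gene, classes) {
  muts <- cohort$mutations |>
    filter(.data$gene == .env$gene, .data$mclass %in% classes,
           !is.na(.data$vaf)) |>
    left_join(select(cohort$samples, "sample_id", "sex"), by = "sample_id")
  per_sample <- muts |>
    mutate(cf = vaf_to_cell_fraction(.data$vaf, .data$chrom, .data$sex)) |>
    summarise(fraction = gene_sample_fraction(.data$cf),
              .by = "sample_id")
  cohort$samples |>
    select("sample_id", "donor_id") |>
    left_join(per_sample, by = "sample_id") |>
    mutate(fraction = dplyr::coalesce(.data$fraction, 0))
}

#' Cohort-level mutant cell fraction of a gene in normal tissue
#'
#' `cohort_mean_fraction()` averages the per-sample mutant cell fractions of a
#' gene over all samples of a (normal-tissue) cohort; unmutated samples
#' contribute 0. `bootstrap_ci()` adds a percentile bootstrap confidence
#' interval obtained by resampling donors: a donor with several (e.g.
#' longitudinal) samples enters as the mean over their samples.
#'
#' @param normal A `carceff_cohort` of normal-tissue samples with VAFs.
#' @param gene Gene symbol.
#' @param classes Mutation classes that qualify; defaults to non-synonymous
#'   SNVs and small indels.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed for the resampling RNG.
#' @param conf Confidence level.
#' @return A one-row tibble: `gene`, `mean_fraction`, `ci_low`, `ci_high`,
#'   `n_samples`, `n_bootstrap`, `flag` (`"unmutated"` when the gene is absent
#'   from every sample).
#' @export
cohort_mean_fraction <- function(normal, gene,
                                 classes = c("nonsynonymous_snv", "indel")) {
  stopifnot(inherits(normal, "carceff_cohort"))
  fr <- sample_gene_fractions(normal, gene, classes)
  tibble(
    gene = gene,
    mean_fraction = mean(fr$fraction),
    ci_low = NA_real_, ci_high = NA_real_,
    n_samples = nrow(fr), n_bootstrap = 0L,
    flag = if (all(fr$fraction == 0)) "unmutated" else NA_character_
  )
}

#' @rdname cohort_mean_fraction
#' @export
bootstrap_ci <- function(normal, gene, B = 1000, seed = NULL,
                         classes = c("nonsynonymous_snv", "indel"),
                         conf = 0.95) {
  if (B < 1) abort("B must be >= 1", class = "carceff_domain_error")
  est <- cohort_mean_fraction(normal, gene, classes)
  fr <- sample_gene_fractions(normal, gene, classes)
  donor_vals <- fr |>
    summarise(fraction = mean(.data$fraction), .by = "donor_id")
  v <- donor_vals$fraction
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(length(v), length(v) * B, replace = TRUE),
                  nrow = length(v))
    colMeans(matrix(v[idx], nrow = length(v)))
  })
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  est$ci_low <- qs[1]
  est$ci_high <- qs[2]
  est$n_bootstrap <- as.integer(B)
  est
}
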