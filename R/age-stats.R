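mutation_ages <- function(cohort, genes = NULL, classes) {
  m <- cohort$mutations |>
    filter(.data$mclass %in% classes)
  if (!is.null(genes)) m <- filter(m, .data$gene %in% genes)
  m |>
    left_join(select(cohort$samples, "sample_id", "age"), by = "sample_id")
}

#' Mutation-weighted mean patient age for a gene
#'
#' Mean age of the patients carrying a gene's qualifying mutations, each
#' mutation contributing its sample's age once (so a gene mutated twice in
#' one sample counts that age twice), with a 95% Wald confidence interval.
#' The default standard error treats per-mutation ages as independent;
#' `cluster = "sample"` aggregates mutations within a sample before computing
#' the standard error, since mutations in one sample share an age.
#'
#' @param cohort A `carceff_cohort`.
#' @param gene Gene symbol.
#' @param classes Qualifying mutation classes.
#' @param conf Confidence level.
#' @param cluster `"none"` or `"sample"`.
#' @return A one-row tibble: `gene`, `mean_age`, `ci_low`, `ci_high`,
#'   `n_mutations`; all `NA` (with `n_mutations = 0`) when the gene has no
#'   qualifying mutation.
#' @export
weighted_mean_age <- function(cohort, gene,
                              classes = c("nonsynonymous_snv", "indel"),
                              conf = 0.95, cluster = c("none", "sample")) {
  cluster <- match.arg(cluster)
  ages <- mutation_ages(cohort, gene, classes)$age
  n <- length(ages)
  if (n == 0) {
    return(tibble(gene = gene, mean_age = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, n_mutations = 0L))
  }
  mu <- mean(ages)
  se <- if (cluster == "none") {
    if (n > 1) sd(ages) / sqrt(n) else 0
  } else {
    m <- mutation_ages(cohort, gene, classes) |>
      count(.data$sample_id, .data$age)
    sqrt(sum((m$n * (m$age - mu))^2)) / n
  }
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(gene = gene, mean_age = mu, ci_low = mu - z * se,
         ci_high = mu + z * se, n_mutations = n)
}

#' Age divergence between driver genes
#'
#' Mutation-count-weighted variance between genes of the per-gene mean
#' mutation ages, divided by the (population) variance of the cohort's
#' patient age distribution; a Kruskal-Wallis test assesses whether mutation
#' ages are independent of gene identity.
#'
#' @param cohort A `carceff_cohort`.
#' @param genes Character vector (at least 2 genes with mutations).
#' @param classes Qualifying mutation classes.
#' @return A one-row tibble: `ratio`, `kw_p`, `n_genes`, `n_mutations`.
#' @export
age_divergence <- function(cohort, genes,
                           classes = c("nonsynonymous_snv", "indel")) {
  ma <- mutation_ages(cohort, genes, classes)
  ma <- ma[!is.na(ma$age), , drop = FALSE]
  used <- unique(ma$gene)
  if (length(used) < 2) {
    abort("need >= 2 genes with at least one mutation",
          class = "carceff_domain_error")
  }
  per_gene <- ma |>
    summarise(mu = mean(.data$age), n = dplyr::n(), .by = "gene")
  grand <- sum(per_gene$mu * per_gene$n) / sum(per_gene$n)
  between <- sum(per_gene$n * (per_gene$mu - grand)^2) / sum(per_gene$n)
  pop_var <- mean((cohort$samples$age - mean(cohort$samples$age))^2)
  kw <- kruskal.test(ma$age, factor(ma$gene))
  tibble(ratio = between / pop_var, kw_p = kw$p.value,
         n_genes = length(used), n_mutations = nrow(ma))
}

#' Age difference of a gene's mutations versus exome-wide synonymous ones
#'
#' Mutation-weighted mean age of the gene's non-synonymous SNVs/small indels
#' minus the mutation-weighted mean age of synonymous mutations across all
#' genes. Negative values indicate enrichment towards younger patients.
#'
#' @param cohort A `carceff_cohort`.
#' @param gene Gene symbol.
#' @return The age difference in years, or `NA` when either class is empty.
#' @export
age_difference_vs_synonymous <- function(cohort, gene) {
  g_ages <- mutation_ages(cohort, gene,
                          c("nonsynonymous_snv", "indel"))$age
  s_ages <- mutation_ages(cohort, NULL, "synonymous")$age
  if (length(g_ages) == 0 || length(s_ages) == 0) return(NA_real_)
  mean(g_ages) - mean(s_ages)
}

#' Permutation test of the non-carcinogenicity null on age differences
#'
#' For each gene, the observed [age_difference_vs_synonymous()] statistic is
#' compared against a null distribution obtained by permuting patient ages
#' among samples (mutation-to-sample assignments fixed), matching the design
#' in which only the age labels are exchangeable under the null. The
#' reported `perm_quantile` is the rank of the observed difference within the
#' null draws, `(1 + \#\{null \le obs\}) / (n_perm + 1)`; small quantiles
#' indicate young-age bias. The two-sided p-value is `2 min(q, 1 - q)`
#' floored at `1/(n_perm + 1)`, and q-values are Benjamini-Hochberg across
#' the supplied gene list. Apply the burden filter ([filter_by_burden()])
#' upstream.
#'
#' @param cohort A `carceff_cohort`.
#' @param genes Character vector of genes.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return A tibble with one row per gene: `gene`, `n_mutations`,
#'   `delta_age`, `perm_quantile`, `p_value`, `q_value`, `n_perm`, `flag`
#'   (`"no_data"` for genes without qualifying mutations, `"uninformative"`
#'   when all ages are equal).
#' @export
permutation_test <- function(cohort, genes, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(cohort, "carceff_cohort"))
  if (n_perm < 100) {
    abort("n_perm must be >= 100", class = "carceff_domain_error")
  }
  smp <- cohort$samples
  n <- nrow(smp)
  ages <- smp$age
  ns_mut <- cohort$mutations |>
    filter(.data$mclass %in% c("nonsynonymous_snv", "indel"),
           .data$gene %in% genes)
  # counts matrix: samples x genes
  C <- matrix(0, nrow = n, ncol = length(genes),
              dimnames = list(smp$sample_id, genes))
  if (nrow(ns_mut) > 0) {
    tab <- ns_mut |> count(.data$sample_id, .data$gene)
    C[cbind(match(tab$sample_id, smp$sample_id),
            match(tab$gene, genes))] <- tab$n
  }
  syn <- cohort$mutations |>
    filter(.data$mclass == "synonymous") |>
    count(.data$sample_id)
  s <- setNames(rep(0, n), smp$sample_id)
  s[syn$sample_id] <- syn$n
  gene_n <- colSums(C)
  has_data <- gene_n > 0 & sum(s) > 0

  delta_from_ages <- function(a) {
    # a: n x B matrix of (permuted) ages; returns genes x B deltas
    gene_means <- crossprod(C, a) / gene_n
    syn_mean <- crossprod(matrix(s, ncol = 1), a) / sum(s)
    sweep(gene_means, 2, syn_mean, "-")
  }
  obs <- drop(delta_from_ages(matrix(ages, ncol = 1)))
  null_mat <- with_seed(seed, {
    A <- vapply(seq_len(n_perm), function(b) sample(ages), numeric(n))
    delta_from_ages(A)
  })
  uninformative <- length(unique(ages)) == 1
  q_low <- (1 + rowSums(null_mat <= obs)) / (n_perm + 1)
  q_high <- (1 + rowSums(null_mat >= obs)) / (n_perm + 1)
  p <- pmin(1, pmax(2 * pmin(q_low, q_high), 1 / (n_perm + 1)))
  p[!has_data] <- NA_real_
  res <- tibble(
    gene = genes,
    n_mutations = as.integer(gene_n),
    delta_age = ifelse(has_data, obs, NA_real_),
    perm_quantile = ifelse(has_data, q_low, NA_real_),
    p_value = p,
    q_value = NA_real_,
    n_perm = as.integer(n_perm),
    flag = dplyr::case_when(
      !has_data ~ "no_data",
      uninformative ~ "uninformative",
      .default = NA_character_
    )
  )
  res$q_value[has_data] <- p.adjust(res$p_value[has_data], method = "BH")
  res
}

#' Rank-biserial correlation between carrier status and patient age
#'
#' The effect size of a two-group rank comparison:
#' \eqn{r = 2U/(n_1 n_2) - 1 \in [-1, 1]}, where `U` counts pairs in which
#' the carrier is older (ties counting one half). Positive values mean
#' carriers are older; negative, younger.
#'
#' @param ages_with Ages of patients carrying the alteration.
#' @param ages_without Ages of patients without it.
#' @param B Optional number of bootstrap resamples for a percentile CI
#'   (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return A one-row tibble: `r`, `n_with`, `n_without` (and `ci_low`,
#'   `ci_high` when `B > 0`).
#' @examples
#' rank_biserial_age_bias(c(30, 35), c(60, 70)) # r = -1
#' @export
rank_biserial_age_bias <- function(ages_with, ages_without, B = 0,
                                   seed = NULL, conf = 0.95) {
  n1 <- length(ages_with)
  n2 <- length(ages_without)
  if (n1 == 0 || n2 == 0) {
    abort("both groups must be non-empty", class = "carceff_domain_error")
  }
  rb <- function(x, y) {
    r <- rank(c(x, y))
    U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    2 * U / (length(x) * length(y)) - 1
  }
  out <- tibble(r = rb(ages_with, ages_without),
                n_with = n1, n_without = n2)
  if (B > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        rb(sample(ages_with, n1, replace = TRUE),
           sample(ages_without, n2, replace = TRUE))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    out$ci_low <- unname(quantile(boots, alpha))
    out$ci_high <- unname(quantile(boots, 1 - alpha))
  }
  out
}

#' Paired age biases of copy-number versus point alterations
#'
#' For each gene with an assigned role, computes the age bias
#' ([rank_biserial_age_bias()]) of non-synonymous SNVs/small indels among
#' samples *without* any SCNA in the gene, and the age bias of the
#' role-matched SCNA type (deletions for tumour suppressors, amplifications
#' for oncogenes) among samples *without* any non-synonymous SNV/indel in
#' the gene; samples carrying both alteration types in the gene are thereby
#' excluded from both computations. Pairs are kept only when each alteration
#' type occurs in at least `min_freq` of samples.
#'
#' @param cohort A `carceff_cohort` containing both SNV/indel and SCNA
#'   records.
#' @param roles Data frame with columns `gene` and `role` (`"tsg"` or
#'   `"oncogene"`).
#' @param min_freq Minimum alteration frequency (fraction of samples).
#' @return A tibble: `gene`, `role`, `r_snv`, `r_scna`, `freq_snv`,
#'   `freq_scna`. Empty when no pair qualifies.
#' @export
scna_snv_bias_table <- function(cohort, roles, min_freq = 0.05) {
  roles <- as_tibble(roles)
  stopifnot(all(c("gene", "role") %in% names(roles)))
  smp <- cohort$samples
  n <- nrow(smp)
  rows <- purrr::pmap(roles, function(gene, role, ...) {
    scna_class <- if (role == "tsg") "scna_del" else "scna_amp"
    m <- filter(cohort$mutations, .data$gene == .env$gene)
    snv_ids <- unique(m$sample_id[m$mclass %in% c("nonsynonymous_snv",
                                                  "indel")])
    any_scna_ids <- unique(m$sample_id[m$mclass %in% c("scna_amp",
                                                       "scna_del")])
    scna_ids <- unique(m$sample_id[m$mclass == scna_class])
    if (length(snv_ids) / n < min_freq || length(scna_ids) / n < min_freq) {
      return(NULL)
    }
    # SNV bias among samples without any SCNA in the gene
    elig <- smp[!smp$sample_id %in% any_scna_ids, , drop = FALSE]
    w_snv <- elig$age[elig$sample_id %in% snv_ids]
    wo_snv <- elig$age[!elig$sample_id %in% snv_ids]
    # SCNA bias among samples without a nonsyn SNV/indel in the gene
    elig2 <- smp[!smp$sample_id %in% snv_ids, , drop = FALSE]
    w_scna <- elig2$age[elig2$sample_id %in% scna_ids]
    wo_scna <- elig2$age[!elig2$sample_id %in% scna_ids]
    if (length(w_snv) == 0 || length(wo_snv) == 0 ||
        length(w_scna) == 0 || length(wo_scna) == 0) {
      return(NULL)
    }
    tibble(gene = gene, role = role,
           r_snv = rank_biserial_age_bias(w_snv, wo_snv)$r,
           r_scna = rank_biserial_age_bias(w_scna, wo_scna)$r,
           freq_snv = length(snv_ids) / n,
           freq_scna = length(scna_ids) / n)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene = character(), role = character(),
                  r_snv = numeric(), r_scna = numeric(),
                  freq_snv = numeric(), freq_scna = numeric())
  }
  out
}
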