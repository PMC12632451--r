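#' Carcinogenic-effect odds ratio
#'
#' The per-cell hazard ratio for cancer initiation conferred by a mutation is
#' estimated by the odds ratio of the mutation's frequency among cancer
#' founder cells (`y`) relative to normal tissue cells (`x`):
#' \deqn{\hat w = \frac{y/(1-y)}{x/(1-x)}.}
#' `x = 0` with `y > 0` gives `Inf` (the mutation is unseen in normal tissue);
#' `y = 0` with `x > 0` gives 0; `x = y = 0` gives `NaN` (undefined).
#'
#' @param y Fraction of cancers in which the mutation is clonal, in \[0, 1\].
#' @param x Mutant cell fraction in normal tissue, in \[0, 1\].
#' @return Numeric vector of odds ratios (possibly `Inf`, 0 or `NaN`).
#' @examples
#' odds_ratio(2 / 3, 1 / 3) # 4
#' odds_ratio(0.05, 1.8e-4) # ~292
#' @export
odds_ratio <- function(y, x) {
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE)) {
    abort("x and y must lie in [0, 1]", class = "carceff_domain_error")
  }
  (y / (1 - y)) / (x / (1 - x))
}

qualifying_presence <- function(cohort, genes, classes, per_donor = FALSE) {
  unit <- if (per_donor) "donor_id" else "sample_id"
  ids <- unique(cohort$samples[[unit]])
  muts <- cohort$mutations |>
    filter(.data$gene %in% genes, .data$mclass %in% classes) |>
    left_join(select(cohort$samples, "sample_id", "donor_id"),
              by = "sample_id")
  pres <- matrix(FALSE, nrow = length(ids), ncol = length(genes),
                 dimnames = list(ids, genes))
  if (nrow(muts) > 0) {
    pres[cbind(match(muts[[unit]], ids), match(muts$gene, genes))] <- TRUE
  }
  pres
}

#' Matched carcinogenic-effect estimates with donor bootstrap
#'
#' For each gene, compares the fraction `y` of cancer samples carrying a
#' qualifying mutation against the cohort-mean mutant cell fraction `x` in
#' the normal-tissue cohort, reporting the odds ratio [odds_ratio()] with a
#' percentile bootstrap confidence interval from `B` resamples of the donors
#' in each cohort independently. Zero cells are reported as exact 0/`Inf`
#' with a flag; `zero_correction = TRUE` instead applies a Haldane-Anscombe
#' style 0.5 pseudo-count to the cancer frequency and half the smallest
#' representable fraction to `x`.
#'
#' @param cancer,normal `carceff_cohort`s (cancer presence/absence; normal
#'   tissue with VAFs).
#' @param genes Character vector of genes to estimate.
#' @param B Bootstrap resamples (donor-level).
#' @param seed RNG seed for resampling.
#' @param classes Qualifying mutation classes.
#' @param per_donor Count cancer frequency per donor instead of per sample.
#' @param zero_correction Apply the 0.5 continuity correction to zero cells.
#' @param conf Confidence level.
#' @return A tibble with one row per gene: `gene`, `method`, `w_hat`,
#'   `ci_low`, `ci_high`, `y`, `x`, `n_cancer`, `n_normal`, `note`.
#' @export
estimate_matched <- function(cancer, normal, genes, B = 1000, seed = NULL,
                             classes = c("nonsynonymous_snv", "indel"),
                             per_donor = FALSE, zero_correction = FALSE,
                             conf = 0.95) {
  stopifnot(inherits(cancer, "carceff_cohort"),
            inherits(normal, "carceff_cohort"))
  if (length(genes) == 0) {
    abort("empty gene list", class = "carceff_domain_error")
  }
  pres <- qualifying_presence(cancer, genes, classes, per_donor)
  n_cancer <- nrow(pres)

  frac_list <- lapply(genes, function(g) {
    sample_gene_fractions(normal, g, classes) |>
      summarise(fraction = mean(.data$fraction), .by = "donor_id")
  })
  donors_n <- frac_list[[1]]$donor_id
  fmat <- do.call(cbind, lapply(frac_list, function(d) d$fraction))
  n_normal <- length(donors_n)

  y <- colMeans(pres)
  x <- colMeans(fmat)

  adj_y <- function(k, n) if (zero_correction) (k + 0.5) / (n + 1) else k / n
  adj_x <- function(x, n) {
    if (zero_correction) pmax(x, 0.5 / (n + 1)) else x
  }
  y_pt <- adj_y(colSums(pres), n_cancer)
  x_pt <- adj_x(x, n_normal)
  w_hat <- odds_ratio(y_pt, x_pt)

  # donor bootstrap, both cohorts independently
  alpha <- (1 - conf) / 2
  ci <- with_seed(seed, {
    idx_c <- matrix(sample.int(n_cancer, n_cancer * B, replace = TRUE),
                    nrow = n_cancer)
    idx_n <- matrix(sample.int(n_normal, n_normal * B, replace = TRUE),
                    nrow = n_normal)
    vapply(seq_along(genes), function(j) {
      yb <- colMeans(matrix(pres[, j][idx_c], nrow = n_cancer))
      xb <- colMeans(matrix(fmat[, j][idx_n], nrow = n_normal))
      wb <- odds_ratio(adj_y(yb * n_cancer, n_cancer), adj_x(xb, n_normal))
      unname(quantile(wb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE))
    }, numeric(2))
  })

  note <- dplyr::case_when(
    y == 0 & x == 0 ~ "undefined",
    x == 0 ~ "infinite",
    y == 0 ~ "zero",
    .default = NA_character_
  )
  tibble(gene = genes, method = "odds_ratio", w_hat = w_hat,
         ci_low = ci[1, ], ci_high = ci[2, ], y = y, x = x,
         n_cancer = n_cancer, n_normal = n_normal, note = note)
}

#' Gene-length benchmark for relative carcinogenic effects
#'
#' When a tissue's normal-state mutations are unobservable (e.g. childhood
#' blood), a gene's mutation frequency in normal tissue is approximated as
#' proportional to its coding length `L`, giving the relative effect
#' \eqn{\hat w c = L^{-1} \hat f / (1 - \hat f)} from the observed mutated
#' fraction \eqn{\hat f} of cancer samples. Confidence intervals are
#' Clopper-Pearson binomial intervals for `f` pushed through the same
#' monotone map. Estimates are on a relative scale (units 1/bp, the constant
#' `c` unknown) and comparable only by rank with other methods.
#'
#' @param cancer A `carceff_cohort`.
#' @param genes Gene annotation tibble with `gene` and `coding_length`.
#' @param classes Qualifying mutation classes.
#' @param conf Confidence level.
#' @return A tibble: `gene`, `method`, `w_hat` (1/bp), `ci_low`, `ci_high`,
#'   `f`, `n_cancer`, `note`.
#' @export
estimate_length_benchmark <- function(cancer, genes,
                                      classes = c("nonsynonymous_snv",
                                                  "indel"),
                                      conf = 0.95) {
  stopifnot(inherits(cancer, "carceff_cohort"))
  genes <- as_tibble(genes)
  if (any(genes$coding_length <= 0)) {
    abort("coding_length must be positive", class = "carceff_domain_error")
  }
  pres <- qualifying_presence(cancer, genes$gene, classes)
  n <- nrow(pres)
  k <- unname(colSums(pres))
  f <- k / n
  ci <- vapply(k, function(ki) {
    as.numeric(binom.test(ki, n, conf.level = conf)$conf.int)
  }, numeric(2))
  map_w <- function(f, L) (f / (1 - f)) / L
  tibble(
    gene = genes$gene, method = "length_benchmark",
    w_hat = map_w(f, genes$coding_length),
    ci_low = map_w(ci[1, ], genes$coding_length),
    ci_high = map_w(ci[2, ], genes$coding_length),
    f = f, n_cancer = n,
    note = dplyr::if_else(f == 1, "infinite", NA_character_)
  )
}
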