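# shared in-code fixtures

toy_cohort <- function(ages, genes_per_sample, tissue = "cancer",
                       mclass = "nonsynonymous_snv", vafs = NULL) {
  n <- length(ages)
  ids <- sprintf("s%02d", seq_len(n))
  muts <- purrr::imap(genes_per_sample, function(gs, i) {
    if (length(gs) == 0) return(NULL)
    tibble::tibble(sample_id = ids[i], gene = gs,
                   mclass = mclass, chrom = "1",
                   pos = seq_along(gs) + i * 100,
                   ref = "A", alt = "T",
                   vaf = if (is.null(vafs)) NA_real_ else vafs[[i]])
  })
  as_cohort(
    samples = tibble::tibble(sample_id = ids, donor_id = paste0("d", ids),
                             age = ages, sex = "female",
                             tissue_state = tissue, cohort_label = "test"),
    mutations = dplyr::bind_rows(muts)
  )
}

# brute-force rank-biserial by pair enumeration
rb_brute <- function(x, y) {
  older <- sum(outer(x, y, ">"))
  younger <- sum(outer(x, y, "<"))
  (older - younger) / (length(x) * length(y))
}
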