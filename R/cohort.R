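#' Somatic mutation cohorts
#'
#' A cohort bundles a sample table (one row per sequenced sample, with donor,
#' age, sex and tissue state) with a mutation table (one row per called
#' mutation), and optionally a gene annotation table. All statistics in the
#' package take a cohort (or its component tibbles) as input. The constructor
#' validates types, ranges and referential integrity, and de-duplicates
#' identical mutation rows. Every filter appends a line to the cohort's
#' provenance log.
#'
#' Expected columns:
#' * `samples`: `sample_id`, `donor_id`, `age` (years, >= 0), `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `tissue_state` (`"cancer"` or
#'   `"normal"`), `cohort_label`, optional `burden`.
#' * `mutations`: `sample_id`, `gene`, `mclass` (one of `"synonymous"`,
#'   `"nonsynonymous_snv"`, `"indel"`, `"scna_amp"`, `"scna_del"`), `chrom`,
#'   optional `pos`, `ref`, `alt`, `vaf` (in \[0, 1\]).
#' * `genes`: `gene`, `coding_length` (bp, > 0), `chrom`, `start`, `end`.
#'
#' @param samples,mutations,genes Data frames as described above.
#' @param provenance Character vector of log lines.
#' @return An object of class `carceff_cohort`: a list with elements
#'   `samples`, `mutations`, `genes` (tibbles or `NULL`) and `provenance`.
#' @examples
#' coh <- as_cohort(
#'   samples = data.frame(
#'     sample_id = c("s1", "s2"), donor_id = c("d1", "d2"),
#'     age = c(60, 70), sex = "female", tissue_state = "cancer",
#'     cohort_label = "toy"
#'   ),
#'   mutations = data.frame(
#'     sample_id = "s1", gene = "TP53", mclass = "nonsynonymous_snv",
#'     chrom = "17", vaf = NA_real_
#'   )
#' )
#' coh
#' @export
as_cohort <- function(samples, mutations, genes = NULL,
                      provenance = character()) {
  samples <- as_tibble(samples)
  mutations <- as_tibble(mutations)

  req_s <- c("sample_id", "donor_id", "age", "sex", "tissue_state",
             "cohort_label")
  miss <- setdiff(req_s, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carceff_format_error")
  }
  if (!"burden" %in% names(samples)) samples$burden <- NA_integer_
  req_m <- c("sample_id", "gene", "mclass", "chrom")
  miss <- setdiff(req_m, names(mutations))
  if (length(miss) > 0) {
    abort(paste0("mutation table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carceff_format_error")
  }
  if (!"vaf" %in% names(mutations)) mutations$vaf <- NA_real_

  if (anyDuplicated(samples$sample_id) > 0) {
    abort("duplicate sample_id in sample table",
          class = "carceff_validation_error")
  }
  if (any(samples$age < 0, na.rm = TRUE)) {
    abort("negative ages in sample table", class = "carceff_validation_error")
  }
  bad <- setdiff(unique(samples$tissue_state), c("cancer", "normal"))
  if (length(bad) > 0) {
    abort(paste0("tissue_state must be 'cancer' or 'normal', found: ",
                 paste(bad, collapse = ", ")),
          class = "carceff_validation_error")
  }
  samples$sex[is.na(samples$sex)] <- "unknown"
  bad <- setdiff(unique(samples$sex), c("male", "female", "unknown"))
  if (length(bad) > 0) {
    abort(paste0("sex must be male/female/unknown, found: ",
                 paste(bad, collapse = ", ")),
          class = "carceff_validation_error")
  }

  n_drop <- sum(is.na(samples$age))
  if (n_drop > 0) {
    dropped <- samples$sample_id[is.na(samples$age)]
    samples <- samples[!is.na(samples$age), , drop = FALSE]
    mutations <- mutations[!mutations$sample_id %in% dropped, , drop = FALSE]
    provenance <- c(provenance,
                    sprintf("dropped %d sample(s) with missing age", n_drop))
  }

  bad_cls <- setdiff(unique(mutations$mclass), mclass_levels())
  if (length(bad_cls) > 0) {
    abort(paste0("unknown mutation class(es): ",
                 paste(bad_cls, collapse = ", ")),
          class = "carceff_format_error")
  }
  if (any(mutations$vaf < 0 | mutations$vaf > 1, na.rm = TRUE)) {
    abort("vaf outside [0, 1]", class = "carceff_validation_error")
  }
  orphans <- setdiff(mutations$sample_id, samples$sample_id)
  if (length(orphans) > 0) {
    abort(paste0("mutation rows reference unknown sample_id(s): ",
                 paste(unique(orphans), collapse = ", ")),
          class = "carceff_validation_error")
  }

  n_before <- nrow(mutations)
  mutations <- distinct(mutations)
  if (nrow(mutations) < n_before) {
    provenance <- c(provenance,
                    sprintf("removed %d duplicate mutation row(s)",
                            n_before - nrow(mutations)))
  }

  if (!is.null(genes)) {
    genes <- as_tibble(genes)
    req_g <- c("gene", "coding_length", "chrom", "start", "end")
    miss <- setdiff(req_g, names(genes))
    if (length(miss) > 0) {
      abort(paste0("gene table is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "carceff_format_error")
    }
    if (any(genes$coding_length <= 0)) {
      abort("coding_length must be positive",
            class = "carceff_validation_error")
    }
    if (any(genes$start > genes$end)) {
      abort("gene start > end", class = "carceff_validation_error")
    }
  }

  structure(list(samples = samples, mutations = mutations, genes = genes,
                 provenance = provenance),
            class = "carceff_cohort")
}

mclass_levels <- function() {
  c("synonymous", "nonsynonymous_snv", "indel", "scna_amp", "scna_del")
}

snv_indel_classes <- function() {
  c("synonymous", "nonsynonymous_snv", "indel")
}

#' @export
print.carceff_cohort <- function(x, ...) {
  st <- table(factor(x$samples$tissue_state, c("cancer", "normal")))
  cat(sprintf("<carceff_cohort> %d samples (%d cancer, %d normal), %d mutations\n",
              nrow(x$samples), st[["cancer"]], st[["normal"]],
              nrow(x$mutations)))
  if (length(x$provenance) > 0) {
    cat("provenance:\n")
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a cohort from tab-separated files
#'
#' Reads the on-disk TSV dialect (`mutations.tsv`, `samples.tsv` and an
#' optional `genes.tsv`) into a validated [as_cohort()] object. Sample files
#' use `age_years`, `sex` coded M/F/NA, `tissue` and `cohort` columns; these
#' are normalised to the internal names. Samples with missing age are dropped
#' and counted in the provenance log.
#'
#' @param mutations_path,samples_path,genes_path File paths; `genes_path` is
#'   optional.
#' @return A `carceff_cohort`.
#' @export
read_cohort <- function(mutations_path, samples_path, genes_path = NULL) {
  # pin types of the known columns (a sex column of all "F" would otherwise
  # be guessed as logical); parsers are restricted to columns present
  read_pinned <- function(path, types) {
    hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
    spec <- do.call(readr::cols,
                    c(as.list(types[intersect(names(types), hdr)]),
                      .default = readr::col_guess()))
    readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                    col_types = spec)
  }
  samples <- read_pinned(samples_path,
                         c(sample_id = "c", donor_id = "c",
                           age_years = "d", sex = "c", tissue = "c",
                           cohort = "c"))
  req <- c("sample_id", "donor_id", "age_years", "sex", "tissue", "cohort")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    abort(paste0("samples file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carceff_format_error")
  }
  samples <- samples |>
    mutate(
      sex = dplyr::case_match(.data$sex, "M" ~ "male", "F" ~ "female",
                              .default = "unknown"),
      age = as.numeric(.data$age_years),
      tissue_state = .data$tissue,
      cohort_label = .data$cohort
    ) |>
    select(dplyr::all_of(c("sample_id", "donor_id", "age", "sex",
                           "tissue_state", "cohort_label")),
           dplyr::any_of("burden"))

  mutations <- read_pinned(mutations_path,
                           c(sample_id = "c", gene = "c", mclass = "c",
                             chrom = "c", ref = "c", alt = "c",
                             vaf = "d"))
  req <- c("sample_id", "gene", "mclass", "chrom")
  miss <- setdiff(req, names(mutations))
  if (length(miss) > 0) {
    abort(paste0("mutations file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carceff_format_error")
  }
  if ("vaf" %in% names(mutations)) mutations$vaf <- as.numeric(mutations$vaf)

  genes <- NULL
  if (!is.null(genes_path)) {
    genes <- readr::read_tsv(genes_path, show_col_types = FALSE,
                             na = c("", "NA"))
    if ("coding_length_bp" %in% names(genes)) {
      genes <- rename(genes, coding_length = "coding_length_bp")
    }
  }
  as_cohort(samples, mutations, genes,
            provenance = sprintf("read from %s + %s", mutations_path,
                                 samples_path))
}

#' Per-sample exonic mutation burden
#'
#' Populates each sample's `burden` with its count of exonic SNV/small-indel
#' records (classes `synonymous`, `nonsynonymous_snv`, `indel`); copy-number
#' records are excluded. Idempotent.
#'
#' @param cohort A `carceff_cohort`.
#' @return The cohort with `samples$burden` filled in.
#' @export
compute_burden <- function(cohort) {
  stopifnot(inherits(cohort, "carceff_cohort"))
  counts <- cohort$mutations |>
    filter(.data$mclass %in% snv_indel_classes()) |>
    count(.data$sample_id, name = "burden")
  cohort$samples <- cohort$samples |>
    select(-"burden") |>
    left_join(counts, by = "sample_id") |>
    mutate(burden = dplyr::coalesce(.data$burden, 0L))
  cohort
}

# Lower-interpolation median on integers: the lower of the two middle order
# statistics for even n, deterministic for downstream thresholds.
median_low <- function(x) {
  sort(x)[ceiling(length(x) / 2)]
}

drop_samples <- function(cohort, drop_ids, why) {
  cohort$samples <- filter(cohort$samples, !.data$sample_id %in% drop_ids)
  cohort$mutations <- filter(cohort$mutations,
                             !.data$sample_id %in% drop_ids)
  cohort$provenance <- c(cohort$provenance,
                         sprintf("removed %d sample(s): %s",
                                 length(drop_ids), why))
  cohort
}

#' Filter samples by mutation burden
#'
#' `filter_by_burden()` removes samples whose exonic mutation burden exceeds
#' `factor` times the cohort median burden (the median is computed on the
#' input cohort, before any removal). `filter_by_burden_ceiling()` applies an
#' absolute burden ceiling instead, e.g. to match a cancer cohort's burden
#' range to that of reference normal-tissue samples. Both recompute burdens
#' first if absent and log removals in the provenance.
#'
#' @param cohort A `carceff_cohort`.
#' @param factor Positive multiple of the median burden to allow.
#' @param ceiling Absolute maximum burden to allow.
#' @return The filtered cohort.
#' @export
filter_by_burden <- function(cohort, factor = 10) {
  stopifnot(inherits(cohort, "carceff_cohort"), factor > 0)
  if (nrow(cohort$samples) == 0) {
    abort("cannot burden-filter an empty cohort",
          class = "carceff_validation_error")
  }
  if (anyNA(cohort$samples$burden)) cohort <- compute_burden(cohort)
  cutoff <- factor * median_low(cohort$samples$burden)
  drop_ids <- cohort$samples$sample_id[cohort$samples$burden > cutoff]
  if (length(drop_ids) == 0) return(cohort)
  drop_samples(cohort, drop_ids,
               sprintf("burden > %g x median (cutoff %g)", factor, cutoff))
}

#' @rdname filter_by_burden
#' @export
filter_by_burden_ceiling <- function(cohort, ceiling) {
  stopifnot(inherits(cohort, "carceff_cohort"), ceiling > 0)
  if (nrow(cohort$samples) == 0) {
    abort("cannot burden-filter an empty cohort",
          class = "carceff_validation_error")
  }
  if (anyNA(cohort$samples$burden)) cohort <- compute_burden(cohort)
  drop_ids <- cohort$samples$sample_id[cohort$samples$burden > ceiling]
  if (length(drop_ids) == 0) return(cohort)
  drop_samples(cohort, drop_ids, sprintf("burden > ceiling %g", ceiling))
}

variant_key <- function(mutations) {
  if (all(c("pos", "ref", "alt") %in% names(mutations)) &&
      !all(is.na(mutations$pos))) {
    paste(mutations$gene, mutations$chrom, mutations$pos, mutations$ref,
          mutations$alt, sep = "|")
  } else {
    paste(mutations$gene, mutations$mclass, sep = "|")
  }
}

#' Exclude donors sharing a mutation between cancer and normal tissue
#'
#' In matched designs, an apparently normal sample may belong to the clone
#' that founded the cancer; such donors are identified by an identical variant
#' present in both their cancer and normal samples and removed from both
#' cohorts. Variant identity uses `(gene, chrom, pos, ref, alt)` when position
#' columns are available, else `(gene, mclass)`.
#'
#' @param cancer,normal Matched `carceff_cohort`s sharing `donor_id`s.
#' @return A list with elements `cancer` and `normal` (filtered cohorts) and
#'   `removed_donors` (character vector).
#' @export
exclude_shared_mutation_donors <- function(cancer, normal) {
  stopifnot(inherits(cancer, "carceff_cohort"),
            inherits(normal, "carceff_cohort"))
  shared_donors <- intersect(cancer$samples$donor_id, normal$samples$donor_id)
  if (length(shared_donors) == 0) {
    warn("no donor overlap between cohorts; returned unchanged")
    return(list(cancer = cancer, normal = normal,
                removed_donors = character()))
  }
  keyed <- function(coh) {
    m <- left_join(coh$mutations,
                   select(coh$samples, "sample_id", "donor_id"),
                   by = "sample_id")
    tibble(donor_id = m$donor_id, key = variant_key(m))
  }
  kc <- keyed(cancer)
  kn <- keyed(normal)
  hit <- inner_join(kc, kn, by = c("donor_id", "key"))
  bad_donors <- unique(hit$donor_id)
  strip <- function(coh) {
    ids <- coh$samples$sample_id[coh$samples$donor_id %in% bad_donors]
    if (length(ids) == 0) return(coh)
    drop_samples(coh, ids, "donor shares a mutation across tissue states")
  }
  list(cancer = strip(cancer), normal = strip(normal),
       removed_donors = bad_donors)
}
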