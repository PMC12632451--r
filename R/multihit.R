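#' Multi-hit carcinogenesis model
#'
#' Along each normal-tissue lineage, mutations arrive as a rate-`v` Poisson
#' process; each mutation carries a carcinogenic effect drawn independently
#' from a Gamma distribution, and the lineage's transformation hazard is the
#' baseline rate `r_base` multiplied by the product of its mutations'
#' effects. Selection in normal tissue is deliberately absent from this
#' model.
#'
#' @param v Mutation arrival rate along a lineage (1/year).
#' @param r_base Baseline transformation hazard with zero mutations (1/year).
#' @param effect_shape,effect_rate Gamma parameters of the per-mutation
#'   carcinogenic effect (defaults shape 2, rate 1).
#' @param lifespan Years.
#' @return An object of class `multihit_model`.
#' @export
multihit_model <- function(v = 0.005, r_base = 1e-9, effect_shape = 2,
                           effect_rate = 1, lifespan = 80) {
  stopifnot(v >= 0, r_base > 0, effect_shape > 0, effect_rate > 0,
            lifespan > 0)
  structure(list(v = v, r_base = r_base, effect_shape = effect_shape,
                 effect_rate = effect_rate, lifespan = lifespan),
            class = "multihit_model")
}

# Draw lineage skeletons: mutation times (sorted) and log-effects.
# Returns a list of tibbles-free structures for speed.
draw_skeletons <- function(model, n) {
  k <- rpois(n, model$v * model$lifespan)
  total <- sum(k)
  times <- runif(total, 0, model$lifespan)
  log_eff <- log(rgamma(total, model$effect_shape, model$effect_rate))
  idx <- rep.int(seq_len(n), k)
  ord <- order(idx, times)
  list(k = k, idx = idx[ord], times = times[ord], log_eff = log_eff[ord])
}

# Per-lineage piecewise-constant log-hazard segments. For lineage with
# mutation times t_1 < ... < t_k, segment j in [t_j, t_{j+1}) has hazard
# r_base * prod_{i<=j} effect_i, accumulated in log space.
skeleton_segments <- function(model, sk, i, pos) {
  # pos: integer range of lineage i's rows in sk$times / sk$log_eff
  t_m <- sk$times[pos]
  breaks <- c(0, t_m, model$lifespan)
  log_h <- log(model$r_base) + c(0, cumsum(sk$log_eff[pos]))
  list(breaks = breaks, log_h = log_h)
}

#' Exact simulation of multi-hit lineages
#'
#' Between consecutive mutation arrivals the transformation hazard is
#' constant, so transformation times are drawn by competing exponentials
#' segment by segment — no discretisation. Hazard products are accumulated
#' as sums of log-effects to avoid overflow.
#'
#' @param model A [multihit_model()].
#' @param n Number of independent lineages.
#' @param seed RNG seed.
#' @param detail Keep per-lineage mutation times and effects as list
#'   columns.
#' @return A tibble with one row per lineage: `n_mut_total` (mutations over
#'   the whole lifespan), `transformed`, `t_cancer`, `n_drivers` (mutations
#'   present at transformation), `mean_log_effect` (of those drivers; `NA`
#'   when none or not transformed), and with `detail = TRUE` list columns
#'   `mutation_times`, `effects`.
#' @export
simulate_lineages <- function(model, n, seed = NULL, detail = FALSE) {
  stopifnot(inherits(model, "multihit_model"), n >= 1)
  with_seed(seed, {
    sk <- draw_skeletons(model, n)
    ends <- cumsum(sk$k)
    starts <- ends - sk$k + 1
    t_cancer <- rep(NA_real_, n)
    n_drivers <- rep(NA_integer_, n)
    mean_log_eff <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      pos <- if (sk$k[i] > 0) seq.int(starts[i], ends[i]) else integer(0)
      seg <- skeleton_segments(model, sk, i, pos)
      nb <- length(seg$breaks)
      for (j in seq_len(nb - 1)) {
        len <- seg$breaks[j + 1] - seg$breaks[j]
        wait <- rexp(1) * exp(-seg$log_h[j])
        if (wait < len) {
          t_cancer[i] <- seg$breaks[j] + wait
          n_drivers[i] <- j - 1L
          mean_log_eff[i] <- if (j > 1) {
            mean(sk$log_eff[pos][seq_len(j - 1)])
          } else {
            NA_real_
          }
          break
        }
      }
    }
    out <- tibble(
      n_mut_total = as.integer(sk$k),
      transformed = !is.na(t_cancer),
      t_cancer = t_cancer,
      n_drivers = n_drivers,
      mean_log_effect = mean_log_eff
    )
    if (detail) {
      out$mutation_times <- unname(split(sk$times, factor(sk$idx,
                                                          seq_len(n))))
      out$effects <- unname(split(exp(sk$log_eff), factor(sk$idx,
                                                          seq_len(n))))
    }
    out
  })
}

#' Sample cancers from the exact conditional-on-transformation law
#'
#' With realistic parameters (e.g. `r_base = 1e-9`) transformation is so
#' rare that unconditional simulation yields essentially no cancers. Because
#' the hazard is piecewise constant given a lineage's mutation history, each
#' lineage's transformation-time density is available in closed form; this
#' function therefore draws `n_skeletons` mutation histories, weights each
#' by its exact probability of transforming within the lifespan, resamples
#' cancers proportionally to those weights, and draws each cancer's
#' transformation time from the lineage's conditional (truncated
#' piecewise-exponential) distribution by inversion. This is an exact
#' sampler for the conditional law, not an approximation.
#'
#' @param model A [multihit_model()].
#' @param n_cancers Number of cancers to sample.
#' @param n_skeletons Number of lineage histories in the importance pool.
#' @param seed RNG seed.
#' @return A tibble with one row per cancer: `t_cancer`, `n_drivers`,
#'   `mean_log_effect` (`NA` for cancers with zero drivers).
#' @export
sample_cancers <- function(model, n_cancers, n_skeletons = 2e5,
                           seed = NULL) {
  stopifnot(inherits(model, "multihit_model"))
  with_seed(seed, {
    sk <- draw_skeletons(model, n_skeletons)
    ends <- cumsum(sk$k)
    starts <- ends - sk$k + 1
    # pass 1: transformation probability per skeleton, without storing the
    # segment decomposition (memory stays linear in the mutation count)
    p_tr <- rep(-expm1(-model$r_base * model$lifespan), n_skeletons)
    which_mut <- which(sk$k > 0)
    for (i in which_mut) {
      pos <- seq.int(starts[i], ends[i])
      seg <- skeleton_segments(model, sk, i, pos)
      H_tot <- sum(exp(seg$log_h) * diff(seg$breaks))
      p_tr[i] <- -expm1(-H_tot)
    }
    pick <- sample.int(n_skeletons, n_cancers, replace = TRUE, prob = p_tr)
    # pass 2: invert the conditional transformation-time CDF only for the
    # picked skeletons (grouped, so each skeleton is decomposed once)
    u <- runif(n_cancers)
    t_cancer <- numeric(n_cancers)
    n_drivers <- integer(n_cancers)
    mean_log_eff <- rep(NA_real_, n_cancers)
    by_skel <- split(seq_len(n_cancers), pick)
    skel_ids <- as.integer(names(by_skel))
    for (b in seq_along(by_skel)) {
      i <- skel_ids[b]
      rows <- by_skel[[b]]
      pos <- if (sk$k[i] > 0) seq.int(starts[i], ends[i]) else integer(0)
      seg <- skeleton_segments(model, sk, i, pos)
      len <- diff(seg$breaks)
      H <- c(0, cumsum(exp(seg$log_h) * len))
      Htarget <- -log1p(-u[rows] * p_tr[i])
      j <- findInterval(Htarget, H, rightmost.closed = TRUE)
      j <- pmin(pmax(j, 1L), length(len))
      t_cancer[rows] <- seg$breaks[j] +
        (Htarget - H[j]) * exp(-seg$log_h[j])
      n_drivers[rows] <- j - 1L
      if (sk$k[i] > 0) {
        cum_mean <- cumsum(sk$log_eff[pos]) / seq_along(pos)
        has <- j > 1L
        mean_log_eff[rows[has]] <- cum_mean[j[has] - 1L]
      }
    }
    tibble(t_cancer = t_cancer, n_drivers = n_drivers,
           mean_log_effect = mean_log_eff)
  })
}

#' Summaries of simulated cancers
#'
#' From lineage outcomes ([simulate_lineages()]) extracts the per-cancer
#' table and an empirical incidence curve (transformations per lineage-year
#' at risk within each age bin).
#'
#' @param outcomes A [simulate_lineages()] result.
#' @param age_step Incidence bin width (years).
#' @param lifespan Upper age limit (defaults to the maximum observed time).
#' @return A list: `cancers` (tibble of `t_cancer`, `n_drivers`,
#'   `mean_log_effect`), `incidence` (tibble of `age`, `incidence`,
#'   `at_risk_years`), `n_cancers`.
#' @export
cancer_summaries <- function(outcomes, age_step = 5, lifespan = NULL) {
  cc <- outcomes[outcomes$transformed, , drop = FALSE]
  if (nrow(cc) == 0) {
    warn("no transformed lineages")
    return(list(cancers = tibble(t_cancer = numeric(),
                                 n_drivers = integer(),
                                 mean_log_effect = numeric()),
                incidence = tibble(age = numeric(), incidence = numeric(),
                                   at_risk_years = numeric()),
                n_cancers = 0L))
  }
  if (is.null(lifespan)) lifespan <- max(cc$t_cancer, 1)
  breaks <- seq(0, lifespan, by = age_step)
  if (max(breaks) < lifespan) breaks <- c(breaks, lifespan)
  end_t <- ifelse(outcomes$transformed, outcomes$t_cancer, lifespan)
  inc <- vapply(seq_len(length(breaks) - 1), function(b) {
    a0 <- breaks[b]; a1 <- breaks[b + 1]
    events <- sum(cc$t_cancer >= a0 & cc$t_cancer < a1)
    at_risk <- sum(pmin(pmax(end_t - a0, 0), a1 - a0))
    c(events / max(at_risk, .Machine$double.eps), at_risk)
  }, numeric(2))
  list(
    cancers = select(cc, "t_cancer", "n_drivers", "mean_log_effect"),
    incidence = tibble(age = head(breaks, -1), incidence = inc[1, ],
                       at_risk_years = inc[2, ]),
    n_cancers = nrow(cc)
  )
}

#' Population incidence curve by exact per-lineage hazards
#'
#' Monte Carlo estimate of the population transformation hazard
#' \eqn{E[r(a) S(a)] / E[S(a)]} over lineage histories, where `r(a)` is a
#' lineage's hazard at age `a` and `S(a)` its survival; usable at realistic
#' (tiny) baseline rates where empirical incidence from
#' [simulate_lineages()] would be all zeros.
#'
#' @param model A [multihit_model()].
#' @param ages Age grid.
#' @param n_skeletons Monte Carlo size.
#' @param seed RNG seed.
#' @return A tibble: `age`, `incidence`.
#' @export
multihit_incidence <- function(model, ages = seq(5, 80, by = 5),
                               n_skeletons = 2e5, seed = NULL) {
  with_seed(seed, {
    sk <- draw_skeletons(model, n_skeletons)
    ends <- cumsum(sk$k)
    starts <- ends - sk$k + 1
    num <- numeric(length(ages))
    den <- numeric(length(ages))
    for (i in seq_len(n_skeletons)) {
      pos <- if (sk$k[i] > 0) seq.int(starts[i], ends[i]) else integer(0)
      seg <- skeleton_segments(model, sk, i, pos)
      len <- diff(seg$breaks)
      Hcum <- c(0, cumsum(exp(seg$log_h) * len))
      j <- findInterval(ages, seg$breaks, rightmost.closed = TRUE)
      j <- pmin(pmax(j, 1), length(len))
      H_a <- Hcum[j] + exp(seg$log_h[j]) * (ages - seg$breaks[j])
      S <- exp(-H_a)
      num <- num + exp(seg$log_h[j]) * S
      den <- den + S
    }
    tibble(age = ages, incidence = num / den)
  })
}

#' Mutation counts in surviving (normal) lineages by age
#'
#' Mean number of carcinogenic mutations among lineages not yet transformed
#' at each age, and the excess driver count of cancers over age-matched
#' normal lineages.
#'
#' @param outcomes A [simulate_lineages()] result with `detail = TRUE`.
#' @param ages Age grid.
#' @return A list: `normal` (tibble of `age`, `mean_mutations`,
#'   `n_at_risk`), `excess` (tibble of cancers' `t_cancer`, `n_drivers`,
#'   `expected_normal` = mean normal-lineage count at that age, `excess`).
#' @export
normal_tissue_summaries <- function(outcomes, ages = seq(5, 80, by = 5)) {
  if (!"mutation_times" %in% names(outcomes)) {
    abort("outcomes must come from simulate_lineages(detail = TRUE)",
          class = "carceff_domain_error")
  }
  counts_at <- function(a) {
    alive <- is.na(outcomes$t_cancer) | outcomes$t_cancer > a
    k <- vapply(outcomes$mutation_times[alive],
                function(tm) sum(tm <= a), numeric(1))
    c(mean(k), sum(alive))
  }
  m <- vapply(ages, counts_at, numeric(2))
  normal <- tibble(age = ages, mean_mutations = m[1, ], n_at_risk = m[2, ])
  cc <- outcomes[outcomes$transformed, , drop = FALSE]
  excess <- tibble(
    t_cancer = cc$t_cancer,
    n_drivers = cc$n_drivers,
    expected_normal = approx(normal$age, normal$mean_mutations,
                             xout = cc$t_cancer, rule = 2)$y
  )
  excess$excess <- excess$n_drivers - excess$expected_normal
  list(normal = normal, excess = excess)
}
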