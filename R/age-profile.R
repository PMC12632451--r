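#' Age distribution of cancers carrying a mutation, versus a neutral mutation
#'
#' For a mutation with selective effect `s` and carcinogenic effect `w`,
#' computes the age density of cancers whose founder carries the mutation,
#' the same density for a neutral reference mutation (same acquisition rate,
#' `s = 0`, `w = 1`), their mean ages, and the ratio of the two mutations'
#' expected frequencies among cancers. The density of mutant-z cancers at age
#' `T` is \eqn{-\partial_T p_0(0,T) \, e^{-N_0 R_0(T)}} (first-cancer density
#' accounting for survival from both mutant- and wild-type-initiated
#' cancers), averaged over the per-person baseline-hazard mixture by midpoint
#' quadrature; means are integrals over the lifespan.
#'
#' @param s Selective effect in normal tissue (1/year); mutant rates are
#'   `a1 = a0 + s`, `b1 = a0`.
#' @param w Carcinogenic effect.
#' @param N0,v,a0,lifespan As in [bp_model()]; `a0` is the baseline
#'   division/loss rate (mutant `a1 = a0 + s`).
#' @param hazard A [bp_hazard_power()] (possibly a mixture) or
#'   [bp_hazard_constant()].
#' @param age_step Grid spacing for the age axis (years).
#' @param dt Euler step for the ODE solves (years).
#' @param n_u Number of quadrature nodes over the mixture parameter.
#' @return An object of class `bp_age_profile`: list with `density` (tibble
#'   of `age`, `dens_z`, `dens_neutral`), `mean_age_z`, `mean_age_neutral`,
#'   `mean_age_shift` (z minus neutral), `odds_vs_neutral` (frequency ratio
#'   among cancers), and the call parameters.
#' @export
age_profile <- function(s, w, N0 = 1e5, v = 1e-8, a0 = 1,
                        hazard = bp_hazard_power(), lifespan = 80,
                        age_step = 1, dt = 0.01, n_u = 64) {
  stopifnot(s >= -a0, w > 0)
  ages <- seq(age_step, lifespan, by = age_step)
  nodes <- mixture_nodes(hazard, n_u)
  p <- hazard$exponent
  dens_z <- numeric(length(ages))
  dens_n <- numeric(length(ages))
  tot_z <- numeric(length(ages))
  tot_n <- numeric(length(ages))
  for (i in seq_along(nodes$coefs)) {
    cf <- nodes$coefs[i]
    wt <- nodes$weights[i]
    R0 <- cf * ages^(p + 1) / (p + 1)
    surv_wt <- exp(-N0 * R0)
    r0T <- cf * ages^p
    for (variant in c("z", "neutral")) {
      ss <- if (variant == "z") s else 0
      ww <- if (variant == "z") w else 1
      prof <- bp_profile_cpp(ages, dt, N0 * v, a0 + ss, a0, ww, cf, p)
      if (!all(prof$ok)) {
        abort("Euler integration unstable in age_profile; use a smaller dt",
              class = "carceff_step_size_error")
      }
      dz <- pmax(-prof$q0, 0) * surv_wt
      dtot <- (pmax(-prof$q0, 0) + N0 * r0T * prof$p0) * surv_wt
      if (variant == "z") {
        dens_z <- dens_z + wt * dz
        tot_z <- tot_z + wt * dtot
      } else {
        dens_n <- dens_n + wt * dz
        tot_n <- tot_n + wt * dtot
      }
    }
  }
  freq_z <- sum(dens_z) / sum(tot_z)
  freq_n <- sum(dens_n) / sum(tot_n)
  structure(list(
    density = tibble(age = ages, dens_z = dens_z, dens_neutral = dens_n),
    mean_age_z = sum(ages * dens_z) / sum(dens_z),
    mean_age_neutral = sum(ages * dens_n) / sum(dens_n),
    mean_age_shift = sum(ages * dens_z) / sum(dens_z) -
      sum(ages * dens_n) / sum(dens_n),
    odds_vs_neutral = freq_z / freq_n,
    s = s, w = w, N0 = N0, v = v, lifespan = lifespan
  ), class = "bp_age_profile")
}

#' @export
print.bp_age_profile <- function(x, ...) {
  cat(sprintf(
    "<bp_age_profile> s = %g, w = %g: mean age %.2f (neutral %.2f, shift %+.2f), freq ratio %.3g\n",
    x$s, x$w, x$mean_age_z, x$mean_age_neutral, x$mean_age_shift,
    x$odds_vs_neutral))
  invisible(x)
}

#' Deterministic clone growth curves for the non-carcinogenicity null
#'
#' Expected size of a mutant clone a years after initiation, under four
#' growth laws used to span realistic normal-tissue dynamics: `exponential`
#' (\eqn{e^{s a}}), `gompertz` (\eqn{K^{1 - e^{-g a}}}, carrying capacity
#' `K`), `logistic` (\eqn{K / (1 + (K - 1) e^{-s a})}) and `polynomial`
#' (\eqn{1 + c a^p}). Each reduces to the neutral constant expectation 1 when
#' its selection parameter (`s`, `g` or `c`) is zero.
#'
#' @param type One of `"exponential"`, `"gompertz"`, `"logistic"`,
#'   `"polynomial"`.
#' @param s Growth-rate parameter (exponential/logistic), per year.
#' @param g Gompertz rate parameter, per year.
#' @param coef Polynomial coefficient `c`.
#' @param K Carrying capacity (cells).
#' @param exponent Polynomial exponent `p`.
#' @return An object of class `growth_curve`; call it on clone ages or pass
#'   it to [null_family_age_shift()].
#' @export
growth_curve <- function(type = c("exponential", "gompertz", "logistic",
                                  "polynomial"),
                         s = 0.1, g = 0.1, coef = 1, K = 1e4, exponent = 2) {
  type <- match.arg(type)
  f <- switch(type,
    exponential = function(a) exp(s * a),
    gompertz = function(a) K^(1 - exp(-g * a)),
    logistic = function(a) K / (1 + (K - 1) * exp(-s * a)),
    polynomial = function(a) 1 + coef * a^exponent
  )
  selected <- switch(type, exponential = s > 0, logistic = s > 0,
                     gompertz = g > 0, polynomial = coef > 0)
  structure(list(type = type, size = f, selected = selected,
                 pars = list(s = s, g = g, coef = coef, K = K,
                             exponent = exponent)),
            class = "growth_curve")
}

# expected mutant cells at ages T: m(T) = N0 v \int_0^T n(T - t0) dt0,
# trapezoid on a fine grid shared across T values (cumulative integral).
expected_mutant_cells <- function(curve, N0, v, ages, step = 0.1) {
  grid <- seq(0, max(ages), by = step)
  n_of_a <- curve$size(grid)
  cum <- c(0, cumsum((head(n_of_a, -1) + n_of_a[-1]) / 2 * diff(grid)))
  N0 * v * approx(grid, cum, xout = ages)$y
}

#' Age shift and frequency ratio under the non-carcinogenicity null
#'
#' For a positively selected but non-carcinogenic mutation (`w = 1`), clones
#' initiate as a Poisson process at rate `N0 * v` and grow deterministically
#' along `curve`; the cancer founder is drawn proportionally to cell
#' fractions. Returns the mean-age difference of mutation-carrying cancers
#' versus neutral-mutation cancers and the ratio of the two frequencies among
#' cancers. Any curve with positive selection gives a non-negative age shift
#' and a frequency ratio at least one; zero selection gives exactly (0, 1).
#' The returned densities allow a CDF-wise stochastic-dominance check.
#'
#' @param curve A [growth_curve()].
#' @param N0,v As in [bp_model()].
#' @param hazard Baseline hazard (mixture integrated by quadrature).
#' @param lifespan Years.
#' @param age_step Age grid spacing.
#' @param n_u Mixture quadrature nodes.
#' @return A list: `mean_age_shift`, `freq_ratio`, `density` (tibble of
#'   `age`, `dens_z`, `dens_neutral`), `curve_type`.
#' @export
null_family_age_shift <- function(curve, N0 = 1e5, v = 1e-8,
                                  hazard = bp_hazard_power(), lifespan = 80,
                                  age_step = 0.5, n_u = 64) {
  stopifnot(inherits(curve, "growth_curve"))
  ages <- seq(age_step, lifespan, by = age_step)
  m_z <- expected_mutant_cells(curve, N0, v, ages)
  m_n <- N0 * v * ages # neutral: constant expected clone size 1
  nodes <- mixture_nodes(hazard, n_u)
  p <- hazard$exponent
  dens_z <- numeric(length(ages))
  dens_n <- numeric(length(ages))
  tot <- numeric(length(ages))
  for (i in seq_along(nodes$coefs)) {
    cf <- nodes$coefs[i]
    wt <- nodes$weights[i]
    r0T <- cf * ages^p
    R0 <- cf * ages^(p + 1) / (p + 1)
    g <- N0 * r0T * exp(-N0 * R0) # cancer age density, w = 1 everywhere
    dens_z <- dens_z + wt * g * m_z / (N0 + m_z)
    dens_n <- dens_n + wt * g * m_n / (N0 + m_n)
    tot <- tot + wt * g
  }
  list(
    mean_age_shift = sum(ages * dens_z) / sum(dens_z) -
      sum(ages * dens_n) / sum(dens_n),
    freq_ratio = (sum(dens_z) / sum(tot)) / (sum(dens_n) / sum(tot)),
    density = tibble(age = ages, dens_z = dens_z, dens_neutral = dens_n),
    curve_type = curve$type
  )
}

#' @importFrom stats approx
NULL
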