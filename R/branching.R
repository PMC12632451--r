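#' Birth-death model of a mutation's trajectory in somatic evolution
#'
#' A normal tissue holds a constant pool of `N0` wild-type cells; cells
#' acquire mutation z at per-cell rate `v`, and mutant cells divide at rate
#' `a1` and are lost at rate `b1`, so the mutant count follows a birth-death
#' process with immigration (transitions \eqn{i \to i+1} at rate
#' \eqn{N_0 v + i a_1} and \eqn{i \to i-1} at rate \eqn{i b_1}). The
#' mutation's selective effect in normal tissue is `s = a1 - b1`. Cancer
#' initiation occurs at per-cell hazard `r0(t)` for wild-type cells and
#' `r1(t) = w * r0(t)` for mutant cells; `w` is the carcinogenic effect.
#'
#' @param N0 Wild-type pool size (cells).
#' @param v Per-cell mutation acquisition rate (1/year).
#' @param a1,b1 Division and loss rates of mutant cells (1/year).
#' @param w Carcinogenic effect (dimensionless, > 0).
#' @param hazard Baseline hazard, from [bp_hazard_constant()] or
#'   [bp_hazard_power()].
#' @param lifespan Maximum age considered (years).
#' @return An object of class `bp_model`.
#' @examples
#' m <- bp_model(N0 = 1e5, v = 1e-8, a1 = 1.1, b1 = 1, w = 10,
#'               hazard = bp_hazard_power(u = -14.5))
#' m$s
#' @export
bp_model <- function(N0 = 1e5, v = 1e-8, a1 = 1, b1 = 1, w = 1,
                     hazard = bp_hazard_power(u = -14.5), lifespan = 80) {
  stopifnot(N0 > 0, v >= 0, a1 >= 0, b1 >= 0, w > 0, lifespan > 0)
  structure(list(N0 = N0, v = v, a1 = a1, b1 = b1, s = a1 - b1, w = w,
                 hazard = hazard, lifespan = lifespan),
            class = "bp_model")
}

#' Baseline carcinogenesis hazards
#'
#' `bp_hazard_constant()` is a constant per-cell hazard. `bp_hazard_power()`
#' is the power-law hazard \eqn{r_0(t) = 10^u t^p} (default exponent 3),
#' caricaturing cancer risk rising with age; when `u` is `NULL` the hazard
#' represents a population mixture with `u` uniform on `u_range` (default
#' (-16, -13)), integrated deterministically by midpoint quadrature where it
#' is used.
#'
#' @param rate Constant hazard (1/cell/year).
#' @param u Log10 coefficient for a single person; `NULL` for the mixture.
#' @param exponent Power-law exponent `p`.
#' @param u_range Mixture support for `u`.
#' @return A list describing the hazard, class `bp_hazard`.
#' @export
bp_hazard_constant <- function(rate) {
  stopifnot(rate >= 0)
  structure(list(form = "constant", coef = rate, exponent = 0,
                 u_range = NULL), class = "bp_hazard")
}

#' @rdname bp_hazard_constant
#' @export
bp_hazard_power <- function(u = NULL, exponent = 3, u_range = c(-16, -13)) {
  structure(list(form = "power_law", coef = if (is.null(u)) NULL else 10^u,
                 exponent = exponent, u_range = if (is.null(u)) u_range),
            class = "bp_hazard")
}

hazard_is_mixture <- function(h) is.null(h$coef)

# baseline hazard value(s) at times t for a concrete (non-mixture) hazard
r0_at <- function(hazard, t) {
  if (hazard_is_mixture(hazard)) {
    abort("hazard is a population mixture; fix u first",
          class = "carceff_domain_error")
  }
  hazard$coef * t^hazard$exponent
}

# cumulative baseline hazard integral from 0 to t
r0_cum <- function(hazard, t) {
  p <- hazard$exponent
  hazard$coef * t^(p + 1) / (p + 1)
}

# midpoint quadrature nodes over the mixture parameter u
mixture_nodes <- function(hazard, n_u = 64) {
  if (!hazard_is_mixture(hazard)) {
    return(list(coefs = hazard$coef, weights = 1))
  }
  lo <- hazard$u_range[1]
  hi <- hazard$u_range[2]
  u <- lo + (seq_len(n_u) - 0.5) / n_u * (hi - lo)
  list(coefs = 10^u, weights = rep(1 / n_u, n_u))
}

#' Solve the backward Kolmogorov equations for the no-cancer probabilities
#'
#' Let \eqn{p_k(t, T)} be the probability of no mutant-z cancer in `(t, T)`
#' given `k` mutant cells at `t`. The backward system
#' \deqn{\partial p_0/\partial t = N_0 v (p_1 - p_0)}
#' \deqn{\partial p_1/\partial t = -(N_0 v + a_1 + b_1 + r_1) p_1 +
#'   (N_0 v + a_1) p_1^2 + b_1 p_0}
#' with \eqn{p_k(T, T) = 1}, together with its T-differentiated companion
#' system (boundary \eqn{\partial p_k/\partial T|_{T \downarrow t} = -k
#' r_1(t)}), is integrated by the explicit Euler method from `T` back to 0.
#' An instability (any probability leaving \[0, 1\] beyond tolerance) raises
#' an error advising a smaller `dt`.
#'
#' @param model A [bp_model()] with a concrete (non-mixture) hazard.
#' @param T Horizon age (years); defaults to the model lifespan.
#' @param dt Euler step (years).
#' @param keep_path Keep the full time path (tibble) or only the `t = 0`
#'   values.
#' @return An object of class `bp_solution`: list with `p0`, `p1`, `dp0`,
#'   `dp1` at `t = 0`, the horizon `T`, step `dt`, the `model`, and (if
#'   requested) `path`, a tibble over the age grid.
#' @export
solve_backward <- function(model, T = model$lifespan, dt = 5e-4,
                           keep_path = FALSE) {
  stopifnot(inherits(model, "bp_model"), dt > 0, T > 0)
  nsteps <- ceiling(T / dt - 1e-9)
  h <- T / nsteps
  tgrid <- seq(0, T, length.out = nsteps + 1)
  r1 <- model$w * r0_at(model$hazard, tgrid)
  sol <- bp_solve_cpp(h, model$N0 * model$v, model$a1, model$b1, r1,
                      keep_path)
  if (!sol$ok) {
    abort("Euler integration unstable: probabilities left [0, 1]; use a smaller dt",
          class = "carceff_step_size_error")
  }
  out <- list(p0 = sol$p0, p1 = sol$p1, dp0 = sol$q0, dp1 = sol$q1,
              T = T, dt = h, model = model)
  if (keep_path) {
    out$path <- tibble(t = tgrid, p0 = sol$path_p0, p1 = sol$path_p1,
                       dp0 = sol$path_q0, dp1 = sol$path_q1)
  }
  structure(out, class = "bp_solution")
}

#' @export
print.bp_solution <- function(x, ...) {
  cat(sprintf("<bp_solution> T = %g, dt = %g; p0(0,T) = %.6g, dp0 = %.4g\n",
              x$T, x$dt, x$p0, x$dp0))
  invisible(x)
}

#' Mutation odds in cancer and in normal tissue from the ODE solution
#'
#' Conditional on no mutant cells at birth and no cancer before `T`, the rate
#' of mutant-z cancer at age `T` is \eqn{-\partial_T p_0(0,T) / p_0(0,T)}
#' while wild-type cancer arises at rate \eqn{N_0 r_0(T)};
#' `cancer_mutation_odds()` is their ratio, the odds that a cancer at age `T`
#' carries the mutation. `normal_tissue_odds()` is the corresponding odds for
#' a normal tissue cell at age `T`,
#' \eqn{[-\partial_T p_0 / r_1(T)] / [N_0 p_0]}. Their ratio equals the
#' carcinogenic effect `w` exactly.
#'
#' @param sol A [solve_backward()] result.
#' @return A non-negative number.
#' @export
cancer_mutation_odds <- function(sol) {
  stopifnot(inherits(sol, "bp_solution"))
  if (sol$p0 <= 0) {
    abort("p0 underflow: hazard too large for this parameterization",
          class = "carceff_domain_error")
  }
  (-sol$dp0 / sol$p0) / (sol$model$N0 * r0_at(sol$model$hazard, sol$T))
}

#' @rdname cancer_mutation_odds
#' @export
normal_tissue_odds <- function(sol) {
  stopifnot(inherits(sol, "bp_solution"))
  if (sol$p0 <= 0) {
    abort("p0 underflow: hazard too large for this parameterization",
          class = "carceff_domain_error")
  }
  r1T <- sol$model$w * r0_at(sol$model$hazard, sol$T)
  (-sol$dp0 / r1T) / (sol$model$N0 * sol$p0)
}

#' Euler step self-check
#'
#' Re-solves with a halved step and reports the relative change in
#' `p0`, `dp0` (Richardson-style convergence diagnostic).
#'
#' @inheritParams solve_backward
#' @return Named numeric: relative changes for `p0` and `dp0`.
#' @export
check_euler_step <- function(model, T = model$lifespan, dt = 5e-4) {
  s1 <- solve_backward(model, T, dt)
  s2 <- solve_backward(model, T, dt / 2)
  c(p0 = abs(s2$p0 - s1$p0) / max(abs(s2$p0), 1e-300),
    dp0 = abs(s2$dp0 - s1$dp0) / max(abs(s2$dp0), 1e-300))
}

#' Exact stochastic simulation of mutant trajectories with carcinogenesis
#'
#' Gillespie-style simulation of the birth-death-immigration process,
#' including cancer initiation at hazard \eqn{(N_0 + w N_1(t)) r_0(t)}; when
#' cancer strikes, the founder is attributed to a mutant cell with
#' probability \eqn{w N_1 / (N_0 + w N_1)}. Inter-event carcinogenesis times
#' are drawn exactly from the closed-form cumulative hazard, so there is no
#' discretisation error. Intended as the Monte Carlo oracle for the ODE
#' solution at reduced scale (small `N0`, inflated `v`).
#'
#' @param model A [bp_model()] with a concrete hazard.
#' @param n Number of independent trajectories.
#' @param seed RNG seed.
#' @param T Horizon (defaults to model lifespan).
#' @return A tibble with one row per trajectory: `n1_end` (mutant count at
#'   the end, i.e. at cancer or at `T`), `t_cancer` (`NA` if none),
#'   `founder_mutant` (1/0/`NA`).
#' @export
simulate_trajectories <- function(model, n, seed = NULL, T = model$lifespan) {
  stopifnot(inherits(model, "bp_model"), n >= 1)
  h <- model$hazard
  if (hazard_is_mixture(h)) {
    abort("hazard is a population mixture; fix u first",
          class = "carceff_domain_error")
  }
  df <- with_seed(seed, {
    bp_simulate_cpp(as.integer(n), T, model$N0, model$v, model$a1,
                    model$b1, model$w, h$coef, h$exponent)
  })
  as_tibble(df)
}
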