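#' Hybrid Beta regression for carcinogenic effects with age adjustment
#'
#' Jointly models, per gene, (i) presence of the gene's mutations in cancer
#' samples and (ii) observed mutant cell fractions in normal-tissue samples,
#' sharing a logit-linear age trend. A cancer sample of age `t` is mutated
#' with probability \eqn{w / (w + e^{a + b t})}, where
#' \eqn{1/(1 + e^{a + b t})} is the expected mutant cell fraction in normal
#' tissue at that age and `w > 0` is the carcinogenic effect. The true cell
#' fraction in a normal sample follows a Beta distribution with shape
#' parameters \eqn{e^{\phi}/(1 + e^{a+bt})} and
#' \eqn{e^{\phi + a + bt}/(1 + e^{a+bt})} (mean \eqn{1/(1+e^{a+bt})},
#' precision \eqn{e^\phi}); the observed fraction is \eqn{X \cdot 1\{X \ge
#' x_0\}} for detection floor `x0`, so sub-floor samples are observed as
#' zero and contribute the Beta CDF at `x0` to the likelihood while detected
#' samples contribute the Beta density. The four parameters
#' \eqn{(a, b, \phi, w)} are estimated by joint maximum likelihood with
#' multi-start quasi-Newton optimisation on \eqn{(a, b, \phi, \log w)}.
#'
#' @param cancer_presence Data frame with columns `age` and `mutated` (0/1).
#' @param normal_fractions Data frame with columns `age` and `fraction`
#'   (observed mutant cell fraction; 0 = below the detection floor).
#' @param x0 Detection floor in (0, 1). Defaults to the smallest positive
#'   observed fraction.
#' @param init Optional numeric vector `c(a, b, phi, w)` of starting values.
#' @param n_starts Number of optimiser starts (jittered around a moment
#'   initialiser).
#' @param seed RNG seed for the start jitter.
#' @param conf Confidence level for the Wald interval on `log w`.
#' @return An object of class `hybrid_beta_fit` with elements `par`
#'   (named `a`, `b`, `phi`, `w`), `loglik`, `vcov` (on the internal scale
#'   with `log w`), `ci_w`, `converged`, `n_cancer`, `n_normal`, `x0`.
#'   Supports [tidy()] and [glance()].
#' @export
fit_hybrid_beta <- function(cancer_presence, normal_fractions, x0 = NULL,
                            init = NULL, n_starts = 5, seed = NULL,
                            conf = 0.95) {
  ct <- as.numeric(cancer_presence$age)
  cy <- as.numeric(cancer_presence$mutated)
  nt <- as.numeric(normal_fractions$age)
  nx <- as.numeric(normal_fractions$fraction)
  if (any(nx < 0 | nx >= 1)) {
    abort("normal fractions must lie in [0, 1)", class = "carceff_domain_error")
  }
  if (is.null(x0)) {
    pos <- nx[nx > 0]
    x0 <- if (length(pos) > 0) min(pos) else 1e-4
  }
  detected <- nx >= x0 & nx > 0

  negll <- function(theta) {
    a <- theta[1]; b <- theta[2]; phi <- theta[3]; lw <- theta[4]
    eta_c <- a + b * ct
    # log P(mutated) = lw - log(w + e^eta); stable via logsumexp
    m <- pmax(lw, eta_c)
    lse <- m + log(exp(lw - m) + exp(eta_c - m))
    ll_c <- sum(cy * (lw - lse) + (1 - cy) * (eta_c - lse))
    eta_n <- a + b * nt
    den <- 1 + exp(eta_n)
    s1 <- exp(phi) / den
    s2 <- exp(phi + eta_n) / den
    ll_n <- suppressWarnings(
      sum(pbeta(x0, s1[!detected], s2[!detected], log.p = TRUE)) +
        sum(dbeta(nx[detected], s1[detected], s2[detected], log = TRUE))
    )
    ll <- ll_c + ll_n
    if (!is.finite(ll)) 1e10 else -ll
  }

  # moment-based initialiser
  xbar <- mean(nx[detected])
  if (!is.finite(xbar) || xbar <= 0) xbar <- x0
  a0 <- qlogis(1 - min(max(xbar, 1e-6), 0.5))
  w0 <- max(odds_ratio(min(max(mean(cy), 1e-4), 1 - 1e-4),
                       min(max(mean(pmax(nx, 0)), 1e-6), 0.5)), 1e-3)
  base <- if (!is.null(init)) {
    c(init[1], init[2], init[3], log(init[4]))
  } else {
    c(a0, 0, log(50), log(w0))
  }

  fits <- with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(i) {
      if (i == 1) base else base + rnorm(4, 0, c(1, 0.02, 0.5, 1))
    })
    lapply(starts, function(st) {
      tryCatch(
        optim(st, negll, method = "BFGS",
              control = list(maxit = 500), hessian = FALSE),
        error = function(e) NULL
      )
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort("hybrid Beta optimisation failed from all starts",
          class = "carceff_nonconvergence")
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  converged <- best$convergence == 0
  theta <- best$par
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  z <- qnorm(1 - (1 - conf) / 2)
  ci_w <- if (!is.null(vc) && all(is.finite(diag(vc))) && vc[4, 4] > 0) {
    exp(theta[4] + c(-1, 1) * z * sqrt(vc[4, 4]))
  } else {
    c(NA_real_, NA_real_)
  }
  out <- structure(list(
    par = c(a = theta[1], b = theta[2], phi = theta[3], w = exp(theta[4])),
    loglik = -best$value,
    vcov = vc,
    ci_w = ci_w,
    converged = converged,
    n_cancer = length(cy), n_normal = length(nx), x0 = x0
  ), class = "hybrid_beta_fit")
  if (!converged) {
    abort("hybrid Beta fit did not converge within the iteration limit",
          class = "carceff_nonconvergence", fit = out)
  }
  out
}

#' @importFrom stats optimHess
#' @export
print.hybrid_beta_fit <- function(x, ...) {
  cat("<hybrid_beta_fit>\n")
  cat(sprintf("  w = %.4g [%.4g, %.4g]\n", x$par[["w"]], x$ci_w[1], x$ci_w[2]))
  cat(sprintf("  a = %.3f, b = %.4f, phi = %.3f; loglik = %.2f\n",
              x$par[["a"]], x$par[["b"]], x$par[["phi"]], x$loglik))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hybrid_beta_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, 4)
  tibble(
    term = c("a", "b", "phi", "log_w"),
    estimate = c(x$par[["a"]], x$par[["b"]], x$par[["phi"]],
                 log(x$par[["w"]])),
    std.error = se
  )
}

#' @exportS3Method generics::glance
glance.hybrid_beta_fit <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged,
         nobs = x$n_cancer + x$n_normal, w = x$par[["w"]],
         ci_low = x$ci_w[1], ci_high = x$ci_w[2])
}
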