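#' Logistic regression for carcinogenic effects with age and burden covariates
#'
#' Models a gene's probability of being mutated in a sample as
#' \eqn{w^{\chi} / (w^{\chi} + e^{a + b t + c m})}, where `t` is age, `m` the
#' exonic mutation burden and \eqn{\chi \in \{0, 1\}} indicates a cancer
#' sample versus a normal-tissue sample. Equivalently
#' \eqn{\mathrm{logit}\,p = \chi \log w - (a + b t + c m)}, an ordinary
#' logistic regression in which the group coefficient is \eqn{\log w}; the
#' MLE is computed with [stats::glm()] and the 95% profile-likelihood
#' interval for `w` by bisection on the deviance (each endpoint satisfies a
#' log-likelihood drop of \eqn{\chi^2_1(conf)/2}).
#'
#' @param samples Data frame with columns `age`, `burden`, `group` (0 =
#'   normal, 1 = cancer) and `mutated` (0/1).
#' @param conf Confidence level for the profile interval.
#' @return An object of class `logistic_effect_fit` with elements `par`
#'   (named `a`, `b`, `c`, `w`), `ci_w`, `loglik`, `separation` (logical flag
#'   for boundary estimates), and the underlying `glm` fit. Supports
#'   [tidy()] and [glance()].
#' @export
fit_logistic_effect <- function(samples, conf = 0.95) {
  d <- as_tibble(samples)
  stopifnot(all(c("age", "burden", "group", "mutated") %in% names(d)))
  if (length(unique(d$group)) < 2) {
    abort("both groups (cancer and normal) must be represented",
          class = "carceff_domain_error")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(mutated ~ age + burden + group, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  be <- coef(fit)
  lw_hat <- unname(be[["group"]])
  separation <- sep_warn || abs(lw_hat) > 15

  # profile deviance for log w: refit with fixed offset group * lw
  dev_at <- function(lw) {
    f <- suppressWarnings(
      glm(mutated ~ age + burden, family = binomial(), data = d,
          offset = lw * d$group)
    )
    f$deviance
  }
  target <- fit$deviance + qchisq(conf, df = 1)
  find_edge <- function(dir) {
    lo <- lw_hat
    step <- 0.25
    hi <- lw_hat + dir * step
    it <- 0
    while (dev_at(hi) < target && it < 80) {
      lo <- hi
      step <- step * 2
      hi <- lw_hat + dir * (abs(hi - lw_hat) + step)
      it <- it + 1
    }
    if (it >= 80) return(dir * Inf)
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (dev_at(mid) < target) lo <- mid else hi <- mid
      if (abs(hi - lo) < 1e-7) break
    }
    (lo + hi) / 2
  }
  ci_lw <- if (separation) c(-Inf, Inf) else c(find_edge(-1), find_edge(1))

  structure(list(
    par = c(a = -unname(be[["(Intercept)"]]), b = -unname(be[["age"]]),
            c = -unname(be[["burden"]]), w = exp(lw_hat)),
    ci_w = exp(ci_lw),
    loglik = as.numeric(stats::logLik(fit)),
    deviance = fit$deviance,
    conf = conf,
    separation = separation,
    glm_fit = fit
  ), class = "logistic_effect_fit")
}

#' @export
print.logistic_effect_fit <- function(x, ...) {
  cat("<logistic_effect_fit>\n")
  cat(sprintf("  w = %.4g [%.4g, %.4g]%s\n", x$par[["w"]], x$ci_w[1],
              x$ci_w[2], if (x$separation) " (separation)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logistic_effect_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "c", "log_w"),
    estimate = c(x$par[["a"]], x$par[["b"]], x$par[["c"]], log(x$par[["w"]])),
    std.error = c(NA_real_, NA_real_, NA_real_,
                  unname(summary(x$glm_fit)$coefficients["group",
                                                         "Std. Error"]))
  )
}

#' @exportS3Method generics::glance
glance.logistic_effect_fit <- function(x, ...) {
  tibble(logLik = x$loglik, deviance = x$deviance,
         separation = x$separation, w = x$par[["w"]],
         ci_low = x$ci_w[1], ci_high = x$ci_w[2])
}
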