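test_that("odds ratio matches hand evaluations and flags zero cells", {
  expect_equal(odds_ratio(0.5, 0.5), 1)
  expect_equal(odds_ratio(2 / 3, 1 / 3), 4)
  expect_equal(odds_ratio(0.05, 1.8e-4), 292.3450, tolerance = 1e-6)
  expect_identical(odds_ratio(0.1, 0), Inf)
  expect_identical(odds_ratio(0, 0.1), 0)
  expect_true(is.nan(odds_ratio(0, 0)))
  expect_error(odds_ratio(1.5, 0.5), class = "carceff_domain_error")
})

test_that("odds ratio reciprocal identity and monotonicity hold", {
  set.seed(5)
  y <- runif(100, 0.01, 0.99)
  x <- runif(100, 0.01, 0.99)
  expect_equal(odds_ratio(y, x) * odds_ratio(x, y), rep(1, 100))
  expect_true(all(diff(odds_ratio(seq(0.1, 0.9, 0.1), 0.3)) > 0))
  expect_true(all(diff(odds_ratio(0.3, seq(0.1, 0.9, 0.1))) < 0))
})

test_that("matched estimator recovers planted effects", {
  genes <- tibble::tibble(gene = c("Gneu", "Gmid", "Ghi"),
                          x = c(0.05, 0.02, 0.01), w = c(1, 10, 100))
  w_hats <- sapply(1:20, function(i) {
    syn <- synth_matched_cohort(genes, n_cancer = 2000, n_normal = 2000,
                                seed = 100 + i)
    estimate_matched(syn$cancer, syn$normal, genes$gene, B = 50,
                     seed = i)$w_hat
  })
  med <- apply(w_hats, 1, median)
  expect_lt(abs(med[1] - 1) / 1, 0.2)
  expect_lt(abs(med[2] - 10) / 10, 0.2)
  expect_lt(abs(med[3] - 100) / 100, 0.2)
})

test_that("matched estimator is deterministic and flags degenerate genes", {
  genes <- tibble::tibble(gene = "G1", x = 0.03, w = 5)
  syn <- synth_matched_cohort(genes, 300, 300, seed = 8)
  a <- estimate_matched(syn$cancer, syn$normal, c("G1", "ABSENT"), B = 100,
                        seed = 3)
  b <- estimate_matched(syn$cancer, syn$normal, c("G1", "ABSENT"), B = 100,
                        seed = 3)
  expect_identical(a, b)
  expect_equal(a$note[a$gene == "ABSENT"], "undefined")
  expect_true(is.nan(a$w_hat[a$gene == "ABSENT"]))
  expect_error(estimate_matched(syn$cancer, syn$normal, character(0)),
               class = "carceff_domain_error")
})

test_that("length benchmark evaluates the closed form and transforms CIs", {
  coh <- toy_cohort(rep(50, 10),
                    c(replicate(5, "G1", simplify = FALSE),
                      replicate(5, character(0), simplify = FALSE)))
  genes <- tibble::tibble(gene = c("G1", "G0"), coding_length = c(1000, 500))
  est <- estimate_length_benchmark(coh, genes)
  expect_equal(est$w_hat[1], (0.5 / 0.5) / 1000) # 1e-3 per bp
  expect_equal(est$w_hat[2], 0)
  # CI endpoints are the binomial CI endpoints pushed through f/(1-f)/L
  bt <- binom.test(5, 10)$conf.int
  expect_equal(est$ci_low[1], (bt[1] / (1 - bt[1])) / 1000)
  expect_equal(est$ci_high[1], (bt[2] / (1 - bt[2])) / 1000)
  expect_error(
    estimate_length_benchmark(coh, tibble::tibble(gene = "G1",
                                                  coding_length = 0)),
    class = "carceff_domain_error"
  )
})

test_that("hybrid Beta regression recovers the generating parameters", {
  gen <- function(seed, n = 2000, a = 4, b = 0.02, phi = log(50), w = 50,
                  x0 = 0.002) {
    withr::with_seed(seed, {
      tc <- runif(n, 36, 90)
      tn <- runif(n, 36, 90)
      eta <- a + b * tn
      X <- rbeta(n, exp(phi) / (1 + exp(eta)),
                 exp(phi + eta) / (1 + exp(eta)))
      list(cancer = data.frame(age = tc,
                               mutated = rbinom(n, 1, w / (w + exp(a + b * tc)))),
           normal = data.frame(age = tn,
                               fraction = ifelse(X >= x0, X, 0)))
    })
  }
  errs <- vapply(1:5, function(i) {
    d <- gen(400 + i)
    fit <- fit_hybrid_beta(d$cancer, d$normal, x0 = 0.002, seed = i,
                           n_starts = 3)
    abs(fit$par[["w"]] - 50) / 50
  }, numeric(1))
  expect_lt(median(errs), 0.25)
})

test_that("hybrid Beta and matched odds ratio agree in rank order", {
  set.seed(77)
  genes <- tibble::tibble(gene = paste0("G", 1:10),
                          x = runif(10, 0.005, 0.05),
                          w = 10^runif(10, 0, 2))
  syn <- synth_matched_cohort(genes, 1500, 1500, seed = 13)
  est <- estimate_matched(syn$cancer, syn$normal, genes$gene, B = 50,
                          seed = 1)
  ages_c <- syn$cancer$samples$age
  w_hb <- vapply(genes$gene, function(g) {
    pres <- carceff:::qualifying_presence(syn$cancer, g,
                                          c("nonsynonymous_snv", "indel"))
    fr <- carceff:::sample_gene_fractions(syn$normal, g,
                                          c("nonsynonymous_snv", "indel"))
    fit <- fit_hybrid_beta(
      data.frame(age = ages_c, mutated = as.numeric(pres[, 1])),
      data.frame(age = syn$normal$samples$age, fraction = fr$fraction),
      x0 = 1e-4, seed = 2, n_starts = 3
    )
    fit$par[["w"]]
  }, numeric(1))
  expect_gt(cor(w_hb, est$w_hat, method = "spearman"), 0.9)
})

test_that("logistic effect model is null-calibrated and profiles correctly", {
  withr::with_seed(31, {
    n <- 1500
    t <- runif(2 * n, 20, 90)
    m <- rpois(2 * n, 10 + 0.3 * t)
    chi <- rep(c(0, 1), each = n)
    p <- 1 / (1 + exp(1 + 0.01 * t + 0.005 * m)) # w = 1
    d <- data.frame(age = t, burden = m, group = chi,
                    mutated = rbinom(2 * n, 1, p))
  })
  fit <- fit_logistic_effect(d)
  expect_lt(abs(log(fit$par[["w"]])), 0.5)
  expect_true(fit$ci_w[1] <= 1 && fit$ci_w[2] >= 1)
  # definitional check: deviance rises by qchisq(.95, 1) at both endpoints
  dev_at <- function(lw) {
    suppressWarnings(glm(mutated ~ age + burden, binomial, data = d,
                         offset = lw * d$group))$deviance
  }
  drop <- c(dev_at(log(fit$ci_w[1])), dev_at(log(fit$ci_w[2]))) -
    fit$deviance
  expect_equal(drop, rep(qchisq(0.95, 1), 2), tolerance = 1e-4)
})

test_that("logistic effect flags complete separation", {
  d <- data.frame(age = rep(50, 40), burden = 10,
                  group = rep(c(0, 1), each = 20),
                  mutated = rep(c(0, 1), each = 20))
  fit <- fit_logistic_effect(d)
  expect_true(fit$separation)
  expect_equal(fit$ci_w, c(0, Inf))
})

test_that("tidy and glance methods return the documented shapes", {
  withr::with_seed(5, {
    d <- data.frame(age = runif(400, 20, 80), burden = rpois(400, 20),
                    group = rep(c(0, 1), each = 200),
                    mutated = rbinom(400, 1, 0.3))
  })
  fit <- fit_logistic_effect(d)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("a", "b", "c", "log_w"))
  gl <- generics::glance(fit)
  expect_true(all(c("w", "ci_low", "ci_high") %in% names(gl)))
})
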