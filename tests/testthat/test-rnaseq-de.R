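# Poisson mixed-model DE stage: filtering, RPKM, model fitting against
# closed forms and numeric-integration oracles, LRT, q-values, calling.

test_that("low-count filter keeps exactly genes with total >= threshold", {
  m <- rbind(g0 = rep(0L, 4), g9 = c(3L, 3L, 2L, 1L),
             g10 = c(3L, 3L, 2L, 2L))
  colnames(m) <- paste0("s", 1:4)
  kept <- filter_low_counts(m)
  expect_identical(rownames(kept), "g10")
  expect_identical(nrow(filter_low_counts(m * 0L)), 0L)
  expect_error(filter_low_counts(matrix(numeric(0), 0, 0)),
               class = "rootheat_validation_error")
})

test_that("RPKM follows count * 1e9 / (libsize * length)", {
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(100, 1000, 1e6), 100)
  expect_equal(compute_rpkm(10, 500, 2e7), 1)
  expect_error(compute_rpkm(1, 0, 1e6), class = "rootheat_validation_error")
  expect_error(compute_rpkm(1, 100, 0), class = "rootheat_validation_error")
})

test_that("fixed-effect fit matches the Poisson GLM closed form", {
  design <- toy_design()
  fit <- fit_gene_glmm(c(2, 2, 4, 4), design, random = character(0))
  expect_equal(fit$beta_trt, log(2), tolerance = 1e-8)
  expect_equal(fit$sigma2_rep, 0)
  expect_equal(fit$sigma2_plate, 0)

  flat <- fit_gene_glmm(c(5, 5, 5, 5), design, random = character(0))
  expect_equal(flat$beta_trt, 0, tolerance = 1e-8)

  expect_error(fit_gene_glmm(c(1.5, 2, 3, 4), design),
               class = "rootheat_validation_error")
  expect_error(fit_gene_glmm(c(-1, 2, 3, 4), design),
               class = "rootheat_validation_error")
})

test_that("marginal likelihood matches brute-force integration", {
  # random tiny instances, one grouping factor, evaluated (not fitted)
  # at random parameter values; quadrature must agree to 1e-4
  set.seed(42)
  design6 <- tibble::tibble(
    sample = paste0("s", 1:6), tissue = "RH",
    treatment = rep(c("control_25C", "heat_40C"), each = 3),
    time_h = 3, replicate = rep(c("r1", "r2", "r3"), 2),
    plate = "p1", libsize = 1e6)
  for (i in 1:25) {
    mu <- runif(1, 3, 80)
    y <- rpois(6, mu)
    b0 <- log(mu / 1e6) + rnorm(1, 0, 0.2)
    bt <- rnorm(1, 0, 0.5)
    s <- runif(1, 0.05, 0.6)
    ll <- glmm_loglik(y, design6, beta0 = b0, beta_trt = bt, sd_rep = s,
                      method = "agq")
    heat <- as.numeric(design6$treatment == "heat_40C")
    oracle <- integrate_loglik(y, b0 + bt * heat + log(design6$libsize),
                               design6$replicate, s)
    expect_equal(ll, oracle, tolerance = 1e-4)
  }
})

test_that("fitted likelihood agrees with integration and with lme4", {
  skip_if_not_installed("lme4")
  design <- toy_design()
  set.seed(7)
  y <- rpois(4, 40)
  fit <- fit_gene_glmm(y, design, random = "replicate", method = "agq")
  # same parameters through the independent integration oracle; a
  # boundary variance of zero reduces to the plain Poisson likelihood
  heat <- as.numeric(design$treatment == "heat_40C")
  eta0 <- fit$beta0 + fit$beta_trt * heat + log(design$libsize)
  oracle <- if (fit$sigma2_rep == 0)
    sum(dpois(y, exp(eta0), log = TRUE))
  else integrate_loglik(y, eta0, design$replicate, sqrt(fit$sigma2_rep))
  expect_equal(fit$loglik, oracle, tolerance = 1e-4)
  # lme4 with adaptive quadrature as an independent fitter; glmer
  # reports the log-likelihood relative to the saturated model
  lfit <- suppressMessages(
    lme4::glmer(y ~ heat + (1 | replicate),
                data = cbind(design, y = y, heat = heat),
                family = poisson, offset = log(design$libsize),
                nAGQ = 15))
  expect_equal(fit$loglik,
               as.numeric(stats::logLik(lfit)) +
                 sum(dpois(y, y, log = TRUE)),
               tolerance = 1e-3)
  expect_equal(fit$beta_trt, unname(lme4::fixef(lfit)[2]), tolerance = 1e-2)

  # a strong replicate effect keeps the variance off the boundary
  y2 <- c(10, 100, 12, 110)
  fit2 <- fit_gene_glmm(y2, design, random = "replicate", method = "agq")
  expect_gt(fit2$sigma2_rep, 0.1)
  lfit2 <- suppressMessages(
    lme4::glmer(y2 ~ heat + (1 | replicate),
                data = cbind(design, y2 = y2, heat = heat),
                family = poisson, offset = log(design$libsize),
                nAGQ = 15))
  expect_equal(fit2$loglik,
               as.numeric(stats::logLik(lfit2)) +
                 sum(dpois(y2, y2, log = TRUE)),
               tolerance = 1e-3)
})

test_that("likelihood-ratio test follows the chi-square(1) reference", {
  design <- toy_design()
  y <- c(10, 12, 30, 28)
  full <- fit_gene_glmm(y, design)
  red <- fit_gene_glmm(y, design, include_treatment = FALSE)
  lrt <- lrt_test(full, red)
  expect_gte(lrt$lrt_stat, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$lrt_stat, 1, lower.tail = FALSE))
  # equal log-likelihoods give stat 0, p 1; numeric noise is clamped
  f2 <- full; f2$loglik <- red$loglik
  expect_equal(lrt_test(f2, red), list(lrt_stat = 0, p_value = 1))
  f3 <- full; f3$loglik <- red$loglik - 1e-9
  expect_equal(lrt_test(f3, red)$lrt_stat, 0)
  # stat 3.841459 sits at the 5% point of chi-square(1)
  f4 <- full; f4$loglik <- red$loglik + 3.841459 / 2
  expect_equal(lrt_test(f4, red)$p_value, 0.05, tolerance = 1e-6)
  # mismatched models rejected
  expect_error(lrt_test(red, full), class = "rootheat_validation_error")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  q <- storey_qvalues(c(0.001, 0.01, 0.5, 0.9), pi0 = 1)
  expect_equal(q, c(0.004, 0.02, 2 / 3, 0.9), tolerance = 1e-12)
  expect_equal(storey_qvalues(1), 1)
  expect_equal(storey_qvalues(rep(0.3, 5)), rep(0.3, 5))
  expect_error(storey_qvalues(numeric(0)),
               class = "rootheat_validation_error")
  expect_error(storey_qvalues(c(0.5, 1.2)),
               class = "rootheat_validation_error")
})

test_that("q-values are monotone in p and bounded by 1", {
  set.seed(1)
  p <- c(runif(300), runif(100, 0, 0.01))
  q <- storey_qvalues(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("the calling rule needs both FDR 1% and two-fold change", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    q_value = c(0.005, 0.005, 0.02),
    log2_fc = c(log2(2.5), log2(1.5), 2))
  out <- call_de(res)
  expect_equal(out$called, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", "none", "none"))
  down <- call_de(tibble::tibble(gene_id = "d", q_value = 0.001,
                                 log2_fc = -3))
  expect_equal(down$direction, "down")
})

test_that("detection rate increases with planted effect size", {
  power_at <- function(effect) {
    cfg <- sim_config(n_genes = 300, de_fraction = 0.2,
                      effect_log_fc = effect, tissues = "RH",
                      timepoints = 3, seed = 77)
    rna <- gen_rnaseq_counts(cfg)
    res <- run_de(rna$counts, rna$design)
    mean(rna$truth$de_genes$gene_id %in% res$gene_id[res$called])
  }
  pw <- vapply(c(log(1.5), log(2), log(4)), power_at, numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], 0.8)
})
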