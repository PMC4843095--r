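# Per-gene Poisson log-linear mixed model:
#   log E[y] = beta0 + beta_trt * heat + log(libsize) + u_replicate + u_plate
# with independent Normal random intercepts. The marginal likelihood is
# evaluated in compiled code by a Laplace approximation over the joint
# random-effect vector, or by adaptive Gauss-Hermite quadrature (15 nodes
# by default) when a single grouping factor is active.

#' Evaluate the marginal log-likelihood of the per-gene Poisson GLMM
#'
#' Computes the marginal Poisson mixed-model log-likelihood at given
#' parameter values (no fitting). Exposed so the integration method can
#' be checked against independent numeric integration.
#'
#' @param y nonnegative integer counts, one per sample.
#' @param design data frame with columns `treatment`, `replicate`,
#'   `plate`, `libsize` (rows matching `y`).
#' @param beta0 intercept (natural-log scale).
#' @param beta_trt treatment effect; use `NULL` to omit the term.
#' @param sd_rep,sd_plate random-intercept SDs; 0 removes a term.
#' @param method `"laplace"` or `"agq"` (adaptive Gauss-Hermite; valid
#'   when exactly one random term is active, otherwise falls back to
#'   Laplace).
#' @param nagq number of quadrature nodes for `"agq"`.
#' @return marginal log-likelihood (scalar).
#' @export
glmm_loglik <- function(y, design, beta0, beta_trt = NULL, sd_rep = 0,
                        sd_plate = 0, method = c("agq", "laplace"),
                        nagq = 15L) {
  method <- match.arg(method)
  d <- prepare_glmm_data(y, design, include_treatment = !is.null(beta_trt))
  par <- c(beta0, beta_trt, sd_rep, sd_plate)
  gh <- gh_rule(nagq)
  cpp_glmm_loglik(par, d$y, d$X, d$offset, d$rep_idx, d$plate_idx,
                  if (method == "agq") 1L else 0L, gh$x, gh$w)
}

prepare_glmm_data <- function(y, design, include_treatment) {
  assert_that(is.numeric(y) && all(is.finite(y)) && all(y >= 0) &&
                all(y == round(y)),
              "counts must be nonnegative integers")
  assert_that(nrow(design) == length(y),
              "design rows must match the count vector")
  needed <- c("treatment", "replicate", "plate", "libsize")
  assert_that(all(needed %in% names(design)),
              paste("design must contain columns:",
                    paste(needed, collapse = ", ")))
  assert_that(all(design$libsize > 0), "library sizes must be positive")
  heat <- as.numeric(design$treatment == "heat_40C")
  if (include_treatment) {
    assert_that(sum(heat == 1) >= 2 && sum(heat == 0) >= 2,
                "need >= 2 samples per treatment group")
    X <- cbind(1, heat)
  } else {
    X <- cbind(rep(1, length(y)))
  }
  list(y = as.numeric(y), X = X, offset = log(design$libsize),
       rep_idx = as.integer(factor(design$replicate)) - 1L,
       plate_idx = as.integer(factor(design$plate)) - 1L,
       heat = heat)
}

#' Fit the per-gene Poisson mixed model
#'
#' Maximizes the marginal Poisson likelihood with log link, library-size
#' offset, an optional treatment fixed effect, and independent Normal
#' random intercepts for biological replicate and plate. Variance
#' estimates may sit on the boundary at 0.
#'
#' @inheritParams glmm_loglik
#' @param include_treatment include the heat-vs-control fixed effect?
#' @param random character subset of `c("replicate", "plate")` naming the
#'   random intercepts to include.
#' @param maxit iteration cap for the outer optimizer.
#' @return an object of class `glmm_fit`: list with `beta0`, `beta_trt`
#'   (NA when excluded), `sigma2_rep`, `sigma2_plate`, `loglik`,
#'   `converged`, `method`, `n_obs`.
#' @export
#' @examples
#' design <- tibble::tibble(
#'   treatment = rep(c("control_25C", "heat_40C"), each = 2),
#'   replicate = c("r1", "r2", "r1", "r2"),
#'   plate = c("p1", "p2", "p2", "p1"),
#'   libsize = rep(1e6, 4))
#' fit <- fit_gene_glmm(c(2, 2, 4, 4), design, random = character(0))
#' fit$beta_trt  # log 2
fit_gene_glmm <- function(y, design, include_treatment = TRUE,
                          random = c("replicate", "plate"),
                          method = c("laplace", "agq"), nagq = 15L,
                          maxit = 200L) {
  method <- match.arg(method)
  if (length(random)) random <- match.arg(random, several.ok = TRUE)
  d <- prepare_glmm_data(y, design, include_treatment)
  fit_glmm_core(d, include_treatment,
                use_rep = "replicate" %in% random,
                use_plate = "plate" %in% random,
                method = method, nagq = nagq, maxit = maxit)
}

# fast path shared with run_de(); `d` as from prepare_glmm_data()
fit_glmm_core <- function(d, include_treatment, use_rep, use_plate,
                          method = "laplace", nagq = 15L, maxit = 200L) {
  gh <- gh_rule(nagq)
  meth <- if (method == "agq") 1L else 0L

  # closed-form Poisson GLM start (exact MLE when no random terms)
  e_off <- exp(d$offset)
  if (include_treatment) {
    s0 <- max(sum(d$y[d$heat == 0]), 0.5)
    s1 <- max(sum(d$y[d$heat == 1]), 0.5)
    b0 <- log(s0 / sum(e_off[d$heat == 0]))
    bt <- log(s1 / sum(e_off[d$heat == 1])) - b0
    beta <- c(b0, bt)
  } else {
    beta <- log(max(sum(d$y), 0.5) / sum(e_off))
  }

  p <- length(beta)
  if (!use_rep && !use_plate) {
    par <- c(beta, 0, 0)
    ll <- cpp_glmm_loglik(par, d$y, d$X, d$offset, d$rep_idx, d$plate_idx,
                          meth, gh$x, gh$w)
    return(new_glmm_fit(beta, 0, 0, ll, TRUE, include_treatment, method,
                        length(d$y)))
  }

  active <- c(use_rep, use_plate)
  start <- c(beta, rep(0.1, sum(active)))
  obj <- function(par) {
    full <- numeric(p + 2)
    full[seq_len(p)] <- par[seq_len(p)]
    full[p + which(active)] <- pmax(par[-seq_len(p)], 0)
    -cpp_glmm_loglik(full, d$y, d$X, d$offset, d$rep_idx, d$plate_idx,
                     meth, gh$x, gh$w)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  if (opt$convergence != 0) {  # restart from the best point found
    opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-8))
    if (opt2$value <= opt$value) opt <- opt2
  }

  est <- opt$par
  sds <- numeric(2)
  sds[which(active)] <- pmax(est[-seq_len(p)], 0)
  new_glmm_fit(est[seq_len(p)], sds[1], sds[2], -opt$value,
               opt$convergence == 0, include_treatment, method, length(d$y))
}

new_glmm_fit <- function(beta, sd_rep, sd_plate, loglik, converged,
                         include_treatment, method, n_obs) {
  structure(list(beta0 = beta[1],
                 beta_trt = if (include_treatment) beta[2] else NA_real_,
                 sigma2_rep = sd_rep^2, sigma2_plate = sd_plate^2,
                 loglik = loglik, converged = converged,
                 include_treatment = include_treatment,
                 method = method, n_obs = n_obs),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson GLMM fit (", x$method, "): loglik ", format(x$loglik),
      if (!x$converged) " [not converged]", "\n", sep = "")
  cat("  beta0 =", format(x$beta0),
      if (x$include_treatment) paste(" beta_trt =", format(x$beta_trt)),
      "\n  sigma2_rep =", format(x$sigma2_rep),
      " sigma2_plate =", format(x$sigma2_plate), "\n")
  invisible(x)
}

#' Likelihood-ratio test for the treatment effect
#'
#' Compares the full model (with treatment) to the reduced model (without)
#' by `2 * (loglik_full - loglik_reduced)`, clamped at zero, against a
#' chi-square reference with 1 degree of freedom.
#'
#' @param full,reduced `glmm_fit` objects for the same gene and samples;
#'   `reduced` must be `full` without the treatment term.
#' @return list with `lrt_stat` and `p_value`.
#' @export
lrt_test <- function(full, reduced) {
  assert_that(inherits(full, "glmm_fit") && inherits(reduced, "glmm_fit"),
              "inputs must be glmm_fit objects")
  assert_that(full$include_treatment && !reduced$include_treatment,
              "full must include treatment; reduced must not")
  assert_that(full$n_obs == reduced$n_obs,
              "models were fitted on different numbers of observations")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(lrt_stat = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
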