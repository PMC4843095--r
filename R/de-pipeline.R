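#' Remove genes with low total counts
#'
#' Keeps exactly the genes whose row total across all samples is at least
#' `min_total` (default 10), preserving row order.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param min_total minimum row total to retain a gene.
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) > 0 && ncol(counts) > 0,
              "count matrix must be non-empty")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be nonnegative integers")
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count * 1e9 / (libsize * gene_length_bp)`.
#'
#' @param count nonnegative read count (vectorized).
#' @param gene_length_bp transcript length in base pairs (> 0).
#' @param libsize mapped library size (> 0).
#' @return numeric RPKM values.
#' @export
#' @examples
#' compute_rpkm(100, 1000, 1e6)  # 100
compute_rpkm <- function(count, gene_length_bp, libsize) {
  assert_that(all(count >= 0), "counts must be nonnegative")
  assert_that(all(gene_length_bp > 0), "gene length must be positive")
  assert_that(all(libsize > 0), "library size must be positive")
  count * 1e9 / (libsize * gene_length_bp)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the distribution of p-values
#' over a lambda grid (0 to 0.9 in steps of 0.05) with a cubic smoothing
#' spline, clips it to (0, 1], and converts p-values to monotone
#' q-values. Forcing `pi0 = 1` reduces to Benjamini-Hochberg.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param lambda grid of lambda values for pi0 estimation.
#' @param pi0 optional fixed pi0 overriding the estimate.
#' @return q-values, same length and order as `p_values`.
#' @export
#' @examples
#' storey_qvalues(c(0.001, 0.01, 0.5, 0.9), pi0 = 1)
storey_qvalues <- function(p_values, lambda = seq(0, 0.90, by = 0.05),
                           pi0 = NULL) {
  assert_that(length(p_values) >= 1, "empty p-value vector")
  assert_that(all(p_values >= 0 & p_values <= 1 & is.finite(p_values)),
              "p-values must lie in [0, 1]")
  m <- length(p_values)
  if (is.null(pi0)) pi0 <- estimate_pi0(p_values, lambda)
  pi0 <- min(max(pi0, 1e-8), 1)
  r <- rank(p_values, ties.method = "max")
  q <- pi0 * m * p_values / r
  o <- order(p_values, decreasing = TRUE)
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

# smoother method of pi0 estimation: pi0(lambda) = #{p > lambda}/(m(1-lambda)),
# cubic spline evaluated at the largest lambda
estimate_pi0 <- function(p, lambda) {
  m <- length(p)
  if (m < 20) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  if (inherits(fit, "try-error")) return(1)
  pi0 <- predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) 1 else min(pi0, 1)
}

#' Apply the differential-expression calling rule
#'
#' A gene is called differentially expressed when its q-value is at most
#' `q_threshold` (default 0.01, i.e. an estimated FDR of 1%) and its fold
#' change is at least `min_fold` (default 2, i.e. `|log2_fc| >= 1`).
#' Direction is the sign of the log2 fold change for called genes.
#'
#' @param results data frame with columns `q_value` and `log2_fc`.
#' @param q_threshold q-value cutoff.
#' @param min_fold minimum fold change (linear scale).
#' @return `results` with `called` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns set.
#' @export
call_de <- function(results, q_threshold = 0.01, min_fold = 2) {
  assert_that(all(c("q_value", "log2_fc") %in% names(results)),
              "results must contain q_value and log2_fc")
  called <- results$q_value <= q_threshold &
    abs(results$log2_fc) >= log2(min_fold)
  results$called <- called
  results$direction <- ifelse(!called, "none",
                              ifelse(results$log2_fc > 0, "up", "down"))
  results
}

#' Run the full gene-level differential-expression stage
#'
#' For every tissue x time combination with both temperature groups
#' present, fits the per-gene Poisson mixed model with and without the
#' treatment term, performs the likelihood-ratio test, converts p-values
#' to Storey q-values within the contrast, and applies the FDR-1% +
#' 2-fold calling rule.
#'
#' @param counts nonnegative integer matrix, genes x samples (already
#'   low-count filtered or not; see `min_total`).
#' @param design sample sheet with columns `sample`, `tissue`,
#'   `treatment`, `time_h`, `replicate`, `plate`, `libsize`.
#' @param q_threshold,min_fold calling thresholds, see [call_de()].
#' @param min_total low-count filter applied before testing.
#' @param method marginal-likelihood method, see [fit_gene_glmm()].
#' @param random random intercepts to include, see [fit_gene_glmm()].
#' @return tibble with one row per gene and contrast: `gene_id`,
#'   `tissue`, `time_h`, `lrt_stat`, `p_value`, `q_value`, `log2_fc`,
#'   `called`, `direction`, `converged`.
#' @export
run_de <- function(counts, design, q_threshold = 0.01, min_fold = 2,
                   min_total = 10, method = "laplace",
                   random = c("replicate", "plate")) {
  counts <- filter_low_counts(counts, min_total = min_total)
  assert_that(all(colnames(counts) %in% design$sample),
              "every count column needs a design row")
  design <- design[match(colnames(counts), design$sample), ]

  contrasts <- unique(design[, c("tissue", "time_h")])
  out <- list()
  for (i in seq_len(nrow(contrasts))) {
    sel <- design$tissue == contrasts$tissue[i] &
      design$time_h == contrasts$time_h[i]
    sub_design <- design[sel, ]
    if (length(unique(sub_design$treatment)) < 2) next
    if (min(table(sub_design$treatment)) < 2) next
    sub_counts <- counts[, sub_design$sample, drop = FALSE]
    res <- de_contrast(sub_counts, sub_design, method = method,
                       random = random)
    res$tissue <- contrasts$tissue[i]
    res$time_h <- contrasts$time_h[i]
    res$q_value <- storey_qvalues(res$p_value)
    out[[length(out) + 1]] <- res
  }
  assert_that(length(out) > 0,
              "no tissue x time contrast with both treatment groups")
  res <- do.call(rbind, out)
  res <- call_de(res, q_threshold = q_threshold, min_fold = min_fold)
  res[, c("gene_id", "tissue", "time_h", "lrt_stat", "p_value", "q_value",
          "log2_fc", "called", "direction", "converged")]
}

# per-gene full/reduced fits and LRT for one (tissue, time) contrast
de_contrast <- function(counts, design, method, random) {
  use_rep <- "replicate" %in% random
  use_plate <- "plate" %in% random
  n_genes <- nrow(counts)
  stat <- p <- l2fc <- numeric(n_genes)
  conv <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    d <- prepare_glmm_data(counts[g, ], design, include_treatment = TRUE)
    full <- fit_glmm_core(d, TRUE, use_rep, use_plate, method = method)
    d0 <- d
    d0$X <- d$X[, 1, drop = FALSE]
    red <- fit_glmm_core(d0, FALSE, use_rep, use_plate, method = method)
    lr <- max(0, 2 * (full$loglik - red$loglik))
    stat[g] <- lr
    p[g] <- pchisq(lr, df = 1, lower.tail = FALSE)
    l2fc[g] <- full$beta_trt / log(2)
    conv[g] <- full$converged && red$converged
  }
  tibble::tibble(gene_id = rownames(counts), lrt_stat = stat, p_value = p,
                 log2_fc = l2fc, converged = conv)
}
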