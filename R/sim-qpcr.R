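#' Simulate qRT-PCR Ct tables reproducing requested fold changes
#'
#' Generates per-gene delta-Ct records (Ct of the gene minus Ct of the
#' cons6 housekeeping gene) such that the expression model
#' `E = Peff^(-delta_ct)` reproduces the requested heat/control fold
#' changes exactly when `ct_noise_sd = 0`:
#' `delta_ct(heat) = delta_ct(control) - log(FC) / log(Peff)`.
#'
#' @param config a [sim_config()] object (provides timepoints,
#'   replicates and the seed).
#' @param gene_fold_changes named positive numeric vector of requested
#'   linear fold changes (heat / control) per gene.
#' @param peff primer efficiency, must lie in (1, 2]; recycled per gene.
#' @param ct_noise_sd SD of Gaussian noise added to each delta-Ct.
#' @return tibble with columns gene_id, Peff, treatment, time_h,
#'   replicate, delta_ct, expression.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' rec <- gen_qpcr(cfg, c(GmHSP1 = 8), peff = 2)
#' subset(rec, treatment == "heat_40C")$delta_ct[1] -
#'   subset(rec, treatment == "control_25C")$delta_ct[1]  # -3
gen_qpcr <- function(config, gene_fold_changes, peff = 2,
                     ct_noise_sd = 0) {
  validate_sim_config(config)
  assert_that(!is.null(names(gene_fold_changes)) &&
                all(gene_fold_changes > 0),
              "gene_fold_changes must be a named positive vector")
  assert_that(all(peff > 1 & peff <= 2),
              "primer efficiency Peff must lie in (1, 2]")
  peff <- rep_len(peff, length(gene_fold_changes))
  times <- config$timepoints[config$timepoints > 0]
  withr::with_seed(derive_seed(config$seed, 4L), {
    out <- list()
    for (g in seq_along(gene_fold_changes)) {
      gene <- names(gene_fold_changes)[g]
      for (t in times) {
        dct_ctrl <- runif(1, 0, 6)
        dct_heat <- dct_ctrl - log(gene_fold_changes[g]) / log(peff[g])
        for (r in seq_len(config$n_replicates)) {
          dct <- c(dct_ctrl, dct_heat) + rnorm(2, 0, ct_noise_sd)
          out[[length(out) + 1]] <- data.frame(
            gene_id = gene, Peff = peff[g],
            treatment = c("control_25C", "heat_40C"), time_h = t,
            replicate = sprintf("r%d", r), delta_ct = dct,
            expression = peff[g]^(-dct))
        }
      }
    }
    tibble::as_tibble(do.call(rbind, out))
  })
}
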