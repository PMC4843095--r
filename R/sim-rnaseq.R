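#' Simulate gene-level RNA-seq counts with planted treatment effects
#'
#' Draws per-gene Poisson counts whose log mean is
#' `log(libsize) + baseline + treatment effect (true DE genes only)
#'  + replicate intercept + plate intercept`,
#' the exact data-generating process assumed by the per-gene mixed model
#' fitted downstream ([fit_gene_glmm()]). Replicate and plate intercepts
#' are drawn independently per gene and per level; the replicate batch is
#' shared by the control and heat arms of the same biological replicate,
#' and plates cross treatments within each tissue x time block.
#'
#' Gene baselines are log relative abundances `log(1/n_genes) + N(0, 1)`,
#' giving the several-orders-of-magnitude spread of expression levels
#' typical of root transcriptomes. A fraction `de_fraction` of genes gets
#' a signed `effect_log_fc` shift in every heat-treated sample.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{design}{tibble sample sheet: sample, tissue, treatment,
#'       time_h, replicate, plate, libsize.}
#'     \item{truth}{list with `de_genes`, a tibble of gene_id and the
#'       signed natural-log effect planted for each true DE gene.}
#'   }
#' @export
#' @examples
#' sim <- gen_rnaseq_counts(sim_config(n_genes = 50, tissues = "RH",
#'                                     timepoints = 3, seed = 7))
#' dim(sim$counts)
gen_rnaseq_counts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    design <- build_rnaseq_design(config)
    n_genes <- config$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))

    n_de <- round(config$de_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    sign_de <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
    effect <- numeric(n_genes)
    effect[de_idx] <- sign_de * config$effect_log_fc

    baseline <- log(1 / n_genes) + rnorm(n_genes, 0, 1)

    rep_levels <- unique(design$rep_key)
    plate_levels <- unique(design$plate_key)
    u_rep <- matrix(rnorm(n_genes * length(rep_levels), 0, config$sigma_rep),
                    n_genes, length(rep_levels),
                    dimnames = list(NULL, rep_levels))
    u_plate <- matrix(rnorm(n_genes * length(plate_levels), 0,
                            config$sigma_plate),
                      n_genes, length(plate_levels),
                      dimnames = list(NULL, plate_levels))

    heat <- as.numeric(design$treatment == "heat_40C")
    log_mu <- outer(baseline, log(design$libsize), "+") +
      outer(effect, heat) +
      u_rep[, design$rep_key, drop = FALSE] +
      u_plate[, design$plate_key, drop = FALSE]
    counts <- matrix(rpois(length(log_mu), exp(log_mu)),
                     n_genes, nrow(design),
                     dimnames = list(gene_ids, design$sample))

    truth <- list(de_genes = tibble::tibble(
      gene_id = gene_ids[de_idx],
      effect_log_fc = effect[de_idx]))
    design$rep_key <- NULL
    design$plate_key <- NULL
    list(counts = counts, design = design, truth = truth)
  })
}

# sample sheet for every tissue x time x treatment x replicate combination;
# rep_key/plate_key are the per-gene random-effect grouping labels
build_rnaseq_design <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      treatment = c("control_25C", "heat_40C"),
                      time_h = config$timepoints,
                      tissue = config$tissues,
                      stringsAsFactors = FALSE)
  trt_idx <- as.integer(grid$treatment == "heat_40C")
  plate_no <- ((trt_idx + grid$replicate - 1L) %% config$n_plates) + 1L
  tibble::tibble(
    sample = sprintf("%s_t%g_%s_r%d", grid$tissue, grid$time_h,
                     ifelse(trt_idx == 1L, "heat", "ctrl"), grid$replicate),
    tissue = grid$tissue,
    treatment = grid$treatment,
    time_h = grid$time_h,
    replicate = sprintf("r%d", grid$replicate),
    plate = sprintf("p%d", plate_no),
    libsize = round(runif(nrow(grid), config$libsize_range[1],
                          config$libsize_range[2])),
    rep_key = sprintf("%s_t%g_r%d", grid$tissue, grid$time_h,
                      grid$replicate),
    plate_key = sprintf("%s_t%g_p%d", grid$tissue, grid$time_h, plate_no))
}
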