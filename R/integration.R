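# Cross-omics integration: directional DE set algebra, time-course core
# sets, mRNA-protein correlation, qPCR fold changes, and term enrichment.

#' Construct a directional DE gene set
#'
#' @param label set label (e.g. a tissue or tissue x time tag).
#' @param up,down character vectors of up- and down-regulated gene ids;
#'   must be disjoint.
#' @return object of class `directional_set`.
#' @export
directional_set <- function(label, up, down) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  assert_that(length(intersect(up, down)) == 0,
              "up and down sets must be disjoint")
  structure(list(label = label, up = up, down = down),
            class = "directional_set")
}

# directional_set from a run_de()/call_de() result table
de_directional_set <- function(results, label = NULL) {
  assert_that(all(c("gene_id", "called", "direction") %in% names(results)),
              "results must carry gene_id, called, direction")
  directional_set(label %||% "de",
                  up = results$gene_id[results$called &
                                         results$direction == "up"],
                  down = results$gene_id[results$called &
                                           results$direction == "down"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition two directional DE sets into common and unique genes
#'
#' Per direction, computes the genes common to both sets and unique to
#' each, so that `|unique_a| + |common| = |a|` holds per direction.
#' Genes regulated in opposite directions in the two sets are counted in
#' neither common set and reported separately as discordant.
#'
#' @param a,b `directional_set` objects.
#' @return object of class `overlap_summary`: id sets `common_up`,
#'   `common_down`, `unique_a_up`, `unique_a_down`, `unique_b_up`,
#'   `unique_b_down`, `discordant`, plus a `counts` named vector.
#' @export
#' @examples
#' a <- directional_set("RH", up = c("g1", "g2", "g3"), down = "g9")
#' b <- directional_set("STR", up = c("g2", "g3", "g4"), down = "g9")
#' overlap_partition(a, b)$counts
overlap_partition <- function(a, b) {
  assert_that(inherits(a, "directional_set") &&
                inherits(b, "directional_set"),
              "inputs must be directional_set objects")
  discordant <- union(intersect(a$up, b$down), intersect(a$down, b$up))
  common_up <- intersect(a$up, b$up)
  common_down <- intersect(a$down, b$down)
  res <- list(
    label_a = a$label, label_b = b$label,
    common_up = common_up, common_down = common_down,
    unique_a_up = setdiff(a$up, common_up),
    unique_a_down = setdiff(a$down, common_down),
    unique_b_up = setdiff(b$up, common_up),
    unique_b_down = setdiff(b$down, common_down),
    discordant = discordant)
  res$counts <- vapply(res[3:9], length, integer(1))
  structure(res, class = "overlap_summary")
}

#' Core and union of directional sets across time points
#'
#' The core set holds genes regulated in the same direction at every
#' time point; the union holds genes regulated (in either direction) at
#' any time point. The reported fraction is `|core| / denominator`,
#' where the denominator convention is configurable: `"union"` (all
#' genes regulated at any time, the default) or `"mean_timepoint"` (the
#' average set size per time point).
#'
#' @param sets list of `directional_set` objects, one per time point
#'   (at least two).
#' @param denominator `"union"` or `"mean_timepoint"`.
#' @return list with `core_up`, `core_down`, `union_ids`, `fraction`.
#' @export
timepoint_core <- function(sets, denominator = c("union",
                                                 "mean_timepoint")) {
  denominator <- match.arg(denominator)
  assert_that(length(sets) >= 2, "need at least two time points")
  core_up <- Reduce(intersect, lapply(sets, `[[`, "up"))
  core_down <- Reduce(intersect, lapply(sets, `[[`, "down"))
  union_ids <- unique(unlist(lapply(sets, function(s) c(s$up, s$down))))
  denom <- switch(denominator,
                  union = length(union_ids),
                  mean_timepoint = mean(vapply(sets, function(s)
                    length(s$up) + length(s$down), numeric(1))))
  frac <- if (denom > 0) (length(core_up) + length(core_down)) / denom else 0
  list(core_up = core_up, core_down = core_down, union_ids = union_ids,
       fraction = frac)
}

#' Correlation between protein and mRNA log2 fold changes
#'
#' Pearson correlation over ids present in both inputs; also reports
#' the fraction of proteins with a matched transcript measurement.
#'
#' @param protein_log2fc,mrna_log2fc named numeric vectors of log2 fold
#'   changes keyed by gene/protein id.
#' @return list with `r` (Pearson correlation, `NA` with a warning when
#'   fewer than 3 ids match), `n_matched`, `matched_fraction`.
#' @export
mrna_protein_correlation <- function(protein_log2fc, mrna_log2fc) {
  assert_that(!is.null(names(protein_log2fc)) &&
                !is.null(names(mrna_log2fc)),
              "inputs must be named by gene/protein id")
  ids <- intersect(names(protein_log2fc), names(mrna_log2fc))
  n <- length(ids)
  frac <- n / length(protein_log2fc)
  if (n < 3) {
    warning("fewer than 3 matched pairs; correlation undefined")
    return(list(r = NA_real_, n_matched = n, matched_fraction = frac))
  }
  list(r = stats::cor(protein_log2fc[ids], mrna_log2fc[ids]),
       n_matched = n, matched_fraction = frac)
}

#' qPCR fold change from delta-Ct values
#'
#' Expression is `E = Peff^(-delta_ct)` relative to the cons6
#' housekeeping gene (`delta_ct = Ct_gene - Ct_cons6`); the fold change
#' is the ratio of heat-treated to control expression.
#'
#' @param delta_ct_heat,delta_ct_ctrl delta-Ct of the heat-treated and
#'   control samples.
#' @param peff primer efficiency in (1, 2].
#' @return positive fold change (heat / control).
#' @export
#' @examples
#' qpcr_fold_change(delta_ct_heat = 0, delta_ct_ctrl = 3, peff = 2)  # 8
qpcr_fold_change <- function(delta_ct_heat, delta_ct_ctrl, peff) {
  assert_that(all(peff > 1 & peff <= 2),
              "primer efficiency Peff must lie in (1, 2]")
  peff^(-delta_ct_heat) / peff^(-delta_ct_ctrl)
}

#' Term enrichment by the one-sided hypergeometric (Fisher) test
#'
#' For each term, tests over-representation of the study set among the
#' term's genes against the background with the exact hypergeometric
#' upper tail, then adjusts across terms.
#'
#' @param study_set character vector of study gene ids (must be a subset
#'   of the background).
#' @param category_map data frame with columns `gene` and `term`.
#' @param background_set character vector of background gene ids.
#' @param fdr q-value threshold for the enriched flag (default 0.05).
#' @param adjust `"BH"` (default) or `"storey"` for the q-value method.
#' @return tibble: term, n_study_hits, n_term, p_value, q_value,
#'   enriched. Terms with no background genes are skipped with a
#'   warning.
#' @export
enrichment_test <- function(study_set, category_map, background_set,
                            fdr = 0.05, adjust = c("BH", "storey")) {
  adjust <- match.arg(adjust)
  study_set <- unique(study_set)
  background_set <- unique(background_set)
  assert_that(all(study_set %in% background_set),
              "study genes must all be in the background")
  assert_that(all(c("gene", "term") %in% names(category_map)),
              "category_map needs gene and term columns")
  category_map <- category_map[category_map$gene %in% background_set, ]
  terms <- unique(category_map$term)
  N <- length(background_set)
  n <- length(study_set)
  rows <- lapply(terms, function(tm) {
    term_genes <- unique(category_map$gene[category_map$term == tm])
    K <- length(term_genes)
    if (K == 0) {
      warning("term ", tm, " has no background genes; skipped")
      return(NULL)
    }
    k <- length(intersect(term_genes, study_set))
    data.frame(term = tm, n_study_hits = k, n_term = K,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res <- tibble::as_tibble(do.call(rbind, rows))
  res$q_value <- if (adjust == "BH") p.adjust(res$p_value, method = "BH")
                 else storey_qvalues(res$p_value)
  res$enriched <- res$q_value <= fdr
  res
}
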