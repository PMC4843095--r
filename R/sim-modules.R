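#' Simulate module-structured expression driven by TF regulator trees
#'
#' Plants `n_modules` regulatory programs. Each program is a binary
#' decision tree whose internal nodes query the discretized state of one
#' transcription factor (`is_up`: state 1, `is_down`: state -1) and whose
#' leaves are condition subsets with distinct mean expression regimes
#' spaced `leaf_sep` apart. Member genes of a module take the leaf mean of
#' each condition plus `N(0, noise_sd^2)` noise.
#'
#' Conditions are the tissue x time heat-vs-control contrasts of the
#' configuration; values are interpreted as log2 fold changes. TF states
#' are drawn per condition, and continuous TF expression consistent with
#' the +/-3 discretization cutoffs is emitted alongside (state 1 around
#' +5, state 0 around 0, state -1 around -5, SD 0.5).
#'
#' @param config a [sim_config()] object; `n_genes` here counts module
#'   member genes (TFs are extra rows named `TF01`, ...).
#' @return list with elements `expr` (gene x condition matrix),
#'   `regulators` (a `regulator_state` as from [discretize_regulators()]),
#'   `tf_expr` (TF x condition matrix of continuous TF expression), and
#'   `truth` (list: `module_assignment` named integer vector,
#'   `regulator_trees` list of planted trees, `split_tfs` character).
#' @export
#' @examples
#' sim <- gen_module_expression(sim_config(n_genes = 60, n_tf = 4,
#'                                         n_modules = 2, tree_depth = 1,
#'                                         tissues = "RH",
#'                                         timepoints = c(3, 6, 12, 24),
#'                                         seed = 3))
#' table(sim$truth$module_assignment)
gen_module_expression <- function(config) {
  validate_sim_config(config)
  assert_that(config$n_modules <= config$n_genes,
              "more modules than genes")
  withr::with_seed(derive_seed(config$seed, 2L), {
    conditions <- as.vector(outer(config$tissues, config$timepoints,
                                  function(ti, tp) sprintf("%s_%gh", ti, tp)))
    n_cond <- length(conditions)
    tf_ids <- sprintf("TF%02d", seq_len(config$n_tf))

    # regulator states per condition; each TF uses 2 or 3 of the labels
    states <- matrix(0L, config$n_tf, n_cond,
                     dimnames = list(tf_ids, conditions))
    for (t in seq_len(config$n_tf)) {
      labs <- if (runif(1) < 0.5) c(1L, -1L) else c(1L, 0L, -1L)
      states[t, ] <- sample(labs, n_cond, replace = TRUE)
      # guarantee every chosen label occurs at least once
      for (l in labs) if (!any(states[t, ] == l))
        states[t, sample.int(n_cond, 1)] <- l
    }
    tf_expr <- matrix(rnorm(length(states), mean = 5 * states, sd = 0.5),
                      config$n_tf, n_cond,
                      dimnames = list(tf_ids, conditions))

    # distinct per-module offsets keep modules distinguishable even when
    # two planted trees happen to query the same TF
    trees <- lapply(seq_len(config$n_modules), function(m)
      plant_tree(conditions, states, depth = config$tree_depth,
                 leaf_sep = config$leaf_sep, noise_sd = config$noise_sd,
                 offset = (m - (config$n_modules + 1) / 2) * config$leaf_sep))

    assignment <- sample(rep_len(seq_len(config$n_modules), config$n_genes))
    gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
    names(assignment) <- gene_ids

    expr <- matrix(0, config$n_genes, n_cond,
                   dimnames = list(gene_ids, conditions))
    for (m in seq_len(config$n_modules)) {
      mu <- leaf_means_by_condition(trees[[m]], conditions)
      idx <- which(assignment == m)
      expr[idx, ] <- matrix(rep(mu, each = length(idx)), length(idx), n_cond) +
        rnorm(length(idx) * n_cond, 0, config$noise_sd)
    }

    regulators <- new_regulator_state(states)
    split_tfs <- unique(unlist(lapply(trees, tree_split_tfs)))
    list(expr = expr, regulators = regulators, tf_expr = tf_expr,
         truth = list(module_assignment = assignment,
                      regulator_trees = trees,
                      split_tfs = split_tfs))
  })
}

# recursively plant a tree over `conditions`; each split must leave both
# children with >= 2 conditions so the learner's defaults can recover it
plant_tree <- function(conditions, states, depth, leaf_sep, noise_sd,
                       used_tfs = character(0), offset = 0) {
  tree <- plant_node(conditions, states, depth, used_tfs)
  leaves <- tree_leaves(tree)
  mus <- (seq_along(leaves) - (length(leaves) + 1) / 2) * leaf_sep + offset
  set_leaf_params(tree, mus, noise_sd^2, counter = new.env())
}

plant_node <- function(conditions, states, depth, used_tfs) {
  if (depth == 0 || length(conditions) < 4)
    return(list(conditions = conditions, mu = NA_real_, sigma2 = NA_real_))
  tf_pool <- setdiff(rownames(states), used_tfs)
  cand <- expand.grid(tf = tf_pool, query = c("is_up", "is_down"),
                      stringsAsFactors = FALSE)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    yes <- conditions[query_predicate(states[cand$tf[i], conditions],
                                      cand$query[i])]
    no <- setdiff(conditions, yes)
    if (length(yes) >= 2 && length(no) >= 2) {
      return(list(
        tf = cand$tf[i], query = cand$query[i],
        yes = plant_node(yes, states, depth - 1, c(used_tfs, cand$tf[i])),
        no = plant_node(no, states, depth - 1, c(used_tfs, cand$tf[i]))))
    }
  }
  list(conditions = conditions, mu = NA_real_, sigma2 = NA_real_)
}

set_leaf_params <- function(tree, mus, sigma2, counter) {
  if (is_leaf(tree)) {
    if (is.null(counter$i)) counter$i <- 0L
    counter$i <- counter$i + 1L
    tree$mu <- mus[counter$i]
    tree$sigma2 <- sigma2
    return(tree)
  }
  tree$yes <- set_leaf_params(tree$yes, mus, sigma2, counter)
  tree$no <- set_leaf_params(tree$no, mus, sigma2, counter)
  tree
}
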