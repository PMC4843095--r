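# Regulator-tree representation shared by the simulator and the learner.
# An internal node is list(tf, query, yes, no); a leaf is
# list(conditions, mu, sigma2). The `yes` child holds conditions where the
# query predicate on the TF state is true.

is_leaf <- function(node) is.null(node$tf)

query_predicate <- function(states, query) {
  if (query == "is_up") states == 1L else states == -1L
}

tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(list(tree))
  c(tree_leaves(tree$yes), tree_leaves(tree$no))
}

tree_split_tfs <- function(tree) {
  if (is_leaf(tree)) return(character(0))
  c(tree$tf, tree_split_tfs(tree$yes), tree_split_tfs(tree$no))
}

tree_depth_of <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + max(tree_depth_of(tree$yes), tree_depth_of(tree$no))
}

# per-condition leaf means in the order of `conditions`
leaf_means_by_condition <- function(tree, conditions) {
  mu <- setNames(numeric(length(conditions)), conditions)
  for (lf in tree_leaves(tree)) mu[lf$conditions] <- lf$mu
  mu[conditions]
}

leaf_params_by_condition <- function(tree, conditions) {
  mu <- setNames(numeric(length(conditions)), conditions)
  s2 <- mu
  for (lf in tree_leaves(tree)) {
    mu[lf$conditions] <- lf$mu
    s2[lf$conditions] <- lf$sigma2
  }
  list(mu = mu[conditions], sigma2 = s2[conditions])
}

# Gaussian log-likelihood of the member-gene values falling in a leaf,
# using the leaf MLE (mean, variance floored at `var_floor`)
leaf_fit <- function(values, var_floor = 1e-4) {
  mu <- mean(values)
  s2 <- max(mean((values - mu)^2), var_floor)
  list(mu = mu, sigma2 = s2,
       loglik = sum(dnorm(values, mu, sqrt(s2), log = TRUE)))
}

#' Learn a regulator decision tree for one gene module
#'
#' Greedy top-down induction: at each node the (TF, query) pair maximizing
#' the summed Gaussian log-likelihood of the member-gene values over the
#' two resulting condition subsets is chosen. A split is accepted only if
#' the likelihood gain is positive and both children retain at least
#' `min_leaf_conditions` conditions. Leaves store the sample mean and the
#' (floored) maximum-likelihood variance of all member values under them.
#'
#' @param member_expr numeric matrix, member genes x conditions.
#' @param regs a `regulator_state` (see [discretize_regulators()]).
#' @param max_depth maximum tree depth (default 3).
#' @param min_leaf_conditions minimum conditions per leaf (default 2).
#' @param var_floor lower bound on leaf variances, preventing degenerate
#'   infinite likelihoods.
#' @return a regulator tree (nested list; leaves carry `conditions`,
#'   `mu`, `sigma2`).
#' @export
learn_tree <- function(member_expr, regs, max_depth = 3,
                       min_leaf_conditions = 2, var_floor = 1e-4) {
  member_expr <- as.matrix(member_expr)
  assert_that(ncol(member_expr) >= 1, "empty condition set")
  assert_that(nrow(member_expr) >= 1, "module has no member genes")
  conditions <- colnames(member_expr)
  assert_that(!is.null(conditions) &&
                all(conditions %in% colnames(regs$states)),
              "conditions must be named and covered by the regulator state")
  grow_node(member_expr, regs, conditions, depth = 0,
            max_depth = max_depth, min_leaf = min_leaf_conditions,
            var_floor = var_floor)
}

grow_node <- function(expr, regs, conditions, depth, max_depth, min_leaf,
                      var_floor) {
  vals <- as.vector(expr[, conditions, drop = FALSE])
  here <- leaf_fit(vals, var_floor)
  leaf <- list(conditions = conditions, mu = here$mu, sigma2 = here$sigma2)
  if (depth >= max_depth || length(conditions) < 2 * min_leaf) return(leaf)

  best <- NULL
  best_gain <- 0
  for (tf in rownames(regs$states)) {
    for (q in c("is_up", "is_down")) {
      yes <- conditions[query_predicate(regs$states[tf, conditions], q)]
      no <- setdiff(conditions, yes)
      if (length(yes) < min_leaf || length(no) < min_leaf) next
      ll <- leaf_fit(as.vector(expr[, yes, drop = FALSE]), var_floor)$loglik +
        leaf_fit(as.vector(expr[, no, drop = FALSE]), var_floor)$loglik
      gain <- ll - here$loglik
      if (gain > best_gain + 1e-9) {
        best_gain <- gain
        best <- list(tf = tf, query = q, yes = yes, no = no)
      }
    }
  }
  if (is.null(best)) return(leaf)
  list(tf = best$tf, query = best$query,
       yes = grow_node(expr, regs, best$yes, depth + 1, max_depth, min_leaf,
                       var_floor),
       no = grow_node(expr, regs, best$no, depth + 1, max_depth, min_leaf,
                      var_floor))
}

# refit the leaf parameters of an existing structure on new member data
refit_tree <- function(tree, member_expr, var_floor = 1e-4) {
  if (is_leaf(tree)) {
    fit <- leaf_fit(as.vector(member_expr[, tree$conditions, drop = FALSE]),
                    var_floor)
    tree$mu <- fit$mu
    tree$sigma2 <- fit$sigma2
    return(tree)
  }
  tree$yes <- refit_tree(tree$yes, member_expr, var_floor)
  tree$no <- refit_tree(tree$no, member_expr, var_floor)
  tree
}

#' Score one gene's expression profile under a regulator tree
#'
#' Sums, over conditions, the Gaussian log density of the gene's value
#' under the leaf containing that condition.
#'
#' @param gene_values named numeric vector of per-condition values
#'   covering the tree's condition set.
#' @param tree a regulator tree from [learn_tree()].
#' @return total log-likelihood (a scalar).
#' @export
score_gene <- function(gene_values, tree) {
  conds <- unlist(lapply(tree_leaves(tree), `[[`, "conditions"))
  assert_that(all(conds %in% names(gene_values)),
              "gene does not cover the tree's condition set")
  p <- leaf_params_by_condition(tree, conds)
  sum(dnorm(gene_values[conds], p$mu, sqrt(p$sigma2), log = TRUE))
}

# total model log-likelihood: each gene scored under its module's tree
network_loglik <- function(expr, trees, assignment) {
  total <- 0
  for (m in seq_along(trees)) {
    idx <- which(assignment == m)
    if (!length(idx)) next
    p <- leaf_params_by_condition(trees[[m]], colnames(expr))
    sub <- expr[idx, , drop = FALSE]
    total <- total + sum(dnorm(t(sub), p$mu, sqrt(p$sigma2), log = TRUE))
  }
  total
}
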