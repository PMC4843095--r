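# Module-network inference: discretization, clustering, tree learning
# against exhaustive enumeration, scoring, reassignment, and the
# alternating fit with its monotone-likelihood guarantee.

test_that("TF discretization assigns states by occupied ranges", {
  m <- rbind(TFa = c(5, 4, -4, -5, 0, 0),
             TFb = c(0.5, 1.0, -1.0, 0.2, 0.1, 0),
             TFc = c(4, 5, 0.2, 0.3, 0.1, 0.2))
  colnames(m) <- paste0("c", 1:6)
  rs <- discretize_regulators(m)
  expect_equal(unname(rs$states["TFa", ]), c(1L, 1L, -1L, -1L, 0L, 0L))
  expect_equal(unname(rs$states["TFb", ]), rep(0L, 6))
  expect_equal(unname(rs$states["TFc", ]), c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(rs$n_categories), c(3L, 1L, 2L))
})

test_that("gene clustering is seeded-deterministic and separates planted profiles", {
  set.seed(10)
  a <- matrix(rnorm(20 * 6, 5, 0.2), 20, 6)
  b <- matrix(rnorm(20 * 6, -5, 0.2), 20, 6)
  expr <- rbind(a, b)
  rownames(expr) <- sprintf("g%02d", 1:40)
  colnames(expr) <- paste0("c", 1:6)
  cl <- cluster_genes_kmeans(expr, 2, seed = 3)
  expect_identical(cl, cluster_genes_kmeans(expr, 2, seed = 3))
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_true(cl[1] != cl[40])
  # duplicate rows land in the same cluster
  expr2 <- rbind(expr, g41 = expr["g01", ])
  cl2 <- cluster_genes_kmeans(expr2, 2, seed = 3)
  expect_equal(unname(cl2["g41"]), unname(cl2["g01"]))
  expect_error(cluster_genes_kmeans(expr, 100),
               class = "rootheat_validation_error")
})

test_that("tree learning recovers a planted depth-1 split and matches exhaustive search", {
  set.seed(21)
  for (case in 1:20) {
    n_tf <- sample(2:6, 1)
    n_cond <- sample(8:12, 1)
    conds <- paste0("c", seq_len(n_cond))
    states <- matrix(sample(c(-1L, 0L, 1L), n_tf * n_cond, replace = TRUE),
                     n_tf, n_cond,
                     dimnames = list(paste0("TF", seq_len(n_tf)), conds))
    expr <- matrix(rnorm(5 * n_cond, 0, 1), 5, n_cond,
                   dimnames = list(paste0("g", 1:5), conds))
    regs <- rootheat:::new_regulator_state(states)
    tree <- learn_tree(expr, regs, max_depth = 1)
    oracle <- exhaustive_depth1(expr, states)
    if (is.null(oracle$tf)) {
      expect_true(rootheat:::is_leaf(tree))
    } else {
      expect_equal(tree$tf, oracle$tf)
      expect_equal(tree$query, oracle$query)
    }
  }
})

test_that("planted strong split is found; degenerate inputs give one leaf", {
  conds <- paste0("c", 1:8)
  states <- matrix(0L, 2, 8, dimnames = list(c("TF1", "TF2"), conds))
  states["TF1", 1:4] <- 1L
  regs <- rootheat:::new_regulator_state(states)
  set.seed(2)
  expr <- matrix(rnorm(10 * 8, 0, 0.1), 10, 8,
                 dimnames = list(paste0("g", 1:10), conds))
  expr[, 1:4] <- expr[, 1:4] + 2
  expr[, 5:8] <- expr[, 5:8] - 2
  tree <- learn_tree(expr, regs, max_depth = 1)
  expect_equal(tree$tf, "TF1")
  expect_equal(tree$query, "is_up")
  expect_equal(tree$yes$mu, 2, tolerance = 0.1)
  expect_equal(tree$no$mu, -2, tolerance = 0.1)

  # constant member values: no positive gain, single leaf
  flat <- matrix(1, 4, 8, dimnames = list(paste0("g", 1:4), conds))
  expect_true(rootheat:::is_leaf(learn_tree(flat, regs)))
  # single condition: trivially one leaf
  one <- expr[, 1, drop = FALSE]
  expect_true(rootheat:::is_leaf(learn_tree(one, regs)))
})

test_that("tree leaves partition the condition set", {
  cfg <- sim_config(n_genes = 60, n_modules = 3, tree_depth = 2,
                    n_tf = 5, tissues = c("RH", "STR"),
                    timepoints = c(3, 6, 12, 24), seed = 31)
  sim <- gen_module_expression(cfg)
  net <- fit_module_network(sim$expr, sim$regulators, k = 3, seed = 31)
  for (tr in net$modules) {
    leaves <- rootheat:::tree_leaves(tr)
    all_conds <- unlist(lapply(leaves, `[[`, "conditions"))
    expect_setequal(all_conds, colnames(sim$expr))
    expect_equal(length(all_conds), ncol(sim$expr))  # no overlap
  }
})

test_that("gene scoring is the summed Gaussian log density of the leaves", {
  leafA <- list(conditions = c("c1", "c2"), mu = 0, sigma2 = 1)
  vals <- c(c1 = 0, c2 = 0)
  expect_equal(score_gene(vals, leafA), 2 * -0.918939, tolerance = 1e-6)
  # merged leaf with equal parameters scores identically to two leaves
  split_tree <- list(tf = "TF1", query = "is_up",
                     yes = list(conditions = "c1", mu = 0, sigma2 = 1),
                     no = list(conditions = "c2", mu = 0, sigma2 = 1))
  expect_equal(score_gene(vals, split_tree), score_gene(vals, leafA))
  # score decays with distance from the leaf mean
  s <- vapply(c(0, 1, 2, 3), function(d)
    score_gene(c(c1 = d, c2 = 0), leafA), numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(score_gene(c(c9 = 1), leafA),
               class = "rootheat_validation_error")
})

test_that("reassignment moves genes to better modules and respects ties", {
  treeA <- list(conditions = c("c1", "c2"), mu = 2, sigma2 = 0.01)
  treeB <- list(conditions = c("c1", "c2"), mu = -2, sigma2 = 0.01)
  expr <- rbind(g1 = c(2, 2), g2 = c(-2, -2))
  colnames(expr) <- c("c1", "c2")
  a <- reassign_genes(expr, list(treeA, treeB),
                      current = c(g1 = 2L, g2 = 2L))
  expect_equal(unname(a), c(1L, 2L))
  # identical trees: tie keeps the current assignment
  tie <- reassign_genes(expr, list(treeA, treeA),
                        current = c(g1 = 2L, g2 = 1L))
  expect_equal(unname(tie), c(2L, 1L))
  # no current assignment: lowest index wins ties
  tie2 <- reassign_genes(expr, list(treeA, treeA))
  expect_equal(unname(tie2), c(1L, 1L))
})

test_that("network fit recovers planted modules with monotone likelihood", {
  cfg <- sim_config(n_genes = 200, n_tf = 5, n_modules = 2,
                    tree_depth = 1, leaf_sep = 4, noise_sd = 0.1,
                    tissues = c("RH", "STR"), timepoints = 1:10,
                    seed = 17)
  sim <- gen_module_expression(cfg)
  net <- fit_module_network(sim$expr, sim$regulators, k = 2,
                            max_depth = 1, seed = 17)
  expect_equal(adjusted_rand_index(
    sim$truth$module_assignment[names(net$assignment)],
    net$assignment), 1)
  expect_true(all(diff(net$history) >= -1e-8))
  learned <- unlist(lapply(net$modules, rootheat:::tree_split_tfs))
  expect_true(all(sim$truth$split_tfs %in% learned))
})

test_that("k = 1 degenerates to a single module and the fit is deterministic", {
  cfg <- sim_config(n_genes = 30, n_modules = 1, tree_depth = 1,
                    n_tf = 3, tissues = "RH", timepoints = c(3, 6, 12, 24),
                    seed = 23)
  sim <- gen_module_expression(cfg)
  net <- fit_module_network(sim$expr, sim$regulators, k = 1, seed = 23)
  expect_equal(net$k, 1)
  expect_true(all(net$assignment == 1))
  expect_lte(length(net$history) - 1, 2)
  net2 <- fit_module_network(sim$expr, sim$regulators, k = 1, seed = 23)
  expect_identical(net, net2)
  expect_error(fit_module_network(sim$expr, sim$regulators, k = 0),
               class = "rootheat_validation_error")
})
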