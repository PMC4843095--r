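#' Discretize transcription-factor expression into regulator states
#'
#' Each TF's per-condition expression values are grouped into K
#' categories, where K is the number of expression ranges the TF actually
#' occupies among "high" (value > `high_cut`), "low" (value < `low_cut`)
#' and "normal" (in between). For K > 1 the values are clustered by 1-D
#' K-means with K centers (initialized at the range means, so the result
#' is deterministic) and clusters are mapped to state labels by center
#' ordering: the highest-center cluster gets the highest occupied label,
#' the lowest gets the lowest, with 1 = highly expressed, 0 = normally
#' expressed, -1 = lowly expressed.
#'
#' The cutoffs apply to the same scale as the input matrix (log2 fold
#' changes in this pipeline) and are exposed as arguments.
#'
#' @param tf_expr numeric matrix, TFs x conditions, with dimnames.
#' @param high_cut,low_cut discretization cutoffs (defaults +3 / -3).
#' @return an object of class `regulator_state`: list with `states`
#'   (integer matrix over \{-1, 0, 1\}) and `n_categories` (per-TF count).
#' @export
#' @examples
#' m <- rbind(TF1 = c(5, 4, -4, -5, 0, 0))
#' colnames(m) <- paste0("c", 1:6)
#' discretize_regulators(m)$states
discretize_regulators <- function(tf_expr, high_cut = 3, low_cut = -3) {
  tf_expr <- as.matrix(tf_expr)
  assert_that(all(is.finite(tf_expr)), "TF expression must be finite")
  assert_that(high_cut > low_cut, "high_cut must exceed low_cut")
  states <- matrix(0L, nrow(tf_expr), ncol(tf_expr),
                   dimnames = dimnames(tf_expr))
  for (t in seq_len(nrow(tf_expr))) {
    v <- tf_expr[t, ]
    range_of <- ifelse(v > high_cut, 1L, ifelse(v < low_cut, -1L, 0L))
    occupied <- sort(unique(range_of), decreasing = TRUE)
    K <- length(occupied)
    if (K == 1L) {
      states[t, ] <- occupied
      next
    }
    assert_that(length(unique(v)) >= K,
                "constant TF cannot be split into multiple categories")
    init <- vapply(occupied, function(r) mean(v[range_of == r]), numeric(1))
    km <- kmeans(v, centers = matrix(init, ncol = 1))
    # clusters ranked by center, highest first, matched to occupied labels
    rank_by_center <- order(km$centers[, 1], decreasing = TRUE)
    lab <- occupied[match(km$cluster, rank_by_center)]
    states[t, ] <- lab
  }
  new_regulator_state(states)
}

new_regulator_state <- function(states) {
  storage.mode(states) <- "integer"
  assert_that(all(states %in% c(-1L, 0L, 1L)),
              "states must lie in {-1, 0, 1}")
  structure(list(states = states,
                 n_categories = apply(states, 1,
                                      function(s) length(unique(s)))),
            class = "regulator_state")
}

#' Cluster gene expression profiles with seeded K-means
#'
#' K-means on row profiles with k-means++ seeding driven by an explicit
#' seed, so repeated runs are identical.
#'
#' @param expr numeric matrix, genes x conditions.
#' @param k number of clusters (must not exceed the number of genes).
#' @param seed integer RNG seed.
#' @return named integer vector mapping gene id to cluster in 1..k.
#' @export
cluster_genes_kmeans <- function(expr, k, seed = 1L) {
  expr <- as.matrix(expr)
  assert_that(is_count(k), "k must be a count >= 1")
  assert_that(k <= nrow(expr), "k exceeds the number of genes")
  withr::with_seed(as.integer(seed), {
    centers <- kmeanspp_init(expr, k)
    if (k == 1L) {
      cl <- rep(1L, nrow(expr))
    } else {
      km <- suppressWarnings(kmeans(expr, centers = centers, iter.max = 100))
      cl <- km$cluster
    }
    setNames(as.integer(cl), rownames(expr))
  })
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center; duplicates perturbed is not
# needed because stats::kmeans tolerates distinct rows only -- guard by
# jittering exact duplicate centers minimally
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers <- x[idx, , drop = FALSE]
  dup <- duplicated(centers)
  if (any(dup))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(rnorm(sum(dup) * ncol(x), 0, 1e-8), sum(dup), ncol(x))
  centers
}
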