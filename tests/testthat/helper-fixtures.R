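# Shared fixtures and small independent oracles used across test files.

# minimal 2x2 (treatment x replicate) sample sheet with crossed plates
toy_design <- function(libsize = rep(1e6, 4)) {
  tibble::tibble(
    sample = c("c1", "c2", "h1", "h2"),
    tissue = "RH",
    treatment = rep(c("control_25C", "heat_40C"), each = 2),
    time_h = 3,
    replicate = c("r1", "r2", "r1", "r2"),
    plate = c("p1", "p2", "p2", "p1"),
    libsize = libsize)
}

# brute-force marginal log-likelihood for a single grouping factor by
# 1-D numeric integration of Poisson x Normal per group
integrate_loglik <- function(y, eta0, group, sd) {
  total <- 0
  for (g in unique(group)) {
    idx <- which(group == g)
    f <- function(u) vapply(u, function(uu) {
      lv <- sum(dpois(y[idx], exp(eta0[idx] + uu), log = TRUE)) +
        dnorm(uu, 0, sd, log = TRUE)
      if (is.finite(lv)) exp(lv) else 0
    }, numeric(1))
    total <- total +
      log(stats::integrate(f, -12 * sd, 12 * sd, rel.tol = 1e-12,
                           abs.tol = 0)$value)
  }
  total
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# exhaustive best depth-1 split: enumerate every (TF, query), compute the
# two-leaf Gaussian likelihood directly
exhaustive_depth1 <- function(expr, states, min_leaf = 2,
                              var_floor = 1e-4) {
  gauss_ll <- function(v) {
    mu <- mean(v)
    s2 <- max(mean((v - mu)^2), var_floor)
    sum(dnorm(v, mu, sqrt(s2), log = TRUE))
  }
  conds <- colnames(expr)
  base <- gauss_ll(as.vector(expr))
  best <- list(ll = base, tf = NULL, query = NULL)
  for (tf in rownames(states)) {
    for (q in c("is_up", "is_down")) {
      hit <- if (q == "is_up") states[tf, conds] == 1 else
        states[tf, conds] == -1
      yes <- conds[hit]
      no <- setdiff(conds, yes)
      if (length(yes) < min_leaf || length(no) < min_leaf) next
      ll <- gauss_ll(as.vector(expr[, yes, drop = FALSE])) +
        gauss_ll(as.vector(expr[, no, drop = FALSE]))
      if (ll > best$ll + 1e-9) best <- list(ll = ll, tf = tf, query = q)
    }
  }
  best
}

# exact hypergeometric upper tail by direct summation of the pmf via
# binomial coefficients (independent of phyper)
hyper_upper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
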