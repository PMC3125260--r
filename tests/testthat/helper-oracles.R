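# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUC by exhaustive pair comparison, the L1
# threshold by grid scan, and the PMD objective by feasible-point search.

# AUC as the exhaustive mean over all positive-negative pairs, ties = 1/2.
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# smallest delta on a fine grid whose normalized soft-threshold meets the
# L1 bound (independent re-statement of the definition)
grid_l1_delta_oracle <- function(v, bound, step = 1e-6) {
  for (delta in seq(0, max(abs(v)), by = step)) {
    w <- sign(v) * pmax(abs(v) - delta, 0)
    n2 <- sqrt(sum(w^2))
    if (n2 == 0) next
    if (sum(abs(w)) / n2 <= bound) return(delta)
  }
  max(abs(v))
}

# Project an arbitrary direction onto the feasible set {|w|_2 <= 1,
# |w|_1 <= bound}: scale down until both constraints hold. Every feasible
# point is a fixed point of this map, including optima with |w|_2 < 1.
project_feasible <- function(v, bound) {
  v / max(sqrt(sum(v^2)), sum(abs(v)) / bound, 1e-300)
}

# n feasible vectors (columns): Gaussian directions with random
# soft-threshold sparsification, projected into the feasible set
random_feasible_matrix <- function(dim, bound, n) {
  V <- matrix(stats::rnorm(dim * n), dim, n)
  delta <- stats::runif(n) * apply(abs(V), 2, max)
  W <- sign(V) * pmax(abs(V) - rep(delta, each = dim), 0)
  W[, colSums(abs(W)) == 0] <- stats::rnorm(dim * sum(colSums(abs(W)) == 0))
  scale <- pmax(sqrt(colSums(W^2)), colSums(abs(W)) / bound)
  W / rep(scale, each = dim)
}

# Best |alpha' Z beta| over n_samples random feasible pairs and all
# axis-aligned pairs, polished by a shrinking stochastic hill climb inside
# the feasible set.
pmd_objective_oracle <- function(Z, c1, c2, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  p <- nrow(Z); q <- ncol(Z)
  b1 <- c1 * sqrt(p); b2 <- c2 * sqrt(q)
  A <- random_feasible_matrix(p, b1, n_samples)
  B <- random_feasible_matrix(q, b2, n_samples)
  obj <- abs(colSums(A * (Z %*% B)))            # paired random samples
  top <- order(-obj)[1:3]
  starts <- lapply(top, function(i) list(a = A[, i], b = B[, i]))
  for (i in seq_len(p)) for (j in seq_len(q)) {  # axis-aligned candidates
    a <- numeric(p); a[i] <- 1
    b <- numeric(q); b[j] <- sign(Z[i, j])
    if (b[j] == 0) b[j] <- 1
    starts <- c(starts, list(list(a = a, b = b)))
  }
  best <- max(obj)
  for (st in starts) {                           # shrinking hill climbs
    alpha <- st$a; beta <- st$b
    cur <- abs(sum(alpha * (Z %*% beta)))
    for (sigma in c(0.3, 0.1, 0.03, 0.01, 3e-3, 1e-3, 3e-4, 1e-4, 3e-5,
                    1e-5)) {
      for (it in 1:400) {    # block-wise moves accept far more often
        a2 <- project_feasible(alpha + sigma * stats::rnorm(p), b1)
        val <- abs(sum(a2 * (Z %*% beta)))
        if (val > cur) { cur <- val; alpha <- a2 }
        b2v <- project_feasible(beta + sigma * stats::rnorm(q), b2)
        val <- abs(sum(alpha * (Z %*% b2v)))
        if (val > cur) { cur <- val; beta <- b2v }
      }
    }
    best <- max(best, cur)
  }
  best
}

# the standard planted benchmark conditions used by the recovery checks
planted_benchmark <- function(seed = 42) {
  comps <- list(planted_component(1:5, 1:5, drug_frac = 0.2,
                                  flip_noise = 0.05),
                planted_component(6:10, 6:10, drug_frac = 0.2,
                                  flip_noise = 0.05))
  generate_planted_dataset(n = 500, p = 50, q = 40, components = comps,
                           background_rate = 0.05, seed = seed)
}

# fraction of each planted support found among the top-5 |weight| features
# of the best-matching component
support_recovery <- function(W, truth, field) {
  sapply(seq_along(truth$components), function(ci) {
    supp <- truth$components[[ci]][[field]]
    best <- 0
    for (k in seq_len(ncol(W))) {
      top <- order(-abs(W[, k]))[1:5]
      best <- max(best, length(intersect(top, supp)) / length(supp))
    }
    best
  })
}

# pooled-AUC ceiling: a truth-aware oracle that scores exactly the planted
# carrier cells
planted_auc_ceiling <- function(sim) {
  S <- matrix(0, nrow(sim$Y), ncol(sim$Y))
  for (ci in seq_along(sim$truth$components))
    S[sim$truth$member_drugs[[ci]],
      sim$truth$components[[ci]]$se_support] <- 1
  global_auc(S, sim$Y)
}
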