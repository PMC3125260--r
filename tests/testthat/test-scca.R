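test_that("cross_product is the entrywise cross sum", {
  expect_equal(cross_product(diag(2), diag(2)), diag(2))
  Xo <- cbind(c(1, 0), c(0, 0)); Yo <- cbind(c(0, 0), c(0, 1))
  expect_equal(cross_product(Xo, Yo), matrix(0, 2, 2))
  set.seed(21)
  Xn <- matrix(rnorm(15), 5, 3); Yn <- matrix(rnorm(10), 5, 2)
  Z <- cross_product(Xn, Yn)
  loop <- matrix(0, 3, 2)
  for (j in 1:3) for (k in 1:2) loop[j, k] <- sum(Xn[, j] * Yn[, k])
  expect_equal(Z, loop)
  expect_error(cross_product(Xn, matrix(0, 4, 2)), "same number of rows")
})

test_that("soft thresholding matches its definition", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  v <- c(-2.5, 0.3, 1.1)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 3), c(0, 0, 0))
  expect_error(soft_threshold(v, -1), ">= 0")
})

test_that("l1_bound_search finds the smallest feasible threshold", {
  e1 <- c(1, 0, 0, 0)
  expect_equal(l1_bound_search(e1, 1), 0)
  expect_equal(l1_bound_search(e1, 1.7), 0)
  v <- rnorm(6)
  expect_equal(l1_bound_search(v, sqrt(6)), 0)  # dense extreme is feasible
  # matches an independent fine-grid scan
  v2 <- c(2, 1, 1)
  delta <- l1_bound_search(v2, 1.2)
  expect_equal(delta, grid_l1_delta_oracle(v2, 1.2), tolerance = 1e-4)
  w <- soft_threshold(v2, delta); w <- w / sqrt(sum(w^2))
  expect_lte(sum(abs(w)), 1.2 + 1e-8)
  expect_error(l1_bound_search(v2, 0.9), ">= 1")
  expect_error(l1_bound_search(c(0, 0), 1.5), "nonzero")
})

test_that("occa_fit is the truncated SVD with adjusted signs", {
  fit <- occa_fit(diag(c(3, 2, 1)), 2)
  expect_equal(fit$d, c(3, 2))
  expect_equal(abs(fit$A), diag(3)[, 1:2], tolerance = 1e-12)
  expect_equal(fit$A, fit$B)
  # rank-1 recovery up to sign
  a <- c(0.6, 0.8); b <- c(1, 0, 0)
  f1 <- occa_fit(2.5 * tcrossprod(a, b), 1)
  expect_equal(abs(drop(f1$A)), a, tolerance = 1e-10)
  expect_equal(abs(drop(f1$B)), b, tolerance = 1e-10)
  expect_equal(f1$d, 2.5, tolerance = 1e-10)
  # truncation error equals the tail singular values (dense-SVD oracle)
  set.seed(31)
  Z <- matrix(rnorm(30), 6, 5)
  f3 <- occa_fit(Z, 3)
  resid <- Z - f3$A %*% (f3$d * t(f3$B))
  expect_equal(svd(resid)$d[1:2], svd(Z)$d[4:5], tolerance = 1e-10)
  expect_error(occa_fit(Z, 6), "min\\(p, q\\)")
})

test_that("unconstrained rank1_pmd reduces to the leading SVD triple", {
  set.seed(41)
  for (rep in 1:5) {
    Z <- matrix(rnorm(48), 8, 6)
    fit <- rank1_pmd(Z, 1, 1)
    s <- svd(Z, nu = 1, nv = 1)
    flip <- sign(sum(fit$alpha * s$u[, 1]))
    expect_equal(fit$alpha, flip * s$u[, 1], tolerance = 1e-6)
    expect_equal(fit$beta, flip * s$v[, 1], tolerance = 1e-6)
    expect_equal(fit$d, s$d[1], tolerance = 1e-8)
  }
})

test_that("rank1_pmd recovers a sparse rank-1 factor exactly", {
  a <- c(0.8, 0.6, 0, 0, 0); b <- c(0, 1, 0, 0)
  Z <- 5 * tcrossprod(a, b)
  fit <- rank1_pmd(Z, c1 = sum(abs(a)) / sqrt(5), c2 = 1 / sqrt(4) + 1e-9)
  expect_equal(abs(fit$alpha), a, tolerance = 1e-8)
  expect_equal(abs(fit$beta), b, tolerance = 1e-8)
  expect_equal(fit$d, 5, tolerance = 1e-8)
})

test_that("rank1_pmd attains the feasible-point oracle objective", {
  Z <- rbind(c(4, 0, 0), c(0, 3, 0), c(0, 0, 1))
  fit <- rank1_pmd(Z, 0.6, 0.6)
  oracle <- pmd_objective_oracle(Z, 0.6, 0.6, n_samples = 1e4, seed = 7)
  expect_gte(fit$d, oracle - 1e-3)
  # constraints hold at the optimum
  expect_equal(sum(fit$alpha^2), 1, tolerance = 1e-8)
  expect_lte(sum(abs(fit$alpha)), 0.6 * sqrt(3) + 1e-8)
  expect_lte(sum(abs(fit$beta)), 0.6 * sqrt(3) + 1e-8)
})

test_that("rank1_pmd rejects infeasible or degenerate inputs", {
  expect_error(rank1_pmd(matrix(0, 3, 3), 1, 1), "nonzero")
  expect_error(rank1_pmd(diag(3), 0.1, 1), "infeasible")
  expect_error(rank1_pmd(diag(3), 1.2, 1), "\\(0, 1\\]")
})

norm_mats <- function(n, p, q, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  Y <- matrix(rbinom(n * q, 1, 0.3), n, q)
  xn <- fit_normalizer(X); yn <- fit_normalizer(Y)
  list(Xn = apply_normalizer(xn, X), Yn = apply_normalizer(yn, Y))
}

test_that("deflation reconstructs Z exactly and stops on exhausted rank", {
  nm <- norm_mats(60, 7, 5, 51)
  params <- scca_params(c1 = 0.7, c2 = 0.7, m = 4)
  fit <- scca_fit(nm$Xn, nm$Yn, params)
  Z <- cross_product(nm$Xn, nm$Yn)
  recon <- fit$A %*% (fit$d * t(fit$B))
  Zres <- Z - recon
  # conservation: sum_k d_k a_k b_k' + Z^(m+1) = Z^(1)
  refit_res <- Z
  for (k in seq_along(fit$d))
    refit_res <- refit_res - fit$d[k] * tcrossprod(fit$A[, k], fit$B[, k])
  expect_equal(recon + refit_res, Z, tolerance = 1e-8)
  expect_lt(sqrt(sum((Zres - refit_res)^2)), 1e-8)

  # exact rank-2 with orthogonal sparse factors deflates to zero
  a1 <- c(1, 0, 0, 0); a2 <- c(0, 1, 0, 0)
  b1 <- c(0, 0, 1); b2 <- c(1, 0, 0)
  Z2 <- 3 * tcrossprod(a1, b1) + 2 * tcrossprod(a2, b2)
  # fabricate normalized data with this cross-product via SVD factors
  s <- svd(Z2)
  Xn <- diag(sqrt(s$d)) %*% t(s$u)
  Yn <- diag(sqrt(s$d)) %*% t(s$v)
  f2 <- suppressWarnings(scca_fit(Xn, Yn, scca_params(c1 = 1, c2 = 1,
                                                      m = 2)))
  Z3 <- Z2 - f2$A %*% (f2$d * t(f2$B))
  expect_lt(sqrt(sum(Z3^2)), 1e-8)
})

test_that("a single-component fit equals rank1_pmd", {
  nm <- norm_mats(40, 6, 4, 61)
  params <- scca_params(c1 = 0.6, c2 = 0.6, m = 1)
  fit <- scca_fit(nm$Xn, nm$Yn, params)
  ref <- rank1_pmd(cross_product(nm$Xn, nm$Yn), 0.6, 0.6, params)
  adj <- adjust_signs(cbind(ref$alpha), cbind(ref$beta))
  expect_equal(unname(fit$A), adj$A, tolerance = 1e-12)
  expect_equal(unname(fit$B), adj$B, tolerance = 1e-12)
  expect_equal(fit$d, ref$d, tolerance = 1e-12)
})

test_that("fitted components recover planted supports", {
  sim <- planted_benchmark(seed = 13)
  model <- scca(sim$X, sim$Y, c1 = 0.3, c2 = 0.3, m = 2)
  for (ci in 1:2) {
    supp_a <- sim$truth$components[[ci]]$sub_support
    supp_b <- sim$truth$components[[ci]]$se_support
    hit_a <- max(sapply(1:2, function(k)
      length(intersect(order(-abs(model$A[, k]))[1:5], supp_a))))
    hit_b <- max(sapply(1:2, function(k)
      length(intersect(order(-abs(model$B[, k]))[1:5], supp_b))))
    expect_gte(hit_a, 4)
    expect_gte(hit_b, 4)
  }
})

test_that("sign adjustment flips pairs keyed on the alpha maximum", {
  A <- cbind(c(-0.9, 0.1), c(0.2, 0.7))
  B <- cbind(c(0.5, -0.5), c(-0.3, 0.6))
  adj <- adjust_signs(A, B)
  expect_equal(adj$A[, 1], c(0.9, -0.1))
  expect_equal(adj$B[, 1], c(-0.5, 0.5))  # flipped together
  expect_equal(adj$A[, 2], A[, 2])        # already positive: untouched
  expect_equal(adj$B[, 2], B[, 2])
  # tie between +0.5 and -0.5: earliest index decides
  tieA <- cbind(c(0.5, -0.5)); tieB <- cbind(c(1, 1))
  expect_equal(adjust_signs(tieA, tieB)$A[, 1], c(0.5, -0.5))
  tieA2 <- cbind(c(-0.5, 0.5))
  expect_equal(adjust_signs(tieA2, tieB)$A[, 1], c(0.5, -0.5))
  # unpaired mode additionally makes the beta maximum positive
  un <- adjust_signs(A, B, paired = FALSE)
  expect_equal(un$B[, 1], c(0.5, -0.5))
})

test_that("canonical correlation is the Pearson correlation of the scores", {
  set.seed(71)
  Xn <- matrix(rnorm(20), 5, 4)
  alpha <- rnorm(4)
  expect_equal(canonical_correlation(Xn, Xn, alpha, alpha), 1)
  expect_equal(canonical_correlation(Xn, -Xn, alpha, alpha), -1)
  Yn <- matrix(rnorm(15), 5, 3)
  beta <- rnorm(3)
  u <- drop(Xn %*% alpha); v <- drop(Yn %*% beta)
  hand <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(canonical_correlation(Xn, Yn, alpha, beta), hand,
               tolerance = 1e-12)
  expect_warning(r <- canonical_correlation(Xn, Yn, rep(0, 4), beta),
                 "zero-variance")
  expect_true(is.na(r))
})

test_that("sparsity constraints hold for every fitted component", {
  for (seed in c(81, 82)) {
    nm <- norm_mats(50, 9, 7, seed)
    for (c1 in c(0.4, 0.8, 1)) {
      fit <- scca_fit(nm$Xn, nm$Yn, scca_params(c1 = c1, c2 = c1, m = 3))
      for (k in seq_along(fit$d)) {
        expect_equal(sum(fit$A[, k]^2), 1, tolerance = 1e-8)
        expect_equal(sum(fit$B[, k]^2), 1, tolerance = 1e-8)
        expect_lte(sum(abs(fit$A[, k])), c1 * sqrt(9) + 1e-8)
        expect_lte(sum(abs(fit$B[, k])), c1 * sqrt(7) + 1e-8)
      }
    }
  }
})

test_that("the unconstrained sparse fit matches the SVD fit", {
  nm <- norm_mats(80, 8, 6, 91)
  Z <- cross_product(nm$Xn, nm$Yn)
  sv <- svd(Z)$d
  expect_gt(min(sv[1:3] - sv[2:4]), 1e-6)  # separated singular values
  sfit <- scca_fit(nm$Xn, nm$Yn, scca_params(c1 = 1, c2 = 1, m = 3))
  ofit <- occa_fit(Z, 3)
  expect_lt(max(abs(sfit$A - ofit$A)), 1e-5)
  expect_lt(max(abs(sfit$B - ofit$B)), 1e-5)
})

test_that("decreasing c1 never densifies the first component", {
  nm <- norm_mats(70, 10, 8, 101)
  Z <- cross_product(nm$Xn, nm$Yn)
  grid <- c(1, 0.8, 0.6, 0.5, 0.4)
  nnz <- sapply(grid, function(c1)
    sum(rank1_pmd(Z, c1, 0.8)$alpha != 0))
  expect_true(all(diff(nnz) <= 0))
})

test_that("the PMD objective is non-decreasing across iterations", {
  nm <- norm_mats(60, 8, 6, 111)
  Z <- cross_product(nm$Xn, nm$Yn)
  # re-run the alternating updates manually, tracking the objective
  params <- scca_params(c1 = 0.5, c2 = 0.5, m = 1)
  beta <- svd(Z, nu = 0, nv = 1)$v[, 1]
  b1 <- 0.5 * sqrt(8); b2 <- 0.5 * sqrt(6)
  obj <- -Inf
  for (it in 1:50) {
    va <- drop(Z %*% beta)
    alpha <- soft_threshold(va, if (sum(abs(va)) / sqrt(sum(va^2)) <= b1) 0
                            else l1_bound_search(va, b1))
    alpha <- alpha / sqrt(sum(alpha^2))
    vb <- drop(crossprod(Z, alpha))
    beta <- soft_threshold(vb, if (sum(abs(vb)) / sqrt(sum(vb^2)) <= b2) 0
                           else l1_bound_search(vb, b2))
    beta <- beta / sqrt(sum(beta^2))
    new_obj <- drop(crossprod(alpha, Z %*% beta))
    expect_gte(new_obj, obj - 1e-10)
    obj <- new_obj
  }
})

test_that("permutation p-values separate planted signal from null", {
  sim <- planted_benchmark(seed = 17)
  xn <- fit_normalizer(sim$X); yn <- fit_normalizer(sim$Y)
  Xn <- apply_normalizer(xn, sim$X); Yn <- apply_normalizer(yn, sim$Y)
  params <- scca_params(c1 = 0.3, c2 = 0.3, m = 1)
  p <- permutation_pvalue(Xn, Yn, params, n_perm = 99, seed = 5)
  expect_equal(p, 1 / 100)  # no permutation beats a strong planted signal
  expect_identical(p, permutation_pvalue(Xn, Yn, params, n_perm = 99,
                                         seed = 5))
  nd <- generate_null_dataset(200, 12, 10, rate = 0.2, seed = 23)
  Xn0 <- apply_normalizer(fit_normalizer(nd$X), nd$X)
  Yn0 <- apply_normalizer(fit_normalizer(nd$Y), nd$Y)
  p0 <- permutation_pvalue(Xn0, Yn0, scca_params(c1 = 0.5, c2 = 0.5,
                                                 m = 1),
                           n_perm = 49, seed = 6)
  expect_gt(p0, 0.05)
})
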