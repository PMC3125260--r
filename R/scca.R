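# Canonical correlation of two binary profile spaces under the
# diagonal-covariance approximation: within-set covariances are replaced by
# the identity, so ordinary CCA reduces to the SVD of the cross-product
# matrix Z = Xn' Yn of the column-normalized data. The sparse variant adds
# L1 constraints on both weight vectors and solves each component as a
# penalized rank-one matrix decomposition (alternating soft-thresholded
# power iterations), extracting successive components by deflation:
#   Z^(k+1) = Z^(k) - d_k alpha_k beta_k' .

#' SCCA fitting parameters
#'
#' @param c1,c2 sparsity fractions in (0, 1] for the substructure and
#'   side-effect weight vectors. A unit-norm vector of length p has L1 norm
#'   between 1 and sqrt(p); the actual constraint is |alpha|_1 <= c1*sqrt(p)
#'   (and likewise for beta with q), so c = 1 is unconstrained and smaller
#'   values force sparser weights. c*sqrt(dim) must be >= 1 for a feasible
#'   unit-norm vector to exist.
#' @param m number of canonical components to extract.
#' @param tol convergence tolerance on the max absolute change of the
#'   weight vectors between alternating updates.
#' @param max_iter iteration cap per component.
#' @param init `"svd"` (deterministic, leading right singular vector) or
#'   `"random"` (unit Gaussian drawn from `seed`).
#' @param seed integer seed for `init = "random"`.
#' @return object of class `scca_params`.
#' @export
scca_params <- function(c1 = 0.05, c2 = 0.05, m = 20L, tol = 1e-7,
                        max_iter = 200L, init = c("svd", "random"),
                        seed = 1L) {
  init <- match.arg(init)
  if (c1 <= 0 || c1 > 1 || c2 <= 0 || c2 > 1)
    stop("c1 and c2 must lie in (0, 1]", call. = FALSE)
  if (m < 1L) stop("m must be a positive integer", call. = FALSE)
  if (tol <= 0 || max_iter < 1L) stop("invalid tol/max_iter", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, m = as.integer(m), tol = tol,
                 max_iter = as.integer(max_iter), init = init,
                 seed = as.integer(seed)),
            class = "scca_params")
}

#' Cross-product matrix of two normalized data sets
#'
#' @param Xn,Yn column-normalized matrices with the same number of rows.
#' @return the p x q matrix Z = Xn' Yn.
#' @export
cross_product <- function(Xn, Yn) {
  if (nrow(Xn) != nrow(Yn))
    stop("Xn and Yn must have the same number of rows", call. = FALSE)
  crossprod(Xn, Yn)
}

#' Soft-thresholding operator
#'
#' Componentwise `sign(v) * max(|v| - delta, 0)`, the proximal map of the
#' L1 penalty.
#'
#' @param v numeric vector.
#' @param delta threshold, `>= 0`.
#' @return shrunken vector of the same length.
#' @export
soft_threshold <- function(v, delta) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  sign(v) * pmax(abs(v) - delta, 0)
}

# L1 norm of soft_threshold(v, delta) rescaled to unit L2 norm; NA when the
# thresholded vector vanishes. Non-increasing in delta.
l1_after_threshold <- function(v, delta) {
  w <- soft_threshold(v, delta)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(NA_real_)
  sum(abs(w)) / nrm
}

#' Find the soft-threshold level that meets an L1 bound
#'
#' Returns the smallest `delta >= 0` such that the unit-L2 rescaling of
#' `soft_threshold(v, delta)` has L1 norm at most `bound`, located by
#' bisection on `[0, max|v_i|]` to within 1e-10.
#'
#' @param v nonzero numeric vector.
#' @param bound L1 bound; must be `>= 1` since no unit-norm vector has a
#'   smaller L1 norm.
#' @return the threshold delta.
#' @export
l1_bound_search <- function(v, bound) {
  if (bound < 1)
    stop("bound must be >= 1: no unit-norm vector has L1 norm < 1",
         call. = FALSE)
  if (all(v == 0)) stop("v must be nonzero", call. = FALSE)
  if (l1_after_threshold(v, 0) <= bound) return(0)
  lo <- 0
  hi <- max(abs(v))
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    l1 <- l1_after_threshold(v, mid)
    if (!is.na(l1) && l1 > bound) lo <- mid else hi <- mid
  }
  hi
}

# Exact threshold level at which the unit-L2 rescaled soft-threshold of v
# meets the L1 bound. On each interval of delta between consecutive sorted
# magnitudes the active set is fixed and the squared ratio condition
# (S1 - k d)^2 = bound^2 (S2 - 2 d S1 + k d^2) is quadratic in d, so the
# unique crossing of the (monotone) L1/L2 ratio can be solved per segment.
# Agrees with l1_bound_search to its bisection tolerance; falls back to it
# if no segment root verifies (degenerate ties).
l1_threshold_exact <- function(v, bound) {
  if (l1_after_threshold(v, 0) <= bound) return(0)
  a <- sort(abs(v[v != 0]), decreasing = TRUE)
  s1 <- cumsum(a)
  s2 <- cumsum(a^2)
  b2 <- bound^2
  n <- length(a)
  for (k in n:1) {
    lo <- if (k < n) a[k + 1L] else 0
    hi <- a[k]
    if (hi <= lo) next
    A <- k * (k - b2)
    B <- 2 * s1[k] * (b2 - k)
    C <- s1[k]^2 - b2 * s2[k]
    disc <- B^2 - 4 * A * C
    if (disc < 0) next
    for (root in (-B + c(-1, 1) * sqrt(disc)) / (2 * A)) {
      if (root >= lo - 1e-12 && root < hi) {
        root <- min(max(root, lo), hi)
        l1 <- l1_after_threshold(v, root)
        if (!is.na(l1) && abs(l1 - bound) < 1e-6) return(root)
      }
    }
  }
  l1_bound_search(v, bound)
}

# One constrained update: maximizer of <z, w> subject to |w|_2 <= 1 and
# |w|_1 <= bound, i.e. soft-thresholding at the exact level, rescaled to
# unit L2 norm. When the largest |z| entries are tied and the thresholded
# family cannot reach the bound at unit L2 norm, the optimum instead has
# the L1 constraint binding at L2 norm < 1: equal mass bound/k on the k
# tied coordinates.
pmd_update <- function(z, bound) {
  if (all(z == 0)) return(z)
  delta <- l1_threshold_exact(z, bound)
  w <- soft_threshold(z, delta)
  if (all(w == 0) || sum(abs(w)) / sqrt(sum(w^2)) > bound + 1e-9) {
    top <- which(abs(z) > max(abs(z)) * (1 - 1e-12))
    w <- numeric(length(z))
    w[top] <- sign(z[top]) * bound / length(top)
    return(w)
  }
  w / sqrt(sum(w^2))
}

#' Rank-one penalized matrix decomposition
#'
#' Maximizes `alpha' Z beta` over unit-L2 vectors subject to
#' `|alpha|_1 <= c1*sqrt(p)` and `|beta|_1 <= c2*sqrt(q)` by alternating
#' soft-thresholded updates (each step solves its constrained subproblem
#' exactly), so the objective is non-decreasing across iterations.
#'
#' @param Z nonzero p x q real matrix.
#' @param c1,c2 sparsity fractions in (0, 1].
#' @param params an [scca_params()] object supplying `tol`, `max_iter`,
#'   `init` and `seed`; its own `c1`/`c2` are ignored in favour of the
#'   explicit arguments.
#' @return list with unit-norm sparse vectors `alpha`, `beta`, the
#'   objective value `d = alpha' Z beta >= 0`, `iterations` and `converged`.
#' @export
rank1_pmd <- function(Z, c1, c2, params = scca_params(c1 = c1, c2 = c2)) {
  p <- nrow(Z); q <- ncol(Z)
  if (all(Z == 0)) stop("Z must be nonzero", call. = FALSE)
  if (c1 <= 0 || c1 > 1 || c2 <= 0 || c2 > 1)
    stop("c1 and c2 must lie in (0, 1]", call. = FALSE)
  b1 <- c1 * sqrt(p)
  b2 <- c2 * sqrt(q)
  if (b1 < 1 || b2 < 1)
    stop("infeasible sparsity: need c1 >= 1/sqrt(p) and c2 >= 1/sqrt(q)",
         call. = FALSE)
  run_from <- function(beta0, max_iter) {
    alpha <- rep(0, p)
    beta <- beta0
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      alpha_new <- pmd_update(drop(Z %*% beta), b1)
      beta_new <- pmd_update(drop(crossprod(Z, alpha_new)), b2)
      delta <- max(max(abs(alpha_new - alpha)), max(abs(beta_new - beta)))
      alpha <- alpha_new
      beta <- beta_new
      if (delta < params$tol) { converged <- TRUE; break }
    }
    d <- drop(crossprod(alpha, Z %*% beta))
    if (d < 0) { beta <- -beta; d <- -d }
    list(alpha = alpha, beta = beta, d = d, iterations = iter,
         converged = converged)
  }
  starts <- list(switch(params$init,
    svd = svd(Z, nu = 0L, nv = 1L)$v[, 1L],
    random = {
      set.seed(params$seed)
      b <- stats::rnorm(q)
      b / sqrt(sum(b^2))
    }))
  # The alternating scheme is multimodal when the L1 constraints bind;
  # deterministic axis-aligned restarts on the strongest columns of Z
  # (beta side) and strongest rows (alpha side, mapped to a beta start by
  # one update sweep) recover the dominant sparse optimum in practice.
  if (c1 < 1 || c2 < 1) {
    for (j in utils::head(order(-colSums(Z^2)), 4L)) {
      e <- numeric(q); e[j] <- 1
      starts <- c(starts, list(e))
    }
    for (i in utils::head(order(-rowSums(Z^2)), 4L)) {
      e <- numeric(p); e[i] <- 1
      starts <- c(starts, list(pmd_update(drop(crossprod(Z, e)), b2)))
    }
  }
  # screen all starts with a short run, then polish the most promising one
  # to full convergence (the objective ordering stabilizes within a few
  # sweeps); a single start is simply run in full
  if (length(starts) > 1L) {
    screened <- lapply(starts, run_from,
                       max_iter = min(15L, params$max_iter))
    pick <- which.max(vapply(screened, `[[`, numeric(1), "d"))
    if (screened[[pick]]$converged) return(screened[[pick]])
    starts <- list(screened[[pick]]$beta)
  }
  best <- run_from(starts[[1L]], params$max_iter)
  if (!best$converged)
    warning("rank1_pmd did not converge in ", params$max_iter,
            " iterations; returning current iterate", call. = FALSE)
  best
}

#' Adjust weight-vector signs for interpretability
#'
#' For each component the pair (alpha_k, beta_k) is flipped together when
#' the entry of alpha_k with the largest absolute value is negative, so that
#' entry becomes positive while the objective alpha' Z beta is preserved.
#' Ties are broken by the earliest index. With `paired = FALSE`, beta_k is
#' additionally flipped on its own when its largest-|.| entry is negative
#' (this changes the sign of the objective and of rho).
#'
#' @param A p x m weight matrix.
#' @param B q x m weight matrix.
#' @param paired flip (alpha, beta) as a pair keyed on alpha (default).
#' @return list with adjusted `A` and `B`.
#' @export
adjust_signs <- function(A, B, paired = TRUE) {
  for (k in seq_len(ncol(A))) {
    if (all(A[, k] == 0)) next
    i <- which.max(abs(A[, k]))
    if (A[i, k] < 0) {
      A[, k] <- -A[, k]
      B[, k] <- -B[, k]
    }
    if (!paired && !all(B[, k] == 0)) {
      j <- which.max(abs(B[, k]))
      if (B[j, k] < 0) B[, k] <- -B[, k]
    }
  }
  list(A = A, B = B)
}

#' Canonical correlation coefficient of one component
#'
#' Pearson correlation between the canonical scores u_i = alpha' x_i and
#' v_i = beta' y_i over the rows of the (normalized) data.
#'
#' @param Xn,Yn normalized data matrices with equal row counts.
#' @param alpha,beta weight vectors.
#' @return correlation in [-1, 1], or `NA` when either score has zero
#'   variance.
#' @export
canonical_correlation <- function(Xn, Yn, alpha, beta) {
  u <- drop(Xn %*% alpha)
  v <- drop(Yn %*% beta)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("degenerate canonical component: zero-variance score",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(u, v)
}

#' Ordinary CCA weights under the diagonal-covariance approximation
#'
#' With within-set covariances replaced by the identity, the canonical
#' weight pairs are the leading singular vectors of Z, so the fit is a
#' truncated SVD.
#'
#' @param Z cross-product matrix.
#' @param m number of components, `1 <= m <= min(p, q)`.
#' @return list with `A` (p x m), `B` (q x m) and singular values `d`.
#' @export
occa_fit <- function(Z, m) {
  if (m < 1L || m > min(dim(Z)))
    stop("m must lie in 1..min(p, q)", call. = FALSE)
  s <- svd(Z, nu = m, nv = m)
  adj <- adjust_signs(s$u, s$v)
  list(A = adj$A, B = adj$B, d = s$d[seq_len(m)])
}

#' Fit sparse CCA on normalized data by deflated penalized decomposition
#'
#' Extracts `params$m` components: each is a [rank1_pmd()] fit of the
#' current matrix `Z^(k)`, after which `d_k alpha_k beta_k'` is subtracted
#' (deflation). `d_k` is taken as `alpha_k' Z^(k) beta_k`, which makes the
#' deflation identity `sum_k d_k alpha_k beta_k' + Z^(m+1) = Z^(1)` exact.
#' Canonical correlations are computed on the training rows; signs are
#' adjusted pairwise per [adjust_signs()].
#'
#' @param Xn,Yn normalized matrices (same rows; columns = features).
#' @param params an [scca_params()] object.
#' @return object of class `cca_model` without normalizers (see [scca()]
#'   for the front end that carries them): fields `A`, `B`, `d`, `rho`,
#'   `params`, `method`.
#' @export
scca_fit <- function(Xn, Yn, params = scca_params()) {
  Z <- cross_product(Xn, Yn)
  p <- nrow(Z); q <- ncol(Z)
  A <- matrix(0, p, 0); B <- matrix(0, q, 0)
  d <- numeric(0); rho <- numeric(0)
  Zk <- Z
  for (k in seq_len(params$m)) {
    if (sqrt(sum(Zk^2)) < 1e-12) {
      message("scca_fit: Z numerically zero after ", k - 1L,
              " components; stopping early")
      break
    }
    fit <- rank1_pmd(Zk, params$c1, params$c2, params)
    if (all(fit$alpha == 0) || all(fit$beta == 0)) {
      message("scca_fit: degenerate component ", k, "; stopping early")
      break
    }
    Zk <- Zk - fit$d * tcrossprod(fit$alpha, fit$beta)
    A <- cbind(A, fit$alpha)
    B <- cbind(B, fit$beta)
    d <- c(d, fit$d)
    rho <- c(rho, canonical_correlation(Xn, Yn, fit$alpha, fit$beta))
  }
  adj <- adjust_signs(A, B)  # pairwise flip: d and rho are preserved
  rownames(adj$A) <- colnames(Xn)
  rownames(adj$B) <- colnames(Yn)
  colnames(adj$A) <- colnames(adj$B) <- paste0("comp", seq_along(d))
  structure(list(A = adj$A, B = adj$B, d = d, rho = rho,
                 x_norm = NULL, y_norm = NULL, params = params,
                 method = "scca"),
            class = "cca_model")
}

#' Fit sparse CCA on raw binary profiles
#'
#' Front end for [scca_fit()]: fits per-column normalizers on the rows of
#' `X` and `Y` (which must already be row-aligned), normalizes, fits, and
#' stores the normalizers in the model for later prediction.
#'
#' @param X drugs x substructures binary matrix.
#' @param Y drugs x side-effects binary matrix, same rows.
#' @param c1,c2,m,... passed to [scca_params()].
#' @return fitted `cca_model` with normalizers attached.
#' @export
scca <- function(X, Y, c1 = 0.05, c2 = 0.05, m = 20L, ...) {
  if (!identical(rownames(X), rownames(Y)))
    stop("X and Y must be row-aligned (see align_by_ids)", call. = FALSE)
  params <- scca_params(c1 = c1, c2 = c2, m = m, ...)
  xn <- fit_normalizer(X)
  yn <- fit_normalizer(Y)
  model <- scca_fit(apply_normalizer(xn, X), apply_normalizer(yn, Y), params)
  model$x_norm <- xn
  model$y_norm <- yn
  model
}

#' Fit ordinary CCA on raw binary profiles
#'
#' Normalizes the columns, forms Z = Xn' Yn, and takes its truncated SVD as
#' the canonical weights; canonical correlations are computed on the
#' training rows.
#'
#' @param X,Y row-aligned binary profile matrices.
#' @param m number of components.
#' @return fitted `cca_model` with normalizers attached.
#' @export
occa <- function(X, Y, m = 20L) {
  if (!identical(rownames(X), rownames(Y)))
    stop("X and Y must be row-aligned (see align_by_ids)", call. = FALSE)
  xn <- fit_normalizer(X)
  yn <- fit_normalizer(Y)
  Xn <- apply_normalizer(xn, X)
  Yn <- apply_normalizer(yn, Y)
  fit <- occa_fit(cross_product(Xn, Yn), m)
  rho <- vapply(seq_len(m), function(k)
    suppressWarnings(canonical_correlation(Xn, Yn, fit$A[, k], fit$B[, k])),
    numeric(1))
  rownames(fit$A) <- colnames(X)
  rownames(fit$B) <- colnames(Y)
  colnames(fit$A) <- colnames(fit$B) <- paste0("comp", seq_len(m))
  structure(list(A = fit$A, B = fit$B, d = fit$d, rho = rho,
                 x_norm = xn, y_norm = yn,
                 params = list(m = as.integer(m)), method = "occa"),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(toupper(x$method), "model:", nrow(x$A), "substructures,",
      nrow(x$B), "side-effects,", length(x$d), "components\n")
  if (length(x$rho))
    cat("canonical correlations:",
        paste(sprintf("%.3f", x$rho), collapse = " "), "\n")
  invisible(x)
}

#' Permutation p-value for a canonical correlation
#'
#' The rows of Yn are permuted `n_perm` times; each time the first
#' component is refitted and its canonical correlation recorded. The
#' p-value uses the add-one estimator
#' `(1 + #\{rho*_1 >= rho_observed\}) / (1 + n_perm)`, where the observed
#' value is the correlation of component `component_index` on the
#' unpermuted data.
#'
#' @param Xn,Yn normalized matrices.
#' @param params [scca_params()] used for the fits.
#' @param component_index which observed component to test.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(Xn, Yn, params = scca_params(),
                               component_index = 1L, n_perm = 99L,
                               seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs_params <- params
  obs_params$m <- as.integer(component_index)
  obs <- scca_fit(Xn, Yn, obs_params)
  if (length(obs$rho) < component_index)
    stop("model has fewer than ", component_index, " components",
         call. = FALSE)
  rho_obs <- obs$rho[component_index]
  one <- params
  one$m <- 1L
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(Yn))
    fit <- scca_fit(Xn, Yn[perm, , drop = FALSE], one)
    if (length(fit$rho) && !is.na(fit$rho[1]) && fit$rho[1] >= rho_obs)
      hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}
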