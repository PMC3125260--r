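# Side-effect prediction for query fingerprints from a fitted CCA model,
# and extraction of the correlated substructure/side-effect sets encoded in
# each component.

# Moore-Penrose pseudo-inverse via SVD; singular values below
# tol * max(singular value) are truncated (B can be rank-deficient under
# strong sparsity).
pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

check_query <- function(model, x) {
  if (is.null(model$x_norm) || is.null(model$y_norm))
    stop("model carries no normalizers; fit with scca()/occa()",
         call. = FALSE)
  x <- as_row_matrix(x)
  if (ncol(x) != nrow(model$A))
    stop("query has ", ncol(x), " features but model expects ",
         nrow(model$A), call. = FALSE)
  x
}

score_dimnames <- function(model, x, S) {
  dimnames(S) <- list(rownames(x), rownames(model$B))
  S
}

#' Predict side-effect profiles by pseudo-inverse reconstruction
#'
#' The query fingerprint is normalized with the training-set normalizer and
#' projected to its canonical components u = A' x. The side-effect profile
#' estimate is the least-squares solution of B' y = u, i.e.
#' y_hat = pinv(B') u, de-normalized back to the side-effect scale with the
#' training-set means and standard deviations.
#'
#' @param model fitted `cca_model` with normalizers.
#' @param x query fingerprint: a p-vector in \{0,1\} or a queries x p
#'   matrix.
#' @return queries x q score matrix (a single query gives one row), with
#'   attribute `method = "pinv"`.
#' @export
predict_profile_pinv <- function(model, x) {
  x <- check_query(model, x)
  xt <- apply_normalizer(model$x_norm, x)
  U <- xt %*% model$A
  P <- pseudo_inverse(t(model$B))           # q x m
  S <- denormalize(model$y_norm, U %*% t(P))
  structure(score_dimnames(model, x, S), method = "pinv")
}

#' Predict side-effect scores by correlation-weighted components
#'
#' Prediction score s(x) = B Lambda A' x_norm, the sum over components of
#' rho_k (alpha_k' x_norm) beta_k: each canonical projection of the query
#' is propagated to the side-effect space through beta_k, weighted by the
#' component's canonical correlation. Scores are left in canonical units
#' (not de-normalized); they are used for ranking side-effects. This is the
#' default predictor.
#'
#' @inheritParams predict_profile_pinv
#' @return queries x q score matrix with attribute `method = "weighted"`.
#' @export
predict_score_weighted <- function(model, x) {
  x <- check_query(model, x)
  rho <- model$rho
  if (anyNA(rho)) {
    warning("NA canonical correlations treated as 0", call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  xt <- apply_normalizer(model$x_norm, x)
  S <- xt %*% model$A %*% (diag(rho, nrow = length(rho)) %*% t(model$B))
  structure(score_dimnames(model, x, S), method = "weighted")
}

#' Predict method dispatcher for cca_model
#'
#' @param object fitted `cca_model`.
#' @param x query fingerprint vector or matrix.
#' @param method `"weighted"` (default, correlation-weighted scores) or
#'   `"pinv"` (pseudo-inverse profile reconstruction).
#' @param ... unused.
#' @return score matrix; see the two predictors.
#' @export
predict.cca_model <- function(object, x, method = c("weighted", "pinv"),
                              ...) {
  method <- match.arg(method)
  switch(method,
         weighted = predict_score_weighted(object, x),
         pinv = predict_profile_pinv(object, x))
}

#' Extract correlated substructure/side-effect sets from a model
#'
#' For each component, returns the substructures and side-effects whose
#' absolute weight exceeds `min_abs_weight`, sorted by decreasing absolute
#' weight, together with the component's canonical correlation.
#'
#' @param model fitted `cca_model`.
#' @param min_abs_weight weight magnitude threshold (default 0 keeps the
#'   nonzero support).
#' @param pvalues optional numeric vector of per-component p-values to
#'   attach.
#' @return list of `component_set` objects with fields `component_index`,
#'   `substructures` and `side_effects` (data frames `feature`, `weight`),
#'   `rho` and optional `pvalue`.
#' @export
extract_component_sets <- function(model, min_abs_weight = 0,
                                   pvalues = NULL) {
  stopifnot(min_abs_weight >= 0)
  pick <- function(w, names) {
    keep <- which(abs(w) > min_abs_weight)
    keep <- keep[order(-abs(w[keep]), keep)]
    data.frame(feature = names[keep], weight = w[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  lapply(seq_along(model$d), function(k) {
    structure(list(
      component_index = k,
      substructures = pick(model$A[, k], rownames(model$A)),
      side_effects = pick(model$B[, k], rownames(model$B)),
      rho = model$rho[k],
      pvalue = if (!is.null(pvalues)) pvalues[k] else NA_real_),
      class = "component_set")
  })
}

#' @export
print.component_set <- function(x, n = 5L, ...) {
  cat("component", x$component_index, sprintf("(rho = %.3f)", x$rho), "\n")
  cat(" substructures:",
      paste(utils::head(x$substructures$feature, n), collapse = ", "), "\n")
  cat(" side-effects: ",
      paste(utils::head(x$side_effects$feature, n), collapse = ", "), "\n")
  invisible(x)
}
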