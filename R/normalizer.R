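# Per-column centering and scaling fitted on training rows only. Standard
# deviations use the population convention (divisor n), kept consistent
# between fitting and de-normalization. Columns constant on the training rows
# are flagged; normalization substitutes sd = 1 for them so the centered
# column becomes identically zero and the feature is inert downstream.

#' Fit a per-column normalizer
#'
#' Computes column means and population standard deviations (divisor n) on
#' the rows of `M`, flagging zero-variance columns.
#'
#' @param M numeric matrix (training rows x features).
#' @return object of class `normalizer` with fields `means`, `sds`,
#'   `zero_var_mask` and `col_names`.
#' @export
fit_normalizer <- function(M) {
  if (!is.matrix(M) || nrow(M) < 2L)
    stop("need a matrix with at least 2 rows to fit a normalizer",
         call. = FALSE)
  means <- colMeans(M)
  vars <- colMeans(M^2) - means^2
  vars[vars < 0] <- 0  # guard round-off
  sds <- sqrt(vars)
  mask <- sds < .Machine$double.eps^0.5
  sds[mask] <- 0
  structure(list(means = means, sds = sds, zero_var_mask = mask,
                 col_names = colnames(M)),
            class = "normalizer")
}

#' @export
print.normalizer <- function(x, ...) {
  cat("normalizer:", length(x$means), "columns,",
      sum(x$zero_var_mask), "zero-variance\n")
  invisible(x)
}

check_norm_dim <- function(norm, M) {
  if (ncol(M) != length(norm$means))
    stop("matrix has ", ncol(M), " columns but normalizer was fitted on ",
         length(norm$means), call. = FALSE)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
}

#' Center and scale a matrix with a fitted normalizer
#'
#' Entry (i, j) becomes (M_ij - mean_j) / sd_j. Zero-variance columns use a
#' substituted sd of 1, so values equal to the training constant map to 0.
#'
#' @param norm a [fit_normalizer()] object.
#' @param M numeric matrix (or a single row as a vector) with matching
#'   columns.
#' @return real matrix of the same shape.
#' @export
apply_normalizer <- function(norm, M) {
  M <- as_row_matrix(M)
  check_norm_dim(norm, M)
  sds <- ifelse(norm$zero_var_mask, 1, norm$sds)
  out <- sweep(M, 2L, norm$means, "-")
  sweep(out, 2L, sds, "/")
}

#' Undo normalization with the training-set mean and standard deviation
#'
#' Entry (i, j) becomes V_ij * sd_j + mean_j, the inverse of
#' [apply_normalizer()]. For zero-variance columns sd_j = 0, so every value
#' de-normalizes to the training constant (the column mean).
#'
#' @param norm a [fit_normalizer()] object.
#' @param V real matrix in normalized units.
#' @return matrix on the original scale.
#' @export
denormalize <- function(norm, V) {
  V <- as_row_matrix(V)
  check_norm_dim(norm, V)
  out <- sweep(V, 2L, norm$sds, "*")
  sweep(out, 2L, norm$means, "+")
}
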