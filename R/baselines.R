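# Baseline side-effect predictors: random assignment by training
# prevalence, k-nearest-neighbour vote on fingerprint similarity, and one
# SVM classifier per side-effect term.

#' Nearest-neighbour parameters
#'
#' @param k neighbour count.
#' @param similarity `"jaccard"` (Tanimoto, the fingerprint standard),
#'   `"cosine"` or `"dot"`.
#' @return object of class `nn_params`.
#' @export
nn_params <- function(k = 10L, similarity = c("jaccard", "cosine", "dot")) {
  similarity <- match.arg(similarity)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), similarity = similarity),
            class = "nn_params")
}

#' SVM parameters
#'
#' The RBF kernel is parameterized as
#' `k(x, x') = exp(-|x - x'|^2 / (2 sigma^2))`.
#'
#' @param kernel `"rbf"`, `"linear"` or `"poly"`.
#' @param sigma RBF width (> 0).
#' @param C regularization cost (> 0).
#' @param degree polynomial degree (poly kernel only).
#' @return object of class `svm_params`.
#' @export
svm_params <- function(kernel = c("rbf", "linear", "poly"), sigma = 0.2,
                       C = 1, degree = 3L) {
  kernel <- match.arg(kernel)
  if (sigma <= 0 || C <= 0) stop("sigma and C must be > 0", call. = FALSE)
  structure(list(kernel = kernel, sigma = sigma, C = C,
                 degree = as.integer(degree)),
            class = "svm_params")
}

#' Random-assignment baseline scores
#'
#' Each side-effect's training prevalence f_j becomes the success
#' probability of an independent 0/1 draw per test drug (`mode = "binary"`,
#' as in the random-assignment description); `mode = "prevalence"` instead
#' emits f_j itself for every test drug, a deterministic diagnostic
#' variant.
#'
#' @param train_Y training drugs x side-effects binary matrix.
#' @param test_ids character ids of the test drugs.
#' @param seed integer RNG seed.
#' @param mode `"binary"` or `"prevalence"`.
#' @return test drugs x side-effects score matrix.
#' @export
random_scores <- function(train_Y, test_ids, seed = 1L,
                          mode = c("binary", "prevalence")) {
  mode <- match.arg(mode)
  if (nrow(train_Y) == 0L) stop("empty training labels", call. = FALSE)
  f <- colMeans(train_Y)
  nt <- length(test_ids)
  S <- if (mode == "prevalence") {
    matrix(f, nt, length(f), byrow = TRUE)
  } else {
    set.seed(seed)
    matrix(stats::rbinom(nt * length(f), 1L, rep(f, each = nt)),
           nt, length(f))
  }
  dimnames(S) <- list(test_ids, colnames(train_Y))
  S
}

# test x train similarity matrix for binary fingerprints
fingerprint_similarity <- function(test_X, train_X, similarity) {
  inter <- tcrossprod(test_X, train_X)
  switch(similarity,
    dot = inter,
    cosine = {
      dn <- outer(sqrt(rowSums(test_X^2)), sqrt(rowSums(train_X^2)))
      s <- inter / dn
      s[dn == 0] <- 0
      s
    },
    jaccard = {
      un <- outer(rowSums(test_X), rowSums(train_X), "+") - inter
      s <- inter / un
      s[un == 0] <- 0  # two empty fingerprints: no evidence of similarity
      s
    })
}

#' k-nearest-neighbour baseline scores
#'
#' For each test drug, the k training drugs with the most similar
#' fingerprints are found; the score for side-effect j is k'/k where k' of
#' the k neighbours carry that side-effect. Similarity ties at the
#' neighbourhood boundary are broken by ascending training-drug id.
#'
#' @param train_X,train_Y training fingerprints and labels (row-aligned).
#' @param test_X test fingerprints in the same column space.
#' @param params an [nn_params()] object.
#' @return test drugs x side-effects score matrix with values in
#'   \{0, 1/k, ..., 1\}.
#' @export
nn_scores <- function(train_X, train_Y, test_X, params = nn_params()) {
  k <- params$k
  if (k > nrow(train_X))
    stop("k exceeds the number of training drugs", call. = FALSE)
  sim <- fingerprint_similarity(test_X, train_X, params$similarity)
  ids <- rownames(train_X)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(nrow(train_X)))
  S <- matrix(0, nrow(test_X), ncol(train_Y),
              dimnames = list(rownames(test_X), colnames(train_Y)))
  for (i in seq_len(nrow(test_X))) {
    nb <- order(-sim[i, ], ids)[seq_len(k)]
    S[i, ] <- colSums(train_Y[nb, , drop = FALSE]) / k
  }
  S
}

#' Per-side-effect SVM baseline scores
#'
#' One binary support-vector classifier is trained per side-effect column;
#' the score is the signed decision value oriented so that positive means
#' the side-effect is predicted present. Side-effects with a single class
#' in the training data cannot be learned; their column is the constant
#' value of that class (0 or 1) and a message is logged.
#'
#' @param train_X,train_Y training fingerprints and labels (row-aligned).
#' @param test_X test fingerprints.
#' @param params an [svm_params()] object.
#' @return test drugs x side-effects decision-value matrix.
#' @export
svm_scores <- function(train_X, train_Y, test_X, params = svm_params()) {
  kern <- switch(params$kernel, rbf = "radial", linear = "linear",
                 poly = "polynomial")
  gamma <- if (params$kernel == "rbf") 1 / (2 * params$sigma^2) else 1
  S <- matrix(0, nrow(test_X), ncol(train_Y),
              dimnames = list(rownames(test_X), colnames(train_Y)))
  degenerate <- character(0)
  for (j in seq_len(ncol(train_Y))) {
    yj <- train_Y[, j]
    if (length(unique(yj)) < 2L) {
      S[, j] <- yj[1]
      degenerate <- c(degenerate, colnames(train_Y)[j])
      next
    }
    fit <- e1071::svm(x = train_X, y = factor(yj, levels = c(0, 1)),
                      scale = FALSE, kernel = kern, cost = params$C,
                      gamma = gamma, degree = params$degree, coef0 = 1,
                      tolerance = 1e-6)
    pred <- stats::predict(fit, test_X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # libsvm's decision value is positive for the class named first in the
    # column label; orient so positive always means label 1
    if (startsWith(colnames(dv)[1], "0/")) dv <- -dv
    S[, j] <- dv[, 1]
  }
  if (length(degenerate))
    message("svm_scores: single-class side-effects given constant scores: ",
            paste(utils::head(degenerate, 10L), collapse = ", "),
            if (length(degenerate) > 10L) ", ...")
  S
}
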