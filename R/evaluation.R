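# Cross-validation harness and metrics: K-fold split shared across
# methods, pooled ("global") ROC AUC over all drug x side-effect pairs,
# per-side-effect AUC, and per-drug top-k accuracy.

#' Split drug ids into K folds
#'
#' Ids are randomly permuted from `seed` and dealt round-robin, so fold
#' sizes differ by at most one. The assignment is computed once per
#' experiment and shared across methods so that every method sees the same
#' training and test drugs.
#'
#' @param ids character drug ids.
#' @param K number of folds (2 <= K <= length(ids)).
#' @param seed integer RNG seed.
#' @return object of class `fold_assignment`: `fold_of`, a named integer
#'   vector mapping id -> fold in 1..K, and `K`.
#' @export
kfold_split <- function(ids, K = 5L, seed = 1L) {
  n <- length(ids)
  if (K < 2L || K > n) stop("K must lie in 2..length(ids)", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  set.seed(seed)
  perm <- sample(ids)
  fold <- rep_len(seq_len(K), n)
  structure(list(fold_of = stats::setNames(fold[match(ids, perm)], ids),
                 K = as.integer(K)),
            class = "fold_assignment")
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Equals the probability that a random positive outscores a random
#' negative, with tied score pairs counting one half; identical to the
#' area under the trapezoidal ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length.
#' @return AUC in [0, 1], or `NA` when labels contain a single class.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks give half credit to ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Global AUC over pooled drug x side-effect pairs
#'
#' Flattens the score and label matrices and computes one merged ROC AUC,
#' the "global ROC" evaluation.
#'
#' @param scores,labels matrices of identical shape.
#' @return pooled AUC, or `NA` if only one class is present.
#' @export
global_auc <- function(scores, labels) {
  stopifnot(identical(dim(scores), dim(labels)))
  roc_auc(as.vector(scores), as.vector(labels))
}

#' Per-side-effect AUC vector
#'
#' One ROC AUC per column; columns lacking both classes give `NA`.
#'
#' @param scores,labels matrices of identical shape (drugs x side-effects).
#' @return named numeric vector of length q.
#' @export
per_label_auc <- function(scores, labels) {
  stopifnot(identical(dim(scores), dim(labels)))
  stats::setNames(
    vapply(seq_len(ncol(scores)),
           function(j) roc_auc(scores[, j], labels[, j]), numeric(1)),
    colnames(scores))
}

#' Top-k prediction accuracy for one drug
#'
#' Fraction of the k top-scoring side-effects that the drug actually has.
#' Ranking is by decreasing score with ties broken by ascending column
#' index (stable).
#'
#' @param scores numeric q-vector of prediction scores for one drug.
#' @param labels 0/1 q-vector of true side-effects.
#' @param k how many top predictions to assess (k <= q).
#' @return accuracy in [0, 1].
#' @export
topk_accuracy <- function(scores, labels, k) {
  if (k < 1L || k > length(scores))
    stop("k must lie in 1..length(scores)", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord[seq_len(k)]])
}

# stable small-integer stream derived from one experiment seed
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 69069 + i * 7919) %% 2147483629)
}

fit_and_score <- function(method, train_X, train_Y, test_X, fold_seed) {
  name <- method$name
  pars <- method$params
  if (name %in% c("scca", "occa")) {
    model <- if (name == "scca") {
      do.call(scca, c(list(X = train_X, Y = train_Y), pars))
    } else {
      occa(train_X, train_Y, m = if (is.null(pars$m)) 20L else pars$m)
    }
    predictor <- if (is.null(method$predictor)) "weighted" else
      method$predictor
    return(predict(model, test_X, method = predictor))
  }
  switch(name,
    random = random_scores(train_Y, rownames(test_X), seed = fold_seed,
                           mode = if (is.null(pars$mode)) "binary" else
                             pars$mode),
    nn = nn_scores(train_X, train_Y, test_X, do.call(nn_params, pars)),
    svm = svm_scores(train_X, train_Y, test_X, do.call(svm_params, pars)),
    stop("unknown method: ", name, call. = FALSE))
}

#' Run a K-fold cross-validation experiment for one method
#'
#' Splits the drugs into folds, and for each fold fits the method (models
#' and normalizers see training rows only) and scores the held-out drugs.
#' Scores are assembled into one drugs x side-effects matrix in the input
#' row order, so the result does not depend on fold processing order.
#'
#' @param X,Y row-aligned binary profile matrices.
#' @param method list describing the method: `name` one of `"scca"`,
#'   `"occa"`, `"nn"`, `"svm"`, `"random"`; `params` a list of its
#'   parameters; for the CCA methods an optional `predictor`
#'   (`"weighted"`/`"pinv"`).
#' @param K number of folds.
#' @param seed integer seed controlling the split and any stochastic
#'   method, via per-fold derived substreams.
#' @param topk per-drug accuracy cutoffs to report; values exceeding q are
#'   dropped.
#' @param folds optional precomputed [kfold_split()] assignment, to share
#'   one split across methods.
#' @return object of class `evaluation_report`: pooled `scores`/`labels`
#'   matrices, `global_auc`, `per_label_auc` (with `mean_label_auc` over
#'   defined entries), `topk_accuracy` (list of per-drug vectors, one per
#'   k), `method_name`, `params`, `folds`.
#' @export
run_cv_experiment <- function(X, Y, method, K = 5L, seed = 1L,
                              topk = c(10L, 100L), folds = NULL) {
  if (!identical(rownames(X), rownames(Y)))
    stop("X and Y must be row-aligned (see align_by_ids)", call. = FALSE)
  if (is.null(folds)) folds <- kfold_split(rownames(X), K, seed)
  scores <- matrix(NA_real_, nrow(X), ncol(Y), dimnames = dimnames(Y))
  for (f in seq_len(folds$K)) {
    te <- names(folds$fold_of)[folds$fold_of == f]
    tr <- setdiff(rownames(X), te)
    scores[te, ] <- fit_and_score(method,
                                  X[tr, , drop = FALSE],
                                  Y[tr, , drop = FALSE],
                                  X[te, , drop = FALSE],
                                  derive_seed(seed, f))
  }
  topk <- topk[topk <= ncol(Y)]
  topk_acc <- lapply(topk, function(k)
    stats::setNames(vapply(seq_len(nrow(Y)), function(i)
      topk_accuracy(scores[i, ], Y[i, ], k), numeric(1)), rownames(Y)))
  names(topk_acc) <- paste0("top", topk)
  pl <- per_label_auc(scores, Y)
  structure(list(scores = scores, labels = Y,
                 global_auc = global_auc(scores, Y),
                 per_label_auc = pl,
                 mean_label_auc = mean(pl, na.rm = TRUE),
                 topk_accuracy = topk_acc,
                 method_name = method$name,
                 params = method$params,
                 folds = folds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("CV evaluation:", x$method_name, "\n")
  cat(sprintf("  global AUC:      %.4f\n", x$global_auc))
  cat(sprintf("  mean label AUC:  %.4f (over %d defined side-effects)\n",
              x$mean_label_auc, sum(!is.na(x$per_label_auc))))
  for (nm in names(x$topk_accuracy))
    cat(sprintf("  %s accuracy:   %.4f (mean over drugs)\n", nm,
                mean(x$topk_accuracy[[nm]])))
  invisible(x)
}
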