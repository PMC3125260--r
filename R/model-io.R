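# Plain-text serialization of fitted models: a directory holding labeled
# TSV weight matrices plus JSON normalizers and fit parameters.

write_weight_tsv <- function(M, path, id_col) {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_weight_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  M
}

normalizer_to_list <- function(norm) {
  list(means = unname(norm$means), sds = unname(norm$sds),
       zero_var_mask = unname(norm$zero_var_mask),
       col_names = norm$col_names)
}

list_to_normalizer <- function(l) {
  structure(list(means = stats::setNames(l$means, l$col_names),
                 sds = stats::setNames(l$sds, l$col_names),
                 zero_var_mask = stats::setNames(l$zero_var_mask,
                                                 l$col_names),
                 col_names = l$col_names),
            class = "normalizer")
}

#' Write a fitted model to a directory
#'
#' Creates `A.tsv`, `B.tsv` (feature-labeled weight matrices), `d.tsv`,
#' `rho.tsv`, `normalizers.json` and `params.json` under `dir`.
#'
#' @param model fitted `cca_model`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_weight_tsv(model$A, file.path(dir, "A.tsv"), "substructure")
  write_weight_tsv(model$B, file.path(dir, "B.tsv"), "side_effect")
  utils::write.table(data.frame(component = seq_along(model$d),
                                d = model$d),
                     file.path(dir, "d.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(component = seq_along(model$rho),
                                rho = model$rho),
                     file.path(dir, "rho.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(x = normalizer_to_list(model$x_norm),
                            y = normalizer_to_list(model$y_norm)),
                       file.path(dir, "normalizers.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(unclass(model$params), list(method = model$method)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a model written by [write_model()]
#'
#' @param dir model directory.
#' @return `cca_model`.
#' @export
read_model <- function(dir) {
  pars <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  norms <- jsonlite::read_json(file.path(dir, "normalizers.json"),
                               simplifyVector = TRUE)
  method <- pars$method
  pars$method <- NULL
  if (method == "scca") {
    pars <- do.call(scca_params, pars)
  }
  structure(list(A = read_weight_tsv(file.path(dir, "A.tsv")),
                 B = read_weight_tsv(file.path(dir, "B.tsv")),
                 d = utils::read.table(file.path(dir, "d.tsv"),
                                       header = TRUE, sep = "\t")$d,
                 rho = utils::read.table(file.path(dir, "rho.tsv"),
                                         header = TRUE, sep = "\t")$rho,
                 x_norm = list_to_normalizer(norms$x),
                 y_norm = list_to_normalizer(norms$y),
                 params = pars, method = method),
            class = "cca_model")
}
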