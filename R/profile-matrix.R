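# Labeled binary profile matrices (drugs x substructure bits, drugs x
# side-effect keywords) and their I/O. A profile matrix is a plain numeric
# matrix with 0/1 entries, unique rownames (drug ids) and unique colnames
# (feature names).

#' Validate a binary profile matrix
#'
#' Checks that `M` is a numeric matrix with entries in \{0, 1\}, and that its
#' row ids and column names are present and unique.
#'
#' @param M matrix to validate.
#' @param what label used in error messages.
#' @return `M`, invisibly, with storage mode double.
#' @export
validate_profile_matrix <- function(M, what = "profile matrix") {
  if (!is.matrix(M) || !is.numeric(M))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop(what, " must have row ids and column names", call. = FALSE)
  if (anyDuplicated(rownames(M)))
    stop(what, ": duplicate row ids: ",
         paste(unique(rownames(M)[duplicated(rownames(M))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(M)))
    stop(what, ": duplicate column names", call. = FALSE)
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(M)) + 1
    j <- ((bad[1] - 1) %/% nrow(M)) + 1
    stop(what, ": non-binary value ", M[i, j], " at row '", rownames(M)[i],
         "', column '", colnames(M)[j], "'", call. = FALSE)
  }
  storage.mode(M) <- "double"
  invisible(M)
}

#' Read a binary profile matrix from delimited text
#'
#' Expects a header row of feature names whose first field is the id column,
#' and one row per drug with 0/1 cells.
#'
#' @param path file path.
#' @param delimiter field delimiter; tab by default.
#' @return numeric 0/1 matrix with drug ids as rownames.
#' @export
read_profile_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate drug ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  feat <- colnames(df)[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop("non-binary cell '", vals[i, j], "' at row '", ids[i],
         "', column '", feat[j], "' in ", path, call. = FALSE)
  }
  dimnames(num) <- list(ids, feat)
  validate_profile_matrix(num)
  num
}

#' Write a binary profile matrix to delimited text
#'
#' Inverse of [read_profile_matrix()]: header row `id` + feature names, one
#' row per drug.
#'
#' @param M binary profile matrix.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
write_profile_matrix <- function(M, path, delimiter = "\t") {
  validate_profile_matrix(M)
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict two profile matrices to their shared drugs
#'
#' Both matrices are restricted to the intersection of their row ids, in
#' lexicographically sorted order, so that row i of each refers to the same
#' drug. Dropped ids are reported via `message()`.
#'
#' @param X,Y binary profile matrices.
#' @return list with elements `X` and `Y`, row-aligned.
#' @export
align_by_ids <- function(X, Y) {
  validate_profile_matrix(X, "X")
  validate_profile_matrix(Y, "Y")
  common <- sort(intersect(rownames(X), rownames(Y)))
  if (length(common) == 0L)
    stop("X and Y share no drug ids", call. = FALSE)
  dx <- setdiff(rownames(X), common)
  dy <- setdiff(rownames(Y), common)
  if (length(dx)) message("align_by_ids: dropping ", length(dx), " X-only ids")
  if (length(dy)) message("align_by_ids: dropping ", length(dy), " Y-only ids")
  list(X = X[common, , drop = FALSE], Y = Y[common, , drop = FALSE])
}
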