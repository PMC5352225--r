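#' Construct a BinaryStateMatrix
#'
#' The interface between data analysis and network modeling: a modules x
#' states matrix of binarized expression values m_i^alpha in \{0, 1\}.
#' Rows are gene modules (named by a representative gene), columns are the
#' inferred cell states.
#'
#' @param values binary matrix, modules in rows, states in columns.
#' @param module_ids,state_ids identifiers (defaults: dimnames).
#' @param member_genes optional list of member genes per module.
#' @param aliases optional character vector recording modules whose binary
#'   pattern duplicates another module's (named signalling aliases).
#' @return an object of class `BinaryStateMatrix`.
#' @export
binary_state_matrix <- function(values, module_ids = NULL, state_ids = NULL,
                                member_genes = NULL, aliases = character()) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1)))
    abort_sf("state matrix entries must be 0/1", "statefate_validation_error")
  storage.mode(values) <- "integer"
  if (is.null(module_ids)) module_ids <- rownames(values) %||% paste0("M", seq_len(nrow(values)))
  if (is.null(state_ids)) state_ids <- colnames(values) %||% paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(module_ids, state_ids)
  if (is.null(member_genes)) member_genes <- stats::setNames(as.list(module_ids), module_ids)
  structure(list(values = values, module_ids = module_ids, state_ids = state_ids,
                 member_genes = member_genes, aliases = aliases),
            class = "BinaryStateMatrix")
}

#' @export
print.BinaryStateMatrix <- function(x, ...) {
  cat(sprintf("BinaryStateMatrix: %d modules x %d states\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$aliases)) cat("aliases:", paste(x$aliases, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.BinaryStateMatrix <- function(x) dim(x$values)

#' Write / read a BinaryStateMatrix as CSV
#'
#' Rows are modules, columns states, entries 0/1 — the same shape as a
#' supplementary module-by-state table, so such a file can be dropped in
#' directly for the modeling half of the pipeline.
#'
#' @param x a [binary_state_matrix()].
#' @param path CSV path.
#' @export
write_state_matrix <- function(x, path) {
  df <- data.frame(module = x$module_ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  binary_state_matrix(m)
}
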