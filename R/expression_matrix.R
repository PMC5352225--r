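#' Construct an ExpressionMatrix
#'
#' The raw container of the pipeline: a cells x genes matrix of UMI counts
#' with cell and gene identifiers, optional per-cell metadata, and a layer
#' tag recording what processing it has seen (`raw`, `subsampled`,
#' `lognorm`).
#'
#' @param counts numeric matrix, cells in rows, genes in columns.
#' @param cell_ids,gene_ids identifiers; default to dimnames or generated.
#' @param cell_meta optional data.frame of per-cell metadata.
#' @param layer one of `"raw"`, `"subsampled"`, `"lognorm"`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                              cell_meta = NULL,
                              layer = c("raw", "subsampled", "lognorm")) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- rownames(counts) %||% paste0("cell_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- colnames(counts) %||% paste0("gene_", seq_len(ncol(counts)))
  if (anyDuplicated(cell_ids)) abort_sf("duplicate cell_ids", "statefate_validation_error")
  if (anyDuplicated(gene_ids)) abort_sf("duplicate gene_ids", "statefate_validation_error")
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    abort_sf("id lengths do not match matrix dimensions", "statefate_validation_error")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort_sf("counts must be finite and non-negative", "statefate_validation_error")
  if (layer != "lognorm" && any(counts != round(counts)))
    abort_sf("counts must be integers", "statefate_format_error")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_meta = cell_meta, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [layer: %s]\n",
              nrow(x$counts), ncol(x$counts), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' CSV/TSV files carry gene ids in the header row and cell ids in the first
#' column (cells in rows, the package's canonical orientation).  MTX files
#' are Matrix Market triplets with `<stem>_rows.tsv` / `<stem>_cols.tsv`
#' id sidecars (rows = cells unless `transpose`).  A sidecar
#' `<stem>_meta.tsv`, if present, is attached as cell metadata.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; guessed from the extension by
#'   default.
#' @param transpose set `TRUE` when the file stores genes in rows.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_sf(paste0("file not found: ", path), "statefate_io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     abort_sf(paste0("cannot guess format for: ", path), "statefate_format_error"))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rid <- paste0(stem, "_rows.tsv"); cid <- paste0(stem, "_cols.tsv")
    rows <- if (file.exists(rid)) readLines(rid) else NULL
    cols <- if (file.exists(cid)) readLines(cid) else NULL
    if (!is.null(rows)) rownames(m) <- rows
    if (!is.null(cols)) colnames(m) <- cols
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, colClasses = "character")
    m <- as.matrix(df)
    suppressWarnings(storage.mode(m) <- "numeric")
    if (any(is.na(m))) abort_sf("non-numeric entries in count file", "statefate_format_error")
  }
  if (transpose) m <- t(m)
  if (any(m != round(m))) abort_sf("non-integer counts in file", "statefate_format_error")
  meta_path <- paste0(sub("\\.[a-zA-Z]+$", "", path), "_meta.tsv")
  meta <- if (file.exists(meta_path)) utils::read.delim(meta_path) else NULL
  expression_matrix(m, cell_meta = meta, layer = "raw")
}

#' Write a count matrix
#'
#' Inverse of [load_expression()]; CSV/TSV with ids, or MTX plus id
#' sidecars.  Round-trips integer matrices bit-identically.
#'
#' @param mat an [expression_matrix()].
#' @param path output file path (extension selects the format).
#' @export
write_expression <- function(mat, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(mat$counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(mat$cell_ids, paste0(stem, "_rows.tsv"))
    writeLines(mat$gene_ids, paste0(stem, "_cols.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(cell_id = mat$cell_ids, mat$counts, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a gene annotation table
#'
#' TSV with columns `gene_id`, `is_tf` (logical or 0/1) and optional
#' `pathway` (semicolon-separated memberships among LIF/BMP/WNT/FGF; a gene
#' may belong to several).
#'
#' @param path TSV path.
#' @return data.frame with `gene_id`, `is_tf`, and a list-column `pathway`.
#' @export
load_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) abort_sf("duplicate gene_id in annotation", "statefate_validation_error")
  df$is_tf <- as.logical(df$is_tf)
  df$pathway <- if ("pathway" %in% names(df)) {
    lapply(strsplit(as.character(df$pathway), ";"), function(p) p[nzchar(p)])
  } else rep(list(character()), nrow(df))
  df
}

#' Drop low-depth cells
#'
#' Removes cells whose total UMI count is below `min_depth` (default the
#' CEL-seq quality threshold of 20,000 UMIs per well).
#'
#' @param mat raw-layer [expression_matrix()].
#' @param min_depth minimum total UMIs per retained cell.
#' @export
filter_cells_min_depth <- function(mat, min_depth = 20000) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  keep <- rowSums(mat$counts) >= min_depth
  if (!any(keep)) abort_sf(
    sprintf("no cells have total UMI >= %d", min_depth), "statefate_empty_result")
  expression_matrix(mat$counts[keep, , drop = FALSE],
                    cell_meta = if (!is.null(mat$cell_meta)) mat$cell_meta[keep, , drop = FALSE],
                    layer = mat$layer)
}

#' Downsample every cell to a fixed UMI depth
#'
#' Draws, for each cell, a uniform sample of `depth` UMIs without
#' replacement from that cell's UMI multiset (a multivariate hypergeometric
#' draw), so that every cell total equals `depth` exactly.  This equalizes
#' read-depth-driven technical variation across cells.
#'
#' @param mat raw-layer [expression_matrix()]; every cell total must be at
#'   least `depth`.
#' @param depth target depth (default 20,000).
#' @param seed RNG seed; same seed gives bit-identical output.
#' @export
subsample_umis <- function(mat, depth = 20000, seed = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  totals <- rowSums(mat$counts)
  low <- which(totals < depth)
  if (length(low) > 0) abort_sf(
    sprintf("cell(s) below target depth %d: %s", depth,
            paste(utils::head(mat$cell_ids[low], 5), collapse = ", ")),
    "statefate_precondition_error")
  set.seed(seed)
  out <- mat$counts
  for (i in seq_len(nrow(out))) {
    if (totals[i] == depth) next
    out[i, ] <- rmvhyper(out[i, ], depth)
  }
  expression_matrix(out, cell_meta = mat$cell_meta, layer = "subsampled")
}

# Sequential multivariate hypergeometric draw: k balls without replacement
# from urns with counts `x`.
rmvhyper <- function(x, k) {
  n <- length(x)
  remaining <- sum(x)
  out <- integer(n)
  for (j in seq_len(n)) {
    if (k == 0) break
    remaining <- remaining - x[j]
    if (remaining == 0) { out[j] <- k; k <- 0; break }
    out[j] <- stats::rhyper(1, x[j], remaining, k)
    k <- k - out[j]
  }
  out
}

#' Log-normalize counts
#'
#' Entrywise `log2(count + 1)` on a depth-equalized matrix.
#'
#' @param mat subsampled-layer [expression_matrix()].
#' @export
lognorm <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (any(mat$counts < 0)) abort_sf("negative counts", "statefate_validation_error")
  out <- log2(mat$counts + 1)
  expression_matrix(out, cell_meta = mat$cell_meta, layer = "lognorm")
}

#' Rescale per-gene-set mean profiles to \[0, 1\]
#'
#' Utility for plotting axes: the mean log expression of a gene set per
#' cell, min/max rescaled across cells.
#'
#' @param mat lognorm-layer [expression_matrix()].
#' @param genes gene ids of the set.
#' @export
normalized_set_mean <- function(mat, genes) {
  v <- rowMeans(mat$counts[, intersect(genes, mat$gene_ids), drop = FALSE])
  if (max(v) == min(v)) return(rep(0, length(v)))
  (v - min(v)) / (max(v) - min(v))
}

#' Restrict a matrix to transcription factors
#'
#' Keeps the genes flagged `is_tf` in the annotation; genes missing from
#' the annotation are treated as non-TF.
#'
#' @param mat an [expression_matrix()].
#' @param annot annotation data.frame from [load_annotation()].
#' @export
restrict_to_tfs <- function(mat, annot) {
  tfs <- annot$gene_id[annot$is_tf]
  keep <- mat$gene_ids %in% tfs
  if (!any(keep)) abort_sf("no transcription factors in matrix", "statefate_empty_result")
  m <- mat
  m$counts <- mat$counts[, keep, drop = FALSE]
  m$gene_ids <- mat$gene_ids[keep]
  m
}
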