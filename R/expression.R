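#' Expression matrix container
#'
#' A light container for a cells-by-genes expression matrix that tracks which
#' processing stage produced it (`raw`, `normalized` or `denoised`). All
#' downstream constructors validate against it, so stage mix-ups (e.g. running
#' MAGIC on raw counts) fail loudly instead of silently degrading results.
#'
#' @param values numeric cells x genes matrix, non-negative.
#' @param gene_ids,cell_ids unique identifiers; default to dimnames of `values`.
#' @param layer one of `"raw"`, `"normalized"`, `"denoised"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (matrix with dimnames), `gene_ids`, `cell_ids`, `layer`.
#' @export
expr_matrix <- function(values, gene_ids = colnames(values),
                        cell_ids = rownames(values),
                        layer = c("raw", "normalized", "denoised")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values)) stop_spathgt("gene_ids length != ncol(values)")
  if (length(cell_ids) != nrow(values)) stop_spathgt("cell_ids length != nrow(values)")
  if (anyDuplicated(gene_ids)) stop_spathgt("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop_spathgt("cell_ids must be unique")
  if (any(!is.finite(values))) stop_spathgt("expression values must be finite")
  if (any(values < 0)) stop_spathgt("expression values must be non-negative")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 layer = layer),
            class = "expr_matrix")
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# internal: subset cells / genes keeping the container consistent
expr_subset <- function(x, cells = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  expr_matrix(v, layer = x$layer)
}

#' Tidy an expression matrix into long format
#'
#' @param x an [expr_matrix].
#' @param ... unused.
#' @return A tibble with columns `cell_id`, `gene_id`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "cell_id") |>
    tidyr::pivot_longer(-"cell_id", names_to = "gene_id", values_to = "value")
}
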