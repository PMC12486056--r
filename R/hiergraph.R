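# The two-level tissue graph: a spatial cell graph plus one gene
# co-expression network per cell type, tied together by implicit membership
# (cell k is linked to the network of its type).

#' Assemble a hierarchical tissue graph
#'
#' Validates and bundles the spatial cell graph, the per-type gene
#' co-expression networks and the denoised expression matrix. Cross-level
#' membership is implicit: cell k is attached to the network of its type.
#'
#' @param cell_graph a [build_spatial_graph()] result with `cell_types` set
#'   (or supplied via `cell_types`).
#' @param gene_networks named list of [build_coexpression_network()] results,
#'   one per cell type present.
#' @param expression an [expr_matrix] (denoised) aligned with the cell graph;
#'   its gene set must equal each network's gene set, in the same order.
#' @param cell_types optional per-cell labels overriding
#'   `cell_graph$cell_types`.
#' @return Object of class `hier_graph`.
#' @export
assemble_hierarchical_graph <- function(cell_graph, gene_networks, expression,
                                        cell_types = NULL) {
  stopifnot(inherits(cell_graph, "spatial_graph"),
            inherits(expression, "expr_matrix"))
  if (!is.null(cell_types)) cell_graph$cell_types <- as.character(cell_types)
  ct <- cell_graph$cell_types
  n <- nrow(cell_graph$positions)
  if (is.null(ct) || length(ct) != n || anyNA(ct))
    stop_spathgt("every cell needs a type label")
  if (nrow(expression$values) != n)
    stop_spathgt("expression and cell graph disagree on cell count")
  if (!identical(expression$cell_ids, cell_graph$cell_ids))
    stop_spathgt("expression and cell graph cell ids differ")
  types <- sort(unique(ct))
  missing <- setdiff(types, names(gene_networks))
  if (length(missing) > 0)
    stop_spathgt("no gene network for cell type(s): ", paste(missing, collapse = ", "))
  for (t in types) {
    net <- gene_networks[[t]]
    if (!inherits(net, "gene_network")) stop_spathgt("gene_networks[['", t, "']] is not a gene_network")
    if (!identical(net$gene_ids, expression$gene_ids))
      stop_spathgt("gene set of network '", t, "' differs from the expression matrix")
  }
  out <- structure(list(cell_graph = cell_graph,
                        gene_networks = gene_networks[types],
                        expression = expression),
                   class = "hier_graph")
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

# memoised structural tables (edge lists, adjacencies); the cache environment
# travels with the object by reference, so repeated encodes of the same graph
# (every training step on a patch) skip the rebuild
hg_cache <- function(hg) {
  ca <- attr(hg, "cache")
  if (is.null(ca)) ca <- new.env(parent = emptyenv())
  if (is.null(ca$cell_ctx)) {
    nC <- n_cells(hg); nV <- n_genes(hg)
    ca$cell_ctx <- edge_ctx(directed_with_self(hg$cell_graph$edges, nC), nC)
    ca$gene_blocks <- lapply(names(hg$gene_networks), function(t) {
      net <- hg$gene_networks[[t]]
      mask <- diag(nV) > 0
      if (nrow(net$edges) > 0) {
        mask[net$edges] <- TRUE
        mask[net$edges[, c(2, 1), drop = FALSE]] <- TRUE
      }
      list(cells = which(hg$cell_graph$cell_types == t), mask = mask)
    })
    ca$cell_of_row <- gene_row_cell(nC, nV)
    ca$A_cell <- spatial_adjacency(hg)
    ca$A_gene <- gene_adjacency(hg)
  }
  ca
}

#' @exportS3Method base::print
print.hier_graph <- function(x, ...) {
  cat(sprintf("<hier_graph> %d cells (%d spatial edges), %d genes, %d type networks\n",
              nrow(x$cell_graph$positions), nrow(x$cell_graph$edges),
              length(x$expression$gene_ids), length(x$gene_networks)))
  invisible(x)
}

n_cells <- function(hg) nrow(hg$cell_graph$positions)
n_genes <- function(hg) length(hg$expression$gene_ids)

# row index of (cell k, gene v) in the |C||V| x d gene embedding matrix
gene_row_index <- function(k, v, n_gene) (k - 1L) * n_gene + v

# cell owning each gene row, length |C||V|
gene_row_cell <- function(nC, nV) rep(seq_len(nC), each = nV)

#' End-to-end graph construction
#'
#' Convenience pipeline: preprocess -> MAGIC denoise -> type partition ->
#' per-type MI networks -> Voronoi spatial graph -> assembled hierarchical
#' graph. Cells dropped by the outlier filter are removed from coordinates and
#' labels consistently.
#'
#' @param raw an [expr_matrix] with `layer == "raw"`.
#' @param positions cells x 2 coordinate matrix aligned with `raw`.
#' @param labels optional per-cell type annotations.
#' @param n_hvg,outlier_mads see [preprocess_expression()].
#' @param k_neighbors,t_steps see [magic_denoise()].
#' @param resolution see [partition_cell_types()].
#' @param tau_mode,tau,target_degree see [build_coexpression_network()].
#' @param prune_quantile see [build_spatial_graph()].
#' @param seed seed for clustering / jitter.
#' @return A `hier_graph`.
#' @export
build_hierarchical_graph <- function(raw, positions, labels = NULL,
                                     n_hvg = ncol(raw$values), outlier_mads = 3,
                                     k_neighbors = 15, t_steps = 3,
                                     resolution = 1,
                                     tau_mode = "adaptive", tau = 0.1,
                                     target_degree = 10,
                                     prune_quantile = 0.99, seed = 1) {
  stopifnot(inherits(raw, "expr_matrix"))
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(raw$values))
    stop_spathgt("positions and expression disagree on cell count")
  norm <- preprocess_expression(raw, n_hvg = n_hvg, outlier_mads = outlier_mads)
  kept <- match(norm$cell_ids, raw$cell_ids)
  positions <- positions[kept, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[kept]
  den <- magic_denoise(norm, k_neighbors = min(k_neighbors, nrow(norm$values) - 1),
                       t_steps = t_steps)
  types <- partition_cell_types(den, labels = labels, resolution = resolution,
                                seed = seed)
  nets <- lapply(sort(unique(types)), function(t) {
    build_coexpression_network(expr_subset(den, cells = which(types == t)),
                               tau_mode = tau_mode, tau = tau,
                               target_degree = target_degree, cell_type = t)
  })
  names(nets) <- sort(unique(types))
  cg <- build_spatial_graph(positions, prune_quantile = prune_quantile,
                            cell_ids = den$cell_ids, cell_types = unname(types),
                            seed = seed)
  assemble_hierarchical_graph(cg, nets, den)
}

#' Save / load a hierarchical graph
#'
#' Single-file store (RDS). Serialization is deterministic for a fixed
#' object, so identical inputs and seed give byte-identical files.
#'
#' @param hg a `hier_graph`.
#' @param path file path.
#' @return `write_hier_graph` returns `path` invisibly; `read_hier_graph`
#'   returns the validated `hier_graph`.
#' @export
write_hier_graph <- function(hg, path) {
  stopifnot(inherits(hg, "hier_graph"))
  attr(hg, "cache") <- NULL   # derived tables are rebuilt on load
  saveRDS(hg, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname write_hier_graph
#' @export
read_hier_graph <- function(path) {
  hg <- readRDS(path)
  if (!inherits(hg, "hier_graph")) stop_spathgt("'", path, "' does not contain a hier_graph")
  assemble_hierarchical_graph(hg$cell_graph, hg$gene_networks, hg$expression)
}

# ---- internal structural helpers used by the model ----

# directed edge list with self-loops from an undirected i<j edge matrix
directed_with_self <- function(edges, n) {
  src <- c(edges[, 1], edges[, 2], seq_len(n))
  dst <- c(edges[, 2], edges[, 1], seq_len(n))
  cbind(src = as.integer(src), dst = as.integer(dst))
}

# directed gene-row edge list (with self-loops) over all cells, offsetting
# each cell's type network into the |C||V|-row block layout
gene_level_edges <- function(hg) {
  nC <- n_cells(hg); nV <- n_genes(hg)
  ct <- hg$cell_graph$cell_types
  per_type <- lapply(hg$gene_networks, function(net)
    directed_with_self(net$edges, nV))
  cells_by_type <- split(seq_len(nC), ct)
  blocks <- lapply(names(cells_by_type), function(t) {
    e <- per_type[[t]]
    cells <- cells_by_type[[t]]
    off <- rep((cells - 1L) * nV, each = nrow(e))
    cbind(src = rep(e[, 1], length(cells)) + off,
          dst = rep(e[, 2], length(cells)) + off)
  })
  do.call(rbind, blocks)
}

# undirected spatial adjacency as a sparse matrix (for GIN / diffusion)
spatial_adjacency <- function(hg) {
  n <- n_cells(hg); e <- hg$cell_graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

# undirected gene-row adjacency over all cells as a sparse matrix
gene_adjacency <- function(hg) {
  nC <- n_cells(hg); nV <- n_genes(hg)
  ct <- hg$cell_graph$cell_types
  ii <- integer(0); jj <- integer(0)
  for (t in names(hg$gene_networks)) {
    e <- hg$gene_networks[[t]]$edges
    cells <- which(ct == t)
    if (nrow(e) == 0 || length(cells) == 0) next
    off <- rep((cells - 1L) * nV, each = nrow(e))
    ii <- c(ii, rep(e[, 1], length(cells)) + off, rep(e[, 2], length(cells)) + off)
    jj <- c(jj, rep(e[, 2], length(cells)) + off, rep(e[, 1], length(cells)) + off)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nC * nV, nC * nV))
}
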