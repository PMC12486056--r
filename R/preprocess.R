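#' Preprocess a raw expression matrix
#'
#' Standard single-cell preprocessing ahead of graph construction: cells whose
#' log1p total count deviates from the median by more than `outlier_mads`
#' median absolute deviations are dropped (zero-total cells always are), the
#' remaining rows are library-size normalized to the median total and log1p
#' transformed, and the gene panel is restricted to the `n_hvg` genes with the
#' highest normalized dispersion (variance/mean ratio of the normalized
#' values; genes with zero mean get dispersion 0).
#'
#' @param raw an [expr_matrix] with `layer == "raw"`.
#' @param n_hvg number of highly variable genes to retain (<= gene count).
#' @param outlier_mads MAD multiplier for the outlier filter on log totals.
#' @return An [expr_matrix] with `layer == "normalized"`.
#' @export
preprocess_expression <- function(raw, n_hvg = ncol(raw$values), outlier_mads = 3) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$layer != "raw") stop_spathgt("preprocess_expression expects layer 'raw', got '",
                                       raw$layer, "'")
  if (n_hvg > ncol(raw$values)) stop_spathgt("n_hvg exceeds the gene count")
  totals <- rowSums(raw$values)
  lt <- log1p(totals)
  dev <- abs(lt - median(lt))
  keep <- totals > 0 & dev <= outlier_mads * stats::mad(lt)
  if (!any(keep)) stop_spathgt("outlier filter removed all cells (outlier_mads = ",
                               outlier_mads, ")")
  v <- raw$values[keep, , drop = FALSE]
  tot <- rowSums(v)
  v <- log1p(v * (median(tot) / tot))

  m <- colMeans(v)
  nd <- ifelse(m > 0, apply(v, 2, var) / m, 0)
  sel <- sort(order(nd, decreasing = TRUE)[seq_len(n_hvg)])
  expr_matrix(v[, sel, drop = FALSE], layer = "normalized")
}

#' MAGIC-style diffusion denoising
#'
#' Builds a k-nearest-neighbour adaptive Gaussian affinity over cells in
#' expression space, symmetrizes it, row-normalizes to a Markov matrix M, and
#' returns \eqn{M^t X}. After diffusion each cell's row is rescaled to its
#' pre-diffusion total, so per-cell totals are conserved exactly; this is the
#' convention tested by the suite (diffusion mixes cells within each gene, so
#' without rescaling neither row nor column mass is invariant).
#'
#' @param X an [expr_matrix] with `layer == "normalized"`.
#' @param k_neighbors neighbours for the affinity graph (< cell count).
#' @param t_steps diffusion steps; `0` is a documented no-op (values returned
#'   unchanged, layer marked `denoised`).
#' @return An [expr_matrix] with `layer == "denoised"`, same shape.
#' @export
magic_denoise <- function(X, k_neighbors = 15, t_steps = 3) {
  stopifnot(inherits(X, "expr_matrix"))
  if (X$layer != "normalized") stop_spathgt("magic_denoise expects layer 'normalized', got '",
                                            X$layer, "'")
  n <- nrow(X$values)
  if (k_neighbors >= n) stop_spathgt("k_neighbors must be < cell count")
  if (t_steps == 0) return(expr_matrix(X$values, layer = "denoised"))

  nn <- FNN::get.knn(X$values, k = k_neighbors)
  sigma <- nn$nn.dist[, max(1L, ceiling(k_neighbors / 2))]
  sigma <- pmax(sigma, 1e-12)
  i <- rep(seq_len(n), k_neighbors)
  j <- as.vector(nn$nn.index)
  a <- exp(-(as.vector(nn$nn.dist) / sigma[i])^2)
  A <- Matrix::sparseMatrix(i = i, j = j, x = a, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  Matrix::diag(A) <- 1
  M <- A / Matrix::rowSums(A)
  out <- X$values
  for (s in seq_len(t_steps)) out <- as.matrix(M %*% out)
  # restore each cell's pre-diffusion total
  tot0 <- rowSums(X$values)
  tot1 <- rowSums(out)
  scale <- ifelse(tot1 > 0, tot0 / tot1, 1)
  out <- out * scale
  out[out < 0] <- 0
  dimnames(out) <- dimnames(X$values)
  expr_matrix(out, layer = "denoised")
}

#' Partition cells into types
#'
#' Returns provided annotations verbatim when present; otherwise runs Leiden
#' community detection (modularity objective) on a k-nearest-neighbour graph
#' of the expression rows at the given resolution. In both paths, any class
#' with fewer than `min_cells` cells is merged into the class with the nearest
#' centroid (mutual-information estimation downstream needs at least 3 cells
#' per type), with a warning.
#'
#' @param X an [expr_matrix] (denoised expression recommended).
#' @param labels optional per-cell labels, one per cell of `X`.
#' @param resolution Leiden resolution parameter.
#' @param k_neighbors kNN graph degree for the clustering path.
#' @param min_cells smallest admissible class size.
#' @param seed seed for the Leiden refinement.
#' @return Character vector of per-cell type labels, named by cell id.
#' @export
partition_cell_types <- function(X, labels = NULL, resolution = 1,
                                 k_neighbors = 15, min_cells = 3, seed = 1) {
  stopifnot(inherits(X, "expr_matrix"))
  n <- nrow(X$values)
  if (!is.null(labels)) {
    if (length(labels) != n) stop_spathgt("labels must have one entry per cell")
    lab <- as.character(labels)
  } else {
    k <- min(k_neighbors, n - 1)
    nn <- FNN::get.knn(X$values, k = k)
    el <- cbind(rep(seq_len(n), k), as.vector(nn$nn.index))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- with_seed(seed,
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution))
    lab <- paste0("L", igraph::membership(comm))
  }
  lab <- merge_small_classes(lab, X$values, min_cells)
  names(lab) <- X$cell_ids
  lab
}

merge_small_classes <- function(lab, values, min_cells) {
  repeat {
    tab <- table(lab)
    small <- names(tab)[tab < min_cells]
    if (length(small) == 0 || length(tab) == 1) break
    cls <- small[which.min(tab[small])]
    cent <- vapply(names(tab), function(cl)
      colMeans(values[lab == cl, , drop = FALSE]), numeric(ncol(values)))
    others <- setdiff(names(tab), cls)
    d <- vapply(others, function(cl) sum((cent[, cls] - cent[, cl])^2), numeric(1))
    target <- others[which.min(d)]
    warning(sprintf("cell-type class '%s' has %d < %d cells; merged into '%s'",
                    cls, tab[[cls]], min_cells, target), call. = FALSE)
    lab[lab == cls] <- target
  }
  lab
}
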