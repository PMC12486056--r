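# Mutual-information gene co-expression networks.
#
# MI is estimated with the plug-in (maximum-likelihood) estimator on an
# equal-frequency discretization of each gene: B = min(16, floor(sqrt(n)))
# bins by default, assigned through average ranks so that tied values (the
# zero mass in sparse data) land in one bin deterministically. Estimates are
# in nats. A constant gene discretizes to a single bin, giving MI = 0 with
# every partner by construction.

#' Equal-frequency discretization
#'
#' @param x numeric vector.
#' @param bins number of bins B.
#' @return Integer vector of bin indices in 1..B.
#' @keywords internal
discretize_ef <- function(x, bins) {
  n <- length(x)
  b <- ceiling(rank(x, ties.method = "average") / n * bins)
  pmin(pmax(as.integer(b), 1L), as.integer(bins))
}

# entropy (nats) of an integer code vector
entropy_nats <- function(code) {
  p <- tabulate(code)
  p <- p[p > 0] / length(code)
  -sum(p * log(p))
}

#' Pairwise mutual information matrix
#'
#' Plug-in MI (nats) between all gene pairs of a cells x genes matrix after
#' equal-frequency discretization. The diagonal holds the discretized marginal
#' entropies (MI of a variable with itself).
#'
#' @param values cells x genes numeric matrix.
#' @param bins bins per gene; default `min(16, floor(sqrt(nrow(values))))`.
#' @return Symmetric genes x genes matrix of MI values.
#' @export
mutual_information_matrix <- function(values, bins = NULL) {
  n <- nrow(values); G <- ncol(values)
  if (is.null(bins)) bins <- min(16L, floor(sqrt(n)))
  bins <- max(2L, as.integer(bins))
  D <- apply(values, 2, discretize_ef, bins = bins)
  H <- apply(D, 2, entropy_nats)
  M <- matrix(0, G, G, dimnames = list(colnames(values), colnames(values)))
  diag(M) <- H
  if (G < 2) return(M)
  for (i in seq_len(G - 1)) {
    di <- D[, i]
    for (j in (i + 1):G) {
      joint <- tabulate(di + bins * (D[, j] - 1L), nbins = bins * bins)
      p <- joint[joint > 0] / n
      Hij <- -sum(p * log(p))
      mi <- H[i] + H[j] - Hij
      M[i, j] <- M[j, i] <- max(mi, 0)
    }
  }
  M
}

#' Build a gene co-expression network for one cell type
#'
#' Estimates pairwise MI between denoised genes within a single cell type and
#' connects gene pairs above a threshold. `tau_mode = "constant"` keeps pairs
#' with MI strictly above `tau`. `tau_mode = "adaptive"` sets the threshold
#' per cell type to the smallest value whose retained-edge mean degree does
#' not exceed `target_degree` (equivalently, keeps the top
#' `floor(target_degree * |V| / 2)` pairs, dropping ties at the cut).
#'
#' @param X_type an [expr_matrix] containing only cells of one type (>= 3
#'   cells, denoised layer).
#' @param tau_mode `"adaptive"` or `"constant"`.
#' @param tau constant-mode threshold (nats).
#' @param target_degree adaptive-mode mean-degree target.
#' @param bins discretization bins (default as in
#'   [mutual_information_matrix()]).
#' @param cell_type label stored on the network.
#' @return An object of class `gene_network`: list with `cell_type`,
#'   `gene_ids`, `edges` (m x 2 integer matrix, i < j), `mi_weights`,
#'   `threshold_used`, `bins`.
#' @export
build_coexpression_network <- function(X_type, tau_mode = c("adaptive", "constant"),
                                       tau = 0.1, target_degree = 10,
                                       bins = NULL, cell_type = "type1") {
  tau_mode <- match.arg(tau_mode)
  stopifnot(inherits(X_type, "expr_matrix"))
  if (X_type$layer == "raw") stop_spathgt("co-expression networks are built on processed (denoised) expression")
  n <- nrow(X_type$values)
  if (n < 3) stop_spathgt("need >= 3 cells to estimate MI (got ", n, ")")
  if (is.null(bins)) bins <- min(16L, floor(sqrt(n)))
  M <- mutual_information_matrix(X_type$values, bins = bins)
  G <- ncol(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  if (tau_mode == "constant") {
    thr <- tau
  } else {
    e_max <- floor(target_degree * G / 2)
    thr <- if (length(w) <= e_max) 0 else sort(w, decreasing = TRUE)[e_max + 1]
  }
  keep <- w > thr
  structure(list(cell_type = cell_type,
                 gene_ids = X_type$gene_ids,
                 edges = unname(ut[keep, , drop = FALSE]),
                 mi_weights = unname(w[keep]),
                 threshold_used = thr,
                 bins = as.integer(bins)),
            class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> type '%s': %d genes, %d edges (tau = %.4g nats)\n",
              x$cell_type, length(x$gene_ids), nrow(x$edges), x$threshold_used))
  invisible(x)
}

#' Tidy a gene co-expression network
#'
#' @param x a `gene_network`.
#' @param ... unused.
#' @return A tibble with columns `gene_a`, `gene_b`, `mi` (nats).
#' @export
tidy.gene_network <- function(x, ...) {
  tibble::tibble(gene_a = x$gene_ids[x$edges[, 1]],
                 gene_b = x$gene_ids[x$edges[, 2]],
                 mi = x$mi_weights)
}
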