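# Spatial cell graph via Voronoi adjacency (Delaunay duality).

#' Build the spatial cell graph
#'
#' Two cells are spatial neighbours iff their Voronoi regions share a border
#' segment, which for points in general position is exactly the Delaunay
#' triangulation. Edges longer than the `prune_quantile` quantile of edge
#' lengths are removed to suppress long convex-hull artifacts (use
#' `prune_quantile = 1` for the raw triangulation). Duplicate coordinates are
#' jittered by a seeded perturbation of 1e-9 times the bounding-box diagonal
#' (triangulation needs general position); a warning reports how many.
#'
#' @param positions cells x 2 numeric matrix.
#' @param prune_quantile quantile of edge lengths above which edges are
#'   dropped.
#' @param cell_ids optional cell identifiers.
#' @param cell_types optional per-cell labels (can be attached later; required
#'   by [assemble_hierarchical_graph()]).
#' @param seed seed for the duplicate jitter.
#' @return Object of class `spatial_graph`: list with `positions`, `edges`
#'   (m x 2 integer, i < j), `edge_lengths`, `cell_ids`, `cell_types`.
#' @export
build_spatial_graph <- function(positions, prune_quantile = 0.99,
                                cell_ids = rownames(positions),
                                cell_types = NULL, seed = 1) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 3) stop_spathgt("need >= 3 cells to triangulate (got ", n, ")")
  if (ncol(positions) != 2) stop_spathgt("positions must be cells x 2")
  ctr <- sweep(positions, 2, colMeans(positions))
  if (qr(ctr)$rank < 2) stop_spathgt("all cells are collinear; no planar triangulation exists")
  key <- paste(positions[, 1], positions[, 2])
  dup <- duplicated(key)
  if (any(dup)) {
    diag_len <- sqrt(sum((apply(positions, 2, max) - apply(positions, 2, min))^2))
    warning(sum(dup), " duplicate coordinate(s) jittered for triangulation",
            call. = FALSE)
    positions[dup, ] <- positions[dup, ] + with_seed(seed,
      matrix(runif(2 * sum(dup), -1, 1), ncol = 2)) * 1e-9 * diag_len
  }
  dd <- deldir::deldir(positions[, 1], positions[, 2], suppressMsge = TRUE)
  e <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
             pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  e <- unique(e)
  len <- sqrt(rowSums((positions[e[, 1], , drop = FALSE] -
                         positions[e[, 2], , drop = FALSE])^2))
  keep <- len <= quantile(len, prune_quantile)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  structure(list(positions = positions,
                 edges = matrix(as.integer(e[keep, , drop = FALSE]), ncol = 2),
                 edge_lengths = unname(len[keep]),
                 cell_ids = as.character(cell_ids),
                 cell_types = if (is.null(cell_types)) NULL else as.character(cell_types),
                 pos_range = cbind(range(positions[, 1]), range(positions[, 2]))),
            class = "spatial_graph")
}

#' @exportS3Method base::print
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d cells, %d edges%s\n", nrow(x$positions),
              nrow(x$edges),
              if (is.null(x$cell_types)) "" else
                sprintf(", %d types", length(unique(x$cell_types)))))
  invisible(x)
}

#' Brute-force Voronoi adjacency
#'
#' Independent geometric oracle: cells i and j are adjacent iff their Voronoi
#' regions share a segment of positive length. For each pair, the
#' perpendicular bisector is parameterised as a line and every other point k
#' contributes the half-line where the bisector is at least as close to i (and
#' j) as to k; the pair is adjacent iff the intersection of those half-lines
#' is an interval of positive length. Exact up to a relative tolerance, O(n^3)
#' — intended for small point sets in tests.
#'
#' @param positions n x 2 matrix, n >= 2.
#' @param tol relative tolerance on interval length.
#' @return m x 2 integer matrix of adjacent pairs (i < j), ordered.
#' @export
voronoi_adjacency_bruteforce <- function(positions, tol = 1e-9) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  scale <- max(1, max(abs(positions)))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi_ <- positions[i, ]; pj <- positions[j, ]
      m <- (pi_ + pj) / 2
      dir <- pj - pi_
      u <- c(-dir[2], dir[1])
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      u <- u / nu
      lo <- -Inf; hi <- Inf
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        pk <- positions[k, ]
        # || m + t u - pi ||^2 <= || m + t u - pk ||^2  =>  a t <= b
        a <- 2 * sum(u * (pk - pi_))
        b <- sum(pk^2) - sum(pi_^2) - 2 * sum(m * (pk - pi_))
        if (abs(a) < 1e-14 * scale^2) {
          if (b < -1e-14 * scale^2) { lo <- Inf; break }
        } else if (a > 0) hi <- min(hi, b / a) else lo <- max(lo, b / a)
      }
      if (hi - lo > tol * scale) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  e <- do.call(rbind, out)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
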