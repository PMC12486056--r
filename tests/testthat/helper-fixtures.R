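# Shared fixtures: all synthetic, built in code at test time.

# small tissue + assembled hierarchical graph; memoised per (n_cells, n_genes,
# seed) so several test files can share one build
.fixture_env <- new.env(parent = emptyenv())

fixture_tissue <- function(n_cells = 300, n_genes = 30, seed = 3, ...) {
  generate_tissue(generator_config(n_cells = n_cells, n_genes = n_genes,
                                   seed = seed, ...))
}

fixture_hg <- function(n_cells = 300, n_genes = 30, seed = 3) {
  key <- paste("hg", n_cells, n_genes, seed)
  if (is.null(.fixture_env[[key]])) {
    tis <- fixture_tissue(n_cells, n_genes, seed)
    raw <- expr_matrix(tis$observed, layer = "raw")
    hg <- suppressWarnings(build_hierarchical_graph(
      raw, as.matrix(tis$cells[, c("x", "y")]), labels = tis$cells$type,
      k_neighbors = 10, target_degree = 8, seed = 2))
    keep <- match(hg$expression$cell_ids, tis$cells$cell_id)
    .fixture_env[[key]] <- list(tissue = tis, hg = hg,
                                types = tis$cells$type[keep],
                                niches = tis$cells$niche[keep])
  }
  .fixture_env[[key]]
}

# tiny model setup reused by model/objective/training tests
fixture_model <- function(d = 8, L = 2, heads = 2, seed = 5, ...) {
  cfg <- model_config(d = d, L = L, heads = heads, seed = seed, ...)
  list(cfg = cfg, params = init_params(cfg))
}

# independent plug-in MI oracle on two discretized vectors (nats)
oracle_mi <- function(x, y, bins) {
  bx <- spathgt:::discretize_ef(x, bins)
  by <- spathgt:::discretize_ef(y, bins)
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

expect_edges_equal <- function(a, b) {
  canon <- function(e) {
    if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
  }
  expect_equal(canon(a), canon(b))
}
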