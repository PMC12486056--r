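test_that("outlier filter drops degenerate cells and normalization log-scales the rest", {
  m <- rbind(c(0, 0, 0), c(5, 3, 2), c(4, 4, 2))
  rownames(m) <- paste0("c", 1:3); colnames(m) <- paste0("g", 1:3)
  out <- preprocess_expression(expr_matrix(m, layer = "raw"), outlier_mads = 3)
  expect_equal(nrow(out$values), 2)
  expect_identical(out$cell_ids, c("c2", "c3"))
  expect_identical(out$layer, "normalized")
  expect_true(all(out$values >= 0))

  # already n_hvg genes -> gene set unchanged, original order kept
  expect_identical(out$gene_ids, c("g1", "g2", "g3"))
})

test_that("HVG selection retains planted informative genes over constant ones", {
  set.seed(1)
  n <- 200
  # informative genes are overdispersed (log-normal rate mixing); the flat
  # genes still vary after library-size normalization but far less
  informative <- matrix(rpois(n * 50, lambda = 5 * exp(rnorm(n * 50, 0, 0.8))),
                        n, 50)
  constant <- matrix(5, n, 50)
  m <- cbind(informative, constant)
  colnames(m) <- c(paste0("inf", 1:50), paste0("const", 1:50))
  rownames(m) <- paste0("c", seq_len(n))
  out <- preprocess_expression(expr_matrix(m, layer = "raw"), n_hvg = 50)
  expect_gte(sum(startsWith(out$gene_ids, "inf")), 45)
})

test_that("preprocess contract errors are explicit", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  e <- expr_matrix(m, layer = "raw")
  expect_error(preprocess_expression(e, n_hvg = 10), "n_hvg")
  expect_error(
    preprocess_expression(
      magic_denoise(preprocess_expression(e), k_neighbors = 2, t_steps = 0)),
    "layer")
  zero <- expr_matrix(matrix(0, 3, 2, dimnames = list(letters[1:3], c("g1", "g2"))),
                      layer = "raw")
  expect_error(preprocess_expression(zero), "outlier filter")
})

test_that("diffusion denoising: no-op at t=0, fixed point on identical cells, conserves totals", {
  set.seed(2)
  m <- matrix(rexp(40 * 10), 40, 10,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:10)))
  X <- preprocess_expression(expr_matrix(m, layer = "raw"))
  d0 <- magic_denoise(X, k_neighbors = 5, t_steps = 0)
  expect_identical(d0$values, X$values)
  expect_identical(d0$layer, "denoised")

  same <- expr_matrix(matrix(rep(c(1, 2, 3), each = 10), 10, 3, byrow = FALSE,
                             dimnames = list(paste0("c", 1:10), paste0("g", 1:3))),
                      layer = "normalized")
  ds <- magic_denoise(same, k_neighbors = 3, t_steps = 4)
  expect_equal(ds$values, same$values, tolerance = 1e-8)

  d3 <- magic_denoise(X, k_neighbors = 5, t_steps = 3)
  expect_equal(rowSums(d3$values), rowSums(X$values), tolerance = 1e-6)
  expect_error(magic_denoise(X, k_neighbors = 40), "k_neighbors")
})

test_that("denoising a masked smooth signal reduces error to the clean signal", {
  set.seed(3)
  n <- 100
  t_ <- seq(0, 1, length.out = n)
  clean <- outer(t_, seq(0.5, 2, length.out = 12), function(a, b) 2 + sin(2 * pi * a * b))
  obs <- clean
  obs[sample(length(obs), 0.4 * length(obs))] <- 0
  dimnames(obs) <- list(paste0("c", 1:n), paste0("g", 1:12))
  X <- expr_matrix(obs, layer = "normalized")
  den <- magic_denoise(X, k_neighbors = 10, t_steps = 3)
  expect_lt(mean((den$values - clean)^2), mean((obs - clean)^2))
})

test_that("cell-type partition returns labels verbatim and merges tiny classes", {
  fx <- fixture_hg()
  den <- fx$hg$expression
  lab <- partition_cell_types(den, labels = fx$types)
  expect_identical(unname(lab), fx$types)

  bad <- fx$types
  bad[1:2] <- "tiny"
  expect_warning(merged <- partition_cell_types(den, labels = bad),
                 "merged")
  expect_false("tiny" %in% merged)
  expect_equal(length(merged), length(bad))
})

test_that("Leiden partition separates two well-separated expression blobs", {
  set.seed(4)
  blob <- rbind(matrix(rnorm(60 * 10, 2, 0.3), 60, 10),
                matrix(rnorm(60 * 10, 7, 0.3), 60, 10))
  blob[blob < 0] <- 0
  dimnames(blob) <- list(paste0("c", 1:120), paste0("g", 1:10))
  X <- expr_matrix(blob, layer = "denoised")
  lab <- partition_cell_types(X, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(nmi_score(lab, rep(1:2, each = 60)), 1)
})
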