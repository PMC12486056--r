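test_that("positive/negative sets match hand enumeration and a brute-force oracle", {
  # A,B type-1 at distance 0.5; C type-2 at 0.7 from A; r = 1
  cg <- structure(list(positions = rbind(A = c(0, 0), B = c(0.5, 0), C = c(0, 0.7)),
                       edges = matrix(integer(0), ncol = 2),
                       edge_lengths = numeric(0),
                       cell_ids = c("A", "B", "C"),
                       cell_types = c("t1", "t1", "t2")),
                  class = "spatial_graph")
  sets <- positive_negative_sets(cg, contrastive_config(radius = 1))
  expect_identical(sets$pairs, cbind(1L, 2L))
  expect_identical(sets$negatives[[1]], 3L)
  expect_identical(sets$negatives[[2]], 3L)
  expect_identical(sets$negatives[[3]], c(1L, 2L))

  # single-type dataset: all negative sets empty
  cg1 <- cg; cg1$cell_types <- rep("t1", 3)
  s1 <- positive_negative_sets(cg1, contrastive_config(radius = 1))
  expect_true(all(lengths(s1$negatives) == 0))

  # oracle equivalence on 200 random cells
  set.seed(1)
  n <- 200
  pos <- matrix(runif(2 * n), n, 2)
  ct <- sample(c("a", "b", "c"), n, replace = TRUE)
  cgr <- structure(list(positions = pos, edges = matrix(integer(0), ncol = 2),
                        edge_lengths = numeric(0),
                        cell_ids = paste0("c", 1:n), cell_types = ct),
                   class = "spatial_graph")
  r <- 0.11
  sets <- positive_negative_sets(cgr, contrastive_config(radius = r))
  D <- as.matrix(dist(pos))
  brute_pairs <- which(D <= r & outer(ct, ct, "==") & upper.tri(D), arr.ind = TRUE)
  brute_pairs <- unname(brute_pairs[order(brute_pairs[, 1], brute_pairs[, 2]), ,
                                    drop = FALSE])
  got <- sets$pairs[order(sets$pairs[, 1], sets$pairs[, 2]), , drop = FALSE]
  expect_equal(got, matrix(as.integer(brute_pairs), ncol = 2))
  for (i in seq_len(n)) {
    expect_identical(sets$negatives[[i]],
                     sort(unname(which(D[i, ] <= r & ct != ct[i]))))
  }
})

test_that("contrastive loss reproduces the closed-form case and degenerate limits", {
  # positive pair with identical embeddings, orthogonal negatives, cosine
  # similarity, temperature 1: per-pair term = log(1 + |N| * exp(-1))
  d <- 8
  for (n_neg in c(1, 3, 5)) {
    nC <- 2 + n_neg
    Zc <- matrix(0, nC, d)
    Zc[1, 1] <- 1; Zc[2, 1] <- 1                  # identical positive pair
    for (k in seq_len(n_neg)) Zc[2 + k, 1 + k] <- 1   # orthogonal negatives
    tape <- spathgt:::ad_tape(record = FALSE)
    sets <- list(pairs = cbind(1L, 2L),
                 negatives = c(list(integer(0)), list(integer(0)),
                               rep(list(integer(0)), n_neg)))
    sets$negatives[[1]] <- 2L + seq_len(n_neg)
    cfg <- contrastive_config(radius = 1, temperature = 1)
    # isolate the cell-cell term through the core with a single pair
    hg_stub <- list(cell_graph = list(cell_types = rep("t", nC),
                                      positions = matrix(0, nC, 2)),
                    gene_networks = list(t = list(edges = matrix(integer(0), ncol = 2))),
                    expression = list(gene_ids = "g1", cell_ids = paste0("c", 1:nC)))
    class(hg_stub) <- "hier_graph"
    Zg <- matrix(rnorm(nC * d), nC, d)
    parts <- spathgt:::contrastive_core(tape, spathgt:::ad_wrap(tape, Zc),
                                        spathgt:::ad_wrap(tape, Zg),
                                        hg_stub, sets, cfg, seed = 1)
    expect_equal(as.numeric(parts$l_cc$val), log(1 + n_neg * exp(-1)),
                 tolerance = 1e-9)
  }
})

test_that("a pair with no negatives contributes zero", {
  d <- 4
  Zc <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  sets <- list(pairs = cbind(1L, 2L), negatives = list(integer(0), integer(0)))
  hg_stub <- list(cell_graph = list(cell_types = c("t", "t"),
                                    positions = matrix(0, 2, 2)),
                  gene_networks = list(t = list(edges = matrix(integer(0), ncol = 2))),
                  expression = list(gene_ids = "g1"))
  class(hg_stub) <- "hier_graph"
  tape <- spathgt:::ad_tape(record = FALSE)
  parts <- spathgt:::contrastive_core(tape, spathgt:::ad_wrap(tape, Zc),
                                      spathgt:::ad_wrap(tape, matrix(rnorm(8), 2, 4)),
                                      hg_stub, sets,
                                      contrastive_config(radius = 1, temperature = 1),
                                      seed = 1)
  expect_equal(as.numeric(parts$l_cc$val), 0, tolerance = 1e-12)
})

test_that("masking is seeded, Bernoulli at the requested rate, and validated", {
  fx <- fixture_hg()
  m1 <- make_masks(fx$hg, gene_rate = 0.3, seed = 7)
  m2 <- make_masks(fx$hg, gene_rate = 0.3, seed = 7)
  expect_identical(m1$gene_mask, m2$gene_mask)
  expect_identical(m1$cell_mask, m2$cell_mask)
  frac <- mean(m1$gene_mask)
  expect_gt(frac, 0.25); expect_lt(frac, 0.35)
  expect_error(make_masks(fx$hg, gene_rate = 0), "rates")
  expect_error(make_masks(fx$hg, cell_rate = 1), "rates")
})

test_that("MAE loss scores masked entries only, as hand-computed", {
  fx <- fixture_hg(n_cells = 40, n_genes = 10, seed = 7)
  hg <- fx$hg
  masks <- make_masks(hg, cell_rate = 0.3, gene_rate = 0.3, seed = 2)
  pos <- hg$cell_graph$positions
  pr <- hg$cell_graph$pos_range
  pn <- cbind((pos[, 1] - pr[1, 1]) / diff(pr[, 1]),
              (pos[, 2] - pr[1, 2]) / diff(pr[, 2]))
  perfect <- structure(list(positions_hat = pn,
                            expression_hat = hg$expression$values),
                       class = "reconstruction")
  expect_equal(mae_loss(perfect, hg, masks), 0, tolerance = 1e-12)

  # positions off by (0.1, 0) at masked cells only -> loss = 0.01
  off <- perfect
  off$positions_hat[masks$cell_mask, 1] <- pn[masks$cell_mask, 1] + 0.1
  expect_equal(mae_loss(off, hg, masks), 0.01, tolerance = 1e-10)

  # values at unmasked entries never enter
  noisy <- off
  noisy$positions_hat[!masks$cell_mask, ] <- 99
  noisy$expression_hat[masks$gene_mask == 0] <- -7
  expect_equal(mae_loss(noisy, hg, masks), mae_loss(off, hg, masks),
               tolerance = 1e-12)
})

test_that("orthogonality penalty is zero at orthonormal columns and 2 for the rank-1 case", {
  Q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  expect_equal(ortho_reg(Q, Q), 0, tolerance = 1e-9)
  ones <- matrix(1, 30, 2)
  expect_equal(ortho_reg(ones, Q), 2, tolerance = 1e-9)
  # row-permutation invariance
  Z <- matrix(rnorm(60), 20, 3)
  expect_equal(ortho_reg(Z, Q), ortho_reg(Z[sample(20), ], Q), tolerance = 1e-12)
})

test_that("the combined loss follows the sigmoid-balanced form exactly", {
  rep0 <- total_loss(2, 4, 10, gamma = 0, lambda = 1e-3)
  expect_equal(rep0$total, 0.5 * 2 + 0.5 * 4 + 1e-3 * 10, tolerance = 1e-12)
  expect_equal(rep0$weight, 0.5)
  rep_inf <- total_loss(2, 4, 0, gamma = 50)
  expect_equal(rep_inf$total, 2, tolerance = 1e-6)
  r <- total_loss(1.3, 0.7, 5, gamma = -0.4, lambda = 2e-3)
  s <- 1 / (1 + exp(0.4))
  expect_equal(r$total, s * 1.3 + (1 - s) * 0.7 + 2e-3 * 5, tolerance = 1e-6)
  expect_error(total_loss(NaN, 1, 1), "l_contrastive")
})
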