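test_that("NMI and macro-F1 agree with hand-computed fixtures", {
  expect_equal(nmi_score(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(nmi_score(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # hand-computed macro F1: per-class F1 = (1, 2/3, 0) -> mean 5/9
  truth <- c("a", "a", "b", "b", "c")
  pred <- c("a", "a", "b", "c", "b")
  f1_a <- 1; f1_b <- 2 * 1 / (2 * 1 + 1 + 1); f1_c <- 0
  expect_equal(macro_f1(truth, pred), mean(c(f1_a, f1_b, f1_c)), tolerance = 1e-12)
  expect_equal(macro_f1(truth, truth), 1)
})

test_that("clustering scores perfect and null cases correctly", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(500 * 4, 0, 0.2), 500, 4),
             matrix(rnorm(500 * 4, 4, 0.2), 500, 4))
  lab <- rep(c("x", "y"), each = 500)
  rs <- cluster_cells(Z, lab, method = "spectral", seed = 1)
  expect_equal(rs$value, 1, tolerance = 1e-9)
  # leiden at modularity resolution 1 may split the tight blobs further but
  # never across them; low resolution recovers them exactly
  rl <- cluster_cells(Z, lab, resolution = 0.05, seed = 1)
  expect_equal(rl$value, 1, tolerance = 1e-9)
  # random labels at n = 1000: NMI close to zero
  r0 <- cluster_cells(Z, sample(lab), method = "spectral", seed = 1)
  expect_lt(r0$value, 0.05)
})

test_that("annotation head separates separable embeddings and not shuffled ones", {
  set.seed(2)
  Z <- rbind(matrix(rnorm(150 * 6, 0, 0.3), 150, 6),
             matrix(rnorm(150 * 6, 3, 0.3), 150, 6),
             matrix(rnorm(150 * 6, -3, 0.3), 150, 6))
  lab <- rep(c("a", "b", "c"), each = 150)
  expect_gt(annotate_cells(Z, lab, split_seed = 1)$value, 0.95)
  r0 <- annotate_cells(Z, sample(lab), split_seed = 1)
  expect_lt(r0$value, 0.55)
  # identical embeddings for all cells carry no information: the head can do
  # no better than predicting one class everywhere
  Zflat <- matrix(1, 300, 6)
  labs2 <- rep(c("a", "b"), c(200, 100))
  rflat <- annotate_cells(Zflat, labs2, split_seed = 1)
  majority_f1 <- macro_f1(rep(c("a", "b"), c(40, 20)), rep("a", 60))
  expect_lte(rflat$value, majority_f1 + 1e-9)
  expect_error(annotate_cells(Z, rep("a", 450)), ">= 2 classes")
})

test_that("tissue classification: separable means, null labels, degenerate class", {
  set.seed(3)
  n_tis <- 12
  tissue <- rep(sprintf("s%02d", 1:n_tis), each = 40)
  cls <- rep(rep(c("good", "poor"), each = 6)[1:n_tis], each = 40)
  shift <- ifelse(cls == "good", 2, -2)
  Z <- matrix(rnorm(length(tissue) * 5), ncol = 5) + shift
  r <- classify_tissue(Z, tissue, cls, seed = 1)
  expect_equal(r$value, 1, tolerance = 1e-9)

  null_cls <- rep(sample(rep(c("good", "poor"), 6)), each = 40)
  r0 <- classify_tissue(matrix(rnorm(length(tissue) * 5), ncol = 5),
                        tissue, null_cls, seed = 1)
  expect_lt(abs(r0$value - 0.5), 0.35)

  one <- rep(c("good", rep("poor", 11)), each = 40)
  expect_error(classify_tissue(Z, tissue, one, seed = 1), "single tissue")
  expect_error(classify_tissue(Z[1:120, ], tissue[1:120], cls[1:120]), ">= 4 tissues")
})

test_that("imputation scores its predictions by pooled Pearson with degenerate guard", {
  fx <- fixture_hg(n_cells = 40, n_genes = 10, seed = 7)
  mdl <- fixture_model(d = 8, L = 1, heads = 2)
  fit <- structure(list(params = mdl$params, model_cfg = mdl$cfg),
                   class = "spathgt_fit")
  r <- impute_genes(fx$hg, fit, mask_fraction = 0.15, mode = "zero_shot", seed = 2)
  pred <- attr(r, "predictions"); truth <- attr(r, "truth")
  expect_equal(r$value, cor(pred, truth), tolerance = 1e-12)
  expect_gte(r$value, -1); expect_lte(r$value, 1)

  # per-gene-mean baseline on the same masks is reproducible and sane
  b <- impute_gene_mean_baseline(fx$hg, attr(r, "masks"))
  expect_equal(length(attr(b, "predictions")), length(pred))
  expect_gt(b$value, 0)

  # constant predictions -> r reported as 0 with a warning
  hgc <- fx$hg
  hgc$expression$values[] <- 1
  expect_warning(bc <- impute_gene_mean_baseline(hgc, attr(r, "masks")),
                 "Pearson|constant")
  expect_equal(bc$value, 0)
})
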