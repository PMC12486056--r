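# The autodiff tape is the substrate of the whole model; its gradients are
# checked here against central finite differences, and the two attention
# implementations (edge-list and block-dense) are cross-checked against each
# other.

fd_grad <- function(f, x, eps = 1e-5) {
  num <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  num
}

test_that("composite op chains differentiate to finite-difference accuracy", {
  set.seed(1)
  n <- 7; d <- 4
  idx <- sample(n, 12, replace = TRUE)
  grp <- sample(4, 12, replace = TRUE)
  W <- matrix(rnorm(d * d), d, d)
  gain <- runif(d, 0.5, 1.5); bias <- rnorm(d)
  run <- function(x, want_grad = FALSE) {
    tape <- spathgt:::ad_tape()
    X <- spathgt:::ad_leaf(tape, x)
    H <- spathgt:::ad_layernorm(spathgt:::ad_mm(X, W), gain, bias)
    G <- spathgt:::ad_rows(H, idx)
    s <- spathgt:::ad_rowdot(G, spathgt:::ad_rows(H, rev(idx)))
    a <- spathgt:::ad_group_softmax(s, grp, 4)
    M <- spathgt:::ad_segsum(spathgt:::ad_rowscale(G, a), grp, 4)
    Z <- spathgt:::ad_colnorm_unit(spathgt:::ad_relu(M))
    L <- spathgt:::ad_mean(spathgt:::ad_square(
      spathgt:::ad_sub(Z, spathgt:::ad_sigmoid(spathgt:::ad_scale(M, 0.3)))))
    if (!want_grad) return(L$val)
    list(loss = L$val, grad = spathgt:::ad_backward(L)[[X$id]])
  }
  x0 <- matrix(rnorm(n * d), n, d)
  r <- run(x0, want_grad = TRUE)
  expect_lt(max(abs(fd_grad(run, x0) - r$grad)), 1e-7)
})

test_that("fused edge attention matches finite differences for Q, K and V", {
  set.seed(2)
  n <- 6; d <- 8; heads <- 2
  edges <- spathgt:::directed_with_self(rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(1, 6)), n)
  ctx <- spathgt:::edge_ctx(edges, n)
  mats <- list(Q = matrix(rnorm(n * d), n, d),
               K = matrix(rnorm(n * d), n, d),
               V = matrix(rnorm(n * d), n, d))
  target <- matrix(rnorm(n * d), n, d)
  run <- function(mats, want_grad = FALSE) {
    tape <- spathgt:::ad_tape()
    hs <- lapply(mats, function(m) spathgt:::ad_leaf(tape, m))
    out <- spathgt:::ad_mha_edges(hs$Q, hs$K, hs$V, ctx, heads)
    L <- spathgt:::ad_mean(spathgt:::ad_square(spathgt:::ad_sub(out, target)))
    if (!want_grad) return(L$val)
    g <- spathgt:::ad_backward(L)
    lapply(hs, function(h) g[[h$id]])
  }
  grads <- run(mats, want_grad = TRUE)
  for (nm in names(mats)) {
    fd <- fd_grad(function(m) { mm <- mats; mm[[nm]] <- m; run(mm) }, mats[[nm]])
    expect_lt(max(abs(fd - grads[[nm]])), 1e-7)
  }
})

test_that("block-dense gene attention equals edge-list attention on the same graph", {
  set.seed(3)
  nV <- 6; nC <- 4; d <- 8; heads <- 2
  net_edges <- rbind(c(1, 2), c(2, 3), c(4, 5), c(3, 6))
  # edge-list form over all cells
  per_cell <- spathgt:::directed_with_self(net_edges, nV)
  off <- rep((seq_len(nC) - 1L) * nV, each = nrow(per_cell))
  edges <- cbind(rep(per_cell[, 1], nC) + off, rep(per_cell[, 2], nC) + off)
  ctx <- spathgt:::edge_ctx(edges, nC * nV)
  mask <- diag(nV) > 0
  mask[net_edges] <- TRUE
  mask[net_edges[, c(2, 1)]] <- TRUE
  blocks <- list(list(cells = seq_len(nC), mask = mask))

  Q <- matrix(rnorm(nC * nV * d), nC * nV, d)
  K <- matrix(rnorm(nC * nV * d), nC * nV, d)
  V <- matrix(rnorm(nC * nV * d), nC * nV, d)
  tape <- spathgt:::ad_tape(record = FALSE)
  h <- lapply(list(Q, K, V), function(m) spathgt:::ad_wrap(tape, m))
  a <- spathgt:::ad_mha_edges(h[[1]], h[[2]], h[[3]], ctx, heads)
  b <- spathgt:::ad_mha_blocks(h[[1]], h[[2]], h[[3]], blocks, nV, heads)
  expect_equal(a$val, b$val, tolerance = 1e-10)

  # and their gradients agree
  target <- matrix(rnorm(nC * nV * d), nC * nV, d)
  gr <- function(op) {
    tape <- spathgt:::ad_tape()
    hs <- lapply(list(Q, K, V), function(m) spathgt:::ad_leaf(tape, m))
    out <- if (op == "edges") spathgt:::ad_mha_edges(hs[[1]], hs[[2]], hs[[3]], ctx, heads)
           else spathgt:::ad_mha_blocks(hs[[1]], hs[[2]], hs[[3]], blocks, nV, heads)
    L <- spathgt:::ad_mean(spathgt:::ad_square(spathgt:::ad_sub(out, target)))
    g <- spathgt:::ad_backward(L)
    lapply(hs, function(h) g[[h$id]])
  }
  ga <- gr("edges"); gb <- gr("blocks")
  for (k in 1:3) expect_equal(ga[[k]], gb[[k]], tolerance = 1e-9)
})

test_that("model parameters all receive finite-difference-correct gradients", {
  fx <- fixture_hg(n_cells = 40, n_genes = 10, seed = 7)
  mdl <- fixture_model(d = 8, L = 2, heads = 2)
  con <- contrastive_config(radius = 0.4, max_pos_pairs = 20, max_negatives = 4,
                            gene_pairs_per_cell_pair = 4, max_gene_pairs = 40)
  sets <- positive_negative_sets(fx$hg$cell_graph, con)
  masks <- make_masks(fx$hg, seed = 3)
  loss_at <- function(params, record = FALSE) {
    tape <- spathgt:::ad_tape(record = record)
    P <- spathgt:::param_handles(tape, params, trainable = record)
    pl <- spathgt:::patch_loss(tape, fx$hg, mdl$cfg, con, P, masks, sets,
                               samp_seed = 11, lambda = 1e-3)
    list(total = as.numeric(pl$total$val), P = P, handle = pl$total)
  }
  r <- loss_at(mdl$params, record = TRUE)
  gr <- spathgt:::ad_backward(r$handle)
  grads <- lapply(r$P, function(h) gr[[h$id]])
  probe <- c("l1.xgc.Wq", "l1.xcg.Wk", "l2.gene.Wo", "l1.cell.ln1g",
             "dec.gene.1.W2", "dec.cell.3.eps", "gamma")
  # cross-level weights in both directions must receive nonzero gradients
  for (nm in c("l1.xgc.Wq", "l1.xcg.Wk", "l2.xgc.Wv", "l2.xcg.Wq")) {
    expect_gt(sqrt(sum(grads[[nm]]^2)), 0)
  }
  set.seed(9)
  eps <- 1e-5
  for (nm in probe) {
    g <- grads[[nm]]; p <- mdl$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- mdl$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- mdl$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp)$total - loss_at(pm)$total) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-6)
    }
  }
})
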