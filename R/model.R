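# The hierarchical graph-transformer encoder and GIN decoder.
#
# One forward implementation serves both inference (non-recording tape) and
# training (recorded tape + backprop); see R/ad.R.

#' Model configuration
#'
#' @param d embedding width (even, divisible by `heads`, >= 4).
#' @param L number of stacked layers (intra-level + cross-level).
#' @param heads attention heads per intra-level transformer.
#' @param agg aggregation of a cell's gene rows into its pooled gene summary:
#'   `"mean"` or `"diffpool"` (a learned soft assignment — differentiable
#'   pooling with a single cluster).
#' @param cross_residual add the cross-level message to the input state
#'   instead of replacing it. Defaults on: the literal gated update can
#'   annihilate the state when gates vanish; set `FALSE` to reproduce the
#'   bare equation.
#' @param cross_level set `FALSE` to ablate cross-level message passing
#'   entirely (the two levels then never exchange information).
#' @param pe_scale positions are min-max normalized to the unit square and
#'   multiplied by this scale before the sinusoidal encoding, so the standard
#'   base-10000 frequency ladder resolves unit-square distances.
#' @param seed seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d = 64, L = 2, heads = 4, agg = c("mean", "diffpool"),
                         cross_residual = TRUE, cross_level = TRUE,
                         pe_scale = 128, seed = 1) {
  agg <- match.arg(agg)
  if (d < 4) stop_spathgt("d must be >= 4 (two coordinate encodings need room)")
  if (d %% 2 != 0) stop_spathgt("d must be even")
  if (d %% heads != 0) stop_spathgt("d must be divisible by heads")
  if (L < 1) stop_spathgt("L must be >= 1")
  structure(list(d = as.integer(d), L = as.integer(L), heads = as.integer(heads),
                 agg = agg, cross_residual = isTRUE(cross_residual),
                 cross_level = isTRUE(cross_level), pe_scale = pe_scale,
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize model parameters
#'
#' Returns the full parameter set as a flat named list of arrays (attention,
#' feed-forward and normalization weights for both levels at every layer, the
#' two directional cross-level projection triples per layer, the 3-layer GIN
#' decoder for each level, and the loss-balance scalar `gamma`).
#'
#' @param cfg a [model_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return Named list of parameter arrays (class `model_params`).
#' @export
init_params <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$d
  with_seed(seed, {
    p <- list()
    attn <- function() list(Wq = glorot(d, d), Wk = glorot(d, d),
                            Wv = glorot(d, d), Wo = glorot(d, d),
                            ln1g = rep(1, d), ln1b = rep(0, d),
                            ln2g = rep(1, d), ln2b = rep(0, d),
                            W1 = glorot(d, 2 * d), b1 = rep(0, 2 * d),
                            W2 = glorot(2 * d, d), b2 = rep(0, d))
    cross <- function() list(Wq = glorot(d, d), Wk = glorot(d, d),
                             Wv = glorot(d, d))
    for (l in seq_len(cfg$L)) {
      for (nm in c("cell", "gene")) {
        blk <- attn()
        for (w in names(blk)) p[[sprintf("l%d.%s.%s", l, nm, w)]] <- blk[[w]]
      }
      for (nm in c("xgc", "xcg")) {
        blk <- cross()
        for (w in names(blk)) p[[sprintf("l%d.%s.%s", l, nm, w)]] <- blk[[w]]
      }
      if (cfg$agg == "diffpool") p[[sprintf("l%d.pool.w", l)]] <- glorot(d, 1)
    }
    for (lv in c("cell", "gene")) {
      p[[sprintf("final.%s.lng", lv)]] <- rep(1, d)
      p[[sprintf("final.%s.lnb", lv)]] <- rep(0, d)
      for (i in 1:3) {
        p[[sprintf("dec.%s.%d.W1", lv, i)]] <- glorot(d, d)
        p[[sprintf("dec.%s.%d.b1", lv, i)]] <- rep(0, d)
        p[[sprintf("dec.%s.%d.W2", lv, i)]] <- glorot(d, d)
        p[[sprintf("dec.%s.%d.b2", lv, i)]] <- rep(0, d)
        p[[sprintf("dec.%s.%d.eps", lv, i)]] <- matrix(0, 1, 1)
        p[[sprintf("dec.%s.%d.lng", lv, i)]] <- rep(1, d)
        p[[sprintf("dec.%s.%d.lnb", lv, i)]] <- rep(0, d)
      }
      k <- if (lv == "cell") 2L else 1L
      p[[sprintf("dec.%s.head.W", lv)]] <- glorot(d, k)
      p[[sprintf("dec.%s.head.b", lv)]] <- rep(0, k)
    }
    p$gamma <- matrix(0, 1, 1)
    structure(p, class = "model_params")
  })
}

# ---- positional encodings ----

sinusoidal_pe <- function(pos, d) {
  half <- d %/% 2
  freqs <- 10000^(-(2 * (seq_len(half) - 1)) / d)
  ang <- outer(as.numeric(pos), freqs)
  out <- matrix(0, length(pos), d)
  out[, 2 * seq_len(half) - 1] <- sin(ang)
  out[, 2 * seq_len(half)] <- cos(ang)
  out
}

minmax01 <- function(x, r = range(x)) {
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0.5, length(x))
}

#' Initial embeddings from positional encodings
#'
#' Gene row (k, v): the sinusoidal encoding of the rank of gene v's denoised
#' expression within cell k (rank 1 = highest, ties broken by gene index),
#' with the raw expression value added directly to the first coordinate. Cell
#' row k: concatenated sinusoidal encodings (d/2 each) of the min-max
#' normalized x and y coordinates, with the raw normalized coordinates added
#' directly to the first coordinate of each half. No learned map is applied
#' before the additions.
#'
#' Under a `mask_spec`, masked cell coordinates and masked gene entries are
#' zeroed before any encoding is computed (mask token = 0).
#'
#' @param hg a `hier_graph`.
#' @param cfg a [model_config()].
#' @param masks optional [make_masks()] result.
#' @return Object of class `embedding_state` at layer 0: list with `cell_emb`
#'   (|C| x d), `gene_emb` (|C||V| x d, row (k-1)|V|+v for cell k / gene v),
#'   `pos_norm`, `expr_input`, ids and sizes.
#' @export
init_embeddings <- function(hg, cfg, masks = NULL) {
  stopifnot(inherits(hg, "hier_graph"), inherits(cfg, "model_config"))
  nC <- n_cells(hg); nV <- n_genes(hg); d <- cfg$d
  X0 <- hg$expression$values
  pos <- hg$cell_graph$positions
  pr <- hg$cell_graph$pos_range
  if (is.null(pr)) pr <- cbind(range(pos[, 1]), range(pos[, 2]))
  pn0 <- cbind(minmax01(pos[, 1], pr[, 1]), minmax01(pos[, 2], pr[, 2]))
  X <- X0; pn <- pn0
  if (!is.null(masks)) {
    X <- X0 * (1 - masks$gene_mask)
    pn[masks$cell_mask, ] <- 0
  }
  ranks <- matrix(0L, nC, nV)
  for (k in seq_len(nC)) ranks[k, ] <- rank(-X[k, ], ties.method = "first")
  gene0 <- sinusoidal_pe(as.vector(t(ranks)), d)
  gene0[, 1] <- gene0[, 1] + as.vector(t(X))
  half <- d %/% 2
  cell0 <- cbind(sinusoidal_pe(pn[, 1] * cfg$pe_scale, half),
                 sinusoidal_pe(pn[, 2] * cfg$pe_scale, half))
  cell0[, 1] <- cell0[, 1] + pn[, 1]
  cell0[, half + 1] <- cell0[, half + 1] + pn[, 2]
  structure(list(cell_emb = cell0, gene_emb = gene0, layer = 0L,
                 n_cells = nC, n_genes = nV,
                 cell_ids = hg$expression$cell_ids,
                 gene_ids = hg$expression$gene_ids,
                 pos_norm = pn, pos_norm_true = pn0,
                 expr_input = X, expr_true = X0),
            class = "embedding_state")
}

#' @exportS3Method base::print
print.embedding_state <- function(x, ...) {
  cat(sprintf("<embedding_state> layer %d: cells %d x %d, gene rows %d x %d\n",
              x$layer, nrow(x$cell_emb), ncol(x$cell_emb),
              nrow(x$gene_emb), ncol(x$gene_emb)))
  invisible(x)
}

# ---- forward blocks (tape ops) ----

param_handles <- function(tape, params, trainable = TRUE) {
  lapply(params, function(v) ad_push(tape, v, track = trainable))
}

mha_block <- function(P, pfx, H, attn, n, heads) {
  g <- function(w) P[[paste0(pfx, w)]]
  Hn <- ad_layernorm(H, g("ln1g"), g("ln1b"))
  Q <- ad_mm(Hn, g("Wq")); K <- ad_mm(Hn, g("Wk")); V <- ad_mm(Hn, g("Wv"))
  M <- if (attn$kind == "edges") {
    ad_mha_edges(Q, K, V, attn$ctx, heads)
  } else {
    ad_mha_blocks(Q, K, V, attn$blocks, attn$nV, heads)
  }
  X1 <- ad_add(H, ad_mm(M, g("Wo")))
  Fn <- ad_layernorm(X1, g("ln2g"), g("ln2b"))
  FF <- ad_addrow(ad_mm(ad_relu(ad_addrow(ad_mm(Fn, g("W1")), g("b1"))),
                        g("W2")), g("b2"))
  ad_add(X1, FF)
}

cross_block <- function(P, pfx, Hto, Hfrom) {
  g <- function(w) P[[paste0(pfx, w)]]
  d <- ncol(Hto$val)
  gate <- ad_scale(ad_rowdot(ad_mm(Hto, g("Wq")), ad_mm(Hfrom, g("Wk"))), 1 / d)
  ad_rowscale(ad_mm(Hto, g("Wv")), gate)
}

pool_genes <- function(P, l, cfg, Hg, cell_of_row, nC, nV) {
  if (cfg$agg == "mean") {
    return(ad_scale(ad_segsum(Hg, cell_of_row, nC), 1 / nV))
  }
  # one-cluster differentiable pooling: softmax assignment over each cell's rows
  s <- ad_mm(Hg, P[[sprintf("l%d.pool.w", l)]])
  a <- ad_group_softmax(s, cell_of_row, nC)
  ad_segsum(ad_rowscale(Hg, a), cell_of_row, nC)
}

# full encoder forward on a tape; returns handles
encoder_forward <- function(tape, hg, cfg, P, masks = NULL, init = NULL) {
  if (is.null(init)) init <- init_embeddings(hg, cfg, masks)
  nC <- init$n_cells; nV <- init$n_genes
  ca <- hg_cache(hg)
  cell_attn <- list(kind = "edges", ctx = ca$cell_ctx)
  gene_attn <- list(kind = "blocks", blocks = ca$gene_blocks, nV = nV)
  cell_of_row <- ca$cell_of_row
  Hc <- ad_wrap(tape, init$cell_emb)
  Hg <- ad_wrap(tape, init$gene_emb)
  for (l in seq_len(cfg$L)) {
    Hc_t <- mha_block(P, sprintf("l%d.cell.", l), Hc, cell_attn, nC, cfg$heads)
    Hg_t <- mha_block(P, sprintf("l%d.gene.", l), Hg, gene_attn, nC * nV, cfg$heads)
    if (cfg$cross_level) {
      Hbar <- pool_genes(P, l, cfg, Hg_t, cell_of_row, nC, nV)
      x_g <- cross_block(P, sprintf("l%d.xgc.", l), Hg_t, ad_rows(Hc_t, cell_of_row))
      x_c <- cross_block(P, sprintf("l%d.xcg.", l), Hc_t, Hbar)
      Hg <- if (cfg$cross_residual) ad_add(Hg_t, x_g) else x_g
      Hc <- if (cfg$cross_residual) ad_add(Hc_t, x_c) else x_c
    } else {
      Hg <- Hg_t
      Hc <- Hc_t
    }
    if (any(!is.finite(Hc$val)) || any(!is.finite(Hg$val)))
      stop_spathgt("non-finite embeddings produced at layer ", l)
  }
  # closing layer norm of the pre-norm stack: puts Zc/Zg rows on a common
  # scale so cosine-based objectives shape a geometry clustering can see
  Hc <- ad_layernorm(Hc, P[["final.cell.lng"]], P[["final.cell.lnb"]])
  Hg <- ad_layernorm(Hg, P[["final.gene.lng"]], P[["final.gene.lnb"]])
  list(Zc = Hc, Zg = Hg, init = init)
}

gin_stack <- function(P, lv, H, A) {
  # GIN update h' = MLP((1 + eps) h + sum_{j in N(i)} h_j); a layer norm after
  # each MLP keeps the sum aggregation from inflating scale across layers
  for (i in 1:3) {
    g <- function(w) P[[sprintf("dec.%s.%d.%s", lv, i, w)]]
    pre <- ad_add(ad_add(H, ad_smul(H, g("eps"))), ad_spmm(A, H))
    H <- ad_addrow(ad_mm(ad_relu(ad_addrow(ad_mm(pre, g("W1")), g("b1"))),
                         g("W2")), g("b2"))
    H <- ad_layernorm(H, g("lng"), g("lnb"))
    if (i < 3) H <- ad_relu(H)
  }
  ad_addrow(ad_mm(H, P[[sprintf("dec.%s.head.W", lv)]]),
            P[[sprintf("dec.%s.head.b", lv)]])
}

decoder_forward <- function(tape, hg, cfg, P, Zc, Zg) {
  ca <- hg_cache(hg)
  A_cell <- ca$A_cell
  A_gene <- ca$A_gene
  pos_hat <- gin_stack(P, "cell", Zc, A_cell)
  expr_hat <- gin_stack(P, "gene", Zg, A_gene)
  list(pos_hat = pos_hat, expr_hat = expr_hat)
}

# ---- user-facing inference ----

#' Encode a hierarchical graph
#'
#' Runs the full encoder: positional-encoding initialization, then L layers
#' of intra-level neighbour-restricted multi-head attention on each level
#' followed by directional cross-level message passing (genes receive their
#' parent cell's state; cells receive the pooled summary of their gene rows),
#' yielding final embeddings Zc (|C| x d) and Zg (|C||V| x d). Deterministic
#' given (graph, config, params).
#'
#' @param hg a `hier_graph`.
#' @param cfg a [model_config()].
#' @param params a [init_params()] result (or trained checkpoint params).
#' @param masks optional [make_masks()] result applied to the inputs.
#' @return An `embedding_state` at layer `cfg$L`.
#' @export
encode <- function(hg, cfg, params, masks = NULL) {
  tape <- ad_tape(record = FALSE)
  P <- param_handles(tape, params, trainable = FALSE)
  out <- encoder_forward(tape, hg, cfg, P, masks = masks)
  st <- out$init
  st$cell_emb <- out$Zc$val
  st$gene_emb <- out$Zg$val
  st$layer <- cfg$L
  st
}

#' Decode embeddings into a reconstruction
#'
#' A 3-layer graph isomorphism network (GIN) runs on the spatial cell graph
#' from Zc to predict the (min-max normalized) cell coordinates, and on the
#' per-cell gene co-expression graphs from Zg to predict each cell's
#' expression vector.
#'
#' @param hg a `hier_graph`.
#' @param state a final `embedding_state` from [encode()].
#' @param params model parameters (decoder weights are used).
#' @param cfg a [model_config()].
#' @return Object of class `reconstruction`: list with `positions_hat`
#'   (|C| x 2, unit-square scale), `expression_hat` (|C| x |V|).
#' @export
decode <- function(hg, state, params, cfg) {
  stopifnot(inherits(state, "embedding_state"))
  tape <- ad_tape(record = FALSE)
  P <- param_handles(tape, params, trainable = FALSE)
  Zc <- ad_wrap(tape, state$cell_emb)
  Zg <- ad_wrap(tape, state$gene_emb)
  dec <- decoder_forward(tape, hg, cfg, P, Zc, Zg)
  nV <- state$n_genes
  xh <- matrix(dec$expr_hat$val, ncol = nV, byrow = TRUE,
               dimnames = list(state$cell_ids, state$gene_ids))
  structure(list(positions_hat = dec$pos_hat$val, expression_hat = xh),
            class = "reconstruction")
}

#' Directional cross-level message passing
#'
#' Row i of the output is the scalar gate
#' \eqn{\langle (H_{to} W_q)_i, (H_{from} W_k)_i \rangle / d} times
#' \eqn{(H_{to} W_v)_i} — the printed directional attention update (note the
#' denominator is d, not sqrt(d)). Every output row is therefore colinear
#' with the corresponding row of \eqn{H_{to} W_v}.
#'
#' @param h_to,h_from aligned row-matrices (same row count).
#' @param Wq,Wk,Wv d x d weight matrices.
#' @return Matrix of the same shape as `h_to`.
#' @export
cross_message_passing <- function(h_to, h_from, Wq, Wk, Wv) {
  if (nrow(h_to) != nrow(h_from)) stop_spathgt("h_to and h_from row counts differ")
  d <- ncol(h_to)
  gate <- rowSums((h_to %*% Wq) * (h_from %*% Wk)) / d
  (h_to %*% Wv) * gate
}

#' Export cell embeddings as a tibble
#'
#' @param state an `embedding_state`.
#' @return Tibble: `cell_id` + d embedding columns (`e1..ed`).
#' @export
cell_embedding_table <- function(state) {
  m <- state$cell_emb
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  tibble::as_tibble(m) |> dplyr::mutate(cell_id = state$cell_ids, .before = 1)
}

#' Export gene embeddings as a tibble
#'
#' @param state an `embedding_state`.
#' @return Tibble: `cell_id`, `gene_id` + d embedding columns.
#' @export
gene_embedding_table <- function(state) {
  m <- state$gene_emb
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  tibble::as_tibble(m) |>
    dplyr::mutate(cell_id = rep(state$cell_ids, each = state$n_genes),
                  gene_id = rep(state$gene_ids, times = state$n_cells),
                  .before = 1)
}
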