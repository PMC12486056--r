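# Pretraining objectives: spatially-aware contrastive loss at three levels
# (cell-cell, gene-gene, cell-gene), masked auto-encoding of coordinates and
# expression, orthogonality regularization, and their learnable combination.
#
# The printed contrastive terms are log-probabilities (<= 0); they are
# implemented as their negation (InfoNCE form), so minimization pulls
# positive pairs together. Each component is averaged over its sampled units
# so batch size does not change the loss scale.

#' Contrastive configuration
#'
#' @param radius spatial radius r (same unit as positions) defining positive
#'   and negative candidates; `NULL` resolves to twice the median spatial
#'   edge length of the graph at hand.
#' @param temperature softmax temperature (> 0).
#' @param similarity `"cosine"` (default) or `"dot"`.
#' @param max_pos_pairs positive cell pairs sampled per evaluation.
#' @param max_negatives negatives kept per anchor cell.
#' @param gene_pairs_per_cell_pair co-expression-adjacent gene pairs sampled
#'   per positive cell pair for the gene-gene term.
#' @param max_gene_pairs overall cap on sampled gene pairs.
#' @param gg_negatives negatives per sampled gene pair (non-adjacent genes in
#'   negative-set cells).
#' @return List of class `contrastive_config`.
#' @export
contrastive_config <- function(radius = NULL, temperature = 0.1,
                               similarity = c("cosine", "dot"),
                               max_pos_pairs = 512, max_negatives = 16,
                               gene_pairs_per_cell_pair = 64,
                               max_gene_pairs = 4096, gg_negatives = 8) {
  similarity <- match.arg(similarity)
  if (!is.null(radius) && radius <= 0) stop_spathgt("radius must be > 0")
  if (temperature <= 0) stop_spathgt("temperature must be > 0")
  structure(list(radius = radius, temperature = temperature,
                 similarity = similarity,
                 max_pos_pairs = as.integer(max_pos_pairs),
                 max_negatives = as.integer(max_negatives),
                 gene_pairs_per_cell_pair = as.integer(gene_pairs_per_cell_pair),
                 max_gene_pairs = as.integer(max_gene_pairs),
                 gg_negatives = as.integer(gg_negatives)),
            class = "contrastive_config")
}

default_radius <- function(cg) {
  if (nrow(cg$edges) == 0) return(Inf)
  2 * median(cg$edge_lengths)
}

#' Positive pairs and per-cell negative sets
#'
#' Positives: unordered same-type cell pairs within Euclidean distance r.
#' Negatives of cell i: different-type cells within r of i. Computed with a
#' uniform-grid spatial index; identical to brute-force enumeration.
#'
#' @param cg a `spatial_graph` with `cell_types` set.
#' @param cfg a [contrastive_config()].
#' @return List with `pairs` (m x 2 integer, i < j) and `negatives` (list of
#'   integer vectors, one per cell), plus the resolved `radius`.
#' @export
positive_negative_sets <- function(cg, cfg = contrastive_config()) {
  stopifnot(inherits(cg, "spatial_graph"))
  if (is.null(cg$cell_types)) stop_spathgt("cell types are required")
  r <- cfg$radius %||% default_radius(cg)
  pos <- cg$positions; n <- nrow(pos); ct <- cg$cell_types
  bx <- floor(pos[, 1] / r); by <- floor(pos[, 2] / r)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  pairs <- vector("list", n)
  negatives <- vector("list", n)
  r2 <- r * r
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(bx[i] + dx, by[i] + dy)
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    d2 <- (pos[cand, 1] - pos[i, 1])^2 + (pos[cand, 2] - pos[i, 2])^2
    within <- cand[d2 <= r2]
    same <- within[ct[within] == ct[i]]
    negatives[[i]] <- sort(within[ct[within] != ct[i]])
    up <- same[same > i]
    if (length(up) > 0) pairs[[i]] <- cbind(i, sort(up))
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- matrix(integer(0), ncol = 2)
    warning("no positive pairs within radius ", signif(r, 4),
            "; contrastive term will be skipped", call. = FALSE)
  }
  list(pairs = unname(pairs), negatives = negatives, radius = r)
}

#' Bernoulli masks for masked auto-encoding
#'
#' Independent Bernoulli masks over cell coordinates and per-cell gene
#' entries, reproducible from the seed. Masked inputs are replaced by zero
#' (the mask token) before encoding.
#'
#' @param hg a `hier_graph`.
#' @param cell_rate,gene_rate masking rates in (0, 1).
#' @param seed integer seed.
#' @return Object of class `mask_spec`: `cell_mask` (logical |C|),
#'   `gene_mask` (|C| x |V| 0/1 matrix), `rates`, `seed`.
#' @export
make_masks <- function(hg, cell_rate = 0.1, gene_rate = 0.3, seed = 1) {
  stopifnot(inherits(hg, "hier_graph"))
  if (cell_rate <= 0 || cell_rate >= 1 || gene_rate <= 0 || gene_rate >= 1)
    stop_spathgt("mask rates must lie in (0, 1)")
  nC <- n_cells(hg); nV <- n_genes(hg)
  with_seed(seed, {
    cm <- runif(nC) < cell_rate
    gm <- matrix(as.numeric(runif(nC * nV) < gene_rate), nC, nV)
    structure(list(cell_mask = cm, gene_mask = gm,
                   rates = c(cell_rate = cell_rate, gene_rate = gene_rate),
                   seed = as.integer(seed)),
              class = "mask_spec")
  })
}

# ---- tape-level loss cores (shared by training and the plain wrappers) ----

# InfoNCE over a ragged set: scores (vector handle, already /temperature),
# groups = unit id per score, pos_flag marks the positive score of each unit.
# Returns the mean over units of log(sum exp) - s_pos.
infonce_from_scores <- function(scores, groups, pos_idx, n_units) {
  sc <- scores_as_col(scores)
  denom <- ad_segsum(ad_exp(sc), groups, n_units)   # n_units x 1
  lse <- ad_log(denom)
  s_pos <- ad_rows(sc, pos_idx)                     # n_units x 1
  ad_scale(ad_sum(ad_sub(lse, s_pos)), 1 / n_units)
}

resample <- function(x, k, replace = FALSE) x[sample.int(length(x), k, replace = replace)]

scores_as_col <- function(h) {
  if (!is.null(dim(h$val))) return(h)
  ad_push(h$tape, matrix(h$val, ncol = 1), h$id,
          function(g) list(as.numeric(g)))
}

sim_rows <- function(Z, cfg) if (cfg$similarity == "cosine") ad_l2norm_rows(Z) else Z

# sample up to k elements deterministically under the current RNG
samp <- function(x, k) if (length(x) <= k) x else x[sort(sample.int(length(x), k))]

contrastive_core <- function(tape, Zc, Zg, hg, sets, cfg, seed) {
  nC <- n_cells(hg); nV <- n_genes(hg)
  ct <- hg$cell_graph$cell_types
  tau <- cfg$temperature
  out <- list(l_cc = NULL, l_gg = NULL, l_cg = NULL)
  zero <- ad_wrap(tape, matrix(0, 1, 1))
  if (nrow(sets$pairs) == 0) {
    return(list(l_cc = zero, l_gg = zero, l_cg = zero))
  }
  with_seed(seed, {
    pr <- sets$pairs
    if (nrow(pr) > cfg$max_pos_pairs)
      pr <- pr[sort(sample.int(nrow(pr), cfg$max_pos_pairs)), , drop = FALSE]
    negs <- lapply(sets$negatives[pr[, 1]], samp, k = cfg$max_negatives)
    nneg <- lengths(negs)
    npair <- nrow(pr)

    Zcs <- sim_rows(Zc, cfg)
    # cell-cell: per pair, scores = {(i,j)} U {(i,k): k in N_i}
    anchors <- c(pr[, 1], rep(pr[, 1], nneg))
    partners <- c(pr[, 2], unlist(negs))
    groups <- c(seq_len(npair), rep(seq_len(npair), nneg))
    s_cc <- ad_scale(ad_rowdot(ad_rows(Zcs, anchors), ad_rows(Zcs, partners)),
                     1 / tau)
    out$l_cc <- infonce_from_scores(s_cc, groups, seq_len(npair), npair)

    # cell-gene: cell i versus the pooled gene row of its positive partner j,
    # negatives are pooled gene rows of cells in N_i
    Zbar <- ad_scale(ad_segsum(Zg, gene_row_cell(nC, nV), nC), 1 / nV)
    Zbs <- sim_rows(Zbar, cfg)
    s_cg <- ad_scale(ad_rowdot(ad_rows(Zcs, anchors), ad_rows(Zbs, partners)),
                     1 / tau)
    out$l_cg <- infonce_from_scores(s_cg, groups, seq_len(npair), npair)

    # gene-gene: adjacent gene pairs (p, q) across positive cell pairs,
    # negatives = non-adjacent genes r in negative cells k
    adj_by_type <- lapply(hg$gene_networks, function(net) {
      adj <- lapply(seq_len(nV), function(v) integer(0))
      for (e in seq_len(nrow(net$edges))) {
        adj[[net$edges[e, 1]]] <- c(adj[[net$edges[e, 1]]], net$edges[e, 2])
        adj[[net$edges[e, 2]]] <- c(adj[[net$edges[e, 2]]], net$edges[e, 1])
      }
      adj
    })
    acc_pair <- vector("list", npair)    # per positive pair: (i, j, p, q) rows
    acc_neg <- vector("list", npair)     # per positive pair: (unit_offset, k, r)
    unit <- 0L
    for (a in seq_len(npair)) {
      if (unit >= cfg$max_gene_pairs) break
      i <- pr[a, 1]; j <- pr[a, 2]
      net <- hg$gene_networks[[ct[i]]]
      if (nrow(net$edges) == 0 || nneg[a] == 0) next
      rows <- samp(seq_len(nrow(net$edges)),
                   min(cfg$gene_pairs_per_cell_pair, cfg$max_gene_pairs - unit))
      adj <- adj_by_type[[ct[i]]]
      pair_rows <- vector("list", length(rows))
      neg_rows <- vector("list", length(rows))
      kept <- 0L
      for (e in rows) {
        p <- net$edges[e, 1]; q <- net$edges[e, 2]
        ks <- samp(negs[[a]], cfg$gg_negatives)
        nonadj <- setdiff(seq_len(nV), c(p, adj[[p]]))
        if (length(nonadj) == 0 || length(ks) == 0) next
        unit <- unit + 1L; kept <- kept + 1L
        rs <- resample(nonadj, length(ks), replace = length(nonadj) < length(ks))
        pair_rows[[kept]] <- c(i, j, p, q)
        neg_rows[[kept]] <- cbind(unit, ks, rs)
      }
      if (kept > 0) {
        acc_pair[[a]] <- do.call(rbind, pair_rows[seq_len(kept)])
        acc_neg[[a]] <- do.call(rbind, neg_rows[seq_len(kept)])
      }
    }
    if (unit > 0) {
      PQ <- do.call(rbind, acc_pair[!vapply(acc_pair, is.null, logical(1))])
      NG <- do.call(rbind, acc_neg[!vapply(acc_neg, is.null, logical(1))])
      gp_i <- PQ[, 1]; gp_j <- PQ[, 2]; gp_p <- PQ[, 3]; gp_q <- PQ[, 4]
      gn_unit <- NG[, 1]; gn_k <- NG[, 2]; gn_r <- NG[, 3]
      Zgs <- sim_rows(Zg, cfg)
      a_rows <- c(gene_row_index(gp_i, gp_p, nV), gene_row_index(gp_i[gn_unit], gp_p[gn_unit], nV))
      b_rows <- c(gene_row_index(gp_j, gp_q, nV), gene_row_index(gn_k, gn_r, nV))
      groups_g <- c(seq_len(unit), gn_unit)
      s_gg <- ad_scale(ad_rowdot(ad_rows(Zgs, a_rows), ad_rows(Zgs, b_rows)),
                       1 / tau)
      out$l_gg <- infonce_from_scores(s_gg, groups_g, seq_len(unit), unit)
    } else {
      out$l_gg <- zero
    }
  })
  out
}

mae_core <- function(tape, pos_hat, expr_hat, init, masks) {
  nC <- nrow(init$pos_norm); nV <- init$n_genes
  zero <- ad_wrap(tape, matrix(0, 1, 1))
  mc <- which(masks$cell_mask)
  pos_term <- if (length(mc) == 0) zero else {
    diff <- ad_sub(ad_rows(pos_hat, mc), init$pos_norm_true[mc, , drop = FALSE])
    ad_scale(ad_sum(ad_square(diff)), 1 / length(mc))
  }
  mg <- which(t(masks$gene_mask) == 1)   # flat gene-row indices (k-1)nV+v
  expr_term <- if (length(mg) == 0) zero else {
    target <- matrix(as.vector(t(init$expr_true))[mg], ncol = 1)
    diff <- ad_sub(ad_rows(expr_hat, mg), target)
    cell_of <- (mg - 1L) %/% nV + 1L
    per_cell <- ad_segsum(ad_square(diff), cell_of, nC)
    counts <- tabulate(cell_of, nC)
    ad_scale(ad_sum(ad_rowscale(per_cell, 1 / pmax(counts, 1))), 1 / nC)
  }
  if (length(mc) == 0 && length(mg) == 0)
    warning("all masks empty; MAE loss is 0", call. = FALSE)
  ad_add(pos_term, expr_term)
}

ortho_core <- function(tape, Zc, Zg) {
  pen <- function(Z) {
    G <- ad_gram(ad_colnorm_unit(Z))
    ad_sum(ad_square(ad_sub(ad_wrap(tape, diag(ncol(Z$val))), G)))
  }
  ad_add(pen(Zc), pen(Zg))
}

total_core <- function(l_con, l_mae, l_ortho, gamma, lambda) {
  s <- ad_sigmoid(gamma)
  one_minus <- ad_sub(ad_wrap(s$tape, matrix(1, 1, 1)), s)
  ad_add(ad_add(ad_smul(l_con, s), ad_smul(l_mae, one_minus)),
         ad_scale(l_ortho, lambda))
}

# ---- plain (non-tape) user-facing wrappers ----

#' Spatially-aware contrastive loss
#'
#' Evaluates the three InfoNCE terms (cell-cell, gene-gene, cell-gene) on a
#' final embedding state, with positives/negatives from
#' [positive_negative_sets()] and seeded subsampling of pairs. Each term is
#' the mean over its sampled units; a unit with an empty negative set
#' contributes 0.
#'
#' @param state an `embedding_state` from [encode()].
#' @param sets a [positive_negative_sets()] result.
#' @param hg the `hier_graph` (provides the co-expression adjacency for the
#'   gene-gene term).
#' @param cfg a [contrastive_config()].
#' @param seed seed for pair/negative subsampling.
#' @return Named numeric: `l_cc`, `l_gg`, `l_cg`, `total`.
#' @export
contrastive_loss <- function(state, sets, hg, cfg = contrastive_config(), seed = 1) {
  tape <- ad_tape(record = FALSE)
  parts <- contrastive_core(tape, ad_wrap(tape, state$cell_emb),
                            ad_wrap(tape, state$gene_emb), hg, sets, cfg, seed)
  v <- vapply(parts, function(h) as.numeric(h$val), numeric(1))
  c(v, total = sum(v))
}

#' Masked auto-encoding loss
#'
#' Mean squared error restricted to masked entries: the positions term is the
#' mean over masked cells of the squared distance between predicted and true
#' min-max-normalized coordinates; the expression term averages each cell's
#' masked-entry MSE over all cells. Values at unmasked entries never enter.
#'
#' @param recon a [decode()] result.
#' @param hg the `hier_graph` holding the true expression and positions.
#' @param masks a [make_masks()] result.
#' @return Nonnegative scalar.
#' @export
mae_loss <- function(recon, hg, masks) {
  stopifnot(inherits(recon, "reconstruction"), inherits(masks, "mask_spec"))
  pos <- hg$cell_graph$positions
  pr <- hg$cell_graph$pos_range
  if (is.null(pr)) pr <- cbind(range(pos[, 1]), range(pos[, 2]))
  pn <- cbind(minmax01(pos[, 1], pr[, 1]), minmax01(pos[, 2], pr[, 2]))
  nC <- n_cells(hg)
  mc <- masks$cell_mask
  pos_term <- if (!any(mc)) 0 else
    mean(rowSums((recon$positions_hat[mc, , drop = FALSE] -
                    pn[mc, , drop = FALSE])^2))
  gm <- masks$gene_mask == 1
  if (!any(mc) && !any(gm)) warning("all masks empty; MAE loss is 0", call. = FALSE)
  err2 <- (recon$expression_hat - hg$expression$values)^2
  per_cell <- vapply(seq_len(nC), function(k) {
    m <- gm[k, ]
    if (!any(m)) 0 else mean(err2[k, m])
  }, numeric(1))
  pos_term + sum(per_cell) / nC
}

#' Orthogonality regularization
#'
#' Squared Frobenius deviation of the column Gram matrices of Zc and Zg from
#' the identity. Columns are scaled to unit norm first, so the identity
#' target is attainable and the penalty scale does not depend on the cell
#' count; the minimum (0) is reached exactly at orthogonal columns.
#'
#' @param Zc,Zg embedding matrices.
#' @return Nonnegative scalar.
#' @export
ortho_reg <- function(Zc, Zg) {
  pen <- function(Z) {
    s <- sqrt(colSums(Z^2) + 1e-12)
    G <- crossprod(sweep(Z, 2, s, "/"))
    sum((diag(ncol(Z)) - G)^2)
  }
  pen(Zc) + pen(Zg)
}

#' Combine loss components
#'
#' \eqn{L = \sigma(\gamma) L_{contrastive} + (1-\sigma(\gamma)) L_{mae} +
#' \lambda L_{ortho}} with learnable balance \eqn{\gamma} (updated by the same
#' optimizer during pretraining).
#'
#' @param l_contrastive,l_mae,l_ortho finite nonnegative components.
#' @param gamma balance scalar.
#' @param lambda orthogonality weight.
#' @return Object of class `loss_report`: tibble row with the components,
#'   `gamma`, the sigmoid weight and `total`.
#' @export
total_loss <- function(l_contrastive, l_mae, l_ortho, gamma = 0, lambda = 1e-3) {
  parts <- c(l_contrastive = l_contrastive, l_mae = l_mae, l_ortho = l_ortho)
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad) > 0) stop_spathgt("non-finite loss component: ",
                                    paste(bad, collapse = ", "))
  s <- 1 / (1 + exp(-gamma))
  structure(tibble::tibble(l_contrastive = l_contrastive, l_mae = l_mae,
                           l_ortho = l_ortho, gamma = gamma, weight = s,
                           total = s * l_contrastive + (1 - s) * l_mae +
                             lambda * l_ortho),
            class = c("loss_report", "tbl_df", "tbl", "data.frame"))
}
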