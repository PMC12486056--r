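#' Configuration for the synthetic-tissue generator
#'
#' The generator plants the four structures the modelling pipeline is built to
#' exploit: (i) cell types with distinct expression programs (marker-gene
#' shifts), (ii) block-structured gene co-expression modules (shared latent
#' factors), (iii) spatial niches that modulate expression within a cell type
#' (Voronoi regions around random anchors, with additive offsets on a subset
#' of genes), and (iv) zero-inflation noise (i.i.d. multiplicative dropout).
#'
#' Defaults describe the reference tissue used throughout the test suite:
#' 1500 cells, 60 genes, 3 types, 3 niches, 2 modules per type, dropout 0.4,
#' niche effect 0.8.
#'
#' @param n_cells,n_genes tissue size.
#' @param n_types,n_niches number of planted cell types / spatial niches.
#' @param modules_per_type co-expression modules per type; modules partition
#'   the gene set and each has a "home" type whose markers it carries.
#' @param niche_effect standard deviation of the additive niche offset applied
#'   to niche-responsive genes (a third of the gene panel).
#' @param dropout_rate probability that an observed entry is zeroed.
#' @param noise_sd per-entry Gaussian noise on the latent scale.
#' @param type_mix_strength probability mass a niche puts on its favoured cell
#'   type (remainder spread uniformly), coupling niches to composition.
#' @param seed integer seed; the tissue is a pure function of the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cells = 1500, n_genes = 60, n_types = 3,
                             n_niches = 3, modules_per_type = 2,
                             niche_effect = 0.8, dropout_rate = 0.4,
                             noise_sd = 0.3, type_mix_strength = 0.5,
                             seed = 1) {
  stopifnot(n_types >= 1, n_niches >= 1, n_cells >= n_types * 3,
            modules_per_type >= 1, niche_effect >= 0,
            dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0,
            type_mix_strength > 0, type_mix_strength <= 1)
  n_modules <- n_types * modules_per_type
  if (n_genes < n_modules) stop_spathgt("need at least one gene per module")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types), n_niches = as.integer(n_niches),
                 modules_per_type = as.integer(modules_per_type),
                 niche_effect = niche_effect, dropout_rate = dropout_rate,
                 noise_sd = noise_sd, type_mix_strength = type_mix_strength,
                 seed = as.integer(seed)),
            class = "generator_config")
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Generate a synthetic spatial tissue
#'
#' Draws cell positions uniformly in the unit square, assigns spatial niches
#' as Voronoi regions of random anchors, samples each cell's type from a
#' niche-dependent mixture, and builds expression as
#' \deqn{X_{kg} = \mathrm{softplus}(b_g + m_{t_k g} + \ell_g f_{k,M(g)} +
#'   e\,w_{n_k g} + \epsilon_{kg})}
#' where \eqn{b_g} is a gene baseline, \eqn{m} the type marker shift (+2 on a
#' type's home-module genes), \eqn{f_{k,m}} a per-cell module factor inducing
#' within-module correlation via loadings \eqn{\ell_g}, \eqn{w} the niche
#' offset on niche-responsive genes scaled by `niche_effect` \eqn{e}, and
#' \eqn{\epsilon} Gaussian noise. Observed expression applies i.i.d.
#' Bernoulli dropout to the clean matrix.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_tissue`: list with `cells` (tibble:
#'   cell_id, x, y, type, niche), `genes` (tibble: gene_id, module,
#'   niche_responsive), `clean` and `observed` cells x genes matrices,
#'   `config`.
#' @export
generate_tissue <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$seed, {
    nC <- cfg$n_cells; nG <- cfg$n_genes
    cell_ids <- sprintf("cell_%04d", seq_len(nC))
    gene_ids <- sprintf("g%03d", seq_len(nG))

    pos <- cbind(x = runif(nC), y = runif(nC))
    # niche anchors by farthest-point sampling from a candidate pool, so the
    # Voronoi regions are meso-scale and roughly balanced (tissue niches are
    # regions, not slivers)
    cand <- cbind(runif(64), runif(64))
    anchors <- cand[sample.int(64, 1), , drop = FALSE]
    while (nrow(anchors) < cfg$n_niches) {
      dmin <- apply(outer(cand[, 1], anchors[, 1], "-")^2 +
                      outer(cand[, 2], anchors[, 2], "-")^2, 1, min)
      anchors <- rbind(anchors, cand[which.max(dmin), ])
    }
    d2 <- outer(pos[, 1], anchors[, 1], "-")^2 + outer(pos[, 2], anchors[, 2], "-")^2
    niche <- max.col(-d2)

    # niche-dependent type mixture: niche j favours type ((j-1) mod T) + 1
    mix <- matrix((1 - cfg$type_mix_strength) / max(cfg$n_types - 1, 1),
                  cfg$n_niches, cfg$n_types)
    if (cfg$n_types == 1) mix[] <- 1
    for (j in seq_len(cfg$n_niches)) {
      fav <- (j - 1L) %% cfg$n_types + 1L
      if (cfg$n_types > 1) mix[j, fav] <- cfg$type_mix_strength
    }
    type <- vapply(niche, function(j) sample.int(cfg$n_types, 1, prob = mix[j, ]),
                   integer(1))

    n_modules <- cfg$n_types * cfg$modules_per_type
    module <- rep(seq_len(n_modules), length.out = nG)
    module <- sort(module)                       # contiguous blocks
    home_type <- (module - 1L) %/% cfg$modules_per_type + 1L

    baseline <- runif(nG, 0.5, 1.5)
    marker <- matrix(0, cfg$n_types, nG)         # type x gene marker shift
    for (t in seq_len(cfg$n_types)) marker[t, home_type == t] <- 2
    loading <- runif(nG, 0.6, 1.0)
    niche_responsive <- seq_len(nG) %in%
      sample.int(nG, max(1L, floor(nG / 3)))
    w <- matrix(0, cfg$n_niches, nG)
    w[, niche_responsive] <- rnorm(cfg$n_niches * sum(niche_responsive))

    factors <- matrix(rnorm(nC * n_modules), nC, n_modules)
    latent <- matrix(baseline, nC, nG, byrow = TRUE) +
      marker[type, , drop = FALSE] +
      factors[, module, drop = FALSE] * matrix(loading, nC, nG, byrow = TRUE) +
      cfg$niche_effect * w[niche, , drop = FALSE] +
      matrix(rnorm(nC * nG, sd = cfg$noise_sd), nC, nG)
    clean <- softplus(latent)
    keep <- matrix(rbinom(nC * nG, 1, 1 - cfg$dropout_rate), nC, nG)
    observed <- clean * keep
    dimnames(clean) <- dimnames(observed) <- list(cell_ids, gene_ids)

    structure(list(
      cells = tibble::tibble(cell_id = cell_ids, x = pos[, 1], y = pos[, 2],
                             type = paste0("T", type),
                             niche = paste0("N", niche)),
      genes = tibble::tibble(gene_id = gene_ids, module = module,
                             niche_responsive = niche_responsive),
      clean = clean, observed = observed, config = cfg),
      class = "synthetic_tissue")
  })
}

#' @exportS3Method base::print
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %d cells x %d genes | %d types, %d niches, seed %d\n",
              nrow(x$cells), ncol(x$clean), x$config$n_types,
              x$config$n_niches, x$config$seed))
  invisible(x)
}

#' Export a synthetic tissue as the CSV triplet dialect
#'
#' Writes `expression.csv` (observed matrix, first column `cell_id`, remaining
#' columns named by gene id), `coords.csv` (`cell_id,x,y`), `types.csv`
#' (`cell_id,cell_type`) — the dialect accepted by [read_dataset()] — plus a
#' ground-truth sidecar `truth_niches.csv` (`cell_id,niche`) and
#' `truth_modules.csv` (`gene_id,module`) for structure-recovery tests.
#'
#' @param tissue a [generate_tissue()] result.
#' @param dir output directory (created if missing).
#' @param overwrite overwrite existing files; if `FALSE` an existing file is an
#'   error.
#' @return Invisibly, a named character vector of the written paths.
#' @export
export_tissue <- function(tissue, dir, overwrite = FALSE) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             coords = file.path(dir, "coords.csv"),
             types = file.path(dir, "types.csv"),
             truth_niches = file.path(dir, "truth_niches.csv"),
             truth_modules = file.path(dir, "truth_modules.csv"))
  if (!overwrite && any(file.exists(paths))) {
    stop_spathgt("refusing to overwrite existing export: ",
                 paste(basename(paths[file.exists(paths)]), collapse = ", "))
  }
  expr_df <- data.frame(cell_id = rownames(tissue$observed),
                        tissue$observed, check.names = FALSE)
  utils::write.csv(expr_df, paths[["expression"]], row.names = FALSE)
  utils::write.csv(tissue$cells[, c("cell_id", "x", "y")], paths[["coords"]],
                   row.names = FALSE)
  utils::write.csv(data.frame(cell_id = tissue$cells$cell_id,
                              cell_type = tissue$cells$type),
                   paths[["types"]], row.names = FALSE)
  utils::write.csv(data.frame(cell_id = tissue$cells$cell_id,
                              niche = tissue$cells$niche),
                   paths[["truth_niches"]], row.names = FALSE)
  utils::write.csv(as.data.frame(tissue$genes[, c("gene_id", "module")]),
                   paths[["truth_modules"]], row.names = FALSE)
  invisible(paths)
}

#' Plot a synthetic tissue
#'
#' Scatter of cell positions coloured by cell type, faceted by niche label.
#'
#' @param object a `synthetic_tissue`.
#' @param colour_by `"type"` or `"niche"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_tissue <- function(object, colour_by = c("type", "niche"), ...) {
  colour_by <- match.arg(colour_by)
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = colour_by) +
    ggplot2::theme_minimal()
}
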