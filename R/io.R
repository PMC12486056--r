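# Dataset readers (CSV triplet, MTX triplet), run configuration, manifests.

#' Read a spatial expression dataset
#'
#' Two on-disk dialects are accepted, both producing the same in-memory
#' triple:
#' \itemize{
#'   \item CSV triplet — `expression.csv` (cells x genes; header row of gene
#'     ids, first column `cell_id`), `coords.csv` (`cell_id,x,y`), optional
#'     `types.csv` (`cell_id,cell_type`).
#'   \item MTX triplet — `expression.mtx` (cells x genes sparse), `cells.txt`
#'     (one cell id per line), `genes.txt` (one gene id per line), plus the
#'     same `coords.csv` / `types.csv`.
#' }
#' Coordinate and label columns are matched by name, never by position. Cell
#' ids must agree across files; a mismatch fails listing the first five
#' offenders.
#'
#' @param path directory containing the triplet, or the expression file
#'   itself (`.csv` or `.mtx`).
#' @param coords,types optional explicit paths overriding the defaults.
#' @return List with `expression` (an [expr_matrix], layer `raw`),
#'   `positions` (cells x 2 matrix) and `labels` (character or `NULL`).
#' @export
read_dataset <- function(path, coords = NULL, types = NULL) {
  if (dir.exists(path)) {
    dir <- path
    expr_path <- if (file.exists(file.path(dir, "expression.csv")))
      file.path(dir, "expression.csv") else file.path(dir, "expression.mtx")
  } else {
    expr_path <- path
    dir <- dirname(path)
  }
  if (!file.exists(expr_path)) stop_spathgt("no expression file at ", expr_path)
  coords <- coords %||% file.path(dir, "coords.csv")
  if (is.null(types) && file.exists(file.path(dir, "types.csv")))
    types <- file.path(dir, "types.csv")

  if (grepl("\\.mtx$", expr_path)) {
    m <- Matrix::readMM(expr_path)
    cells <- readLines(file.path(dir, "cells.txt"))
    genes <- readLines(file.path(dir, "genes.txt"))
    if (nrow(m) != length(cells) || ncol(m) != length(genes))
      stop_spathgt("MTX dimensions do not match cells.txt/genes.txt")
    values <- as.matrix(m)
    dimnames(values) <- list(cells, genes)
  } else {
    df <- utils::read.csv(expr_path, check.names = FALSE)
    if (!"cell_id" %in% names(df)) stop_spathgt("expression.csv needs a cell_id column")
    cells <- as.character(df$cell_id)
    values <- as.matrix(df[setdiff(names(df), "cell_id")])
    if (!is.numeric(values)) stop_spathgt("non-numeric expression values in ", expr_path)
    rownames(values) <- cells
  }
  expr <- expr_matrix(values, layer = "raw")

  cdf <- utils::read.csv(coords)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(cdf)))
    stop_spathgt("coords.csv must have columns cell_id,x,y")
  pos <- align_by_cell(cdf, expr$cell_ids, "coords.csv")
  positions <- as.matrix(pos[, c("x", "y")])
  rownames(positions) <- expr$cell_ids

  labels <- NULL
  if (!is.null(types)) {
    tdf <- utils::read.csv(types)
    if (!all(c("cell_id", "cell_type") %in% names(tdf)))
      stop_spathgt("types.csv must have columns cell_id,cell_type")
    labels <- as.character(align_by_cell(tdf, expr$cell_ids, "types.csv")$cell_type)
  }
  list(expression = expr, positions = positions, labels = labels)
}

align_by_cell <- function(df, cell_ids, what) {
  idx <- match(cell_ids, as.character(df$cell_id))
  if (anyNA(idx)) {
    miss <- head(cell_ids[is.na(idx)], 5)
    stop_spathgt(what, " is missing cell id(s): ", paste(miss, collapse = ", "))
  }
  df[idx, , drop = FALSE]
}

# ---- run configuration (YAML) ----

run_config_schema <- function() {
  list(
    simulate = setdiff(names(formals(generator_config)), ""),
    graph = c("n_hvg", "outlier_mads", "k_neighbors", "t_steps", "resolution",
              "tau_mode", "tau", "target_degree", "prune_quantile", "seed"),
    model = setdiff(names(formals(model_config)), ""),
    objectives = setdiff(names(formals(contrastive_config)), ""),
    training = setdiff(names(formals(train_config)), ""),
    eval = c("task", "mask_fraction", "mode", "k", "resolution", "seed",
             "hidden", "method")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with sections `simulate`, `graph`, `model`,
#' `objectives`, `training`, `eval` (all optional). Unknown sections or keys
#' are rejected. The returned list carries a `config_hash` attribute that is
#' stable under key reordering.
#'
#' @param path YAML file path.
#' @return Named list of sections with attribute `config_hash`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  schema <- run_config_schema()
  bad_sections <- setdiff(names(cfg), names(schema))
  if (length(bad_sections) > 0)
    stop_spathgt("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (s in names(cfg)) {
    bad <- setdiff(names(cfg[[s]]), schema[[s]])
    if (length(bad) > 0)
      stop_spathgt("unknown key(s) in section '", s, "': ",
                   paste(bad, collapse = ", "))
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Write a run manifest
#'
#' Every pipeline run writes a JSON manifest next to its outputs: the
#' resolved configuration and its hash, the seeds in effect, and package /
#' R versions — enough to reproduce the artifact.
#'
#' @param path output JSON path.
#' @param config resolved configuration list.
#' @param seed master seed in effect.
#' @param extra optional named list of extra fields.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  m <- c(list(config = config, config_hash = config_hash(config),
              seed = seed,
              package_version = as.character(utils::packageVersion("spathgt")),
              r_version = as.character(getRversion()),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(m)
}
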