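#' Cell-by-gene expression matrix with per-cell annotations
#'
#' The basic container used throughout the package: a dense numeric matrix of
#' nonnegative expression values with cells as rows and genes as columns, plus
#' a per-cell annotation table. Values are raw counts unless a function states
#' otherwise.
#'
#' @param values Numeric matrix, cells x genes, no negative entries.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cells Data frame with one row per cell and columns `barcode`,
#'   `cell_type`, `donor`, `modality` (modality is `"sc"` or `"sn"`).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (matrix), `gene_ids` (character) and `cells` (tibble).
#' @export
expr_matrix <- function(values, gene_ids, cells) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  cells <- tibble::as_tibble(cells)
  if (ncol(values) != length(gene_ids)) {
    rlang::abort("length(gene_ids) must equal ncol(values)")
  }
  if (anyDuplicated(gene_ids)) {
    rlang::abort("gene_ids must be unique")
  }
  if (nrow(cells) != nrow(values)) {
    rlang::abort("cell annotation table must have one row per cell")
  }
  needed <- c("barcode", "cell_type", "donor", "modality")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    rlang::abort(paste0("cell annotations lack column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(values < 0)) {
    rlang::abort("expression values must be nonnegative")
  }
  colnames(values) <- gene_ids
  rownames(values) <- cells$barcode
  structure(list(values = values, gene_ids = gene_ids, cells = cells),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes\n", nrow(x$values), ncol(x$values)))
  tab <- table(x$cells$cell_type, x$cells$modality)
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by cells and/or genes
#'
#' @param m An `expr_matrix`.
#' @param cells Integer or logical index over rows (cells).
#' @param genes Integer, logical, or character index over genes.
#' @return A new `expr_matrix`.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  ann <- m$cells
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    ann <- ann[cells, , drop = FALSE]
  }
  gid <- m$gene_ids
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, gid)
    v <- v[, genes, drop = FALSE]
    gid <- gid[genes]
  }
  expr_matrix(v, gid, ann)
}

#' Drop a set of genes from an expression matrix
#'
#' @param m An `expr_matrix`.
#' @param gene_set Character vector of gene ids to remove.
#' @return `expr_matrix` restricted to the complement of `gene_set`.
#' @export
drop_genes <- function(m, gene_set) {
  keep <- !(m$gene_ids %in% gene_set)
  if (!any(keep)) rlang::abort("gene removal set covers all genes")
  subset_cells(m, genes = which(keep))
}

#' Remove cell types with too few cells
#'
#' Retains exactly the cells whose cell type has at least `min_cells` members
#' in `m`; cell order is preserved. The default threshold of 50 cells matches
#' common deconvolution-reference practice: rarer types give unstable
#' signatures and cannot support held-out experiments.
#'
#' @param m An `expr_matrix`.
#' @param min_cells Minimum number of cells a type needs to be retained.
#' @return Filtered `expr_matrix`.
#' @export
filter_cell_types <- function(m, min_cells = 50) {
  stopifnot(inherits(m, "expr_matrix"), min_cells >= 1)
  counts <- table(m$cells$cell_type)
  keep_types <- names(counts)[counts >= min_cells]
  keep <- m$cells$cell_type %in% keep_types
  if (!any(keep)) rlang::abort("no cell types survive filter")
  subset_cells(m, cells = which(keep))
}

#' Restrict two expression matrices to their common genes
#'
#' Both outputs contain exactly the intersection of the two gene vocabularies,
#' in identical order. The ordering of the first matrix is preserved, which
#' keeps downstream reference/bulk alignment deterministic.
#'
#' @param a,b `expr_matrix` objects.
#' @return A list with elements `a` and `b`, gene-aligned.
#' @export
align_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  common <- a$gene_ids[a$gene_ids %in% b$gene_ids]
  if (length(common) == 0) rlang::abort("gene sets are disjoint: empty intersection")
  list(a = subset_cells(a, genes = common),
       b = subset_cells(b, genes = common))
}

#' Counts-per-million followed by log(1 + x)
#'
#' Each row (sample or cell) is scaled to sum to 1e6 and the natural log of
#' (x + 1) is applied elementwise. Rows that sum to zero cannot be normalized
#' and raise an error naming the offending row.
#'
#' @param values Numeric matrix, rows are samples/cells, columns genes.
#' @return Matrix of the same shape.
#' @export
cpm_log1p <- function(values) {
  values <- as.matrix(values)
  rs <- rowSums(values)
  bad <- which(rs <= 0)
  if (length(bad)) {
    nm <- rownames(values)[bad[1]]
    rlang::abort(sprintf("row %s has zero total counts; cannot CPM-normalize",
                         if (is.null(nm)) as.character(bad[1]) else nm))
  }
  log1p(values / rs * 1e6)
}

#' Sum disjoint groups of cells into aggregate profiles
#'
#' Draws `n_groups` disjoint groups of `group_size` cells each (sampling
#' without replacement over the whole matrix) and returns the elementwise sum
#' of each group. Aggregating counts before testing reduces single-cell
#' sparsity and avoids pseudo-replication in downstream differential
#' expression. Errors rather than re-using cells when too few are available.
#'
#' @param m An `expr_matrix` (typically already restricted to one cell type).
#' @param group_size Number of cells summed per aggregate.
#' @param n_groups Number of aggregates to form.
#' @param seed Integer seed.
#' @return Numeric matrix, `n_groups` x genes.
#' @export
aggregate_cells <- function(m, group_size = 10, n_groups, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"), group_size >= 1, n_groups >= 1)
  n <- nrow(m$values)
  if (n < group_size * n_groups) {
    rlang::abort(sprintf(
      "need %d cells for %d disjoint groups of %d, have %d",
      group_size * n_groups, n_groups, group_size, n))
  }
  idx <- with_seed(seed, sample.int(n, group_size * n_groups))
  groups <- split(idx, rep(seq_len(n_groups), each = group_size))
  out <- vapply(groups, function(g) colSums(m$values[g, , drop = FALSE]),
                numeric(ncol(m$values)))
  out <- t(out)
  colnames(out) <- m$gene_ids
  rownames(out) <- paste0("agg", seq_len(n_groups))
  out
}

# Run `expr` with a temporary RNG state seeded at `seed`, restoring the
# caller's RNG afterwards. All stochastic package functions go through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
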