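#' Write / read an expression matrix as MTX plus TSV sidecars
#'
#' `matrix.mtx` holds the counts in MatrixMarket coordinate format with cells
#' as rows; `genes.tsv` holds one gene id per line and `cells.tsv` the cell
#' annotations (`barcode`, `cell_type`, `donor`, `modality`).
#'
#' @param m An [expr_matrix()].
#' @param dir Output directory (created if needed).
#' @return `write_expr_matrix` the directory invisibly; `read_expr_matrix`
#'   the `expr_matrix`.
#' @export
write_expr_matrix <- function(m, dir) {
  stopifnot(inherits(m, "expr_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(m$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(dir) {
  values <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  cells <- tibble::as_tibble(
    utils::read.table(file.path(dir, "cells.tsv"), sep = "\t", header = TRUE,
                      colClasses = "character"))
  expr_matrix(values, gene_ids, cells)
}

#' Write / read a paired dataset's planted truth record as JSON
#'
#' @param dataset A [generate_paired_dataset()] result.
#' @param path JSON path.
#' @return `write_truth` the path invisibly; `read_truth` the truth list.
#' @export
write_truth <- function(dataset, path) {
  tr <- dataset$truth
  jsonlite::write_json(
    list(biased_gene_set = tr$biased_gene_set,
         retention = as.list(tr$retention),
         programs = as.data.frame(tr$programs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(biased_gene_set = as.character(raw$biased_gene_set),
       retention = unlist(raw$retention),
       programs = as.matrix(raw$programs))
}

#' Write / read a plain-text gene list (one gene per line)
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `write_gene_list` the path invisibly; `read_gene_list` the vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) readLines(path)

#' Serialize a DEG catalog to JSON
#'
#' @param catalog A `deg_catalog`.
#' @param path JSON path.
#' @return `write_deg_catalog` the path invisibly; `read_deg_catalog` the
#'   catalog.
#' @export
write_deg_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "deg_catalog"))
  payload <- list(
    alpha = catalog$alpha,
    dataset_union = catalog$dataset_union,
    provenance = catalog$provenance,
    per_type = lapply(catalog$per_type, function(e) {
      list(table = e$table, deg_set = e$deg_set)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_deg_catalog
#' @export
read_deg_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_type <- lapply(raw$per_type, function(e) {
    list(table = tibble::as_tibble(e$table),
         deg_set = as.character(unlist(e$deg_set)))
  })
  structure(list(per_type = per_type,
                 dataset_union = as.character(unlist(raw$dataset_union)),
                 provenance = tibble::as_tibble(raw$provenance),
                 alpha = raw$alpha), class = "deg_catalog")
}

#' Write a reference as MTX + annotated cells.tsv + genes.tsv
#'
#' The cell annotation gains `source_modality` and `transformed` provenance
#' columns.
#'
#' @param ref A [build_reference()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(ref$expression, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(ref$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(ref$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a signature matrix as CSV (genes x types)
#'
#' @param sig A [signature_matrix()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_signature <- function(sig, path) {
  utils::write.csv(as.data.frame(unclass(sig)), path, row.names = TRUE)
  invisible(path)
}

#' Write a pseudobulk set as CSVs
#'
#' `expression.csv` (samples x genes) and `truth.csv` (sample, scheme, one
#' column per type).
#'
#' @param ps A [generate_pseudobulk_set()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_pseudobulk_set <- function(ps, dir) {
  stopifnot(inherits(ps, "pseudobulk_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ps$expression, file.path(dir, "expression.csv"))
  utils::write.csv(ps$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an experiment configuration from YAML
#'
#' Validates the invariants an experiment needs: seeds for every stochastic
#' stage and declared prerequisites for gene-pruned variants.
#'
#' @param path YAML path.
#' @return A named list of class `experiment_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A raw configuration list.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed)) rlang::abort("config must set a seed")
  cfg$specs <- cfg$specs %||% c("scRNA All (PosCtrl)", "snRNA All (NegCtrl)")
  unknown <- setdiff(cfg$specs, reference_variants)
  if (length(unknown)) {
    rlang::abort(paste0("unknown reference variant(s): ",
                        paste(unknown, collapse = ", ")))
  }
  if (any(grepl("-DEG|-Random", cfg$specs)) && is.null(cfg$deg) &&
      is.null(cfg$deg_backend)) {
    cfg$deg_backend <- "deseq2"
  }
  structure(cfg, class = c("experiment_config", "list"))
}
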