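#' Differentially expressed genes between modalities, per cell type
#'
#' For each matched cell type, cells from each modality are summed into
#' disjoint 10-cell aggregates and the aggregates are tested gene-by-gene for
#' a modality effect with a negative-binomial GLM Wald test (DESeq2), adjusted
#' within type by Benjamini-Hochberg. Genes with adjusted p below `alpha` form
#' that type's DEG set; the catalog's `dataset_union` is the union over types.
#'
#' Aggregation reduces single-cell sparsity so that count-model assumptions
#' hold; groups are disjoint, so aggregates are independent replicates.
#'
#' @param sc,sn [expr_matrix()] objects sharing a gene vocabulary.
#' @param matched_types Cell types to test; default: types present in both
#'   modalities with at least `2 * group_size` cells in each. A held-out type
#'   can be excluded by passing the remaining types explicitly.
#' @param group_size Cells summed per aggregate (default 10).
#' @param alpha Adjusted-p threshold defining a DEG (default 0.01). With
#'   `alpha >= 1` every gene with a finite p-value is returned.
#' @param n_aggregates Aggregates per modality per type; default
#'   `floor(n_cells / group_size)` capped at the smaller modality, minimum 2.
#' @param backend `"deseq2"` (NB GLM Wald; adjusted p-values are plain BH:
#'   independent filtering and Cook's cutoff are disabled) or `"welch"`
#'   (Welch t-test on log-CPM aggregates).
#' @param seed Integer seed for the aggregate draws.
#'
#' @return A `deg_catalog`: list with `per_type` (per-type tibble of `gene`,
#'   `p`, `padj` plus `deg_set`), `dataset_union`, `provenance`, `alpha`.
#' @export
compute_modality_degs <- function(sc, sn, matched_types = NULL, group_size = 10,
                                  alpha = 0.01, n_aggregates = NULL,
                                  backend = c("deseq2", "welch"), seed = 1) {
  backend <- match.arg(backend)
  stopifnot(inherits(sc, "expr_matrix"), inherits(sn, "expr_matrix"))
  if (!identical(sc$gene_ids, sn$gene_ids)) {
    rlang::abort("sc and sn must share an identical ordered gene vocabulary; run align_genes() first")
  }
  sc_n <- table(sc$cells$cell_type)
  sn_n <- table(sn$cells$cell_type)
  if (is.null(matched_types)) {
    matched_types <- intersect(names(sc_n)[sc_n >= 2 * group_size],
                               names(sn_n)[sn_n >= 2 * group_size])
  } else {
    missing <- matched_types[!(matched_types %in% names(sc_n) &
                                 matched_types %in% names(sn_n))]
    if (length(missing)) {
      rlang::abort(paste0("matched type(s) missing from one modality: ",
                          paste(missing, collapse = ", ")))
    }
  }
  if (!length(matched_types)) rlang::abort("no matched cell types to test")

  per_type <- list()
  prov <- list()
  for (i in seq_along(matched_types)) {
    tp <- matched_types[[i]]
    m_sc <- subset_cells(sc, cells = which(sc$cells$cell_type == tp))
    m_sn <- subset_cells(sn, cells = which(sn$cells$cell_type == tp))
    n_agg <- n_aggregates %||%
      max(2, min(floor(nrow(m_sc$values) / group_size),
                 floor(nrow(m_sn$values) / group_size)))
    agg_sc <- aggregate_cells(m_sc, group_size, n_agg, seed = seed + 1000L * i)
    agg_sn <- aggregate_cells(m_sn, group_size, n_agg, seed = seed + 1000L * i + 1L)
    tab <- switch(backend,
      deseq2 = deg_test_deseq2(agg_sc, agg_sn),
      welch  = deg_test_welch(agg_sc, agg_sn))
    deg <- if (alpha >= 1) tab$gene[is.finite(tab$p)]
           else tab$gene[!is.na(tab$padj) & tab$padj < alpha]
    per_type[[tp]] <- list(table = tab, deg_set = deg)
    prov[[tp]] <- tibble::tibble(cell_type = tp, n_aggregates = n_agg,
                                 group_size = group_size, backend = backend)
  }
  structure(list(
    per_type = per_type,
    dataset_union = sort(unique(unlist(lapply(per_type, `[[`, "deg_set")))),
    provenance = dplyr::bind_rows(prov),
    alpha = alpha), class = "deg_catalog")
}

# NB GLM Wald test on aggregates via DESeq2; plain BH adjustment.
deg_test_deseq2 <- function(agg_sc, agg_sn) {
  counts <- t(rbind(agg_sc, agg_sn))  # genes x samples
  mode(counts) <- "integer"
  coldata <- S4Vectors::DataFrame(
    modality = factor(rep(c("sc", "sn"), c(nrow(agg_sc), nrow(agg_sn))),
                      levels = c("sc", "sn")))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, design = ~ modality)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, independentFiltering = FALSE, cooksCutoff = FALSE,
                         pAdjustMethod = "BH")
  tibble::tibble(gene = rownames(res), p = res$pvalue, padj = res$padj,
                 log2fc = res$log2FoldChange)
}

# Welch two-sample t-test per gene on log aggregates (vectorized).
# Library sizes are equalized with median-of-ratios size factors (computed
# over genes positive in every aggregate, as in DESeq) so that a minority of
# strongly depleted genes does not shift the apparent level of every other
# gene the way plain CPM scaling would.
deg_test_welch <- function(agg_sc, agg_sn) {
  all_agg <- rbind(agg_sc, agg_sn)
  ok <- colSums(all_agg == 0) == 0
  if (!any(ok)) rlang::abort("no gene is observed in every aggregate")
  log_ref <- colMeans(log(all_agg[, ok, drop = FALSE]))
  sf <- apply(all_agg[, ok, drop = FALSE], 1, function(r) {
    exp(stats::median(log(r) - log_ref))
  })
  norm <- log1p(all_agg / sf)
  a <- norm[seq_len(nrow(agg_sc)), , drop = FALSE]
  b <- norm[-seq_len(nrow(agg_sc)), , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[se2 == 0] <- NA_real_
  tibble::tibble(gene = colnames(a), p = unname(p),
                 padj = unname(stats::p.adjust(p, method = "BH")),
                 log2fc = unname(m2 - m1) / log(2))
}

#' @export
print.deg_catalog <- function(x, ...) {
  cat(sprintf("<deg_catalog> %d cell type(s), union of %d DEGs at padj < %g\n",
              length(x$per_type), length(x$dataset_union), x$alpha))
  invisible(x)
}

#' Tidy a DEG catalog into a long per-gene table
#'
#' @param x A `deg_catalog`.
#' @param ... Unused.
#' @return Tibble with columns `cell_type`, `gene`, `p`, `padj`, `log2fc`,
#'   `is_deg`.
#' @method tidy deg_catalog
#' @export
tidy.deg_catalog <- function(x, ...) {
  purrr::imap_dfr(x$per_type, function(entry, tp) {
    entry$table |>
      dplyr::mutate(cell_type = tp, is_deg = .data$gene %in% entry$deg_set,
                    .before = 1)
  })
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-dataset intersection of per-dataset DEG unions
#'
#' A gene qualifies when it is differentially expressed in at least one cell
#' type in every catalog supplied.
#'
#' @param catalogs List of `deg_catalog` objects (>= 2).
#' @return Character vector of gene ids.
#' @export
intersection_degs <- function(catalogs) {
  stopifnot(length(catalogs) >= 2)
  unions <- lapply(catalogs, function(ct) ct$dataset_union)
  sort(Reduce(intersect, unions))
}

#' Union of DEG unions over all datasets except one
#'
#' @param catalogs Named list of `deg_catalog` objects.
#' @param exclude_dataset Name of the catalog to leave out.
#' @return Character vector of gene ids.
#' @export
other_datasets_degs <- function(catalogs, exclude_dataset) {
  if (!exclude_dataset %in% names(catalogs)) {
    rlang::abort(sprintf("dataset '%s' not present in catalogs", exclude_dataset))
  }
  others <- catalogs[setdiff(names(catalogs), exclude_dataset)]
  sort(unique(as.character(unlist(lapply(others, function(ct) ct$dataset_union)))))
}

#' Size-matched random gene set avoiding the DEG sets
#'
#' Samples uniformly without replacement from `pool` minus `exclusions`; used
#' as the negative control for DEG pruning (removing an arbitrary gene set of
#' the same size).
#'
#' @param pool Character vector: eligible gene ids (the shared reference/bulk
#'   feature space).
#' @param size Number of genes to draw.
#' @param exclusions Gene ids that may not be drawn (DEG union and
#'   cross-dataset intersection).
#' @param seed Integer seed.
#' @return Character vector of `size` gene ids.
#' @export
sample_random_genes <- function(pool, size, exclusions = character(), seed = 1) {
  eligible <- setdiff(pool, exclusions)
  if (length(eligible) < size) {
    rlang::abort(sprintf("only %d eligible genes for a sample of %d",
                         length(eligible), size))
  }
  if (size == 0) return(character())
  with_seed(seed, sort(sample(eligible, size)))
}
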