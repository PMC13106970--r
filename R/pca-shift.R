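#' Fit the PCA model underlying the latent-space shift
#'
#' Counts are log(1+x) transformed, standardized per gene to zero mean and
#' unit variance (zero-variance genes are dropped and recorded so they can be
#' restored as zeros on back-projection), and a PCA is fitted to the
#' concatenation of the whole-cell cells and the overlapping nuclear cells.
#' The number of retained components is the smallest reaching at least
#' `variance_target` cumulative explained variance. The held-out cell type
#' must already be absent from both inputs.
#'
#' @param sc [expr_matrix()] of whole-cell training cells.
#' @param sn_overlap [expr_matrix()] of nuclear cells of types shared with sc.
#' @param variance_target Cumulative explained-variance fraction (default
#'   0.75); 1 keeps all components and makes the projection lossless.
#' @return A `pca_model`: centering/scaling vectors, retained loading matrix,
#'   `k`, explained-variance profile, gene bookkeeping.
#' @export
fit_pca <- function(sc, sn_overlap = NULL, variance_target = 0.75) {
  stopifnot(inherits(sc, "expr_matrix"),
            variance_target > 0, variance_target <= 1)
  x <- sc$values
  if (!is.null(sn_overlap)) {
    stopifnot(inherits(sn_overlap, "expr_matrix"))
    if (!identical(sc$gene_ids, sn_overlap$gene_ids)) {
      rlang::abort("sc and sn_overlap must share gene vocabulary")
    }
    x <- rbind(x, sn_overlap$values)
  }
  if (nrow(x) < 2) rlang::abort("need at least 2 training cells")
  xl <- log1p(x)
  center <- colMeans(xl)
  scale_ <- apply(xl, 2, stats::sd)
  keep <- scale_ > 0
  if (!any(keep)) rlang::abort("all genes have zero variance")
  xs <- sweep(sweep(xl[, keep, drop = FALSE], 2, center[keep]), 2,
              scale_[keep], "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  structure(list(
    gene_ids = sc$gene_ids, keep = keep,
    center = center[keep], scale = scale_[keep],
    rotation = pc$rotation[, seq_len(k), drop = FALSE],
    k = k, variance_target = variance_target, explained = ev,
    n_train = nrow(x)), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> k = %d components (%.1f%% variance), %d genes, %d training cells\n",
              x$k, 100 * sum(x$explained[seq_len(x$k)]), sum(x$keep), x$n_train))
  invisible(x)
}

#' Project cells into a fitted PCA space
#'
#' @param model A `pca_model`.
#' @param m An [expr_matrix()] or counts matrix with the model's genes.
#' @return Cells x k latent matrix.
#' @export
project_pca <- function(model, m) {
  v <- if (inherits(m, "expr_matrix")) m$values else as.matrix(m)
  if (ncol(v) != length(model$gene_ids)) rlang::abort("gene set mismatch with PCA model")
  xs <- sweep(sweep(log1p(v[, model$keep, drop = FALSE]), 2, model$center), 2,
              model$scale, "/")
  xs %*% model$rotation
}

#' Back-project latent coordinates to expression
#'
#' Inverts the projection, un-standardizes, applies expm1, clips negatives to
#' zero and restores dropped zero-variance genes as zeros.
#'
#' @param model A `pca_model`.
#' @param z Cells x k latent matrix.
#' @return Cells x genes nonnegative expression matrix.
#' @export
inverse_pca <- function(model, z) {
  xs <- z %*% t(model$rotation)
  xl <- sweep(sweep(xs, 2, model$scale, "*"), 2, model$center, "+")
  out <- matrix(0, nrow(z), length(model$gene_ids),
                dimnames = list(rownames(z), model$gene_ids))
  out[, model$keep] <- pmax(expm1(xl), 0)
  out
}

#' Per-cell shift field anchoring nuclear cells to the whole-cell centroid
#'
#' For every overlapping nuclear cell, the shift vector is the whole-cell
#' centroid minus that cell's latent position (the vector later added to a
#' missing cell's coordinates).
#'
#' @param sc_latent Latent coordinates of whole-cell cells.
#' @param overlap_latent Latent coordinates of overlapping nuclear cells.
#' @param k_nn Neighbour count used when the field is applied (default 10).
#' @return A `latent_shift`: `overlap_latent`, `shifts`, `centroid`, `k_nn`.
#' @export
latent_shift <- function(sc_latent, overlap_latent, k_nn = 10) {
  sc_latent <- as.matrix(sc_latent); overlap_latent <- as.matrix(overlap_latent)
  stopifnot(ncol(sc_latent) == ncol(overlap_latent), k_nn >= 1)
  centroid <- colMeans(sc_latent)
  shifts <- sweep(-overlap_latent, 2, centroid, "+")
  structure(list(overlap_latent = overlap_latent, shifts = shifts,
                 centroid = centroid, k_nn = k_nn), class = "latent_shift")
}

#' Shift missing-type cells by their neighbours' shift vectors
#'
#' Each missing-type cell receives the mean shift vector of its `k_nn`
#' nearest overlapping nuclear cells (Euclidean distance in the latent space);
#' ties are broken by stable cell index.
#'
#' @param missing_latent Latent coordinates of the missing-type cells.
#' @param shifts A [latent_shift()].
#' @return Shifted latent matrix, same shape as `missing_latent`.
#' @export
neighbor_shift <- function(missing_latent, shifts) {
  stopifnot(inherits(shifts, "latent_shift"))
  missing_latent <- as.matrix(missing_latent)
  ov <- shifts$overlap_latent
  k <- shifts$k_nn
  if (nrow(ov) < k) {
    rlang::abort(sprintf("only %d overlap cells for k_nn = %d", nrow(ov), k))
  }
  # squared-distance matrix missing x overlap via the expansion trick
  d2 <- outer(rowSums(missing_latent^2), rowSums(ov^2), "+") -
    2 * missing_latent %*% t(ov)
  shift_mat <- t(apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)]   # order() is stable: ties -> lowest index
    colMeans(shifts$shifts[nn, , drop = FALSE])
  }))
  if (ncol(missing_latent) == 1) shift_mat <- matrix(shift_mat, ncol = 1)
  missing_latent + shift_mat
}

#' PCA latent-shift transform of missing-type nuclear cells
#'
#' Projects the missing cells into the fitted PCA space, applies the
#' neighbour-based shift toward the whole-cell centroid, back-projects to
#' expression, and rescales every cell to the target library size (by default
#' the median whole-cell library size).
#'
#' @param missing_sn [expr_matrix()] of the missing-type nuclear cells.
#' @param model A `pca_model` fitted without the missing type.
#' @param shifts A [latent_shift()] built in the same latent space.
#' @param target_lib_size Per-cell total counts of the output.
#' @return Cells x genes nonnegative matrix, rows summing to
#'   `target_lib_size`.
#' @export
pca_ls_transform <- function(missing_sn, model, shifts, target_lib_size) {
  stopifnot(inherits(missing_sn, "expr_matrix"))
  if (!identical(missing_sn$gene_ids, model$gene_ids)) {
    rlang::abort("gene set mismatch between missing cells and PCA model")
  }
  z <- project_pca(model, missing_sn)
  z_shifted <- neighbor_shift(z, shifts)
  out <- inverse_pca(model, z_shifted)
  rescale_rows(out, target_lib_size)
}

# Rescale each row to a fixed total; errors on all-zero rows.
rescale_rows <- function(x, target) {
  rs <- rowSums(x)
  if (any(rs <= 0)) rlang::abort("cannot rescale: a cell has zero total expression")
  x / rs * target
}

#' Median library size of an expression matrix
#'
#' @param m [expr_matrix()] or counts matrix.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Scalar library size.
#' @export
median_lib_size <- function(m, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  v <- if (inherits(m, "expr_matrix")) m$values else as.matrix(m)
  rs <- rowSums(v)
  if (stat == "median") stats::median(rs) else mean(rs)
}
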