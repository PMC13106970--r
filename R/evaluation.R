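#' Pearson correlation of two vectors
#'
#' @param u,v Numeric vectors of equal length >= 2, both nonconstant.
#' @return Sample Pearson correlation.
#' @export
pearson <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    rlang::abort("correlation undefined for constant input")
  }
  stats::cor(u, v)
}

#' Root mean squared error
#'
#' @param u,v Numeric vectors of equal, positive length.
#' @return sqrt(mean((u - v)^2)).
#' @export
rmse <- function(u, v) {
  if (!length(u) || length(u) != length(v)) {
    rlang::abort("rmse needs two nonempty vectors of equal length")
  }
  sqrt(mean((u - v)^2))
}

#' Cosine similarity
#'
#' @param u,v Numeric vectors, both nonzero.
#' @return dot(u, v) / (||u|| ||v||).
#' @export
cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) rlang::abort("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Accuracy metrics under the three evaluation scenarios
#'
#' Compares predicted and ground-truth proportion tables. `all_cells`
#' computes a per-sample Pearson and RMSE across all type columns;
#' `non_removed` does the same after dropping the held-out column with no
#' renormalization (the exclusion is an evaluation choice, not a rescaling);
#' `removed_only` computes one Pearson/RMSE across samples on the held-out
#' column alone, since a per-sample correlation over a single type is
#' undefined.
#'
#' @param pred,truth Proportion tables ([deconvolve_nnls()] /
#'   [generate_pseudobulk_set()] `truth`) sharing samples and types.
#' @param scenario `"all_cells"`, `"non_removed"` or `"removed_only"`.
#' @param held_out_type Required for the latter two scenarios.
#' @return A tibble of class `scenario_metrics`: columns `sample`, `pearson`,
#'   `rmse` (per sample) or a single row with `sample = NA` (removed_only);
#'   attributes `scenario` and `held_out_type`.
#' @export
scenario_metrics <- function(pred, truth,
                             scenario = c("all_cells", "non_removed",
                                          "removed_only"),
                             held_out_type = NULL) {
  scenario <- match.arg(scenario)
  p <- prop_matrix(pred); t_ <- prop_matrix(truth)
  common_types <- intersect(colnames(p), colnames(t_))
  if (!length(common_types)) rlang::abort("no shared cell types")
  if (!is.null(rownames(p)) && !is.null(rownames(t_))) {
    t_ <- t_[match(rownames(p), rownames(t_)), , drop = FALSE]
  }
  stopifnot(nrow(p) == nrow(t_))
  p <- p[, common_types, drop = FALSE]; t_ <- t_[, common_types, drop = FALSE]

  if (scenario != "all_cells") {
    if (is.null(held_out_type)) {
      rlang::abort(sprintf("scenario '%s' needs held_out_type", scenario))
    }
    if (!all(held_out_type %in% common_types)) {
      rlang::abort("held-out type missing from proportion columns (controls have no direct comparison)")
    }
  }
  if (scenario == "non_removed") {
    keep <- setdiff(common_types, held_out_type)
    if (length(keep) < 2) {
      rlang::abort("fewer than 2 remaining types: per-sample correlation undefined; use removed_only-style pooling")
    }
    p <- p[, keep, drop = FALSE]; t_ <- t_[, keep, drop = FALSE]
  }
  # constant vectors (e.g. a degenerate estimate) give NA, dropped pairwise
  # downstream, rather than aborting a whole sweep
  safe_pearson <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }
  out <- if (scenario == "removed_only") {
    pu <- p[, held_out_type[1]]; tu <- t_[, held_out_type[1]]
    tibble::tibble(sample = NA_character_,
                   pearson = safe_pearson(pu, tu), rmse = rmse(pu, tu))
  } else {
    tibble::tibble(
      sample = rownames(p) %||% as.character(seq_len(nrow(p))),
      pearson = vapply(seq_len(nrow(p)),
                       function(i) safe_pearson(p[i, ], t_[i, ]), numeric(1)),
      rmse = vapply(seq_len(nrow(p)), function(i) rmse(p[i, ], t_[i, ]),
                    numeric(1)))
  }
  structure(out, scenario = scenario, held_out_type = held_out_type,
            class = c("scenario_metrics", class(out)))
}

#' Summarize scenario metrics
#'
#' @param x A [scenario_metrics()] tibble.
#' @param n_boot,level,seed Bootstrap settings for the CI of the mean.
#' @param ... Unused.
#' @return One-row tibble: mean and bootstrap CI per metric.
#' @method glance scenario_metrics
#' @export
glance.scenario_metrics <- function(x, n_boot = 1000, level = 0.95,
                                    seed = 1, ...) {
  pe <- x$pearson[!is.na(x$pearson)]
  ci_p <- bootstrap_ci_mean(pe, n_boot, level, seed)
  ci_r <- bootstrap_ci_mean(x$rmse, n_boot, level, seed + 1)
  tibble::tibble(
    scenario = attr(x, "scenario"), n = nrow(x),
    pearson_mean = mean(pe), pearson_low = ci_p[1], pearson_high = ci_p[2],
    rmse_mean = mean(x$rmse), rmse_low = ci_r[1], rmse_high = ci_r[2])
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Numeric vector (>= 1 value).
#' @param n_boot Resamples (default 1000).
#' @param level Coverage (default 0.95, i.e. the 2.5/97.5 percentiles).
#' @param seed Integer seed.
#' @return Length-2 vector `c(low, high)`.
#' @export
bootstrap_ci_mean <- function(values, n_boot = 1000, level = 0.95, seed = 1) {
  if (!length(values)) rlang::abort("empty input")
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i) {
      mean(sample(values, length(values), replace = TRUE))
    }, numeric(1))
    a <- (1 - level) / 2
    unname(stats::quantile(means, c(a, 1 - a)))
  })
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed independent Student's t-test assuming equal variances; missing
#' values are dropped per group.
#'
#' @param a,b Numeric vectors (each >= 2 non-missing values).
#' @return List with `t` and `p`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) rlang::abort("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    rlang::abort("degenerate (zero pooled variance) with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Cosine similarity of transformed nuclear profiles to whole-cell signatures
#'
#' For each cell type present on both sides: sample `n_cells` cells per side,
#' sum them into an aggregate (reducing sparsity), CPM-log1p normalize both
#' aggregates (so similarity reflects relative expression patterns, not
#' depth) and take the cosine.
#'
#' @param transformed_sn [expr_matrix()] of (possibly transformed) nuclear
#'   cells.
#' @param sc [expr_matrix()] of whole-cell cells, gene-aligned.
#' @param n_cells Cells aggregated per side (default 50).
#' @param seed Integer seed.
#' @return Tibble: `cell_type`, `cosine`.
#' @export
celltype_signature_similarity <- function(transformed_sn, sc, n_cells = 50,
                                          seed = 1) {
  stopifnot(inherits(transformed_sn, "expr_matrix"), inherits(sc, "expr_matrix"))
  if (!identical(transformed_sn$gene_ids, sc$gene_ids)) {
    rlang::abort("inputs must be gene-aligned")
  }
  types <- intersect(unique(transformed_sn$cells$cell_type),
                     unique(sc$cells$cell_type))
  if (!length(types)) rlang::abort("no shared cell types")
  rows <- purrr::map_dfr(sort(types), function(tp) {
    a <- subset_cells(transformed_sn,
                      cells = which(transformed_sn$cells$cell_type == tp))
    b <- subset_cells(sc, cells = which(sc$cells$cell_type == tp))
    if (nrow(a$values) < n_cells || nrow(b$values) < n_cells) {
      rlang::abort(sprintf("type '%s' has fewer than %d cells on one side",
                           tp, n_cells))
    }
    # same per-type seed on both sides: identical inputs give cosine exactly 1
    agg_a <- aggregate_cells(a, group_size = n_cells, n_groups = 1,
                             seed = seed + match(tp, sort(types)))
    agg_b <- aggregate_cells(b, group_size = n_cells, n_groups = 1,
                             seed = seed + match(tp, sort(types)))
    tibble::tibble(cell_type = tp,
                   cosine = cosine(cpm_log1p(agg_a)[1, ], cpm_log1p(agg_b)[1, ]))
  })
  rows
}

#' Pairwise cosine concordance of proportion estimates
#'
#' Flattens each entity's proportion table row-major and computes all
#' pairwise cosines; used for inter-transform and inter-donor robustness.
#'
#' @param estimates Named list of proportion tables sharing samples x types
#'   shape and ordering.
#' @return A `concordance_matrix`: symmetric entity x entity matrix with unit
#'   diagonal.
#' @export
concordance_matrix <- function(estimates) {
  stopifnot(length(estimates) >= 2, !is.null(names(estimates)))
  mats <- lapply(estimates, prop_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("estimates differ in samples x types shape")
  }
  vecs <- vapply(mats, function(m) as.numeric(t(m)), numeric(prod(dims[, 1])))
  k <- length(estimates)
  cm <- matrix(1, k, k, dimnames = list(names(estimates), names(estimates)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cm[i, j] <- cm[j, i] <- cosine(vecs[, i], vecs[, j])
    }
  }
  structure(cm, class = c("concordance_matrix", class(cm)))
}

#' Off-diagonal entries of a concordance matrix, long form
#'
#' Each unordered pair appears once per member entity, matching "averaged per
#' transform" semantics downstream.
#'
#' @param cm A [concordance_matrix()].
#' @return Tibble: `entity`, `other`, `cosine`.
#' @export
concordance_long <- function(cm) {
  ents <- rownames(cm)
  purrr::map_dfr(ents, function(e) {
    others <- setdiff(ents, e)
    tibble::tibble(entity = e, other = others, cosine = cm[e, others])
  })
}
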