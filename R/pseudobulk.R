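#' Random cell-type proportions from a symmetric Dirichlet
#'
#' Draws a proportion vector from a flat Dirichlet (all concentrations 1),
#' converts it to integer cell counts against `n_cells`, and redraws until
#' every type receives at least one cell.
#'
#' @param n_types Number of cell types (>= 1).
#' @param n_cells Cells composing the pseudobulk (default 1000).
#' @param seed Integer seed.
#' @return List with `proportions` (numeric, sums to 1) and `counts`
#'   (integers summing to `n_cells`, all >= 1).
#' @export
random_proportions <- function(n_types, n_cells = 1000, seed = 1) {
  stopifnot(n_types >= 1)
  if (n_cells < n_types) {
    rlang::abort("n_cells < n_types: zero counts unavoidable")
  }
  with_seed(seed, {
    repeat {
      p <- as.numeric(rdirichlet(1, rep(1, n_types)))
      counts <- integerize_counts(p, n_cells)
      if (all(counts >= 1)) {
        return(list(proportions = p, counts = counts))
      }
    }
  })
}

#' Realistic cell-type proportions around an empirical vector
#'
#' Perturbs the empirical proportions with iid Gaussian noise (SD 0.01 by
#' default), clips negatives, renormalizes to sum 1, integerizes and redraws
#' on zero counts.
#'
#' @param empirical Numeric vector of base proportions (sums to 1).
#' @param sd Noise standard deviation (default 0.01).
#' @param n_cells Cells composing the pseudobulk.
#' @param seed Integer seed.
#' @return As [random_proportions()].
#' @export
realistic_proportions <- function(empirical, sd = 0.01, n_cells = 1000, seed = 1) {
  stopifnot(all(empirical >= 0), abs(sum(empirical) - 1) < 1e-6)
  n_types <- length(empirical)
  if (n_cells < n_types) {
    rlang::abort("n_cells < n_types: zero counts unavoidable")
  }
  with_seed(seed, {
    repeat {
      p <- empirical + stats::rnorm(n_types, 0, sd)
      p <- pmax(p, 0)
      if (sum(p) == 0) next
      p <- p / sum(p)
      counts <- integerize_counts(p, n_cells)
      if (all(counts >= 1)) {
        return(list(proportions = p, counts = counts))
      }
    }
  })
}

# proportions * n_cells -> integers summing to n_cells by the largest-
# remainder method: floor everything, then hand the missing cells to the
# types with the largest fractional parts (ties to the lowest index), so no
# count deviates from proportion * n_cells by 1 or more.
integerize_counts <- function(p, n_cells) {
  raw <- p * n_cells
  counts <- floor(raw)
  rem <- raw - counts
  short <- n_cells - sum(counts)
  if (short > 0) {
    give <- order(-rem)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Compose one pseudobulk from sampled cells
#'
#' Samples the requested number of cells per type from the pool (without
#' replacement when enough cells are available, with replacement otherwise),
#' sums their expression, adds iid Gaussian noise (SD 0.05 by default,
#' mimicking technical variation on the summed-count scale) and clips
#' negatives to zero.
#'
#' @param pool [expr_matrix()] of whole-cell profiles.
#' @param counts Named integer vector: cells per type.
#' @param noise_sd Gaussian noise SD (0 disables noise).
#' @param seed Integer seed.
#' @return Named numeric gene vector.
#' @export
make_pseudobulk <- function(pool, counts, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(pool, "expr_matrix"), !is.null(names(counts)))
  absent <- setdiff(names(counts), unique(pool$cells$cell_type))
  if (length(absent)) {
    rlang::abort(paste0("requested type(s) absent from pool: ",
                        paste(absent, collapse = ", ")))
  }
  with_seed(seed, {
    idx <- unlist(lapply(names(counts), function(tp) {
      ix <- which(pool$cells$cell_type == tp)
      k <- counts[[tp]]
      if (k == 0) return(integer())
      sample(ix, k, replace = k > length(ix))
    }), use.names = FALSE)
    bulk <- colSums(pool$values[idx, , drop = FALSE])
    if (noise_sd > 0) bulk <- bulk + stats::rnorm(length(bulk), 0, noise_sd)
    pmax(bulk, 0)
  })
}

#' Generate a full pseudobulk set with ground-truth proportions
#'
#' Produces `n_per_scheme` samples under each of the two proportion schemes
#' (random Dirichlet and realistic-with-noise), each a sum of `n_cells`
#' whole-cell profiles, with the ground-truth proportion matrix and a scheme
#' label per sample. Defaults give 1,000 samples: 500 random + 500 realistic.
#'
#' @param pool [expr_matrix()] of whole-cell profiles (apply
#'   [filter_cell_types()] first).
#' @param empirical Base proportions for the realistic scheme; default: the
#'   observed type proportions of the pool.
#' @param n_per_scheme Samples per scheme (default 500).
#' @param n_cells Cells per pseudobulk (default 1000).
#' @param noise_sd Gaussian noise SD on summed counts (default 0.05).
#' @param realistic_sd Proportion noise SD for the realistic scheme.
#' @param seed Integer seed.
#' @return A `pseudobulk_set`: `expression` (samples x genes), `truth`
#'   (tibble: `sample`, `scheme`, one column per type, rows summing to 1),
#'   `n_cells`, `seed`.
#' @export
generate_pseudobulk_set <- function(pool, empirical = NULL, n_per_scheme = 500,
                                    n_cells = 1000, noise_sd = 0.05,
                                    realistic_sd = 0.01, seed = 1) {
  stopifnot(inherits(pool, "expr_matrix"), n_per_scheme >= 1)
  types <- sort(unique(pool$cells$cell_type))
  if (is.null(empirical)) {
    empirical <- as.numeric(table(factor(pool$cells$cell_type, types))) /
      nrow(pool$values)
  }
  stopifnot(length(empirical) == length(types))
  schemes <- rep(c("random", "realistic"), each = n_per_scheme)
  n_total <- length(schemes)
  expr <- matrix(0, n_total, ncol(pool$values),
                 dimnames = list(sprintf("pb%04d", seq_len(n_total)),
                                 pool$gene_ids))
  truth <- matrix(0, n_total, length(types),
                  dimnames = list(rownames(expr), types))
  for (i in seq_len(n_total)) {
    si <- seed + i
    pr <- if (schemes[i] == "random") {
      random_proportions(length(types), n_cells, seed = si)
    } else {
      realistic_proportions(empirical, sd = realistic_sd, n_cells, seed = si)
    }
    names(pr$counts) <- types
    truth[i, ] <- pr$counts / n_cells
    expr[i, ] <- make_pseudobulk(pool, pr$counts, noise_sd = noise_sd,
                                 seed = si + 500000L)
  }
  structure(list(
    expression = expr,
    truth = tibble::as_tibble(truth) |>
      tibble::add_column(sample = rownames(expr), scheme = schemes,
                         .before = 1),
    n_cells = n_cells, seed = as.integer(seed)), class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("<pseudobulk_set> %d samples (%s) x %d genes, %d cells each\n",
              nrow(x$expression),
              paste(sprintf("%d %s", table(x$truth$scheme),
                            names(table(x$truth$scheme))), collapse = " + "),
              ncol(x$expression), x$n_cells))
  invisible(x)
}
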