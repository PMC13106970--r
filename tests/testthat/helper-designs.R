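# Small designs shared across test files. Kept deliberately tiny so unit
# tests stay fast; full-scale runs live in test-acceptance.R.

tiny_design <- function(seed = 1, ...) {
  args <- list(
    n_genes = 300,
    cell_types = c(A = 60, B = 60, C = 60),
    n_donors_sc = 2, n_donors_sn = 2,
    frac_biased_genes = 0.2,
    depletion_range = c(0.1, 0.1),
    missing_types = list(sc = character(), sn = character()),
    seed = seed)
  do.call(synthetic_design, utils::modifyList(args, list(...)))
}

# matched-type miniature of the full design (all types in both modalities)
matched_design <- function(seed = 1, ...) {
  args <- list(
    cell_types = c(A = 200, B = 200, C = 200, D = 200),
    missing_types = list(sc = character(), sn = character()),
    seed = seed)
  do.call(synthetic_design, utils::modifyList(args, list(...)))
}

# stronger-gap regime used for the VAE benchmarks: nuclear depletion deep
# enough that the modality gap dominates reconstruction error
vae_benchmark_design <- function(seed = 1, ...) {
  args <- list(
    n_genes = 800,
    cell_types = c(A = 150, B = 150, C = 150, D = 150),
    frac_biased_genes = 0.3,
    depletion_range = c(0.05, 0.05),
    missing_types = list(sc = character(), sn = character()),
    seed = seed)
  do.call(synthetic_design, utils::modifyList(args, list(...)))
}

# toy expr_matrix built directly from a value matrix
toy_expr <- function(values, types = rep("A", nrow(values)),
                     donor = "d1", modality = "sc") {
  values <- as.matrix(values)
  expr_matrix(values, sprintf("g%d", seq_len(ncol(values))),
              tibble::tibble(barcode = sprintf("c%d", seq_len(nrow(values))),
                             cell_type = types,
                             donor = rep(donor, length.out = nrow(values)),
                             modality = rep(modality, length.out = nrow(values))))
}
# second, independent percentile-bootstrap implementation built from the
# definition: resampled means, then the 2.5/97.5 percentiles by linear
# interpolation of order statistics
bootstrap_oracle <- function(values, n_boot = 1000, level = 0.95, seed = 1) {
  set.seed(seed)
  n <- length(values)
  means <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    means[i] <- mean(values[sample.int(n, n, replace = TRUE)])
  }
  s <- sort(means)
  pct <- function(p) {
    h <- (n_boot - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n_boot)] - s[lo])
  }
  a <- (1 - level) / 2
  c(pct(a), pct(1 - a))
}

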