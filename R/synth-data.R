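#' Design for a synthetic paired single-cell / single-nucleus dataset
#'
#' Encodes the statistical structure the rest of the package assumes about
#' paired whole-cell (sc) and nuclear (sn) data: negative-binomial counts on
#' top of log-normal per-type gene programs, a planted set of modality-biased
#' ("nuclear-depleted") genes whose sn expression is multiplicatively reduced,
#' modality-specific library sizes, log-normal donor effects, and cell types
#' present in only one modality.
#'
#' Defaults mirror a full tissue study in miniature: 2,000 genes, five cell
#' types at 200 cells per type and modality, 3 sc donors and 4 sn donors, 10%
#' of genes nuclear-depleted 8-fold (retention factor 0.125), one sc-only type
#' and one sn-only type.
#'
#' @param n_genes Number of genes.
#' @param cell_types Named integer vector: cells per type, per modality
#'   (split near-equally across that modality's donors).
#' @param n_donors_sc,n_donors_sn Donor counts per modality.
#' @param frac_biased_genes Fraction of genes that are modality-biased.
#' @param depletion_range Interval in (0, 1] from which per-gene sn retention
#'   factors of biased genes are drawn uniformly; `c(0.125, 0.125)` plants a
#'   fixed 8-fold depletion.
#' @param base_mean_log_sd SD (log scale) of per-type log-normal fold factors
#'   on the shared baseline gene program.
#' @param nb_dispersion Shared negative-binomial dispersion (inverse size).
#' @param sc_lib_size,sn_lib_size Expected counts per cell by modality.
#' @param donor_effect_sd SD (log scale) of multiplicative per-(donor, gene)
#'   effects; 0 disables donor variation.
#' @param missing_types List with elements `sc` and `sn`: cell types absent
#'   from that modality.
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return An object of class `synthetic_design` (a validated list).
#' @export
synthetic_design <- function(n_genes = 2000,
                             cell_types = c(A = 200, B = 200, C = 200,
                                            D = 200, E = 200),
                             n_donors_sc = 3,
                             n_donors_sn = 4,
                             frac_biased_genes = 0.10,
                             depletion_range = c(0.125, 0.125),
                             base_mean_log_sd = 1,
                             nb_dispersion = 0.25,
                             sc_lib_size = 5000,
                             sn_lib_size = 3000,
                             donor_effect_sd = 0.03,
                             missing_types = list(sc = "E", sn = "D"),
                             seed = 1) {
  stopifnot(n_genes >= 1, length(cell_types) >= 1, !is.null(names(cell_types)),
            n_donors_sc >= 1, n_donors_sn >= 1,
            frac_biased_genes >= 0, frac_biased_genes <= 1,
            length(depletion_range) == 2,
            all(depletion_range > 0), all(depletion_range <= 1),
            depletion_range[1] <= depletion_range[2],
            base_mean_log_sd >= 0, nb_dispersion > 0,
            sc_lib_size > 0, sn_lib_size > 0, donor_effect_sd >= 0)
  if (any(cell_types <= 0)) rlang::abort("all per-type cell counts must be positive")
  missing_types <- list(sc = as.character(missing_types$sc %||% character()),
                        sn = as.character(missing_types$sn %||% character()))
  absent_everywhere <- intersect(missing_types$sc, missing_types$sn)
  if (length(absent_everywhere)) {
    rlang::abort(paste0("invalid design: cell type(s) present in neither modality: ",
                        paste(absent_everywhere, collapse = ", ")))
  }
  unknown <- setdiff(unlist(missing_types), names(cell_types))
  if (length(unknown)) {
    rlang::abort(paste0("missing_types names unknown cell type(s): ",
                        paste(unknown, collapse = ", ")))
  }
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 n_donors_sc = n_donors_sc, n_donors_sn = n_donors_sn,
                 frac_biased_genes = frac_biased_genes,
                 depletion_range = depletion_range,
                 base_mean_log_sd = base_mean_log_sd,
                 nb_dispersion = nb_dispersion,
                 sc_lib_size = sc_lib_size, sn_lib_size = sn_lib_size,
                 donor_effect_sd = donor_effect_sd,
                 missing_types = missing_types, seed = as.integer(seed)),
            class = "synthetic_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate one modality given type programs (genes x types), retention-adjusted,
# returning an expr_matrix. Donor effects multiply gene relative abundance.
simulate_modality <- function(design, programs, modality, lib_size, n_donors) {
  types <- setdiff(names(design$cell_types), design$missing_types[[modality]])
  size <- 1 / design$nb_dispersion
  donor_eff <- matrix(
    exp(stats::rnorm(n_donors * design$n_genes, 0, design$donor_effect_sd)),
    nrow = n_donors)
  rows <- list(); ann <- list(); k <- 0
  for (tp in types) {
    n_cells <- design$cell_types[[tp]]
    per_donor <- diff(round(seq(0, n_cells, length.out = n_donors + 1)))
    for (d in seq_len(n_donors)) {
      nd <- per_donor[d]
      if (nd == 0) next
      rel <- programs[, tp] * donor_eff[d, ]
      p <- rel / sum(rel)
      mu <- lib_size * p
      cnt <- matrix(stats::rnbinom(nd * design$n_genes,
                                   mu = rep(mu, each = nd), size = size),
                    nrow = nd)
      k <- k + 1
      rows[[k]] <- cnt
      ann[[k]] <- tibble::tibble(
        cell_type = tp,
        donor = sprintf("%s_donor%d", modality, d),
        n = nd)
    }
  }
  values <- do.call(rbind, rows)
  ann <- dplyr::bind_rows(ann)
  cells <- tibble::tibble(
    barcode = sprintf("%s_cell%05d", modality, seq_len(nrow(values))),
    cell_type = rep(ann$cell_type, ann$n),
    donor = rep(ann$donor, ann$n),
    modality = modality)
  expr_matrix(values, rownames(programs), cells)
}

#' Generate a paired sc/sn dataset with planted ground truth
#'
#' Draws per-type gene programs (a shared log-normal baseline times per-type
#' log-normal folds), samples a set of modality-biased genes and their sn
#' retention factors, applies log-normal donor effects, and emits
#' negative-binomial counts for both modalities at their respective library
#' sizes. Cell relative-abundance vectors are renormalized per cell, so the
#' nuclear depletion acts on relative (composition) scale exactly as library
#' size normalization later sees it.
#'
#' @param design A [synthetic_design()].
#' @return An object of class `paired_modality_dataset`: list with `sc` and
#'   `sn` ([expr_matrix()] sharing `gene_ids`), `gene_ids`, `truth` (planted
#'   `biased_gene_set`, per-type `programs`, per-gene `retention`), `design`.
#' @export
generate_paired_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    g <- design$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(g))
    types <- names(design$cell_types)
    baseline <- exp(stats::rnorm(g, 0, 1))
    programs <- vapply(types, function(tp)
      baseline * exp(stats::rnorm(g, 0, design$base_mean_log_sd)),
      numeric(g))
    rownames(programs) <- gene_ids
    n_biased <- round(design$frac_biased_genes * g)
    biased <- if (n_biased > 0) sort(sample.int(g, n_biased)) else integer()
    retention <- rep(1, g)
    if (n_biased > 0) {
      retention[biased] <- stats::runif(n_biased, design$depletion_range[1],
                                        design$depletion_range[2])
    }
    names(retention) <- gene_ids
    sn_programs <- programs * retention

    sc <- simulate_modality(design, programs, "sc",
                            design$sc_lib_size, design$n_donors_sc)
    sn <- simulate_modality(design, sn_programs, "sn",
                            design$sn_lib_size, design$n_donors_sn)
    structure(list(
      sc = sc, sn = sn, gene_ids = gene_ids,
      truth = list(biased_gene_set = gene_ids[biased],
                   programs = programs,
                   retention = retention),
      design = design), class = "paired_modality_dataset")
  })
}

#' @export
print.paired_modality_dataset <- function(x, ...) {
  cat(sprintf("<paired_modality_dataset> %d genes, %d sc cells, %d sn cells, %d biased genes\n",
              length(x$gene_ids), nrow(x$sc$values), nrow(x$sn$values),
              length(x$truth$biased_gene_set)))
  invisible(x)
}

#' Generate synthetic "real bulk" samples from a paired dataset
#'
#' Stands in for an external bulk cohort: each bulk is a proportion-weighted
#' mixture of the whole-cell (sc-side) type programs, scaled to a bulk library
#' size, with Poisson count noise. Proportions are drawn per sample from a
#' symmetric Dirichlet (`scheme = "random"`) or supplied directly.
#'
#' @param dataset A [generate_paired_dataset()] result.
#' @param n_bulks Number of bulk samples (>= 1).
#' @param proportions Optional matrix (`n_bulks` x types, rows summing to 1)
#'   fixing the mixing proportions; overrides `scheme`.
#' @param scheme `"random"` for symmetric Dirichlet draws.
#' @param types Cell types to mix; defaults to all sc-side types.
#' @param lib_size Expected total counts per bulk.
#' @param seed Integer seed.
#' @return List with `bulks` (samples x genes matrix) and `proportions`
#'   (tibble: sample plus one column per type, rows summing to 1).
#' @export
generate_synthetic_bulks <- function(dataset, n_bulks = 100, proportions = NULL,
                                     scheme = "random", types = NULL,
                                     lib_size = 1e6, seed = 1) {
  stopifnot(inherits(dataset, "paired_modality_dataset"))
  if (n_bulks < 1) rlang::abort("n_bulks must be >= 1")
  sc_types <- setdiff(names(dataset$design$cell_types),
                      dataset$design$missing_types$sc)
  types <- types %||% sc_types
  stopifnot(all(types %in% sc_types))
  progs <- dataset$truth$programs[, types, drop = FALSE]
  q <- sweep(progs, 2, colSums(progs), "/")  # per-type composition
  with_seed(seed, {
    if (is.null(proportions)) {
      proportions <- rdirichlet(n_bulks, rep(1, length(types)))
    } else {
      proportions <- as.matrix(proportions)
      stopifnot(nrow(proportions) == n_bulks, ncol(proportions) == length(types))
    }
    colnames(proportions) <- types
    mix <- proportions %*% t(q)           # samples x genes composition
    mu <- mix * lib_size
    bulks <- matrix(stats::rpois(length(mu), lambda = mu), nrow = n_bulks)
    colnames(bulks) <- dataset$gene_ids
    rownames(bulks) <- sprintf("bulk%04d", seq_len(n_bulks))
    list(bulks = bulks,
         proportions = tibble::as_tibble(proportions) |>
           tibble::add_column(sample = rownames(bulks), .before = 1))
  })
}

# Symmetric-capable Dirichlet sampler via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
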