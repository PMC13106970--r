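#' Build the transform closure for a held-out experiment
#'
#' Trains the models a latent-transform variant needs — the PCA model and
#' shift field, or an (un)conditional VAE — on data with the held-out type
#' excluded, on the gene set left after removal, and returns the
#' `function(cells, target_lib_size)` handle a [reference_spec()] expects.
#' Raw variants return `NULL` (no transform).
#'
#' @param name Reference variant name (see [reference_variants]).
#' @param sc,sn Gene-aligned [expr_matrix()] objects.
#' @param held_out_type Cell type(s) to be supplied from the nuclear side.
#' @param gene_removal_set Genes dropped before training (the -DEG variants
#'   train their models on the reduced feature space).
#' @param k_nn Neighbour count for the latent shifts.
#' @param vae_args List of extra arguments to [fit_vae()] (e.g. `max_epochs`,
#'   `hidden_dim`).
#' @param seed Integer seed for model training.
#' @return A transform function, or `NULL` for non-transform variants.
#' @export
make_heldout_transform <- function(name, sc, sn, held_out_type,
                                   gene_removal_set = character(),
                                   k_nn = 10, vae_args = list(), seed = 1) {
  if (!variant_rules(name)$needs_transform) return(NULL)
  keep <- setdiff(sc$gene_ids, gene_removal_set)
  sc_r <- subset_cells(sc, genes = keep)
  sn_r <- subset_cells(sn, genes = keep)
  sc_train <- subset_cells(sc_r, cells = which(!sc_r$cells$cell_type %in% held_out_type))
  overlap_types <- setdiff(intersect(unique(sc_r$cells$cell_type),
                                     unique(sn_r$cells$cell_type)),
                           held_out_type)
  sn_overlap <- subset_cells(sn_r, cells = which(sn_r$cells$cell_type %in% overlap_types))

  if (grepl("^PCA LS", name)) {
    model <- fit_pca(sc_train, sn_overlap)
    shifts <- latent_shift(project_pca(model, sc_train),
                           project_pca(model, sn_overlap), k_nn = k_nn)
    return(function(cells, target_lib_size) {
      pca_ls_transform(cells, model, shifts, target_lib_size)
    })
  }

  train <- expr_matrix(rbind(sc_train$values, sn_overlap$values), keep,
                       dplyr::bind_rows(sc_train$cells, sn_overlap$cells))
  if (grepl("^scVI LS", name)) {
    model <- do.call(fit_vae, c(list(train = train, conditional = FALSE,
                                     seed = seed), vae_args))
    return(function(cells, target_lib_size) {
      vae_ls_transform(cells, model, sn_overlap, sc_train, target_lib_size,
                       k_nn = k_nn)
    })
  }
  model <- do.call(fit_vae, c(list(train = train, conditional = TRUE,
                                   seed = seed), vae_args))
  function(cells, target_lib_size) {
    vae_cond_transform(cells, model, target_lib_size)
  }
}

#' Held-out sweep: every cell type, every requested reference variant
#'
#' For each held-out-eligible cell type (present in both modalities), builds
#' the requested reference variants (training per-held-out models for the
#' latent transforms, computing the DEG catalog with the held-out type
#' excluded for the pruned variants), deconvolves the shared pseudobulk set
#' with the built-in NNLS solver, and evaluates all three scenarios.
#' Controls are evaluated under `all_cells` only (they have no held-out
#' type to compare).
#'
#' The pseudobulk pool and the reference use disjoint sc donors (pool = first
#' donor) so pseudobulks are independent of the reference, unless
#' `split_by_donor = FALSE`.
#'
#' @param dataset A [generate_paired_dataset()] result (or a list with
#'   gene-aligned `sc` and `sn` [expr_matrix()]s).
#' @param specs Character vector of variant names to run.
#' @param held_out_types Types to sweep; default: all types in both
#'   modalities.
#' @param n_per_scheme,n_cells Pseudobulk settings.
#' @param min_cells Cell-type filter threshold.
#' @param deg_backend Backend for [compute_modality_degs()].
#' @param vae_args Extra [fit_vae()] arguments for VAE variants.
#' @param split_by_donor Keep the pseudobulk pool donor-disjoint from the
#'   reference?
#' @param seed Integer seed.
#' @param outdir Optional directory for metric CSVs and the manifest.
#' @return List: `metrics` (tibble: `held_out`, `transform`, `scenario`,
#'   `sample`, `pearson`, `rmse`), `estimates` (nested list of proportion
#'   tables), `pseudobulks`, `manifest`.
#' @export
run_heldout_sweep <- function(dataset, specs = c("scRNA All (PosCtrl)",
                                                 "snRNA All (NegCtrl)",
                                                 "snRNA"),
                              held_out_types = NULL,
                              n_per_scheme = 50, n_cells = 500,
                              min_cells = 50, deg_backend = "deseq2",
                              vae_args = list(), split_by_donor = TRUE,
                              seed = 1, outdir = NULL) {
  unknown <- setdiff(specs, reference_variants)
  if (length(unknown)) {
    rlang::abort(paste0("unknown reference variant(s): ",
                        paste(unknown, collapse = ", ")))
  }
  al <- align_genes(filter_cell_types(dataset$sc, min_cells),
                    filter_cell_types(dataset$sn, min_cells))
  sc <- al$a; sn <- al$b
  if (split_by_donor && dplyr::n_distinct(sc$cells$donor) >= 2) {
    pool_donor <- sort(unique(sc$cells$donor))[1]
    pool <- subset_cells(sc, cells = which(sc$cells$donor == pool_donor))
    sc_ref <- subset_cells(sc, cells = which(sc$cells$donor != pool_donor))
  } else {
    pool <- sc; sc_ref <- sc
  }
  held_out_types <- held_out_types %||%
    intersect(unique(sc_ref$cells$cell_type), unique(sn$cells$cell_type))
  if (!length(held_out_types)) rlang::abort("no held-out-eligible cell types")

  pb <- generate_pseudobulk_set(pool, n_per_scheme = n_per_scheme,
                                n_cells = n_cells, seed = seed)
  needs_deg <- any(grepl("-DEG|-Random", specs))
  metrics <- list(); estimates <- list(); manifest <- list()

  for (held in held_out_types) {
    deg_union <- character()
    if (needs_deg) {
      matched <- setdiff(intersect(unique(sc_ref$cells$cell_type),
                                   unique(sn$cells$cell_type)), held)
      catalog <- compute_modality_degs(sc_ref, sn, matched_types = matched,
                                       backend = deg_backend, seed = seed)
      deg_union <- catalog$dataset_union
    }
    for (name in specs) {
      rules <- variant_rules(name)
      removal <- if (!rules$needs_removal) character()
        else if (name == "-Random Genes") {
          sample_random_genes(sc_ref$gene_ids, length(deg_union),
                              exclusions = deg_union, seed = seed)
        } else deg_union
      transform <- make_heldout_transform(name, sc_ref, sn, held,
                                          gene_removal_set = removal,
                                          vae_args = vae_args, seed = seed)
      spec <- reference_spec(name,
                             held_out_type = if (rules$needs_heldout) held,
                             gene_removal_set = removal,
                             transform = transform, seed = seed)
      ref <- build_reference(spec, sc_ref, sn)
      est <- deconvolve_nnls(pb$expression[, ref$gene_ids, drop = FALSE],
                             signature_matrix(ref))
      estimates[[held]][[name]] <- est
      scen <- if (rules$needs_heldout) {
        c("all_cells", "non_removed", "removed_only")
      } else "all_cells"
      for (s in scen) {
        sm <- scenario_metrics(est, pb$truth, scenario = s,
                               held_out_type = if (s != "all_cells") held)
        metrics[[length(metrics) + 1]] <- sm |>
          dplyr::mutate(held_out = held, transform = name, scenario = s,
                        .before = 1)
      }
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        held_out = held, transform = name, n_ref_cells = nrow(ref$expression),
        n_genes = length(ref$gene_ids), n_removed = length(removal),
        seed = seed)
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  list(metrics = metrics, estimates = estimates, pseudobulks = pb,
       manifest = manifest)
}

#' Donor-robustness sweep
#'
#' Builds one reference per (nuclear donor, transform): all whole-cell types
#' plus the sn-only type's cells from that donor alone, raw or transformed.
#' All references deconvolve the same bulk samples; inter-donor cosines are
#' computed per transform across donor-specific estimates, inter-transform
#' cosines across donor-pooled estimates.
#'
#' @param dataset A [generate_paired_dataset()] result.
#' @param bulks Samples x genes matrix to deconvolve (default: synthetic
#'   bulks generated from the dataset).
#' @param transforms Variant names (held-out-style variants).
#' @param min_cells Cell-type filter threshold.
#' @param vae_args Extra [fit_vae()] arguments.
#' @param seed Integer seed.
#' @return List: `donor_pairs` and `transform_pairs` tibbles (ready for
#'   [robustness_score()]), `donor_concordance` (per transform),
#'   `transform_concordance`, `manifest`.
#' @export
run_donor_robustness <- function(dataset, bulks = NULL,
                                 transforms = c("snRNA", "PCA LS"),
                                 min_cells = 20, vae_args = list(), seed = 1) {
  al <- align_genes(filter_cell_types(dataset$sc, min_cells),
                    filter_cell_types(dataset$sn, min_cells))
  sc <- al$a; sn <- al$b
  sn_only <- setdiff(unique(sn$cells$cell_type), unique(sc$cells$cell_type))
  if (!length(sn_only)) rlang::abort("no sn-only cell type to reintroduce")
  held <- sn_only[1]
  donors <- sort(unique(sn$cells$donor[sn$cells$cell_type == held]))
  if (length(donors) < 2) rlang::abort("need >= 2 sn donors")
  if (is.null(bulks)) {
    bulks <- generate_synthetic_bulks(dataset, n_bulks = 50, seed = seed)$bulks
  }

  per_donor_est <- list(); pooled_est <- list(); manifest <- list()
  for (name in transforms) {
    rules <- variant_rules(name)
    build_one <- function(sn_subset, tag) {
      transform <- make_heldout_transform(name, sc, sn_subset, held,
                                          vae_args = vae_args, seed = seed)
      spec <- reference_spec(name, held_out_type = held,
                             transform = transform, seed = seed)
      ref <- build_reference(spec, sc, sn_subset)
      est <- deconvolve_nnls(bulks[, ref$gene_ids, drop = FALSE],
                             signature_matrix(ref))
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        transform = name, donor = tag, n_ref_cells = nrow(ref$expression))
      est
    }
    for (d in donors) {
      keep <- sn$cells$cell_type != held | sn$cells$donor == d
      per_donor_est[[name]][[d]] <- build_one(
        subset_cells(sn, cells = which(keep)), d)
    }
    pooled_est[[name]] <- build_one(sn, "all")
  }

  donor_cm <- lapply(per_donor_est, concordance_matrix)
  donor_pairs <- purrr::imap_dfr(donor_cm, function(cm, name) {
    concordance_long(cm) |>
      dplyr::distinct(pair = paste(pmin(.data$entity, .data$other),
                                   pmax(.data$entity, .data$other)),
                      .keep_all = TRUE) |>
      dplyr::transmute(transform = name, cosine = .data$cosine)
  })
  if (length(pooled_est) >= 2) {
    transform_cm <- concordance_matrix(pooled_est)
    transform_pairs <- concordance_long(transform_cm) |>
      dplyr::transmute(transform = .data$entity, cosine = .data$cosine)
  } else {
    transform_cm <- NULL
    transform_pairs <- tibble::tibble(transform = character(),
                                      cosine = numeric())
  }

  list(donor_pairs = donor_pairs, transform_pairs = transform_pairs,
       donor_concordance = donor_cm, transform_concordance = transform_cm,
       manifest = dplyr::bind_rows(manifest))
}
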