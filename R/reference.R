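#' Named reference variants
#'
#' The catalogue of controls and transformations a reference can be built
#' as. The two "All" controls and the all-nuclear pruned variant use a single
#' modality with no held-out type; every other variant takes all non-held-out
#' types from the whole-cell (sc) side and the held-out type(s) from the
#' nuclear (sn) side, raw, gene-pruned, and/or transformed.
#'
#' @format Character vector of the 14 variant names.
#' @export
reference_variants <- c(
  "scRNA All (PosCtrl)", "snRNA All (NegCtrl)", "snRNA All (-DEG Int.)",
  "snRNA", "snRNA (-DEG)",
  "PCA LS", "PCA LS (-DEG)",
  "scVI LS", "scVI LS (-DEG)",
  "scVIcond", "scVIcond (-DEG)",
  "-DEG Int.", "-DEG Other Datasets", "-Random Genes")

# name -> what the row requires
variant_rules <- function(name) {
  needs_heldout <- !(name %in% c("scRNA All (PosCtrl)", "snRNA All (NegCtrl)",
                                 "snRNA All (-DEG Int.)"))
  needs_removal <- grepl("-DEG|-Random", name)
  needs_transform <- grepl("^(PCA LS|scVI LS|scVIcond)", name)
  all_sn <- name %in% c("snRNA All (NegCtrl)", "snRNA All (-DEG Int.)")
  all_sc <- name == "scRNA All (PosCtrl)"
  list(needs_heldout = needs_heldout, needs_removal = needs_removal,
       needs_transform = needs_transform, all_sn = all_sn, all_sc = all_sc)
}

#' Specification of one reference variant
#'
#' Validates a variant request against its row definition: the "All" controls
#' take no held-out type; pruned variants require a nonempty gene-removal
#' set; latent-transform variants require a transform function.
#'
#' @param name One of [reference_variants].
#' @param held_out_type Cell type(s) supplied from the nuclear side (may be a
#'   vector in the real-setting mode where several types exist only in sn).
#' @param gene_removal_set Gene ids dropped from all cells.
#' @param transform Function `(missing_sn: expr_matrix, target_lib_size) ->
#'   matrix` applied to the held-out nuclear cells.
#' @param cells_per_type Cells sampled per type; `NULL` = minimum available
#'   across the types and source modalities involved.
#' @param seed Integer seed; the same seed samples the same cell indices
#'   across variants of one experiment, so variant differences isolate the
#'   transform.
#' @return A `reference_spec`.
#' @export
reference_spec <- function(name, held_out_type = NULL,
                           gene_removal_set = character(),
                           transform = NULL, cells_per_type = NULL, seed = 1) {
  if (!name %in% reference_variants) {
    rlang::abort(sprintf("unknown reference variant '%s'", name))
  }
  rules <- variant_rules(name)
  if (rules$needs_heldout && is.null(held_out_type)) {
    rlang::abort(sprintf("variant '%s' requires a held-out cell type", name))
  }
  if (!rules$needs_heldout && !is.null(held_out_type)) {
    rlang::abort(sprintf("variant '%s' takes no held-out type", name))
  }
  if (rules$needs_removal && !length(gene_removal_set)) {
    rlang::abort(sprintf("variant '%s' requires a gene-removal set", name))
  }
  if (!rules$needs_removal && length(gene_removal_set)) {
    rlang::abort(sprintf("variant '%s' removes no genes", name))
  }
  if (rules$needs_transform && is.null(transform)) {
    rlang::abort(sprintf("variant '%s' requires a transform function", name))
  }
  if (!rules$needs_transform && !is.null(transform)) {
    rlang::abort(sprintf("variant '%s' applies no transform", name))
  }
  structure(list(name = name, held_out_type = held_out_type,
                 gene_removal_set = unique(as.character(gene_removal_set)),
                 transform = transform, cells_per_type = cells_per_type,
                 seed = as.integer(seed), rules = rules),
            class = "reference_spec")
}

#' Assemble a reference from a spec
#'
#' Draws `cells_per_type` cells per type (seeded, without replacement, the
#' same indices for every variant sharing a seed), takes non-held-out types
#' from the sc side and held-out type(s) from the sn side (raw or
#' transformed), and drops the removal genes from all cells. Every cell
#' carries its source modality in the annotation so the variant's provenance
#' can be audited.
#'
#' @param spec A [reference_spec()].
#' @param sc,sn Gene-aligned [expr_matrix()] objects.
#' @param target_lib_size Library size handed to the transform (default:
#'   median sc library size).
#' @return A `reference`: `expression` (cells x genes), `cells` annotation
#'   tibble (with `source_modality` and `transformed`), `gene_ids`, `spec`.
#' @export
build_reference <- function(spec, sc, sn, target_lib_size = NULL) {
  stopifnot(inherits(spec, "reference_spec"),
            inherits(sc, "expr_matrix"), inherits(sn, "expr_matrix"))
  if (!identical(sc$gene_ids, sn$gene_ids)) {
    rlang::abort("sc and sn must be gene-aligned")
  }
  rules <- spec$rules
  held <- spec$held_out_type
  sc_types <- sort(unique(sc$cells$cell_type))
  sn_types <- sort(unique(sn$cells$cell_type))

  if (rules$all_sc) {
    plan <- tibble::tibble(cell_type = sc_types, source = "sc")
  } else if (rules$all_sn) {
    plan <- tibble::tibble(cell_type = sn_types, source = "sn")
  } else {
    missing_sn <- setdiff(held, sn_types)
    if (length(missing_sn)) {
      rlang::abort(paste0("held-out type(s) absent from sn: ",
                          paste(missing_sn, collapse = ", ")))
    }
    plan <- dplyr::bind_rows(
      tibble::tibble(cell_type = setdiff(sc_types, held), source = "sc"),
      tibble::tibble(cell_type = held, source = "sn"))
  }
  if (!nrow(plan)) rlang::abort("no cell types to build the reference from")

  avail <- vapply(seq_len(nrow(plan)), function(i) {
    m <- if (plan$source[i] == "sc") sc else sn
    sum(m$cells$cell_type == plan$cell_type[i])
  }, integer(1))
  zero <- plan$cell_type[avail == 0]
  if (length(zero)) {
    rlang::abort(paste0("cell type(s) missing from source modality: ",
                        paste(zero, collapse = ", ")))
  }
  n_per <- spec$cells_per_type %||% min(avail)
  if (any(avail < n_per)) {
    rlang::abort(sprintf("cells_per_type = %d exceeds availability (min %d)",
                         n_per, min(avail)))
  }

  keep_genes <- setdiff(sc$gene_ids, spec$gene_removal_set)
  if (!length(keep_genes)) rlang::abort("gene removal set covers all genes")

  blocks <- list(); ann <- list()
  all_types <- sort(plan$cell_type)
  for (i in seq_len(nrow(plan))) {
    tp <- plan$cell_type[i]
    src <- plan$source[i]
    m <- if (src == "sc") sc else sn
    ix <- which(m$cells$cell_type == tp)
    # per-type seed keyed by type name order, so controls and transform
    # variants of one experiment sample the same cells
    take <- with_seed(spec$seed + match(tp, all_types),
                      sample(ix, n_per))
    cells <- subset_cells(m, cells = take, genes = keep_genes)
    transformed <- FALSE
    if (src == "sn" && rules$needs_transform) {
      tl <- target_lib_size %||% median_lib_size(subset_cells(sc, genes = keep_genes))
      vals <- spec$transform(cells, tl)
      stopifnot(is.matrix(vals), nrow(vals) == n_per,
                ncol(vals) == length(keep_genes))
      cells$values <- unname(vals)
      dimnames(cells$values) <- list(cells$cells$barcode, cells$gene_ids)
      transformed <- TRUE
    }
    blocks[[i]] <- cells$values
    ann[[i]] <- dplyr::mutate(cells$cells, source_modality = src,
                              transformed = transformed)
  }
  expression <- do.call(rbind, blocks)
  cells <- dplyr::bind_rows(ann)
  structure(list(expression = expression, cells = cells,
                 gene_ids = keep_genes, spec = spec),
            class = "reference")
}

#' @export
print.reference <- function(x, ...) {
  cat(sprintf("<reference> '%s': %d cells (%d types) x %d genes\n",
              x$spec$name, nrow(x$expression),
              dplyr::n_distinct(x$cells$cell_type), length(x$gene_ids)))
  invisible(x)
}

#' Per-type mean signature matrix of a reference
#'
#' @param ref A `reference`.
#' @return A `signature_matrix`: genes x cell-types matrix of per-type mean
#'   expression, types in alphabetical order.
#' @export
signature_matrix <- function(ref) {
  stopifnot(inherits(ref, "reference"))
  types <- sort(unique(ref$cells$cell_type))
  sig <- vapply(types, function(tp) {
    colMeans(ref$expression[ref$cells$cell_type == tp, , drop = FALSE])
  }, numeric(ncol(ref$expression)))
  rownames(sig) <- ref$gene_ids
  structure(sig, class = c("signature_matrix", class(sig)))
}
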