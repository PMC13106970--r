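#' Non-negative least squares deconvolution
#'
#' The built-in solver: both the signature matrix and each bulk sample are
#' CPM-normalized (removing depth confounding on both sides), then per
#' sample the Lawson-Hanson NNLS problem min ||S x - b|| s.t. x >= 0 is
#' solved on the normalized profiles and the solution normalized to sum 1.
#' Proportions are therefore relative to depth-normalized reference
#' profiles: when every bulk-contributing cell has the same RNA content,
#' they read directly as cell fractions, and a reference type's own
#' sequencing depth cannot bias its estimate. Estimates are invariant to
#' positive rescaling of a bulk sample.
#'
#' @param bulks Samples x genes matrix (raw counts or CPM; rows > 0).
#' @param sig A [signature_matrix()] (genes x types) aligned to the bulks'
#'   genes.
#' @return A proportion table: tibble with `sample` plus one column per cell
#'   type; rows sum to 1.
#' @export
deconvolve_nnls <- function(bulks, sig) {
  bulks <- as.matrix(bulks)
  if (ncol(bulks) != nrow(sig) ||
      (!is.null(colnames(bulks)) && !is.null(rownames(sig)) &&
       !identical(colnames(bulks), rownames(sig)))) {
    rlang::abort("bulks and signature are not gene-aligned")
  }
  if (any(rowSums(bulks) <= 0)) rlang::abort("all-zero bulk sample")
  s_cpm <- sweep(unclass(sig), 2, colSums(sig), "/") * 1e6
  b_cpm <- bulks / rowSums(bulks) * 1e6
  est <- t(apply(b_cpm, 1, function(b) {
    x <- pracma::lsqnonneg(s_cpm, b)$x
    if (sum(x) <= 0) rlang::abort("NNLS returned the zero vector")
    x / sum(x)
  }))
  colnames(est) <- colnames(sig)
  samples <- rownames(bulks) %||% sprintf("sample%04d", seq_len(nrow(bulks)))
  tibble::as_tibble(est) |>
    tibble::add_column(sample = samples, .before = 1)
}

#' Proportion table to matrix
#'
#' @param tbl Tibble with a `sample` column (and optionally `scheme`) plus
#'   one numeric column per type, or an already-numeric matrix.
#' @return Numeric matrix samples x types with rownames.
#' @export
prop_matrix <- function(tbl) {
  if (is.matrix(tbl)) return(tbl)
  keep <- setdiff(names(tbl), c("sample", "scheme"))
  m <- as.matrix(tbl[keep])
  rownames(m) <- tbl$sample
  m
}

#' Adapter contract for external deconvolution tools
#'
#' Marshals the reference and bulks to an external tool's on-disk format,
#' invokes it, and parses the proportions back, validating that type order
#' matches the reference and that rows sum to 1. Supported tool ids:
#' `"instaprism"` (run for `config$n_iterations`, default 5000), `"scaden"`
#' and `"scdc"` (each reference treated as a single batch). When the tool is
#' not installed a capability error of class `modshift_capability_error` is
#' raised; the built-in NNLS solver is never silently substituted.
#'
#' @param bulks Samples x genes matrix.
#' @param ref A [build_reference()] result.
#' @param tool_id One of `"instaprism"`, `"scaden"`, `"scdc"`.
#' @param config List of tool options (`n_iterations`, `command`, `workdir`).
#' @return A proportion table as in [deconvolve_nnls()].
#' @export
run_external_adapter <- function(bulks, ref, tool_id, config = list()) {
  tool_id <- match.arg(tool_id, c("instaprism", "scaden", "scdc"))
  stopifnot(inherits(ref, "reference"))
  command <- config$command %||% switch(tool_id,
    instaprism = "InstaPrism", scaden = "scaden", scdc = "SCDC")
  available <- nzchar(Sys.which(command)) ||
    (tool_id == "instaprism" && requireNamespace("InstaPrism", quietly = TRUE))
  if (!available) {
    rlang::abort(
      sprintf("external tool '%s' (%s) is not installed or discoverable",
              tool_id, command),
      class = "modshift_capability_error")
  }
  workdir <- config$workdir %||% tempfile("adapter")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  write_reference(ref, workdir)
  utils::write.csv(as.matrix(bulks), file.path(workdir, "bulks.csv"))
  out_file <- file.path(workdir, "proportions.csv")
  status <- system2(command, args = c(workdir, out_file))
  if (status != 0 || !file.exists(out_file)) {
    rlang::abort(sprintf("tool '%s' failed (exit %d)", tool_id, status))
  }
  est <- read_proportions(out_file)
  validate_proportions(est, sort(unique(ref$cells$cell_type)))
}

# Reorder columns to the reference's type order and check the row-sum
# invariant; shared by all adapters.
validate_proportions <- function(est, type_order, tol = 1e-6) {
  missing <- setdiff(type_order, names(est))
  if (length(missing)) {
    rlang::abort(paste0("adapter output lacks type(s): ",
                        paste(missing, collapse = ", ")))
  }
  est <- est[c("sample", type_order)]
  rs <- rowSums(prop_matrix(est))
  if (any(abs(rs - 1) > tol)) {
    rlang::abort("proportion rows fail normalization beyond tolerance")
  }
  est
}

#' Write / read a proportion table as CSV
#'
#' Samples as rows (first column `sample`), cell types as columns.
#'
#' @param est Proportion table tibble.
#' @param path CSV path.
#' @return `write_proportions` the path invisibly; `read_proportions` the
#'   tibble.
#' @export
write_proportions <- function(est, path) {
  utils::write.csv(est, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
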