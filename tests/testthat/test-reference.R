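ref_dataset <- function(seed = 31) {
  generate_paired_dataset(tiny_design(seed = seed))
}

test_that("variant specs are validated against their row definitions", {
  expect_error(reference_spec("no such"), "unknown")
  expect_error(reference_spec("snRNA"), "held-out")
  expect_error(reference_spec("scRNA All (PosCtrl)", held_out_type = "A"),
               "no held-out")
  expect_error(reference_spec("snRNA (-DEG)", held_out_type = "A"),
               "removal")
  expect_error(reference_spec("snRNA", held_out_type = "A",
                              gene_removal_set = "g1"),
               "removes no genes")
  expect_error(reference_spec("PCA LS", held_out_type = "A"), "transform")
  expect_error(reference_spec("snRNA", held_out_type = "A",
                              transform = identity),
               "no transform")
})

test_that("the positive control is all whole-cell with no pruning", {
  ds <- ref_dataset()
  ref <- build_reference(reference_spec("scRNA All (PosCtrl)", seed = 2),
                         ds$sc, ds$sn)
  expect_true(all(ref$cells$source_modality == "sc"))
  expect_false(any(ref$cells$transformed))
  expect_identical(ref$gene_ids, ds$sc$gene_ids)
  counts <- table(ref$cells$cell_type)
  expect_true(all(counts == counts[1]))
})

test_that("a pruned mixed reference drops the genes and keeps held-out cells raw sn", {
  ds <- ref_dataset()
  removal <- ds$gene_ids[3]
  ref <- build_reference(
    reference_spec("snRNA (-DEG)", held_out_type = "C",
                   gene_removal_set = removal, seed = 2),
    ds$sc, ds$sn)
  expect_false(removal %in% ref$gene_ids)
  src <- ref$cells |> dplyr::distinct(cell_type, source_modality)
  expect_equal(src$source_modality[src$cell_type == "C"], "sn")
  expect_true(all(src$source_modality[src$cell_type != "C"] == "sc"))
  expect_false(any(ref$cells$transformed))
  # held-out cell expression is genuinely the raw sn counts
  bc <- ref$cells$barcode[ref$cells$cell_type == "C"][1]
  orig <- ds$sn$values[ds$sn$cells$barcode == bc, ref$gene_ids]
  expect_equal(ref$expression[ref$cells$barcode == bc, ], orig,
               ignore_attr = TRUE)
})

test_that("the random-genes control is size-matched and DEG-disjoint", {
  ds <- ref_dataset()
  deg_union <- ds$gene_ids[1:20]
  rnd <- sample_random_genes(ds$gene_ids, length(deg_union),
                             exclusions = deg_union, seed = 5)
  ref <- build_reference(
    reference_spec("-Random Genes", held_out_type = "B",
                   gene_removal_set = rnd, seed = 2),
    ds$sc, ds$sn)
  expect_length(rnd, length(deg_union))
  expect_length(intersect(rnd, deg_union), 0)
  expect_length(setdiff(ds$gene_ids, ref$gene_ids), length(rnd))
})

test_that("variants sharing a seed sample the same cells", {
  ds <- ref_dataset()
  a <- build_reference(reference_spec("snRNA", held_out_type = "C", seed = 9),
                       ds$sc, ds$sn)
  b <- build_reference(
    reference_spec("snRNA (-DEG)", held_out_type = "C",
                   gene_removal_set = ds$gene_ids[1:5], seed = 9),
    ds$sc, ds$sn)
  expect_identical(a$cells$barcode, b$cells$barcode)
  # a transform variant also reuses them
  tr <- function(cells, target_lib_size) {
    cells$values / rowSums(cells$values) * target_lib_size
  }
  d <- build_reference(reference_spec("PCA LS", held_out_type = "C",
                                      transform = tr, seed = 9),
                       ds$sc, ds$sn)
  expect_identical(a$cells$barcode, d$cells$barcode)
  expect_true(all(d$cells$transformed[d$cells$cell_type == "C"]))
})

test_that("errors name missing types and refuse total gene removal", {
  ds <- ref_dataset()
  expect_error(build_reference(reference_spec("snRNA", held_out_type = "Z",
                                              seed = 1),
                               ds$sc, ds$sn),
               "Z")
  expect_error(build_reference(
    reference_spec("snRNA (-DEG)", held_out_type = "A",
                   gene_removal_set = ds$gene_ids, seed = 1),
    ds$sc, ds$sn),
    "all genes")
})

test_that("signature matrix is the per-type mean in declared order", {
  v <- rbind(c(1, 2), c(3, 4), c(5, 6))
  m <- toy_expr(v, types = c("B", "A", "B"))
  ref <- structure(list(expression = m$values, cells = m$cells,
                        gene_ids = m$gene_ids,
                        spec = reference_spec("scRNA All (PosCtrl)")),
                   class = "reference")
  sig <- signature_matrix(ref)
  expect_equal(colnames(sig), c("A", "B"))
  # hand oracle: A = cell 2; B = mean of cells 1 and 3
  expect_equal(unname(sig[, "A"]), c(3, 4))
  expect_equal(unname(sig[, "B"]), c(3, 4))
  # duplicating every cell leaves the signature unchanged
  m2 <- toy_expr(rbind(v, v), types = rep(c("B", "A", "B"), 2))
  ref2 <- structure(list(expression = m2$values, cells = m2$cells,
                         gene_ids = m2$gene_ids, spec = ref$spec),
                    class = "reference")
  expect_equal(signature_matrix(ref2), sig, ignore_attr = TRUE)
  # single cell per type equals that cell
  m3 <- toy_expr(v[1:2, ], types = c("A", "B"))
  ref3 <- structure(list(expression = m3$values, cells = m3$cells,
                         gene_ids = m3$gene_ids, spec = ref$spec),
                    class = "reference")
  expect_equal(unname(signature_matrix(ref3)[, "A"]), v[1, ])
})
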