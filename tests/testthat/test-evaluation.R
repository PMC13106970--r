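test_that("elementary metrics match hand-computed values", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(-1, -2, -3)), -1.0)
  # hand covariance / sd computation: r = 3 / (sqrt(2) * sqrt(14/3))
  expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820)
  expect_error(pearson(c(1, 1), c(1, 2)), "constant")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0.5, 0.5), c(0.6, 0.4)), 0.1)
  u <- runif(5); v <- runif(5); pm <- c(3, 1, 5, 2, 4)
  expect_equal(rmse(u[pm], v[pm]), rmse(u, v))
  expect_error(rmse(numeric(), numeric()), "nonempty")

  expect_equal(cosine(c(1, 2), c(1, 2)), 1.0)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0.0)
  expect_equal(round(cosine(c(1, 2, 3), c(4, 5, 6)), 4), 0.9746)
  expect_equal(cosine(c(1, 2, 3), c(4, 5, 6)), 32 / sqrt(1078))
  expect_error(cosine(c(0, 0), c(1, 1)), "zero vector")
})

make_props <- function(m, types, samples = sprintf("s%d", seq_len(nrow(m)))) {
  colnames(m) <- types
  tibble::as_tibble(m) |> tibble::add_column(sample = samples, .before = 1)
}

test_that("the three scenarios follow their definitions on a hand-built table", {
  truth <- make_props(rbind(c(0.5, 0.3, 0.2),
                            c(0.25, 0.15, 0.6),
                            c(0.1, 0.8, 0.1)), c("A", "B", "C"))
  pred <- make_props(rbind(c(0.45, 0.35, 0.2),
                           c(0.3, 0.1, 0.6),
                           c(0.2, 0.7, 0.1)), c("A", "B", "C"))
  all_c <- scenario_metrics(pred, truth, "all_cells")
  # direct formula evaluation per sample
  for (i in 1:3) {
    p <- unlist(pred[i, c("A", "B", "C")]); t_ <- unlist(truth[i, c("A", "B", "C")])
    expect_equal(all_c$pearson[i], stats::cor(p, t_))
    expect_equal(all_c$rmse[i], sqrt(mean((p - t_)^2)))
  }
  non_r <- scenario_metrics(pred, truth, "non_removed", held_out_type = "C")
  for (i in 1:3) {
    p <- unlist(pred[i, c("A", "B")]); t_ <- unlist(truth[i, c("A", "B")])
    expect_equal(non_r$pearson[i], stats::cor(p, t_))
    expect_equal(non_r$rmse[i], sqrt(mean((p - t_)^2)))
  }
  rem <- scenario_metrics(pred, truth, "removed_only", held_out_type = "C")
  expect_equal(rem$pearson, stats::cor(pred$C, truth$C))
  expect_equal(rem$rmse, sqrt(mean((pred$C - truth$C)^2)))
  # perfect prediction: Pearson 1 (where defined) and RMSE 0
  perf <- scenario_metrics(truth, truth, "all_cells")
  expect_equal(perf$pearson, rep(1, 3), tolerance = 1e-12)
  expect_true(all(perf$rmse == 0))
})

test_that("scenario edge cases error with guidance or align by construction", {
  truth2 <- make_props(rbind(c(0.6, 0.4), c(0.2, 0.8)), c("A", "B"))
  expect_error(scenario_metrics(truth2, truth2, "non_removed",
                                held_out_type = "B"),
               "removed_only")
  expect_error(scenario_metrics(truth2, truth2, "non_removed"), "held_out")
  expect_error(scenario_metrics(truth2, truth2, "removed_only",
                                held_out_type = "Z"),
               "missing")
  # all_cells over k types equals non_removed when the held-out column is
  # excluded from both tables
  truth3 <- make_props(rbind(c(0.5, 0.3, 0.2), c(0.25, 0.15, 0.6)),
                       c("A", "B", "C"))
  pred3 <- make_props(rbind(c(0.3, 0.4, 0.3), c(0.25, 0.15, 0.6)),
                      c("A", "B", "C"))
  sub <- c("sample", "A", "B")
  expect_equal(
    scenario_metrics(pred3[sub], truth3[sub], "all_cells")$pearson,
    scenario_metrics(pred3, truth3, "non_removed", held_out_type = "C")$pearson)
})

test_that("bootstrap CI matches an independent percentile implementation", {
  expect_equal(bootstrap_ci_mean(rep(3.5, 7), seed = 1), c(3.5, 3.5))
  set.seed(123)
  vals <- rnorm(20)
  expect_identical(bootstrap_ci_mean(vals, seed = 5),
                   bootstrap_ci_mean(vals, seed = 5))
  expect_equal(bootstrap_ci_mean(vals, seed = 5),
               bootstrap_oracle(vals, seed = 5), tolerance = 1e-12)
  expect_error(bootstrap_ci_mean(numeric()), "empty")
})

test_that("bootstrap interval width shrinks with sample size", {
  widths <- vapply(c(10, 100, 1000), function(n) {
    set.seed(n)
    ci <- bootstrap_ci_mean(rnorm(n), seed = 3)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the pooled t-test matches its closed form and symmetries", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  r1 <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  # pooled variance 1, se = sqrt(2/3), t = -3 / se
  expect_equal(round(r1$t, 3), -3.674)
  r2 <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r1$t)
  expect_equal(r2$p, r1$p)
  # missing values are dropped
  r3 <- two_sample_ttest(c(1, 2, 3, NA), c(4, 5, NA, 6))
  expect_equal(r3$t, r1$t)
  expect_error(two_sample_ttest(c(1), c(2, 3)), ">= 2")
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "degenerate")
})

test_that("cell-type signature similarity detects the planted direction", {
  ds <- generate_paired_dataset(tiny_design(seed = 2))
  # sn side replaced by a copy of sc: perfect similarity by construction
  sims <- celltype_signature_similarity(ds$sc, ds$sc, n_cells = 50, seed = 1)
  expect_equal(sims$cosine, rep(1, 3), tolerance = 1e-12)
  s1 <- celltype_signature_similarity(ds$sn, ds$sc, n_cells = 50, seed = 4)
  expect_identical(s1, celltype_signature_similarity(ds$sn, ds$sc,
                                                     n_cells = 50, seed = 4))
  # planted depletion lowers similarity relative to a zero-effect twin
  for (r in 1:5) {
    planted <- generate_paired_dataset(tiny_design(seed = 60 + r))
    null_twin <- generate_paired_dataset(tiny_design(
      seed = 60 + r, frac_biased_genes = 0,
      sn_lib_size = 5000, sc_lib_size = 5000))
    s_planted <- celltype_signature_similarity(planted$sn, planted$sc,
                                               n_cells = 50, seed = r)
    s_null <- celltype_signature_similarity(null_twin$sn, null_twin$sc,
                                            n_cells = 50, seed = r)
    expect_lt(mean(s_planted$cosine), mean(s_null$cosine))
  }
  expect_error(celltype_signature_similarity(ds$sn, ds$sc, n_cells = 1000),
               "fewer than")
})

test_that("concordance matrices are symmetric with unit diagonal", {
  m1 <- make_props(rbind(c(0.7, 0.3), c(0.4, 0.6)), c("A", "B"))
  m2 <- make_props(rbind(c(0.6, 0.4), c(0.5, 0.5)), c("A", "B"))
  m3 <- make_props(rbind(c(0.1, 0.9), c(0.9, 0.1)), c("A", "B"))
  cm <- concordance_matrix(list(x = m1, y = m1, z = m3))
  expect_equal(cm["x", "y"], 1.0)
  expect_equal(diag(unclass(cm)), c(x = 1, y = 1, z = 1), tolerance = 1e-12)
  expect_equal(unclass(cm), t(unclass(cm)))
  # three-entity oracle by direct cosine of flattened tables
  cm2 <- concordance_matrix(list(a = m1, b = m2, c = m3))
  flat <- function(m) as.numeric(t(prop_matrix(m)))
  for (p1 in c("a", "b", "c")) for (p2 in c("a", "b", "c")) {
    want <- cosine(flat(get(paste0("m", match(p1, c("a", "b", "c"))))),
                   flat(get(paste0("m", match(p2, c("a", "b", "c"))))))
    expect_equal(cm2[p1, p2], want, tolerance = 1e-12)
  }
  long <- concordance_long(cm2)
  expect_equal(nrow(long), 6)
  expect_false(any(long$entity == long$other))
  expect_error(concordance_matrix(list(a = m1, b = m2[1, ])), "shape")
})
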