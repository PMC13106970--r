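test_that("accuracy min-max endpoints and invariances hold", {
  m <- tibble::tibble(dataset = "d1",
                      transform = c("t1", "t2"),
                      pearson = c(0.2, 0.8),
                      rmse = c(0.3, 0.1))
  sc <- accuracy_score(m)
  expect_equal(sc$accuracy[sc$transform == "t1"], 0)
  expect_equal(sc$accuracy[sc$transform == "t2"], 1)
  # increasing affine map of RMSE within a dataset leaves scores unchanged
  m2 <- dplyr::mutate(m, rmse = 5 * rmse + 2)
  expect_equal(accuracy_score(m2)$accuracy, sc$accuracy)
  # transform order is irrelevant
  expect_equal(dplyr::arrange(accuracy_score(m[2:1, ]), transform),
               dplyr::arrange(sc, transform))
  expect_error(accuracy_score(tibble::tibble()), "nonempty")
})

# independent spreadsheet-style recomputation of the accuracy pipeline
accuracy_oracle <- function(metrics) {
  out <- list()
  for (tr in unique(metrics$transform)) out[[tr]] <- c(p = 0, r = 0, n = 0)
  for (d in unique(metrics$dataset)) {
    sub <- metrics[metrics$dataset == d, ]
    mm <- function(x) if (max(x) == min(x)) rep(0.5, length(x))
      else (x - min(x)) / (max(x) - min(x))
    pn <- mm(sub$pearson)
    rn <- mm(max(sub$rmse) - sub$rmse)
    for (tr in unique(sub$transform)) {
      sel <- sub$transform == tr
      out[[tr]] <- out[[tr]] + c(mean(pn[sel]), mean(rn[sel]), 1)
    }
  }
  vapply(out, function(v) (v[1] / v[3] + v[2] / v[3]) / 2, numeric(1))
}

test_that("accuracy equals the step-by-step oracle on a 3x2 toy", {
  set.seed(4)
  metrics <- tidyr::expand_grid(dataset = c("d1", "d2"),
                                transform = c("t1", "t2", "t3"),
                                rep = 1:4) |>
    dplyr::mutate(pearson = runif(dplyr::n(), 0.2, 0.95),
                  rmse = runif(dplyr::n(), 0.05, 0.4))
  got <- accuracy_score(metrics)
  want <- accuracy_oracle(metrics)
  expect_equal(got$accuracy, unname(want[got$transform]), tolerance = 1e-12)
  expect_true(all(got$accuracy >= 0 & got$accuracy <= 1))
})

test_that("robustness endpoints, ties, and the hand oracle agree", {
  donor <- tibble::tibble(transform = rep(c("t1", "t2", "t3"), each = 3),
                          cosine = c(0.99, 0.98, 0.97, 0.9, 0.88, 0.86,
                                     0.8, 0.78, 0.76))
  trans <- tibble::tibble(transform = rep(c("t1", "t2", "t3"), each = 2),
                          cosine = c(0.95, 0.94, 0.9, 0.89, 0.7, 0.71))
  rs <- robustness_score(donor, trans)
  # t1 holds both axis maxima
  expect_equal(rs$robustness[rs$transform == "t1"] >
                 rs$robustness[rs$transform == "t3"], TRUE)
  # hand oracle
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  dn <- mm(donor$cosine); tn <- mm(trans$cosine)
  want_t1 <- (mean(dn[1:3]) + mean(tn[1:2])) / 2
  expect_equal(rs$robustness[rs$transform == "t1"], want_t1, tolerance = 1e-12)
  # all-identical cosines: degenerate rule gives 0.5 everywhere
  flat <- robustness_score(dplyr::mutate(donor, cosine = 0.9),
                           dplyr::mutate(trans, cosine = 0.9))
  expect_true(all(flat$robustness == 0.5))
  # a transform at both maxima of a two-transform problem scores 1
  rs2 <- robustness_score(donor[donor$transform != "t2", ],
                          trans[trans$transform != "t2", ])
  expect_equal(rs2$robustness[rs2$transform == "t1"],
               (mean(mm(donor$cosine[c(1:3, 7:9)])[1:3]) +
                  mean(mm(trans$cosine[c(1:2, 5:6)])[1:2])) / 2)
})

test_that("adding a dominated transform never improves another's rank", {
  m <- tibble::tibble(dataset = "d1",
                      transform = rep(c("t1", "t2"), each = 3),
                      pearson = c(0.9, 0.85, 0.88, 0.6, 0.55, 0.65),
                      rmse = c(0.05, 0.06, 0.055, 0.2, 0.22, 0.18))
  base <- accuracy_score(m)
  worse <- dplyr::bind_rows(m, tibble::tibble(
    dataset = "d1", transform = "t_bad",
    pearson = c(0.1, 0.12, 0.11), rmse = c(0.5, 0.52, 0.51)))
  ext <- accuracy_score(worse)
  rank_of <- function(tbl, tr) rank(-tbl$accuracy)[tbl$transform == tr]
  expect_lte(rank_of(ext, "t1"), rank_of(base, "t1") + 1)
  expect_true(ext$accuracy[ext$transform == "t_bad"] ==
                min(ext$accuracy))
  expect_gt(ext$accuracy[ext$transform == "t1"],
            ext$accuracy[ext$transform == "t2"])
})

test_that("composite scores join cleanly and plot", {
  acc <- tibble::tibble(transform = c("t1", "t2"), accuracy = c(0.9, 0.4),
                        pearson_score = c(0.9, 0.4), rmse_score = c(0.9, 0.4))
  rob <- tibble::tibble(transform = c("t1", "t2"), robustness = c(0.8, 0.6),
                        donor_score = c(0.8, 0.6), transform_score = c(0.8, 0.6))
  cs <- composite_scores(acc, rob)
  expect_s3_class(cs, "composite_scores")
  expect_equal(cs$accuracy, c(0.9, 0.4))
  p <- ggplot2::autoplot(cs)
  expect_s3_class(p, "ggplot")
})
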