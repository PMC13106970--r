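# Tiny training sets keep these fast; the full planted-effect benchmark of
# the conditional transform lives in test-acceptance.R.

tiny_vae_data <- function(seed = 1, n_genes = 60, n_per = 40) {
  ds <- generate_paired_dataset(tiny_design(
    seed = seed, n_genes = n_genes,
    cell_types = stats::setNames(c(n_per, n_per), c("A", "B")),
    frac_biased_genes = 0.2, depletion_range = c(0.1, 0.1),
    donor_effect_sd = 0))
  expr_matrix(rbind(ds$sc$values, ds$sn$values), ds$gene_ids,
              dplyr::bind_rows(ds$sc$cells, ds$sn$cells))
}

fit_tiny <- function(train, conditional, seed = 1, ...) {
  args <- utils::modifyList(
    list(train = train, conditional = conditional, hidden_dim = 16,
         max_epochs = 15, batch_size = 32, seed = seed),
    list(...))
  do.call(fit_vae, args)
}

test_that("the latent representation has the configured dimensionality", {
  train <- tiny_vae_data()
  m <- fit_tiny(train, conditional = FALSE, max_epochs = 3)
  expect_equal(ncol(encode_vae(m, train)), 30)
  m5 <- fit_tiny(train, conditional = TRUE, latent_dim = 5, max_epochs = 3)
  expect_equal(ncol(encode_vae(m5, train)), 5)
})

test_that("training decreases the model's own objective and is deterministic", {
  train <- tiny_vae_data()
  m1 <- fit_tiny(train, conditional = TRUE, seed = 7)
  expect_lt(vae_loss(m1, train, "trained"), vae_loss(m1, train, "init"))
  m2 <- fit_tiny(train, conditional = TRUE, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$val_history, m2$val_history)
})

test_that("hand-derived gradients match finite differences", {
  ns <- asNamespace("modshift")
  set.seed(1)
  g <- 6; n <- 8; L <- 3; H <- 4
  x <- matrix(rpois(n * g, 20), n, g)
  lab <- rep(1:2, 4); lib <- rowSums(x)
  iw <- function(a, b) matrix(rnorm(a * b, 0, 0.3), a, b)
  p <- list(W1 = iw(g + 2, H), b1 = rnorm(H), W2 = iw(H, H), b2 = rnorm(H),
            Wm = iw(H, L), bm = rnorm(L), Wv = iw(H, L), bv = rnorm(L),
            U1 = iw(L + 2, H), c1 = rnorm(H), U2 = iw(H, H), c2 = rnorm(H),
            U3 = iw(H, g), c3 = rnorm(g),
            logtheta = matrix(rnorm(2 * g, 0, 0.2), 2, g))
  f <- function(pp) {
    set.seed(4242)
    ns$vae_objective(pp, x, lab, lib, TRUE, L,
                     eps = matrix(rnorm(n * L), n, L))
  }
  set.seed(4242)
  gr <- ns$vae_grad(p, x, lab, lib, TRUE, L)
  for (nm in names(p)) {
    idx <- seq_len(min(6, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + 1e-5; up <- f(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2e-5; dn <- f(pp)
      expect_equal(gr[[nm]][i], (up - dn) / 2e-5, tolerance = 1e-4)
    }
  }
})

test_that("transform outputs are nonnegative, rescaled, and deterministic", {
  train <- tiny_vae_data(seed = 2)
  sc <- subset_cells(train, cells = which(train$cells$modality == "sc"))
  sn <- subset_cells(train, cells = which(train$cells$modality == "sn"))
  sn_a <- subset_cells(sn, cells = which(sn$cells$cell_type == "A"))
  m_u <- fit_tiny(train, conditional = FALSE, seed = 3)
  m_c <- fit_tiny(train, conditional = TRUE, seed = 3)

  out_ls <- vae_ls_transform(sn_a, m_u, sn, sc, target_lib_size = 1500,
                             k_nn = 5)
  expect_true(all(out_ls >= 0))
  expect_equal(rowSums(out_ls), rep(1500, nrow(out_ls)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(out_ls, vae_ls_transform(sn_a, m_u, sn, sc, 1500, k_nn = 5))

  out_c <- vae_cond_transform(sn_a, m_c, target_lib_size = 1200)
  expect_true(all(out_c >= 0))
  expect_equal(rowSums(out_c), rep(1200, nrow(out_c)), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(vae_ls_transform(sn_a, m_c, sn, sc, 1000), "unconditional")
  expect_error(vae_cond_transform(sn_a, m_u, 1000), "conditional")
})

test_that("a conditional model trained on zero-effect data barely reacts to the label", {
  ds <- generate_paired_dataset(tiny_design(
    seed = 5, n_genes = 60, cell_types = c(A = 50, B = 50),
    frac_biased_genes = 0, donor_effect_sd = 0,
    sc_lib_size = 3000, sn_lib_size = 3000))
  train <- expr_matrix(rbind(ds$sc$values, ds$sn$values), ds$gene_ids,
                       dplyr::bind_rows(ds$sc$cells, ds$sn$cells))
  m <- fit_vae(train, conditional = TRUE, hidden_dim = 16, max_epochs = 30,
               batch_size = 32, seed = 2)
  sn_cells <- subset_cells(train, cells = which(train$cells$modality == "sn"))
  z <- encode_vae(m, sn_cells, label = "sn")
  dec_sn <- decode_vae(m, z, 3000, label = "sn")
  dec_sc <- decode_vae(m, z, 3000, label = "sc")
  rel <- abs(dec_sc - dec_sn) / pmax(dec_sn, 1e-8)
  expect_lt(stats::median(rel), 0.05)
})

test_that("model state survives a save/load round trip", {
  train <- tiny_vae_data(seed = 4)
  m <- fit_tiny(train, conditional = FALSE, max_epochs = 3)
  path <- file.path(tempdir(), "vae_test.rds")
  saved <- save_vae(m, path)
  expect_true(file.exists(saved[["sidecar"]]))
  m2 <- load_vae(path)
  expect_identical(m$params, m2$params)
  meta <- jsonlite::read_json(saved[["sidecar"]])
  expect_equal(meta$latent_dim, 30)
  unlink(saved)
})
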