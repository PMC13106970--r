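#' Negative-binomial variational autoencoder for count matrices
#'
#' A compact VAE for cell-by-gene counts with the architecture used for
#' modality alignment: two hidden ReLU layers on each side, a 30-dimensional
#' Gaussian latent space, and a negative-binomial likelihood whose mean is
#' the cell library size times a softmax over genes. In the conditional
#' variant a one-hot modality label ("sc"/"sn") is appended to the encoder
#' input and concatenated to the latent vector before the decoder, and the
#' per-gene NB dispersion is indexed by the label (gene-batch dispersion);
#' the unconditional variant ignores labels entirely and uses a single
#' per-gene dispersion. Training maximizes the evidence lower bound with
#' reparameterized sampling and Adam, with early stopping when the validation
#' loss fails to improve for `patience` epochs (the best parameters are
#' restored). Inference (encoding/decoding) uses the posterior mean, so
#' transforms are deterministic given a trained model.
#'
#' @param train [expr_matrix()] of training cells; when `conditional = TRUE`
#'   the `modality` annotation supplies the labels and both modalities must be
#'   present.
#' @param conditional Condition encoder/decoder on the modality label?
#' @param latent_dim Latent dimensionality (default 30).
#' @param hidden_dim Width of the two hidden layers (default 128).
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction held out for validation, stratified by
#'   (modality, cell type).
#' @param seed Integer seed governing initialization, splits, shuffling and
#'   reparameterization noise; the same seed and data give identical models.
#' @param verbose Print per-epoch losses?
#'
#' @return A `vae_model`: parameter list, architecture fields, training
#'   history, and the initial parameters (for objective-decrease checks).
#' @export
fit_vae <- function(train, conditional = FALSE, latent_dim = 30,
                    hidden_dim = 128, max_epochs = 100, patience = 10,
                    batch_size = 128, lr = 1e-3, val_frac = 0.1,
                    seed = 1, verbose = FALSE) {
  stopifnot(inherits(train, "expr_matrix"))
  x <- train$values
  if (all(x == 0)) rlang::abort("degenerate training matrix: all counts are zero")
  labels <- factor(train$cells$modality, levels = c("sc", "sn"))
  if (conditional && length(unique(labels)) < 2) {
    rlang::abort("conditional model needs cells from both modalities")
  }
  g <- ncol(x)
  n_lab <- if (conditional) 2L else 1L
  d_in <- g + if (conditional) 2L else 0L
  d_z <- latent_dim + if (conditional) 2L else 0L

  with_seed(seed, {
    init_w <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
    }
    params <- list(
      W1 = init_w(d_in, hidden_dim), b1 = numeric(hidden_dim),
      W2 = init_w(hidden_dim, hidden_dim), b2 = numeric(hidden_dim),
      Wm = init_w(hidden_dim, latent_dim), bm = numeric(latent_dim),
      Wv = init_w(hidden_dim, latent_dim), bv = rep(-1, latent_dim),
      U1 = init_w(d_z, hidden_dim), c1 = numeric(hidden_dim),
      U2 = init_w(hidden_dim, hidden_dim), c2 = numeric(hidden_dim),
      U3 = init_w(hidden_dim, g), c3 = numeric(g),
      logtheta = matrix(0, n_lab, g))
    init_params <- params

    n <- nrow(x)
    strata <- interaction(labels, train$cells$cell_type, drop = TRUE)
    val_idx <- unlist(lapply(split(seq_len(n), strata), function(ix) {
      nv <- max(1, round(length(ix) * val_frac))
      sample(ix, nv)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (!length(train_idx)) rlang::abort("no training cells left after split")

    adam <- list(m = lapply(params, function(p) p * 0),
                 v = lapply(params, function(p) p * 0), t = 0)
    lab_int <- as.integer(labels)
    lib <- rowSums(x)

    val_loss_of <- function(pp) {
      vae_objective(pp, x[val_idx, , drop = FALSE], lab_int[val_idx],
                    lib[val_idx], conditional, latent_dim, deterministic = TRUE)
    }

    best <- list(loss = Inf, params = params, epoch = 0)
    wait <- 0; history <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(train_idx)
      starts <- seq(1, length(perm), by = batch_size)
      for (s in starts) {
        ix <- perm[s:min(s + batch_size - 1, length(perm))]
        gr <- vae_grad(params, x[ix, , drop = FALSE], lab_int[ix], lib[ix],
                       conditional, latent_dim)
        adam$t <- adam$t + 1
        ct <- adam$t
        for (nm in names(params)) {
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * gr[[nm]]
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * gr[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - 0.9^ct)
          vhat <- adam$v[[nm]] / (1 - 0.999^ct)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      vl <- val_loss_of(params)
      history <- c(history, vl)
      if (verbose) message(sprintf("epoch %d: val loss %.4f", epoch, vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
    structure(list(
      params = best$params, init_params = init_params,
      conditional = conditional, latent_dim = latent_dim,
      hidden_dim = hidden_dim, gene_ids = train$gene_ids,
      labels = c("sc", "sn"), seed = as.integer(seed),
      epochs_run = length(history), best_epoch = best$epoch,
      val_history = history), class = "vae_model")
  })
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model> %s, latent %d, hidden %d, %d genes, %d epochs (best %d)\n",
              if (x$conditional) "conditional" else "unconditional",
              x$latent_dim, x$hidden_dim, length(x$gene_ids),
              x$epochs_run, x$best_epoch))
  invisible(x)
}

relu <- function(x) pmax(x, 0)

# Encoder forward pass: returns hidden activations and latent Gaussian stats.
vae_encode_pass <- function(p, xin) {
  e1 <- sweep(xin %*% p$W1, 2, p$b1, "+"); a1 <- relu(e1)
  e2 <- sweep(a1 %*% p$W2, 2, p$b2, "+"); a2 <- relu(e2)
  mu <- sweep(a2 %*% p$Wm, 2, p$bm, "+")
  lvr <- sweep(a2 %*% p$Wv, 2, p$bv, "+")
  list(e1 = e1, a1 = a1, e2 = e2, a2 = a2, mu = mu, lvr = lvr,
       lv = pmin(pmax(lvr, -6), 6))
}

# Decoder forward pass: softmax mean fractions scaled by library size.
vae_decode_pass <- function(p, d0, lib) {
  f1p <- sweep(d0 %*% p$U1, 2, p$c1, "+"); f1 <- relu(f1p)
  f2p <- sweep(f1 %*% p$U2, 2, p$c2, "+"); f2 <- relu(f2p)
  s <- sweep(f2 %*% p$U3, 2, p$c3, "+")
  s <- s - apply(s, 1, max)
  es <- exp(s)
  rho <- es / rowSums(es)
  list(f1p = f1p, f1 = f1, f2p = f2p, f2 = f2, rho = rho, mux = lib * rho)
}

nb_loglik <- function(x, mu, theta) {
  mu <- pmax(mu, 1e-10)
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + x * (log(mu) - log(theta + mu))
}

onehot <- function(lab_int, n = 2) {
  out <- matrix(0, length(lab_int), n)
  out[cbind(seq_along(lab_int), lab_int)] <- 1
  out
}

# Mean per-cell negative ELBO. `deterministic` uses z = mu (no sampling);
# training draws reparameterized z through the caller's RNG.
vae_objective <- function(p, x, lab_int, lib, conditional, latent_dim,
                          deterministic = FALSE, eps = NULL) {
  b <- nrow(x)
  xin <- log1p(x)
  if (conditional) xin <- cbind(xin, onehot(lab_int))
  enc <- vae_encode_pass(p, xin)
  if (deterministic) {
    z <- enc$mu
  } else {
    if (is.null(eps)) eps <- matrix(stats::rnorm(b * latent_dim), b, latent_dim)
    z <- enc$mu + eps * exp(enc$lv / 2)
  }
  d0 <- if (conditional) cbind(z, onehot(lab_int)) else z
  dec <- vae_decode_pass(p, d0, lib)
  theta <- exp(p$logtheta)[if (conditional) lab_int else rep(1L, b), , drop = FALSE]
  ll <- sum(nb_loglik(x, dec$mux, theta))
  kl <- 0.5 * sum(enc$mu^2 + exp(enc$lv) - enc$lv - 1)
  (-ll + kl) / b
}

# Gradient of the minibatch objective by hand-derived backpropagation.
vae_grad <- function(p, x, lab_int, lib, conditional, latent_dim) {
  b <- nrow(x)
  xin <- log1p(x)
  oh <- if (conditional) onehot(lab_int) else NULL
  if (conditional) xin <- cbind(xin, oh)
  enc <- vae_encode_pass(p, xin)
  eps <- matrix(stats::rnorm(b * latent_dim), b, latent_dim)
  sd_z <- exp(enc$lv / 2)
  z <- enc$mu + eps * sd_z
  d0 <- if (conditional) cbind(z, oh) else z
  dec <- vae_decode_pass(p, d0, lib)
  lab_rows <- if (conditional) lab_int else rep(1L, b)
  ltheta <- p$logtheta[lab_rows, , drop = FALSE]
  theta <- exp(ltheta)
  mu_x <- pmax(dec$mux, 1e-10)
  xptheta <- x + theta
  ratio <- xptheta / (theta + mu_x)   # (x+theta)/(theta+mu), reused twice

  # d(-ll)/d mu_x, scaled by 1/B
  g_mux <- -(x / mu_x - ratio) / b
  r <- rowSums(g_mux * dec$rho)
  g_s <- (lib * dec$rho) * sweep(g_mux, 1, r)   # grad wrt softmax logits

  grad <- list()
  grad$U3 <- crossprod(dec$f2, g_s); grad$c3 <- colSums(g_s)
  g_f2 <- tcrossprod(g_s, p$U3) * (dec$f2p > 0)
  grad$U2 <- crossprod(dec$f1, g_f2); grad$c2 <- colSums(g_f2)
  g_f1 <- tcrossprod(g_f2, p$U2) * (dec$f1p > 0)
  grad$U1 <- crossprod(d0, g_f1); grad$c1 <- colSums(g_f1)
  g_d0 <- tcrossprod(g_f1, p$U1)
  g_z <- g_d0[, seq_len(latent_dim), drop = FALSE]

  # dispersion gradient, accumulated per label; digamma(theta) has only one
  # distinct row per label, so it is computed on the small matrix and indexed
  dg_theta <- digamma(exp(p$logtheta))[lab_rows, , drop = FALSE]
  dll_dlth <- theta * (digamma(xptheta) - dg_theta +
                         ltheta - log(theta + mu_x) + 1 - ratio)
  g_lth <- matrix(0, nrow(p$logtheta), ncol(p$logtheta))
  for (l in unique(lab_rows)) {
    g_lth[l, ] <- -colSums(dll_dlth[lab_rows == l, , drop = FALSE]) / b
  }
  grad$logtheta <- g_lth

  # KL and reparameterization paths
  g_mu <- g_z + enc$mu / b
  clamp_ok <- (enc$lvr > -6) & (enc$lvr < 6)
  g_lv <- (g_z * eps * 0.5 * sd_z + 0.5 * (exp(enc$lv) - 1) / b) * clamp_ok

  g_a2 <- tcrossprod(g_mu, p$Wm) + tcrossprod(g_lv, p$Wv)
  grad$Wm <- crossprod(enc$a2, g_mu); grad$bm <- colSums(g_mu)
  grad$Wv <- crossprod(enc$a2, g_lv); grad$bv <- colSums(g_lv)
  g_e2 <- g_a2 * (enc$e2 > 0)
  grad$W2 <- crossprod(enc$a1, g_e2); grad$b2 <- colSums(g_e2)
  g_a1 <- tcrossprod(g_e2, p$W2)
  g_e1 <- g_a1 * (enc$e1 > 0)
  grad$W1 <- crossprod(xin, g_e1); grad$b1 <- colSums(g_e1)
  grad[names(p)]
}

#' Encode cells to the latent posterior mean
#'
#' @param model A `vae_model`.
#' @param m [expr_matrix()] or counts matrix over the model's genes.
#' @param label Modality label used for conditional encoding (`"sc"` or
#'   `"sn"`); taken from the cell annotations when `NULL`. Ignored by
#'   unconditional models.
#' @return Cells x latent_dim matrix of posterior means.
#' @export
encode_vae <- function(model, m, label = NULL) {
  v <- if (inherits(m, "expr_matrix")) m$values else as.matrix(m)
  if (ncol(v) != length(model$gene_ids)) rlang::abort("gene set mismatch with VAE model")
  xin <- log1p(v)
  if (model$conditional) {
    lab <- vae_label_int(model, m, label, nrow(v))
    xin <- cbind(xin, onehot(lab))
  }
  vae_encode_pass(model$params, xin)$mu
}

#' Decode latent coordinates to expression means
#'
#' @param model A `vae_model`.
#' @param z Cells x latent_dim matrix.
#' @param lib_size Scalar or per-cell vector of output library sizes.
#' @param label Modality label for conditional decoding.
#' @return Cells x genes nonnegative matrix; each row sums to its library
#'   size (the decoder emits mean fractions through a softmax).
#' @export
decode_vae <- function(model, z, lib_size, label = NULL) {
  z <- as.matrix(z)
  if (model$conditional) {
    lab <- vae_label_int(model, NULL, label, nrow(z))
    d0 <- cbind(z, onehot(lab))
  } else {
    d0 <- z
  }
  out <- vae_decode_pass(model$params, d0, rep(lib_size, length.out = nrow(z)))$mux
  colnames(out) <- model$gene_ids
  rownames(out) <- rownames(z)
  out
}

vae_label_int <- function(model, m, label, n) {
  if (is.null(label)) {
    if (inherits(m, "expr_matrix")) {
      label <- m$cells$modality
    } else {
      rlang::abort("conditional model needs a modality label")
    }
  }
  lab <- match(rep(label, length.out = n), model$labels)
  if (anyNA(lab)) rlang::abort("labels must be 'sc' or 'sn'")
  lab
}

#' Deterministic objective of a VAE on a dataset
#'
#' Evaluates the model's own loss (mean per-cell negative ELBO with the
#' posterior mean in place of a sample) at the trained or the initial
#' parameters; used to verify that training decreased the objective.
#'
#' @param model A `vae_model`.
#' @param m [expr_matrix()] over the model's genes.
#' @param at `"trained"` or `"init"`.
#' @return Scalar loss.
#' @export
vae_loss <- function(model, m, at = c("trained", "init")) {
  at <- match.arg(at)
  p <- if (at == "trained") model$params else model$init_params
  lab <- match(m$cells$modality, model$labels)
  vae_objective(p, m$values, lab, rowSums(m$values), model$conditional,
                model$latent_dim, deterministic = TRUE)
}

#' VAE latent-shift transform of missing-type nuclear cells
#'
#' Encodes the whole-cell cells (for the centroid), the overlapping nuclear
#' cells (for the shift field) and the missing cells with an unconditional
#' model, applies the neighbour-based shift, decodes, and scales every cell
#' to the target library size.
#'
#' @param missing_sn [expr_matrix()] of missing-type nuclear cells.
#' @param model Unconditional `vae_model` trained without the missing type on
#'   the sc side.
#' @param overlap_sn [expr_matrix()] of overlapping nuclear cells.
#' @param sc [expr_matrix()] of whole-cell cells.
#' @param target_lib_size Output per-cell total (typically the median sc
#'   library size).
#' @param k_nn Neighbour count (default 10).
#' @return Cells x genes nonnegative matrix, rows summing to the target.
#' @export
vae_ls_transform <- function(missing_sn, model, overlap_sn, sc,
                             target_lib_size, k_nn = 10) {
  if (model$conditional) rlang::abort("vae_ls_transform requires an unconditional model")
  sc_lat <- encode_vae(model, sc)
  ov_lat <- encode_vae(model, overlap_sn)
  mis_lat <- encode_vae(model, missing_sn)
  shifts <- latent_shift(sc_lat, ov_lat, k_nn = k_nn)
  z <- neighbor_shift(mis_lat, shifts)
  decode_vae(model, z, target_lib_size)
}

#' Conditional-VAE label-switch transform of missing-type nuclear cells
#'
#' Passes each nuclear cell through the conditional model's encoder and
#' decoder with the whole-cell (`"sc"`) label at the decoder, so the decoder
#' renders the cell as its whole-cell counterpart; deterministic (posterior
#' mean), rescaled to the target library size.
#'
#' @param missing_sn [expr_matrix()] of missing-type nuclear cells.
#' @param model Conditional `vae_model`.
#' @param target_lib_size Output per-cell total.
#' @param encode_label Label used at the encoder (default `"sc"`, matching a
#'   full label switch; `"sn"` encodes with the native label instead).
#' @return Cells x genes nonnegative matrix, rows summing to the target.
#' @export
vae_cond_transform <- function(missing_sn, model, target_lib_size,
                               encode_label = "sc") {
  if (!model$conditional) rlang::abort("vae_cond_transform requires a conditional model")
  z <- encode_vae(model, missing_sn, label = encode_label)
  decode_vae(model, z, target_lib_size, label = "sc")
}

#' Save / load a VAE model
#'
#' The parameter state goes to a single binary artifact; a JSON sidecar
#' records architecture and training metadata.
#'
#' @param model A `vae_model`.
#' @param path Path of the binary artifact (`.rds`); the sidecar is written
#'   next to it with extension `.json`.
#' @return `save_vae` the paths invisibly; `load_vae` the model.
#' @export
save_vae <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  meta <- list(conditional = model$conditional, latent_dim = model$latent_dim,
               hidden_dim = model$hidden_dim, n_genes = length(model$gene_ids),
               seed = model$seed, epochs_run = model$epochs_run,
               best_epoch = model$best_epoch)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(model = path, sidecar = side))
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vae_model"))
  model
}
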