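#' Assemble a causal dataset for one target gene
#'
#' Bundles the observed-confounder matrix X (binary mutations of background
#' genes), the binary treatment vector M (mutation status of the target
#' gene) and the continuous outcome Y (process activity) after validation.
#'
#' @param X binary numeric matrix, N samples x K confounder genes.
#' @param M binary numeric vector of length N.
#' @param Y finite numeric vector of length N.
#' @param sample_ids optional character vector of length N.
#' @return object of class `cebp_dataset`.
#' @export
causal_dataset <- function(X, M, Y, sample_ids = NULL) {
  X <- as.matrix(X)
  M <- as.numeric(M)
  Y <- as.numeric(Y)
  n <- length(Y)
  if (nrow(X) != n || length(M) != n)
    stop("X, M and Y must describe the same samples", call. = FALSE)
  if (!all(X %in% c(0, 1))) stop("X must be binary", call. = FALSE)
  if (!all(M %in% c(0, 1))) stop("M must be binary", call. = FALSE)
  if (!all(is.finite(Y))) stop("Y must be finite", call. = FALSE)
  if (sum(M) == 0 || sum(M) == n)
    stop("both treatment arms must be nonempty", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(n))
  structure(list(X = X, M = M, Y = Y, sample_ids = sample_ids),
            class = "cebp_dataset")
}

#' @export
print.cebp_dataset <- function(x, ...) {
  cat(sprintf("Causal dataset: %d samples, %d observed confounders, %d treated\n",
              length(x$Y), ncol(x$X), sum(x$M)))
  invisible(x)
}

zero_grads_ <- function(net) tree_map(net, function(v)
  if (is.numeric(v)) v * 0 else v)

wrap_grads_ <- function(bk, net) list(W = bk$dW, b = bk$db,
                                      out_act = net$out_act)

#' Initialize the variational causal model
#'
#' Builds every network of the model: the shared inference representation
#' g(x, y) with per-arm posterior heads f0/f1, the auxiliary networks
#' q(m|x) and q(y|x, m), and the generative decoders p(x|z), p(m|z) and the
#' per-arm outcome heads of p(y|z, m). Main networks use `hidden_depth`
#' ELU hidden layers of `hidden_width` units; the treatment networks
#' q(m|x) and p(m|z) use a single hidden layer. Initialization is
#' deterministic given `seed`.
#'
#' @param K number of observed confounder genes.
#' @param d latent confounder dimension.
#' @param cfg a [cebp_config()].
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return object of class `cebp_model`.
#' @export
init_model <- function(K, d = cfg$latent_dim, cfg = cebp_config(),
                       seed = NULL) {
  stopifnot(K >= 1, d >= 1)
  build <- function() {
    w <- cfg$hidden_width
    dep <- cfg$hidden_depth
    # shared representation uses dep-1 hidden layers + ELU output, each arm
    # head adds one more hidden layer: dep hidden layers end to end
    nets <- list(
      enc_g  = mlp_init(K + 1, w, w, max(dep - 1, 0), out_act = "elu"),
      enc_h0 = mlp_init(w, 2 * d, w, 1),
      enc_h1 = mlp_init(w, 2 * d, w, 1),
      aux_m  = mlp_init(K, 1, w, 1),
      aux_y  = mlp_init(K + 1, 1, w, dep),
      dec_x  = mlp_init(d, K, w, dep),
      dec_m  = mlp_init(d, 1, w, 1),
      dec_y0 = mlp_init(d, 1, w, dep),
      dec_y1 = mlp_init(d, 1, w, dep)
    )
    structure(list(nets = nets, K = as.integer(K), d = as.integer(d),
                   width = w, depth = dep, outcome_sd = cfg$outcome_sd),
              class = "cebp_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.cebp_model <- function(x, ...) {
  cat(sprintf("CEBP variational causal model: K=%d confounders, d=%d latent, %dx%d ELU\n",
              x$K, x$d, x$depth, x$width))
  invisible(x)
}

#' Approximate posterior over the latent confounder
#'
#' Routes each sample through the shared representation g(x, y) and the
#' head of its observed treatment arm (f0 for untreated, f1 for treated),
#' returning the diagonal-Gaussian posterior parameters. Posterior
#' standard deviations are mapped through softplus, so they are strictly
#' positive.
#'
#' @param model a `cebp_model`.
#' @param X confounder matrix (n x K).
#' @param y outcome vector.
#' @param m binary treatment vector.
#' @return list with `mu` and `sd` (both n x d).
#' @export
infer_posterior <- function(model, X, y, m) {
  fw <- encoder_forward_(model, X, y, m)
  list(mu = fw$mu, sd = fw$s)
}

encoder_forward_ <- function(model, X, y, m) {
  nets <- model$nets
  n <- nrow(X)
  d <- model$d
  g_fw <- mlp_forward(nets$enc_g, cbind(X, y))
  H <- g_fw$out
  mu <- matrix(0, n, d)
  sraw <- matrix(0, n, d)
  i0 <- which(m == 0)
  i1 <- which(m == 1)
  h0_fw <- h1_fw <- NULL
  if (length(i0)) {
    h0_fw <- mlp_forward(nets$enc_h0, H[i0, , drop = FALSE])
    mu[i0, ] <- h0_fw$out[, seq_len(d), drop = FALSE]
    sraw[i0, ] <- h0_fw$out[, d + seq_len(d), drop = FALSE]
  }
  if (length(i1)) {
    h1_fw <- mlp_forward(nets$enc_h1, H[i1, , drop = FALSE])
    mu[i1, ] <- h1_fw$out[, seq_len(d), drop = FALSE]
    sraw[i1, ] <- h1_fw$out[, d + seq_len(d), drop = FALSE]
  }
  s <- softplus_(sraw) + 1e-3
  list(g_fw = g_fw, H = H, h0_fw = h0_fw, h1_fw = h1_fw,
       i0 = i0, i1 = i1, mu = mu, sraw = sraw, s = s)
}

#' Decode latent draws into observation parameters
#'
#' @param model a `cebp_model`.
#' @param z latent matrix (n x d).
#' @param m binary treatment vector (gates the outcome head:
#'   y-mean = m * f_y1(z) + (1 - m) * f_y0(z)).
#' @return list with `x_logits` (n x K Bernoulli logits), `m_prob`
#'   (treatment probability, in (0,1)), `y_mean`, and the per-arm means
#'   `y0`, `y1`; the outcome sd is fixed at `model$outcome_sd`.
#' @export
decode <- function(model, z, m) {
  nets <- model$nets
  lx <- mlp_forward(nets$dec_x, z)$out
  lm <- mlp_forward(nets$dec_m, z)$out[, 1]
  y0 <- mlp_forward(nets$dec_y0, z)$out[, 1]
  y1 <- mlp_forward(nets$dec_y1, z)$out[, 1]
  m <- as.numeric(m)
  list(x_logits = lx, m_prob = sigmoid_(lm),
       y_mean = m * y1 + (1 - m) * y0, y0 = y0, y1 = y1)
}

# Full forward (and optional backward) pass for one reparameterized draw.
# Returns the negative mean per-sample objective as `loss`.
cevae_batch_ <- function(model, X, m, y, eta, grad = FALSE) {
  nets <- model$nets
  n <- nrow(X)
  d <- model$d
  enc <- encoder_forward_(model, X, y, m)
  mu <- enc$mu; s <- enc$s
  z <- mu + s * eta

  dx_fw <- mlp_forward(nets$dec_x, z);  lx <- dx_fw$out
  dm_fw <- mlp_forward(nets$dec_m, z);  lm <- dm_fw$out[, 1]
  dy0_fw <- mlp_forward(nets$dec_y0, z); y0 <- dy0_fw$out[, 1]
  dy1_fw <- mlp_forward(nets$dec_y1, z); y1 <- dy1_fw$out[, 1]
  ymean <- m * y1 + (1 - m) * y0
  am_fw <- mlp_forward(nets$aux_m, X);            lqm <- am_fw$out[, 1]
  ay_fw <- mlp_forward(nets$aux_y, cbind(X, m));  qy <- ay_fw$out[, 1]

  eps2 <- model$outcome_sd^2
  ll_x <- rowSums(X * lx - softplus_(lx))
  ll_m <- m * lm - softplus_(lm)
  ll_y <- -0.5 * log(2 * pi * eps2) - (y - ymean)^2 / (2 * eps2)
  kl <- gaussian_kl_(mu, s)
  lq_m <- m * lqm - softplus_(lqm)
  lq_y <- -0.5 * log(2 * pi * eps2) - (y - qy)^2 / (2 * eps2)

  loss <- -mean(ll_x + ll_m + ll_y - kl + lq_m + lq_y)
  terms <- c(recon_x = mean(ll_x), recon_m = mean(ll_m),
             recon_y = mean(ll_y), kl = mean(kl),
             aux_m = mean(lq_m), aux_y = mean(lq_y))
  if (!grad) return(list(loss = loss, terms = terms))

  # ---- backward: d(loss)/d(param), loss = -mean(objective) ----
  dlx <- (sigmoid_(lx) - X) / n
  bk_x <- mlp_backward(nets$dec_x, dx_fw, dlx)
  dlm <- matrix((sigmoid_(lm) - m) / n, ncol = 1)
  bk_m <- mlp_backward(nets$dec_m, dm_fw, dlm)
  dymean <- (ymean - y) / (n * eps2)
  bk_y0 <- mlp_backward(nets$dec_y0, dy0_fw,
                        matrix(dymean * (1 - m), ncol = 1))
  bk_y1 <- mlp_backward(nets$dec_y1, dy1_fw, matrix(dymean * m, ncol = 1))
  dz <- bk_x$dIn + bk_m$dIn + bk_y0$dIn + bk_y1$dIn
  dmu <- dz + mu / n
  ds <- dz * eta + (s - 1 / s) / n
  dsraw <- ds * sigmoid_(enc$sraw)

  dH <- matrix(0, n, ncol(enc$H))
  g_h0 <- zero_grads_(nets$enc_h0)
  g_h1 <- zero_grads_(nets$enc_h1)
  if (length(enc$i0)) {
    bk_h0 <- mlp_backward(nets$enc_h0, enc$h0_fw,
                          cbind(dmu[enc$i0, , drop = FALSE],
                                dsraw[enc$i0, , drop = FALSE]))
    dH[enc$i0, ] <- bk_h0$dIn
    g_h0 <- wrap_grads_(bk_h0, nets$enc_h0)
  }
  if (length(enc$i1)) {
    bk_h1 <- mlp_backward(nets$enc_h1, enc$h1_fw,
                          cbind(dmu[enc$i1, , drop = FALSE],
                                dsraw[enc$i1, , drop = FALSE]))
    dH[enc$i1, ] <- bk_h1$dIn
    g_h1 <- wrap_grads_(bk_h1, nets$enc_h1)
  }
  bk_g <- mlp_backward(nets$enc_g, enc$g_fw, dH)
  bk_am <- mlp_backward(nets$aux_m, am_fw,
                        matrix((sigmoid_(lqm) - m) / n, ncol = 1))
  bk_ay <- mlp_backward(nets$aux_y, ay_fw,
                        matrix((qy - y) / (n * eps2), ncol = 1))

  grads <- list(
    enc_g  = wrap_grads_(bk_g, nets$enc_g),
    enc_h0 = g_h0,
    enc_h1 = g_h1,
    aux_m  = wrap_grads_(bk_am, nets$aux_m),
    aux_y  = wrap_grads_(bk_ay, nets$aux_y),
    dec_x  = wrap_grads_(bk_x, nets$dec_x),
    dec_m  = wrap_grads_(bk_m, nets$dec_m),
    dec_y0 = wrap_grads_(bk_y0, nets$dec_y0),
    dec_y1 = wrap_grads_(bk_y1, nets$dec_y1)
  )
  list(loss = loss, terms = terms, grads = grads)
}

#' Evidence lower bound of a batch
#'
#' Per-sample objective:
#' E_q[log p(x|z) + log p(m|z) + log p(y|m,z)] - KL(q(z|x,m,y) || N(0,I))
#' plus the auxiliary log-likelihoods log q(m|x) and log q(y|x,m).
#' The KL term is computed in closed form for the diagonal Gaussian
#' posterior; the expectation uses `n_mc` reparameterized draws. The
#' returned `loss` is the negative mean objective (what training
#' minimizes).
#'
#' @param model a `cebp_model`.
#' @param ds a `cebp_dataset` (or any list with `X`, `M`, `Y`).
#' @param n_mc number of reparameterized draws.
#' @param seed RNG seed for the draws.
#' @return list with `loss` (scalar) and `terms` (named means of the
#'   individual terms, including `kl`).
#' @export
cevae_elbo <- function(model, ds, n_mc = 1L, seed = 1L) {
  with_seed(seed, {
    n <- length(ds$Y)
    loss <- 0
    terms <- NULL
    for (t in seq_len(n_mc)) {
      eta <- matrix(stats::rnorm(n * model$d), n, model$d)
      out <- cevae_batch_(model, ds$X, ds$M, ds$Y, eta, grad = FALSE)
      loss <- loss + out$loss
      terms <- if (is.null(terms)) out$terms else terms + out$terms
    }
    list(loss = loss / n_mc, terms = terms / n_mc)
  })
}

#' Train the variational causal model
#'
#' Splits the data into train/validation/test by a seeded shuffle
#' (70/10/20 by default), minimizes the negative ELBO with Adam (learning
#' rate and weight decay from `cfg`), and applies early stopping on the
#' validation objective, returning the parameters of the best validation
#' epoch.
#'
#' Parameters are tracked as an exponential moving average over epochs
#' (Polyak-style averaging, decay `ema_decay`); the averaged parameters are
#' what validation scores and what the returned model carries. Averaging
#' smooths the epoch-to-epoch oscillation of the counterfactual heads and
#' substantially reduces run-to-run spread of the ATE; `ema_decay = 0`
#' disables it.
#'
#' @param ds a `cebp_dataset`.
#' @param cfg a [cebp_config()].
#' @param seed integer seed controlling initialization, splits, batching
#'   and reparameterization noise.
#' @param verbose emit per-epoch progress messages.
#' @param ema_decay per-epoch decay of the parameter average (0 disables).
#' @return list with `model` (trained `cebp_model`) and `trace`
#'   (per-epoch train/validation losses, split indices, `best_epoch`,
#'   `seed`).
#' @export
train_cevae <- function(ds, cfg = cebp_config(), seed = cfg$base_seed,
                        verbose = FALSE, ema_decay = 0.9) {
  stopifnot(inherits(ds, "cebp_dataset"), inherits(cfg, "cebp_config"))
  with_seed(seed, {
    n <- length(ds$Y)
    d <- cfg$latent_dim
    perm <- sample.int(n)
    n_tr <- max(1L, floor(cfg$split_fractions[1] * n))
    n_val <- max(1L, floor(cfg$split_fractions[2] * n))
    if (n_tr + n_val >= n) stop("dataset too small to split", call. = FALSE)
    idx_tr <- perm[seq_len(n_tr)]
    idx_val <- perm[n_tr + seq_len(n_val)]
    idx_te <- perm[(n_tr + n_val + 1):n]
    if (length(unique(ds$M[idx_tr])) < 2)
      stop("training split contains a single treatment arm; ",
           "re-seed or use a larger dataset", call. = FALSE)

    model <- init_model(ncol(ds$X), d, cfg, seed = NULL)
    state <- adam_init(model$nets)
    Xv <- ds$X[idx_val, , drop = FALSE]
    mv <- ds$M[idx_val]
    yv <- ds$Y[idx_val]
    # fixed reparameterization noise for validation: keeps the objective
    # comparable across epochs so early stopping is not driven by MC noise
    eta_v <- matrix(stats::rnorm(length(idx_val) * d), length(idx_val), d)

    best_val <- Inf
    best_nets <- model$nets
    best_epoch <- 0L
    wait <- 0L
    ema_nets <- model$nets
    tr_trace <- val_trace <- numeric(0)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- idx_tr[sample.int(n_tr)]
      starts <- seq(1, n_tr, by = cfg$batch_size)
      ep_loss <- 0
      for (st in starts) {
        b <- ord[st:min(st + cfg$batch_size - 1, n_tr)]
        eta <- matrix(stats::rnorm(length(b) * d), length(b), d)
        fb <- cevae_batch_(model, ds$X[b, , drop = FALSE], ds$M[b],
                           ds$Y[b], eta, grad = TRUE)
        upd <- adam_step(model$nets, fb$grads, state,
                         lr = cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        model$nets <- upd$nets
        state <- upd$state
        ep_loss <- ep_loss + fb$loss * length(b)
      }
      if (ema_decay > 0) {
        w_new <- if (epoch == 1) 1 else 1 - ema_decay
        ema_nets <- tree_map2(ema_nets, model$nets, function(a, b)
          if (is.numeric(a)) (1 - w_new) * a + w_new * b else a)
      } else ema_nets <- model$nets
      eval_model <- model
      eval_model$nets <- ema_nets
      val_loss <- cevae_batch_(eval_model, Xv, mv, yv, eta_v,
                               grad = FALSE)$loss
      tr_trace <- c(tr_trace, ep_loss / n_tr)
      val_trace <- c(val_trace, val_loss)
      if (verbose)
        cebp_log(sprintf("epoch %3d train %.4f val %.4f", epoch,
                         ep_loss / n_tr, val_loss))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_nets <- ema_nets
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model$nets <- best_nets
    list(model = model,
         trace = list(train = tr_trace, validation = val_trace,
                      best_epoch = best_epoch, seed = seed,
                      split = list(train = idx_tr, validation = idx_val,
                                   test = idx_te)))
  })
}

#' Predict both potential outcomes for every sample
#'
#' Draws `n_mc` latent samples from the posterior q(z | x, y, m)
#' conditioned on each sample's observed data, and averages the outcome
#' heads over the draws: y-hat(m=a) = mean_t f_ya(z_t). Both arms are
#' predicted for every sample, so the unobserved arm is the counterfactual.
#'
#' @param ds a `cebp_dataset`.
#' @param model trained `cebp_model`.
#' @param n_mc Monte Carlo draws per sample.
#' @param seed RNG seed.
#' @return n x 2 matrix with columns `y0`, `y1`.
#' @export
predict_counterfactuals <- function(ds, model, n_mc = 100L, seed = 1L) {
  with_seed(seed, {
    n <- length(ds$Y)
    d <- model$d
    post <- infer_posterior(model, ds$X, ds$Y, ds$M)
    acc0 <- acc1 <- numeric(n)
    for (t in seq_len(n_mc)) {
      z <- post$mu + post$sd * matrix(stats::rnorm(n * d), n, d)
      acc0 <- acc0 + mlp_forward(model$nets$dec_y0, z)$out[, 1]
      acc1 <- acc1 + mlp_forward(model$nets$dec_y1, z)$out[, 1]
    }
    cbind(y0 = acc0 / n_mc, y1 = acc1 / n_mc)
  })
}

#' Average treatment effect from a trained model
#'
#' ATE = (1/N) * sum_i [y-hat_i(m=1) - y-hat_i(m=0)] over all N samples.
#'
#' @inheritParams predict_counterfactuals
#' @param subset optional integer indices restricting the population
#'   (e.g. a test split); default all samples.
#' @return ATE scalar.
#' @export
estimate_ate <- function(ds, model, n_mc = 100L, seed = 1L, subset = NULL) {
  cf <- predict_counterfactuals(ds, model, n_mc = n_mc, seed = seed)
  if (!is.null(subset)) cf <- cf[subset, , drop = FALSE]
  mean(cf[, "y1"] - cf[, "y0"])
}

#' Replicate-aggregated ATE estimate
#'
#' Trains the model `cfg$n_replicates` times with seeds
#' `cfg$base_seed + 0 .. R-1` and reports the mean and sample standard
#' deviation of the per-replicate ATEs (the "mean ± std over independent
#' runs" convention).
#'
#' @param ds a `cebp_dataset`.
#' @param cfg a [cebp_config()].
#' @param verbose emit progress messages.
#' @return object of class `cebp_ate`: list with `ate_mean`, `ate_std`,
#'   `per_replicate`, `seeds`, `n_mc`.
#' @export
run_replicates <- function(ds, cfg = cebp_config(), verbose = FALSE) {
  r <- cfg$n_replicates
  seeds <- cfg$base_seed + seq_len(r) - 1L
  ates <- numeric(r)
  for (i in seq_len(r)) {
    fit <- train_cevae(ds, cfg, seed = seeds[i])
    ates[i] <- estimate_ate(ds, fit$model, n_mc = cfg$n_mc_samples,
                            seed = seeds[i])
    if (verbose)
      cebp_log(sprintf("replicate %d/%d: ATE %.4f", i, r, ates[i]))
  }
  if (r == 1) {
    warning("single replicate: reporting std of 0", call. = FALSE)
    std <- 0
  } else std <- stats::sd(ates)
  structure(list(ate_mean = mean(ates), ate_std = std,
                 per_replicate = ates, seeds = seeds,
                 n_mc = cfg$n_mc_samples),
            class = "cebp_ate")
}

#' @export
print.cebp_ate <- function(x, ...) {
  cat(sprintf("ATE %.4f +/- %.4f (%d replicates)\n",
              x$ate_mean, x$ate_std, length(x$per_replicate)))
  invisible(x)
}
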