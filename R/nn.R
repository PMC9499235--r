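# Minimal dense-network machinery for the variational causal model.
# Everything is batch-first (n x features) and written against BLAS matmuls;
# gradients are exact analytic backprop, no autodiff.

# masked arithmetic instead of pmin/pmax: measurably faster on the batch
# matrices that dominate training time
elu_ <- function(a) {
  neg <- a < 0
  a * !neg + expm1(a * neg)
}

# derivative of ELU from the pre-activation: exp(a) below 0, 1 above
elu_grad_ <- function(a) exp(a * (a < 0))

sigmoid_ <- function(a) 1 / (1 + exp(-a))

# numerically stable log(1 + exp(a))
softplus_ <- function(a) a * (a > 0) + log1p(exp(-abs(a)))

#' @noRd
mlp_init <- function(n_in, n_out, width, n_hidden, out_act = "linear") {
  sizes <- c(n_in, rep(width, n_hidden), n_out)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd),
                     fan_in, sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, out_act = out_act)
}

#' @noRd
mlp_forward <- function(net, X) {
  L <- length(net$W)
  ins <- vector("list", L)
  pre <- vector("list", L)
  h <- X
  n <- nrow(X)
  for (l in seq_len(L)) {
    ins[[l]] <- h
    a <- h %*% net$W[[l]]
    a <- a + rep(net$b[[l]], each = n)
    pre[[l]] <- a
    h <- if (l < L || net$out_act == "elu") elu_(a) else a
  }
  list(out = h, ins = ins, pre = pre)
}

# dOut: gradient of the loss wrt the network output (post out_act)
#' @noRd
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut
  if (net$out_act == "elu") delta <- delta * elu_grad_(fw$pre[[L]])
  dIn <- NULL
  for (l in L:1) {
    dW[[l]] <- crossprod(fw$ins[[l]], delta)
    db[[l]] <- colSums(delta)
    dIn <- tcrossprod(delta, net$W[[l]])
    if (l > 1) delta <- dIn * elu_grad_(fw$pre[[l - 1]])
  }
  list(dW = dW, db = db, dIn = dIn)
}

# closed-form KL(N(mu, diag(s^2)) || N(0, I)) per row
gaussian_kl_ <- function(mu, s) {
  rowSums(0.5 * (mu^2 + s^2 - 1) - log(s))
}

# recursive elementwise combinators over nested parameter lists -------------

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) tree_map2(x, y, f), a, b) else f(a, b)
}

tree_map3 <- function(a, b, c, f) {
  if (is.list(a)) Map(function(x, y, z) tree_map3(x, y, z, f), a, b, c)
  else f(a, b, c)
}

# Adam with L2 weight decay folded into the gradient ----------------------

#' @noRd
adam_init <- function(nets) {
  zeros <- function(x) tree_map(x, function(v)
    if (is.numeric(v)) v * 0 else v)
  list(m = zeros(nets), v = zeros(nets), t = 0L)
}

#' @noRd
adam_step <- function(nets, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0)
    grads <- tree_map2(grads, nets, function(g, p) {
      if (is.numeric(p)) g + weight_decay * p else g
    })
  state$m <- tree_map2(state$m, grads, function(m, g)
    if (is.numeric(g)) beta1 * m + (1 - beta1) * g else m)
  state$v <- tree_map2(state$v, grads, function(v, g)
    if (is.numeric(g)) beta2 * v + (1 - beta2) * g * g else v)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  nets <- tree_map3(nets, state$m, state$v, function(p, m, v) {
    if (is.numeric(p)) p - lr * (m / c1) / (sqrt(v / c2) + eps) else p
  })
  list(nets = nets, state = state)
}
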