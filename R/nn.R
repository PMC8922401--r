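#' @useDynLib dtalearn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Neural-network primitives: broadcast helpers, layer normalization,
# softmax, multi-head self-attention transformer blocks (forward and
# backward), and the Adam optimizer.  Everything operates on plain R
# matrices; a batch of B sequences of length T with width W is stored as a
# (B*T) x W matrix with row (b-1)*T + t holding position t of sequence b.
# Gradients are hand-derived and verified against finite differences in
# the test suite.

# broadcast a length-ncol vector over all rows (compiled hot path)
br_add <- function(x, v) add_bias_cpp(x, v)
br_mul <- function(x, v) x * rep(v, each = nrow(x))

relu <- function(x) relu_cpp(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# ---- layer normalization (per row) ------------------------------------

ln_forward <- function(x, g, b, eps = 1e-5) {
  ln_forward_cpp(x, g, b, eps)
}

ln_backward <- function(dy, cache, g) {
  out <- ln_backward_cpp(dy, cache$xhat, cache$si, g)
  out$dg <- as.vector(out$dg)
  out$db <- as.vector(out$db)
  out
}

# ---- transformer encoder block stack (pre-LN) -------------------------

# parameter initialization for an L-layer encoder of a given width;
# returns a flat named list "<prefix>L<l>.<name>" plus a final layer norm.
# Weights are fan-in scaled (sd = 1/sqrt(fan_in)) so activations and
# logits start at unit scale even at miniature widths.
tf_init <- function(width, n_layers, ffn_mult = 4L, prefix = "") {
  p <- list()
  wff <- width * ffn_mult
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                  nr, nc)
  for (l in seq_len(n_layers)) {
    nm <- function(s) paste0(prefix, "L", l, ".", s)
    p[[nm("Wq")]] <- rmat(width, width); p[[nm("bq")]] <- numeric(width)
    p[[nm("Wk")]] <- rmat(width, width); p[[nm("bk")]] <- numeric(width)
    p[[nm("Wv")]] <- rmat(width, width); p[[nm("bv")]] <- numeric(width)
    p[[nm("Wo")]] <- rmat(width, width); p[[nm("bo")]] <- numeric(width)
    p[[nm("ln1g")]] <- rep(1, width); p[[nm("ln1b")]] <- numeric(width)
    p[[nm("W1")]] <- rmat(width, wff); p[[nm("b1")]] <- numeric(wff)
    p[[nm("W2")]] <- rmat(wff, width); p[[nm("b2")]] <- numeric(width)
    p[[nm("ln2g")]] <- rep(1, width); p[[nm("ln2b")]] <- numeric(width)
  }
  p[[paste0(prefix, "lnf.g")]] <- rep(1, width)
  p[[paste0(prefix, "lnf.b")]] <- numeric(width)
  p
}

# forward pass through the block stack
#   X0      (B*T) x W input embeddings
#   pad     length B*T logical, TRUE at padding positions (masked as keys)
# returns final hidden states (after the closing layer norm), the
# post-residual state of every layer, and the cache for backward
tf_forward <- function(params, prefix, X0, B, T, pad, width, n_heads,
                       n_layers) {
  dh <- width %/% n_heads
  stopifnot(dh * n_heads == width)
  X <- X0
  states <- vector("list", n_layers)
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    nm <- function(s) params[[paste0(prefix, "L", l, ".", s)]]
    ln1 <- ln_forward(X, nm("ln1g"), nm("ln1b"))
    Qm <- br_add(ln1$y %*% nm("Wq"), nm("bq"))
    Km <- br_add(ln1$y %*% nm("Wk"), nm("bk"))
    Vm <- br_add(ln1$y %*% nm("Wv"), nm("bv"))
    mh <- mha_forward_cpp(Qm, Km, Vm, pad, B, T, n_heads)
    O <- mh$O
    att <- br_add(O %*% nm("Wo"), nm("bo"))
    X2 <- X + att
    ln2 <- ln_forward(X2, nm("ln2g"), nm("ln2b"))
    Hpre <- br_add(ln2$y %*% nm("W1"), nm("b1"))
    Hact <- relu(Hpre)
    ff <- br_add(Hact %*% nm("W2"), nm("b2"))
    Xout <- X2 + ff
    caches[[l]] <- list(Xin = X, ln1 = ln1, Qm = Qm, Km = Km, Vm = Vm,
                        A = mh$A, O = O, X2 = X2, ln2 = ln2, Hact = Hact)
    states[[l]] <- Xout
    X <- Xout
  }
  lnf <- ln_forward(X, params[[paste0(prefix, "lnf.g")]],
                    params[[paste0(prefix, "lnf.b")]])
  list(final = lnf$y, states = states,
       cache = list(layers = caches, lnf = lnf, B = B, T = T, pad = pad,
                    width = width, n_heads = n_heads, n_layers = n_layers))
}

# backward pass; dFinal is the gradient at the final (post layer norm)
# output.  Returns the gradient at X0 plus parameter gradients.
tf_backward <- function(params, prefix, cache, dFinal) {
  B <- cache$B; T <- cache$T; width <- cache$width
  n_heads <- cache$n_heads; n_layers <- cache$n_layers
  g <- list()
  lb <- ln_backward(dFinal, cache$lnf,
                    params[[paste0(prefix, "lnf.g")]])
  g[[paste0(prefix, "lnf.g")]] <- lb$dg
  g[[paste0(prefix, "lnf.b")]] <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(n_layers))) {
    cc <- cache$layers[[l]]
    nm <- function(s) paste0(prefix, "L", l, ".", s)
    pget <- function(s) params[[nm(s)]]
    # FFN branch: Xout = X2 + ff
    dff <- dX
    g[[nm("W2")]] <- t(cc$Hact) %*% dff
    g[[nm("b2")]] <- colSums(dff)
    dHact <- dff %*% t(pget("W2"))
    dHpre <- dHact * (cc$Hact > 0)
    g[[nm("W1")]] <- t(cc$ln2$y) %*% dHpre
    g[[nm("b1")]] <- colSums(dHpre)
    dn2 <- dHpre %*% t(pget("W1"))
    lb2 <- ln_backward(dn2, cc$ln2, pget("ln2g"))
    g[[nm("ln2g")]] <- lb2$dg
    g[[nm("ln2b")]] <- lb2$db
    dX2 <- dX + lb2$dx
    # attention branch: X2 = Xin + att
    datt <- dX2
    g[[nm("Wo")]] <- t(cc$O) %*% datt
    g[[nm("bo")]] <- colSums(datt)
    dO <- datt %*% t(pget("Wo"))
    mb <- mha_backward_cpp(dO, cc$A, cc$Qm, cc$Km, cc$Vm, B, T, n_heads)
    dQ <- mb$dQ; dK <- mb$dK; dV <- mb$dV
    n1y <- cc$ln1$y
    g[[nm("Wq")]] <- t(n1y) %*% dQ; g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- t(n1y) %*% dK; g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- t(n1y) %*% dV; g[[nm("bv")]] <- colSums(dV)
    dn1 <- dQ %*% t(pget("Wq")) + dK %*% t(pget("Wk")) +
      dV %*% t(pget("Wv"))
    lb1 <- ln_backward(dn1, cc$ln1, pget("ln1g"))
    g[[nm("ln1g")]] <- lb1$dg
    g[[nm("ln1b")]] <- lb1$db
    dX <- dX2 + lb1$dx
  }
  list(dX0 = dX, grads = g)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# sum two gradient lists (union of names)
add_grads <- function(a, b, w = 1) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) w * b[[nm]] else a[[nm]] + w * b[[nm]]
  }
  a
}
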