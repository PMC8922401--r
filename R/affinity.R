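# The supervised affinity network: two squeeze-and-excitation CNN feature
# extractors (one per input modality), global max pooling, highway-gated
# layers and a fully connected regression (or classification) head.
# Forward and backward passes are hand-written on plain matrices; a batch
# of B embedding matrices (T x Win each) is processed as a stacked
# (B*T) x Win matrix, exactly as in the encoder code.

#' Affinity model configuration
#'
#' The `"benchmark"` preset mirrors the field's standard settings (kernel
#' 3; 256 then 512 convolution channels; fully connected sizes 1024,
#' 1024, 512, 1; dropout 0.4 after the first two FC layers; batch 256,
#' 100 epochs).  For the learning rate both conventions in circulation
#' are shipped: 3e-4 (default) and 1e-3 (`lr_preset = "alt"`).  The
#' `"miniature"` preset scales the same architecture down for desk-scale
#' experiments.
#'
#' @param compound_width,protein_width Input embedding widths.
#' @param compound_len,protein_len Fixed input lengths (positions).
#' @param preset `"benchmark"` or `"miniature"`.
#' @param kernel_size Convolution kernel (odd; `"same"` padding).
#' @param conv_channels Two channel counts for the stacked SE blocks.
#' @param fc_sizes Fully connected sizes, ending in 1.
#' @param dropout Dropout rate after the first two FC layers (training
#'   only).
#' @param n_highway Number of highway layers.
#' @param se_reduction Bottleneck reduction ratio of the excitation
#'   network.
#' @param task `"regression"` (mean squared error) or `"classification"`
#'   (binary cross-entropy, sigmoid output).
#' @param lr,epochs,batch,patience Training schedule; `patience` is the
#'   early-stopping patience on validation loss (`Inf` disables).
#' @param lr_preset `"table"` (3e-4) or `"alt"` (1e-3); ignored when `lr`
#'   is given explicitly.
#' @return A `dta_config` list.
#' @export
dta_config <- function(compound_width, protein_width,
                       compound_len = 100L, protein_len = 1000L,
                       preset = c("benchmark", "miniature"),
                       kernel_size = NULL, conv_channels = NULL,
                       fc_sizes = NULL, dropout = NULL, n_highway = 2L,
                       se_reduction = NULL, task = c("regression",
                                                     "classification"),
                       lr = NULL, epochs = NULL, batch = NULL,
                       patience = 20L, lr_preset = c("table", "alt")) {
  preset <- match.arg(preset)
  task <- match.arg(task)
  lr_preset <- match.arg(lr_preset)
  if (preset == "benchmark") {
    conv_channels <- conv_channels %||% c(256L, 512L)
    fc_sizes <- fc_sizes %||% c(1024L, 1024L, 512L, 1L)
    dropout <- dropout %||% 0.4
    se_reduction <- se_reduction %||% 16L
    lr <- lr %||% if (lr_preset == "table") 3e-4 else 1e-3
    epochs <- epochs %||% 100L
    batch <- batch %||% 256L
  } else {
    conv_channels <- conv_channels %||% c(16L, 32L)
    fc_sizes <- fc_sizes %||% c(64L, 32L, 1L)
    dropout <- dropout %||% 0.1
    se_reduction <- se_reduction %||% 4L
    lr <- lr %||% 1e-3
    epochs <- epochs %||% 40L
    batch <- batch %||% 64L
  }
  kernel_size <- kernel_size %||% 3L
  stopifnot(length(conv_channels) == 2L,
            fc_sizes[length(fc_sizes)] == 1L,
            dropout >= 0, dropout < 1, kernel_size %% 2L == 1L)
  structure(list(compound_width = as.integer(compound_width),
                 protein_width = as.integer(protein_width),
                 compound_len = as.integer(compound_len),
                 protein_len = as.integer(protein_len),
                 kernel_size = as.integer(kernel_size),
                 conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout,
                 n_highway = as.integer(n_highway),
                 se_reduction = as.integer(se_reduction), task = task,
                 lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), patience = patience),
            class = "dta_config")
}

he_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                  nr, nc)

se_init <- function(channels, reduction) {
  r <- max(1L, channels %/% reduction)
  list(A = he_mat(channels, r), ab = numeric(r),
       B = he_mat(r, channels), bb = numeric(channels))
}

dta_init_params <- function(cfg) {
  k <- cfg$kernel_size
  C1 <- cfg$conv_channels[1L]; C2 <- cfg$conv_channels[2L]
  p <- list()
  for (br in c("c", "p")) {
    win <- if (br == "c") cfg$compound_width else cfg$protein_width
    p[[paste0(br, ".conv1.W")]] <- he_mat(k * win, C1)
    p[[paste0(br, ".conv1.b")]] <- numeric(C1)
    se1 <- se_init(C1, cfg$se_reduction)
    p[[paste0(br, ".se1.A")]] <- se1$A; p[[paste0(br, ".se1.ab")]] <- se1$ab
    p[[paste0(br, ".se1.B")]] <- se1$B; p[[paste0(br, ".se1.bb")]] <- se1$bb
    p[[paste0(br, ".conv2.W")]] <- he_mat(k * C1, C2)
    p[[paste0(br, ".conv2.b")]] <- numeric(C2)
    se2 <- se_init(C2, cfg$se_reduction)
    p[[paste0(br, ".se2.A")]] <- se2$A; p[[paste0(br, ".se2.ab")]] <- se2$ab
    p[[paste0(br, ".se2.B")]] <- se2$B; p[[paste0(br, ".se2.bb")]] <- se2$bb
  }
  D <- 2L * C2
  for (l in seq_len(cfg$n_highway)) {
    p[[paste0("hw", l, ".Wt")]] <- he_mat(D, D)
    p[[paste0("hw", l, ".bt")]] <- rep(-1, D)   # carry-biased at start
    p[[paste0("hw", l, ".Wh")]] <- he_mat(D, D)
    p[[paste0("hw", l, ".bh")]] <- numeric(D)
  }
  sizes <- c(D, cfg$fc_sizes)
  for (l in seq_along(cfg$fc_sizes)) {
    p[[paste0("fc", l, ".W")]] <- he_mat(sizes[l], sizes[l + 1L])
    p[[paste0("fc", l, ".b")]] <- numeric(sizes[l + 1L])
  }
  p
}

# ---- convolution as shifted-column stacking ('same' padding) ----------

# row r of the output receives position t+dir of the same sequence
shift_stack <- function(X, B, T, dir) {
  out <- matrix(0, nrow(X), ncol(X))
  t_of <- rep(seq_len(T), B)
  if (dir == -1L) {
    sel <- which(t_of > 1L)
    out[sel, ] <- X[sel - 1L, , drop = FALSE]
  } else {
    sel <- which(t_of < T)
    out[sel, ] <- X[sel + 1L, , drop = FALSE]
  }
  out
}

unshift_add <- function(dX, dS, B, T, dir) {
  t_of <- rep(seq_len(T), B)
  if (dir == -1L) {
    sel <- which(t_of > 1L)
    dX[sel - 1L, ] <- dX[sel - 1L, , drop = FALSE] + dS[sel, , drop = FALSE]
  } else {
    sel <- which(t_of < T)
    dX[sel + 1L, ] <- dX[sel + 1L, , drop = FALSE] + dS[sel, , drop = FALSE]
  }
  dX
}

conv1d_forward <- function(X, W, b, B, T, k) {
  stopifnot(k == 3L)   # the architecture fixes kernel 3
  Xcol <- cbind(shift_stack(X, B, T, -1L), X, shift_stack(X, B, T, +1L))
  list(out = br_add(Xcol %*% W, b), Xcol = Xcol)
}

conv1d_backward <- function(dOut, cache, W, B, T) {
  win <- ncol(cache$Xcol) / 3L
  dXcol <- dOut %*% t(W)
  dX <- dXcol[, (win + 1L):(2L * win), drop = FALSE]
  dX <- unshift_add(dX, dXcol[, 1:win, drop = FALSE], B, T, -1L)
  dX <- unshift_add(dX, dXcol[, (2L * win + 1L):(3L * win), drop = FALSE],
                    B, T, +1L)
  list(dX = dX, dW = t(cache$Xcol) %*% dOut, db = colSums(dOut))
}

# ---- squeeze and excitation -------------------------------------------

se_apply <- function(U, A, ab, Bm, bb, samp, T, gate_override = NULL) {
  z <- rowsum(U, samp) / T                 # squeeze: per-channel mean
  apre <- br_add(z %*% A, ab)
  a <- relu(apre)
  spre <- br_add(a %*% Bm, bb)
  s <- sigmoid(spre)                       # excitation gate in (0,1)
  if (!is.null(gate_override)) {
    s <- matrix(gate_override, nrow(s), ncol(s), byrow = TRUE)
  }
  list(out = U * s[samp, , drop = FALSE], z = z, a = a, s = s,
       apre = apre)
}

se_backward <- function(dOut, U, cache, A, Bm, samp, T) {
  s_rows <- cache$s[samp, , drop = FALSE]
  dU <- dOut * s_rows
  ds <- rowsum(dOut * U, samp)
  dspre <- ds * cache$s * (1 - cache$s)
  dB <- t(cache$a) %*% dspre
  dbb <- colSums(dspre)
  da <- dspre %*% t(Bm)
  dapre <- da * (cache$apre > 0)
  dA <- t(cache$z) %*% dapre
  dab <- colSums(dapre)
  dz <- dapre %*% t(A)
  dU <- dU + dz[samp, , drop = FALSE] / T
  list(dU = dU, dA = dA, dab = dab, dB = dB, dbb = dbb)
}

# ---- global max pooling ----------------------------------------------

pool_max <- function(U, B, T) {
  C <- ncol(U)
  v <- matrix(-Inf, B, C)
  arg <- matrix(1L, B, C)
  base <- (seq_len(B) - 1L) * T
  for (t in seq_len(T)) {
    cand <- U[base + t, , drop = FALSE]
    upd <- cand > v
    v[upd] <- cand[upd]
    arg[upd] <- t
  }
  list(v = v, arg = arg)
}

pool_max_backward <- function(dv, arg, B, T, C) {
  dU <- matrix(0, B * T, C)
  rows <- (rep(seq_len(B), C) - 1L) * T + as.vector(arg)
  dU[cbind(rows, rep(seq_len(C), each = B))] <- as.vector(dv)
  dU
}

# ---- one feature-extractor branch -------------------------------------

branch_forward <- function(params, br, X, B, T, cfg) {
  nm <- function(s) params[[paste0(br, ".", s)]]
  samp <- rep(seq_len(B), each = T)
  cv1 <- conv1d_forward(X, nm("conv1.W"), nm("conv1.b"), B, T,
                        cfg$kernel_size)
  U1 <- relu(cv1$out)
  se1 <- se_apply(U1, nm("se1.A"), nm("se1.ab"), nm("se1.B"), nm("se1.bb"),
                  samp, T)
  cv2 <- conv1d_forward(se1$out, nm("conv2.W"), nm("conv2.b"), B, T,
                        cfg$kernel_size)
  U2 <- relu(cv2$out)
  se2 <- se_apply(U2, nm("se2.A"), nm("se2.ab"), nm("se2.B"), nm("se2.bb"),
                  samp, T)
  pl <- pool_max(se2$out, B, T)
  list(v = pl$v,
       cache = list(cv1 = cv1, U1 = U1, se1 = se1, cv2 = cv2, U2 = U2,
                    se2 = se2, pool = pl, samp = samp, B = B, T = T))
}

branch_backward <- function(params, br, dv, cache, cfg) {
  nm <- function(s) params[[paste0(br, ".", s)]]
  key <- function(s) paste0(br, ".", s)
  B <- cache$B; T <- cache$T; samp <- cache$samp
  g <- list()
  dU2s <- pool_max_backward(dv, cache$pool$arg, B, T,
                            ncol(cache$se2$out))
  sb2 <- se_backward(dU2s, cache$U2, cache$se2, nm("se2.A"), nm("se2.B"),
                     samp, T)
  g[[key("se2.A")]] <- sb2$dA; g[[key("se2.ab")]] <- sb2$dab
  g[[key("se2.B")]] <- sb2$dB; g[[key("se2.bb")]] <- sb2$dbb
  dU2pre <- sb2$dU * (cache$cv2$out > 0)
  cb2 <- conv1d_backward(dU2pre, cache$cv2, nm("conv2.W"), B, T)
  g[[key("conv2.W")]] <- cb2$dW; g[[key("conv2.b")]] <- cb2$db
  sb1 <- se_backward(cb2$dX, cache$U1, cache$se1, nm("se1.A"), nm("se1.B"),
                     samp, T)
  g[[key("se1.A")]] <- sb1$dA; g[[key("se1.ab")]] <- sb1$dab
  g[[key("se1.B")]] <- sb1$dB; g[[key("se1.bb")]] <- sb1$dbb
  dU1pre <- sb1$dU * (cache$cv1$out > 0)
  cb1 <- conv1d_backward(dU1pre, cache$cv1, nm("conv1.W"), B, T)
  g[[key("conv1.W")]] <- cb1$dW; g[[key("conv1.b")]] <- cb1$db
  g
}

# ---- highway + fully connected head -----------------------------------

highway_forward <- function(x, Wt, bt, Wh, bh, gate_override = NULL) {
  tpre <- br_add(x %*% Wt, bt)
  tg <- sigmoid(tpre)
  if (!is.null(gate_override)) {
    tg <- matrix(gate_override, nrow(tg), ncol(tg), byrow = TRUE)
  }
  hpre <- br_add(x %*% Wh, bh)
  h <- relu(hpre)
  list(y = tg * h + (1 - tg) * x, x = x, tg = tg, h = h, hpre = hpre)
}

highway_backward <- function(dy, cache, Wt, Wh) {
  tg <- cache$tg; h <- cache$h; x <- cache$x
  dtg <- dy * (h - x)
  dh <- dy * tg
  dx <- dy * (1 - tg)
  dtpre <- dtg * tg * (1 - tg)
  dhpre <- dh * (cache$hpre > 0)
  list(dx = dx + dtpre %*% t(Wt) + dhpre %*% t(Wh),
       dWt = t(x) %*% dtpre, dbt = colSums(dtpre),
       dWh = t(x) %*% dhpre, dbh = colSums(dhpre))
}

# full forward pass; Ec/Ep are lists of (len x width) embedding matrices
dta_forward <- function(params, cfg, Ec, Ep, training = FALSE,
                        drop_masks = NULL) {
  B <- length(Ec)
  Xc <- do.call(rbind, Ec)
  Xp <- do.call(rbind, Ep)
  fc_branch <- branch_forward(params, "c", Xc, B, cfg$compound_len, cfg)
  fp_branch <- branch_forward(params, "p", Xp, B, cfg$protein_len, cfg)
  x <- cbind(fc_branch$v, fp_branch$v)
  hw <- vector("list", cfg$n_highway)
  for (l in seq_len(cfg$n_highway)) {
    hw[[l]] <- highway_forward(x, params[[paste0("hw", l, ".Wt")]],
                               params[[paste0("hw", l, ".bt")]],
                               params[[paste0("hw", l, ".Wh")]],
                               params[[paste0("hw", l, ".bh")]])
    x <- hw[[l]]$y
  }
  n_fc <- length(cfg$fc_sizes)
  fc <- vector("list", n_fc)
  for (l in seq_len(n_fc)) {
    pre <- br_add(x %*% params[[paste0("fc", l, ".W")]],
                  params[[paste0("fc", l, ".b")]])
    act <- if (l < n_fc) relu(pre) else pre
    mask <- NULL
    if (l <= 2L && l < n_fc && training && cfg$dropout > 0) {
      mask <- drop_masks[[l]] %||%
        (matrix(stats::runif(length(act)) >= cfg$dropout,
                nrow(act), ncol(act)) / (1 - cfg$dropout))
      act <- act * mask
    }
    fc[[l]] <- list(x = x, pre = pre, mask = mask)
    x <- act
  }
  list(out = as.vector(x),
       cache = list(fc_branch = fc_branch, fp_branch = fp_branch, hw = hw,
                    fc = fc, B = B))
}

dta_backward <- function(params, cfg, cache, dout) {
  g <- list()
  n_fc <- length(cfg$fc_sizes)
  dx <- matrix(dout, cache$B, 1L)
  for (l in rev(seq_len(n_fc))) {
    cc <- cache$fc[[l]]
    if (!is.null(cc$mask)) dx <- dx * cc$mask
    if (l < n_fc) dx <- dx * (cc$pre > 0)
    g[[paste0("fc", l, ".W")]] <- t(cc$x) %*% dx
    g[[paste0("fc", l, ".b")]] <- colSums(dx)
    dx <- dx %*% t(params[[paste0("fc", l, ".W")]])
  }
  for (l in rev(seq_len(cfg$n_highway))) {
    hb <- highway_backward(dx, cache$hw[[l]],
                           params[[paste0("hw", l, ".Wt")]],
                           params[[paste0("hw", l, ".Wh")]])
    g[[paste0("hw", l, ".Wt")]] <- hb$dWt
    g[[paste0("hw", l, ".bt")]] <- hb$dbt
    g[[paste0("hw", l, ".Wh")]] <- hb$dWh
    g[[paste0("hw", l, ".bh")]] <- hb$dbh
    dx <- hb$dx
  }
  C2 <- cfg$conv_channels[2L]
  g <- add_grads(g, branch_backward(params, "c", dx[, 1:C2, drop = FALSE],
                                    cache$fc_branch$cache, cfg))
  g <- add_grads(g, branch_backward(params, "p",
                                    dx[, (C2 + 1L):(2L * C2), drop = FALSE],
                                    cache$fp_branch$cache, cfg))
  g
}

# loss + gradients on one batch (pure given drop_masks)
dta_loss_grads <- function(params, cfg, Ec, Ep, y, training = TRUE,
                           drop_masks = NULL, grads = TRUE) {
  fw <- dta_forward(params, cfg, Ec, Ep, training, drop_masks)
  B <- length(y)
  if (cfg$task == "regression") {
    loss <- mean((fw$out - y)^2)
    dout <- 2 * (fw$out - y) / B
  } else {
    x <- fw$out
    loss <- mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
    dout <- (sigmoid(x) - y) / B
  }
  out <- list(loss = loss, pred = fw$out)
  if (grads) out$grads <- dta_backward(params, cfg, fw$cache, dout)
  out
}

#' Train the affinity network
#'
#' Fits the twin SE-block feature extractors, highway stack and fully
#' connected head on interaction pairs with precomputed entity
#' embeddings, minimizing mean squared error (regression) or binary
#' cross-entropy (classification) with Adam.  The best-on-validation
#' parameters are kept, with early stopping on validation loss.  Runs
#' with the same seed reproduce the same loss curve.
#'
#' @param pairs Data.frame with `compound_id`, `protein_id`, `affinity`.
#' @param compound_emb,protein_emb Named lists of embedding matrices
#'   (from [encode_entities()] or [encode_onehot()]), shaped
#'   `(compound_len, compound_width)` / `(protein_len, protein_width)`.
#' @param config A [dta_config()].
#' @param val Validation set: a fraction of the pairs (default 0.1) or an
#'   integer index vector into `pairs`; 0 disables validation (the
#'   training loss then drives checkpoint selection).
#' @param seed Integer seed (initialization, batch order, dropout).
#' @param verbose Print per-epoch losses.
#' @return A `dta_model`: list with `config`, `params` (best checkpoint),
#'   `log` (epoch, train_loss, val_loss, val_ci), `best_epoch`.
#' @export
dta_train <- function(pairs, compound_emb, protein_emb, config,
                      val = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "dta_config"), nrow(pairs) >= 1L)
  y_all <- pairs$affinity
  if (anyNA(y_all)) stop("NA affinities in training pairs", call. = FALSE)
  if (config$task == "regression" && stats::sd(y_all) == 0) {
    stop("all affinities identical: nothing to regress", call. = FALSE)
  }
  miss_c <- setdiff(pairs$compound_id, names(compound_emb))
  miss_p <- setdiff(pairs$protein_id, names(protein_emb))
  if (length(miss_c) || length(miss_p)) {
    stop("missing embeddings for some entities", call. = FALSE)
  }
  n <- nrow(pairs)
  log_rows <- list()
  with_seed(seed, {
    if (length(val) == 1L && val < 1) {
      n_val <- floor(n * val)
      val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
    } else {
      val_idx <- as.integer(val)
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0L) stop("no training pairs left",
                                      call. = FALSE)
    Ec_val <- compound_emb[pairs$compound_id[val_idx]]
    Ep_val <- protein_emb[pairs$protein_id[val_idx]]
    y_val <- y_all[val_idx]
    params <- dta_init_params(config)
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stale <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      tl <- 0
      for (s in seq(1L, length(ord), by = config$batch)) {
        take <- ord[s:min(s + config$batch - 1L, length(ord))]
        res <- dta_loss_grads(params, config,
                              compound_emb[pairs$compound_id[take]],
                              protein_emb[pairs$protein_id[take]],
                              y_all[take], training = TRUE)
        upd <- adam_step(params, res$grads, state, config$lr)
        params <- upd$params
        state <- upd$state
        tl <- tl + res$loss * length(take) / length(ord)
      }
      if (length(val_idx)) {
        vres <- dta_loss_grads(params, config, Ec_val, Ep_val, y_val,
                               training = FALSE, grads = FALSE)
        vl <- vres$loss
        vci <- if (config$task == "regression" &&
                     length(unique(y_val)) > 1L) {
          concordance_index(y_val, vres$pred)
        } else NA_real_
      } else {
        vl <- tl
        vci <- NA_real_
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = tl,
                                   val_loss = vl, val_ci = vci)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f ci %.3f", ep, tl,
                        vl, vci))
      }
      if (vl < best$loss) {
        best <- list(loss = vl, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })
  structure(list(config = config, params = best$params,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch,
                 seed = seed),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dta_model (%s): SE-CNN %d/%d channels, %d highway, FC %s>\n",
    cfg$task, cfg$conv_channels[1L], cfg$conv_channels[2L], cfg$n_highway,
    paste(cfg$fc_sizes, collapse = "-")))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epochs; best epoch %d (val loss %.4f)\n",
                nrow(x$log), x$best_epoch,
                x$log$val_loss[x$best_epoch]))
  }
  invisible(x)
}

#' @export
summary.dta_model <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("  parameters: %d\n  inputs: compound (%d x %d), protein (%d x %d)\n",
              n_par, object$config$compound_len, object$config$compound_width,
              object$config$protein_len, object$config$protein_width))
  invisible(object)
}

#' Predict affinities for compound-protein pairs
#'
#' @param object A `dta_model`.
#' @param pairs Data.frame with `compound_id`, `protein_id`.
#' @param compound_emb,protein_emb Named embedding lists as in
#'   [dta_train()].
#' @param batch Batch size for the forward passes.
#' @param ... Unused.
#' @return Numeric vector: affinity scores (regression) or probabilities
#'   in `(0, 1)` (classification).
#' @export
predict.dta_model <- function(object, pairs, compound_emb, protein_emb,
                              batch = 64L, ...) {
  out <- numeric(nrow(pairs))
  for (s in seq(1L, nrow(pairs), by = batch)) {
    take <- s:min(s + batch - 1L, nrow(pairs))
    fw <- dta_forward(object$params, object$config,
                      compound_emb[pairs$compound_id[take]],
                      protein_emb[pairs$protein_id[take]],
                      training = FALSE)
    out[take] <- fw$out
  }
  if (object$config$task == "classification") sigmoid(out) else out
}

# ---- exported architectural primitives --------------------------------

#' Squeeze-and-excitation block on a single feature map
#'
#' Projects the input `(T, in)` matrix to `(T, out_channels)` by a
#' kernel-3 "same" 1-D convolution with ReLU, squeezes a per-channel
#' descriptor by global average pooling over positions, passes it through
#' the bottleneck excitation network (ReLU then sigmoid self-gating), and
#' scales each channel of the feature map by its gate weight in `[0, 1]`
#' -- so the block is a per-channel contraction of the convolved map, and
#' forcing the gate to all-ones returns the convolved map unchanged.
#'
#' @param X Input matrix `(T, in_width)`.
#' @param out_channels Channels of the convolved map.
#' @param reduction Bottleneck reduction ratio.
#' @param params Optional parameter list (as produced with `seed`);
#'   supplying it makes the call deterministic.
#' @param seed Seed for parameter initialization when `params` is `NULL`.
#' @param gate_override Optional fixed gate vector (length
#'   `out_channels`), bypassing the excitation network.
#' @return List with `output`, `U` (convolved map), `gate`, `descriptor`
#'   (the squeeze), and `params`.
#' @export
se_block <- function(X, out_channels, reduction = 16L, params = NULL,
                     seed = 1L, gate_override = NULL) {
  stopifnot(is.matrix(X))
  if (!all(is.finite(X))) stop("non-finite input", call. = FALSE)
  if (is.null(params)) {
    params <- with_seed(seed, {
      se <- se_init(out_channels, reduction)
      list(W = he_mat(3L * ncol(X), out_channels),
           b = numeric(out_channels), A = se$A, ab = se$ab, B = se$B,
           bb = se$bb)
    })
  }
  T <- nrow(X)
  cv <- conv1d_forward(X, params$W, params$b, 1L, T, 3L)
  U <- relu(cv$out)
  se <- se_apply(U, params$A, params$ab, params$B, params$bb,
                 rep(1L, T), T, gate_override)
  list(output = se$out, U = U, gate = as.vector(se$s),
       descriptor = as.vector(se$z), params = params)
}

#' Highway layer on a feature vector
#'
#' `y = T(x) * H(x) + (1 - T(x)) * x` with a sigmoid transform gate
#' `T` and a ReLU transform `H`; the carry gate is `1 - T(x)`.  Forcing
#' the gate to 0 returns the input unchanged; forcing it to 1 returns
#' the transform stream.
#'
#' @param x Numeric vector (or 1-row matrix).
#' @param params Optional list with `Wt`, `bt`, `Wh`, `bh`.
#' @param seed Seed for initialization when `params` is `NULL`.
#' @param gate_override Optional fixed transform-gate value(s) in
#'   `[0, 1]`.
#' @return List with `y`, `transform` (H(x)), `gate`, `params`.
#' @export
highway_layer <- function(x, params = NULL, seed = 1L,
                          gate_override = NULL) {
  xm <- matrix(x, 1L)
  d <- ncol(xm)
  if (is.null(params)) {
    params <- with_seed(seed, list(Wt = he_mat(d, d), bt = rep(-1, d),
                                   Wh = he_mat(d, d), bh = numeric(d)))
  }
  hw <- highway_forward(xm, params$Wt, params$bt, params$Wh, params$bh,
                        gate_override)
  list(y = as.vector(hw$y), transform = as.vector(hw$h),
       gate = as.vector(hw$tg), params = params)
}

#' Global max pooling over positions
#'
#' @param U Feature map `(T, C)`.
#' @return Numeric vector of per-channel maxima (length `C`).
#' @export
global_max_pool <- function(U) {
  stopifnot(is.matrix(U))
  apply(U, 2L, max)
}

#' Run one feature-extractor branch of a model
#'
#' Applies the stacked SE blocks and global max pooling of a trained (or
#' freshly initialized) model to a single embedding matrix, returning the
#' branch feature vector (length `conv_channels[2]`).
#'
#' @param E Embedding matrix `(len, width)` matching the branch's input
#'   contract.
#' @param model A `dta_model`, or a list with `params` and `config`.
#' @param branch `"compound"` or `"protein"`.
#' @return Numeric feature vector.
#' @export
feature_extract <- function(E, model, branch = c("compound", "protein")) {
  branch <- match.arg(branch)
  cfg <- model$config
  br <- if (branch == "compound") "c" else "p"
  T <- if (branch == "compound") cfg$compound_len else cfg$protein_len
  win <- if (branch == "compound") cfg$compound_width else cfg$protein_width
  if (!is.matrix(E) || nrow(E) != T || ncol(E) != win) {
    stop(sprintf("embedding must be a %d x %d matrix", T, win),
         call. = FALSE)
  }
  as.vector(branch_forward(model$params, br, E, 1L, T, cfg)$v)
}
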