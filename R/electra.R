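# Replaced-token-detection (generator/discriminator) pretraining of
# contextual sequence encoders.
#
# A small generator (a width-reduced transformer with tied token
# embeddings) fills masked positions with sampled predictions; the
# discriminator (the encoder that is kept) learns to tell replaced tokens
# from originals.  Token ids are zero-based with <PAD> = 0 and <MASK> = 1,
# matching the vocabulary; the <PAD> embedding row is fixed at zero and
# padding positions are excluded from attention keys and from both losses.

#' Encoder configuration
#'
#' Defaults describe the miniature desk-scale encoder (2 transformer
#' layers of width 64); the full-scale configuration in the field (width
#' 256, 12 layers) is reachable through the same arguments.
#'
#' @param vocab_size Vocabulary size (including the two specials).
#' @param width Embedding/hidden width of the discriminator encoder.
#' @param n_layers Number of transformer layers.
#' @param n_heads Attention heads (`width` must be divisible).
#' @param max_positions Longest sequence the encoder accepts; longer
#'   corpus strings are truncated for pretraining.
#' @param generator_fraction Generator width as a fraction of `width`.
#' @param mask_prob Per-position masking probability.
#' @param ffn_mult Feed-forward expansion factor.
#' @param disc_weight Weight of the discriminator loss in the joint
#'   objective (discriminator : generator = `disc_weight` : 1).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(vocab_size, width = 64L, n_layers = 2L,
                           n_heads = 4L, max_positions = 128L,
                           generator_fraction = 0.25, mask_prob = 0.15,
                           ffn_mult = 4L, disc_weight = 50) {
  stopifnot(width %% n_heads == 0L, mask_prob >= 0, mask_prob < 1,
            vocab_size >= 3L)
  g_width <- max(8L, as.integer(round(width * generator_fraction)))
  g_heads <- if (g_width %% n_heads == 0L) n_heads else 1L
  structure(list(vocab_size = as.integer(vocab_size),
                 width = as.integer(width), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 max_positions = as.integer(max_positions),
                 generator_fraction = generator_fraction,
                 g_width = g_width, g_heads = g_heads,
                 mask_prob = mask_prob, ffn_mult = as.integer(ffn_mult),
                 disc_weight = disc_weight),
            class = "encoder_config")
}

# parameter initialization; the <PAD> embedding row (id 0) is zero and
# receives no gradient (padding never reaches a loss term).  Weights are
# fan-in scaled so tied-embedding logits start at unit scale.
electra_init_params <- function(config) {
  V <- config$vocab_size; W <- config$width; P <- config$max_positions
  Wg <- config$g_width
  rmat <- function(nr, nc, fan = nr) {
    matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fan)), nr, nc)
  }
  p <- list(
    tok_emb = rmat(V, W, fan = W),
    pos_emb = rmat(P, W, fan = W),
    g_in = rmat(W, Wg),
    g_pos = rmat(P, Wg, fan = Wg),
    g_out = rmat(Wg, W),
    g_vb = numeric(V),
    d_head.w = rmat(W, 1L),
    d_head.b = 0
  )
  p$tok_emb[1L, ] <- 0
  c(p, tf_init(W, config$n_layers, config$ffn_mult, "d."),
    tf_init(Wg, config$n_layers, config$ffn_mult, "g."))
}

#' Select positions to mask
#'
#' Each non-padding position is independently selected with probability
#' `mask_prob`; selected positions carry the `<MASK>` id (1) in the
#' returned masked sequence.
#'
#' @param ids Zero-based integer id vector (0 = `<PAD>`).
#' @param mask_prob Masking probability in `[0, 1)`.
#' @param seed Optional seed for a reproducible draw.
#' @return List with `masked_ids`, `selected` (logical) and the original
#'   `ids`.
#' @export
mask_tokens <- function(ids, mask_prob, seed = NULL) {
  if (length(ids) == 0L) stop("ids is empty", call. = FALSE)
  if (mask_prob < 0 || mask_prob >= 1) {
    stop("mask_prob must lie in [0, 1)", call. = FALSE)
  }
  draw <- function() stats::runif(length(ids)) < mask_prob & ids != 0L
  selected <- if (is.null(seed)) draw() else with_seed(seed, draw())
  masked <- ids
  masked[selected] <- 1L
  list(masked_ids = masked, selected = selected, ids = ids)
}

#' Build a corrupted sequence from generator predictions
#'
#' The corrupted sequence equals the original except at the selected
#' positions, which carry the generator's sampled predictions; the
#' replacement flag of a position is the elementwise inequality of
#' corrupted and original ids (a generator that happens to sample the
#' true token yields a `FALSE` flag).
#'
#' @param ids Original zero-based id vector.
#' @param selected Logical vector of masked positions.
#' @param predictions Integer predictions, one per selected position (in
#'   position order).
#' @return List with `corrupted_ids`, `replaced_flags`, `original_ids`.
#' @export
corrupt_ids <- function(ids, selected, predictions) {
  stopifnot(length(selected) == length(ids),
            length(predictions) == sum(selected))
  corrupted <- ids
  corrupted[selected] <- predictions
  list(corrupted_ids = corrupted, replaced_flags = corrupted != ids,
       original_ids = ids)
}

# rowsum-based scatter-add of `inc` rows into `target` rows given by `idx`
scatter_add_rows <- function(target, idx, inc) {
  rs <- rowsum(inc, group = idx)
  rows <- as.integer(rownames(rs))
  target[rows, ] <- target[rows, , drop = FALSE] + rs
  target
}

# Joint generator + discriminator losses and gradients on one batch.
#   ids       B x T zero-based id matrix (0 = PAD)
#   mask_sel  B x T logical; pad positions are never treated as selected
#   repl      integer replacements for the selected positions (row-major
#             over sequences); when NULL they are sampled from the
#             generator's output distribution (categorical, temperature 1)
# Returns losses, the sampled/los replacements, per-position disc
# probabilities, and (optionally) gradients for every parameter.
electra_losses <- function(params, config, ids, mask_sel, repl = NULL,
                           grads = TRUE) {
  B <- nrow(ids); T <- ncol(ids)
  W <- config$width; Wg <- config$g_width; V <- config$vocab_size
  ids_vec <- as.vector(t(ids))
  pad <- ids_vec == 0L
  msel <- as.vector(t(mask_sel)) & !pad
  pos_idx <- rep(seq_len(T), B)
  emb_rows <- ids_vec + 1L

  # --- generator forward on the masked input
  gin_ids <- ids_vec
  gin_ids[msel] <- 1L
  X0g <- params$tok_emb[gin_ids + 1L, , drop = FALSE] %*% params$g_in +
    params$g_pos[pos_idx, , drop = FALSE]
  gf <- tf_forward(params, "g.", X0g, B, T, pad, Wg, config$g_heads,
                   config$n_layers)
  mask_rows <- which(msel)
  n_mask <- length(mask_rows)
  loss_gen <- 0
  probs_gen <- NULL
  if (n_mask > 0L) {
    Fm <- gf$final[mask_rows, , drop = FALSE]
    M <- Fm %*% params$g_out
    logits_g <- br_add(M %*% t(params$tok_emb), params$g_vb)
    logits_g[, 1:2] <- -1e9            # never predict the specials
    probs_gen <- softmax_rows(logits_g)
    true_ids <- ids_vec[mask_rows]
    loss_gen <- mean(-log(pmax(probs_gen[cbind(seq_len(n_mask),
                                               true_ids + 1L)], 1e-12)))
    if (is.null(repl)) {
      repl <- vapply(seq_len(n_mask), function(i) {
        sample.int(V, 1L, prob = probs_gen[i, ]) - 1L
      }, integer(1))
    }
  } else {
    repl <- integer(0)
  }

  # --- discriminator forward on the corrupted input
  corrupted <- ids_vec
  corrupted[mask_rows] <- repl
  flags <- corrupted != ids_vec
  X0d <- params$tok_emb[corrupted + 1L, , drop = FALSE] +
    params$pos_emb[pos_idx, , drop = FALSE]
  df <- tf_forward(params, "d.", X0d, B, T, pad, W, config$n_heads,
                   config$n_layers)
  logits_d <- as.vector(df$final %*% params$d_head.w) + params$d_head.b
  valid <- !pad
  n_valid <- sum(valid)
  x <- logits_d[valid]
  y <- as.numeric(flags[valid])
  loss_disc <- mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
  total <- loss_gen + config$disc_weight * loss_disc

  out <- list(loss = total, loss_gen = loss_gen, loss_disc = loss_disc,
              repl = repl, flags = flags, pad = pad,
              probs = sigmoid(logits_d))
  if (!grads) return(out)

  g <- list()
  dtok <- matrix(0, V, W)
  # discriminator path (weight disc_weight)
  dlog <- numeric(B * T)
  dlog[valid] <- (sigmoid(x) - y) / n_valid * config$disc_weight
  g$d_head.w <- t(df$final) %*% dlog
  g$d_head.b <- sum(dlog)
  dFinal_d <- outer(dlog, as.vector(params$d_head.w))
  bd <- tf_backward(params, "d.", df$cache, dFinal_d)
  g <- add_grads(g, bd$grads)
  dtok <- scatter_add_rows(dtok, corrupted + 1L, bd$dX0)
  g$pos_emb <- scatter_add_rows(matrix(0, config$max_positions, W),
                                pos_idx, bd$dX0)
  # generator path
  if (n_mask > 0L) {
    dLg <- probs_gen
    dLg[cbind(seq_len(n_mask), ids_vec[mask_rows] + 1L)] <-
      dLg[cbind(seq_len(n_mask), ids_vec[mask_rows] + 1L)] - 1
    dLg <- dLg / n_mask
    dLg[, 1:2] <- 0
    g$g_vb <- colSums(dLg)
    Fm <- gf$final[mask_rows, , drop = FALSE]
    M <- Fm %*% params$g_out
    dM <- dLg %*% params$tok_emb
    dtok <- dtok + t(dLg) %*% M
    g$g_out <- t(Fm) %*% dM
    dFinal_g <- matrix(0, B * T, Wg)
    dFinal_g[mask_rows, ] <- dM %*% t(params$g_out)
    bg <- tf_backward(params, "g.", gf$cache, dFinal_g)
    g <- add_grads(g, bg$grads)
    g$g_in <- t(params$tok_emb[gin_ids + 1L, , drop = FALSE]) %*% bg$dX0
    dtok <- scatter_add_rows(dtok, gin_ids + 1L, bg$dX0 %*% t(params$g_in))
    g$g_pos <- scatter_add_rows(matrix(0, config$max_positions, Wg),
                                pos_idx, bg$dX0)
  }
  dtok[1L, ] <- 0                      # <PAD> embedding stays zero
  g$tok_emb <- dtok
  out$grads <- g
  out
}

# tokenize an input string according to the encoder's kind/mode
encoder_tokenize <- function(encoder, x, source_id = NA_character_) {
  if (inherits(x, "token_seq")) return(x)
  if (encoder$kind == "protein") {
    tokenize_protein(x, source_id = source_id)
  } else {
    tokenize_smiles(x, mode = encoder$tokenize_mode, source_id = source_id)
  }
}

encoder_ids <- function(encoder, x) {
  if (is.numeric(x)) return(as.integer(x))
  ts <- encoder_tokenize(encoder, x)
  encode_tokens(encoder$vocab, ts$tokens)
}

# ids for a whole corpus, truncated to max_positions
corpus_to_ids <- function(encoder, corpus) {
  lapply(corpus, function(s) {
    ids <- encoder_ids(encoder, s)
    if (length(ids) > encoder$config$max_positions) {
      ids <- ids[seq_len(encoder$config$max_positions)]
    }
    ids
  })
}

# stack a list of id vectors into a zero-padded B x T matrix
pad_id_matrix <- function(id_list) {
  T <- max(lengths(id_list))
  do.call(rbind, lapply(id_list, function(v) {
    c(v, rep(0L, T - length(v)))
  }))
}

#' Pretrain a contextual encoder by replaced-token detection
#'
#' Jointly trains a small masked-language-model generator and the
#' discriminator encoder on a corpus: masked positions are filled with
#' generator samples, and the discriminator learns to flag the positions
#' whose token differs from the original.  The discriminator encoder is
#' what the embedding stage uses downstream.  The joint objective is
#' `generator cross-entropy + disc_weight * discriminator binary
#' cross-entropy`, optimized with Adam; padding contributes to neither
#' loss.  Seeded runs are bit-reproducible.
#'
#' @param corpus Character vector of strings (or list of `token_seq`).
#' @param kind `"compound"` or `"protein"`.
#' @param vocab Optional vocabulary; built from the corpus when `NULL`.
#' @param config Optional [encoder_config()]; a miniature default is
#'   derived from the vocabulary when `NULL`.
#' @param epochs,batch,lr Training schedule (defaults 10 / 64 / 1e-3 for
#'   the miniature scale; the full-scale convention of batch 256 and lr
#'   1e-5 over 100 epochs is reachable through the same arguments).
#' @param seed Integer seed covering initialization, masking, generator
#'   sampling and batch order.
#' @param tokenize_mode SMILES tokenization for compound corpora
#'   (`"char"` or `"atom"`).
#' @param checkpoint_dir Optional directory; a checkpoint is written after
#'   every epoch.
#' @param verbose Print per-epoch losses.
#' @return An `electra_encoder`: list with `config`, `vocab`, `params`,
#'   `kind`, `tokenize_mode` and a per-epoch `log` data.frame.
#' @export
pretrain_electra <- function(corpus, kind = c("compound", "protein"),
                             vocab = NULL, config = NULL, epochs = 10L,
                             batch = 64L, lr = 1e-3, seed = 1L,
                             tokenize_mode = c("char", "atom"),
                             checkpoint_dir = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  tokenize_mode <- match.arg(tokenize_mode)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  tokenized <- lapply(seq_along(corpus), function(i) {
    s <- corpus[[i]]
    if (inherits(s, "token_seq")) s
    else if (kind == "protein") tokenize_protein(s)
    else tokenize_smiles(s, mode = tokenize_mode)
  })
  if (is.null(vocab)) vocab <- build_vocabulary(tokenized, kind)
  if (is.null(config)) config <- encoder_config(vocab$size)
  if (vocab$size != config$vocab_size) {
    stop(sprintf("vocabulary size %d does not match config vocab_size %d",
                 vocab$size, config$vocab_size), call. = FALSE)
  }
  enc <- structure(list(config = config, vocab = vocab, params = NULL,
                        kind = kind, tokenize_mode = tokenize_mode),
                   class = "electra_encoder")
  id_list <- corpus_to_ids(enc, tokenized)
  keep <- lengths(id_list) > 0L
  id_list <- id_list[keep]
  n <- length(id_list)
  log_rows <- vector("list", epochs)
  with_seed(seed, {
    params <- electra_init_params(config)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch)
      tl <- gl <- dl <- 0
      for (s in starts) {
        take <- ord[s:min(s + batch - 1L, n)]
        ids <- pad_id_matrix(id_list[take])
        sel <- matrix(stats::runif(length(ids)) < config$mask_prob,
                      nrow(ids), ncol(ids))
        res <- electra_losses(params, config, ids, sel)
        upd <- adam_step(params, res$grads, state, lr)
        params <- upd$params
        state <- upd$state
        w <- length(take) / n
        tl <- tl + res$loss * w
        gl <- gl + res$loss_gen * w
        dl <- dl + res$loss_disc * w
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = tl, loss_gen = gl,
                                   loss_disc = dl)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f (gen %.4f, disc %.4f)",
                        ep, tl, gl, dl))
      }
      if (!is.null(checkpoint_dir)) {
        enc$params <- params
        enc$log <- do.call(rbind, log_rows[seq_len(ep)])
        save_encoder(enc, checkpoint_dir)
      }
    }
    enc$params <- params
  })
  enc$log <- do.call(rbind, log_rows)
  enc
}

#' @export
print.electra_encoder <- function(x, ...) {
  cat(sprintf(
    "<electra_encoder %s: width %d, %d layers, %d heads, vocab %d%s>\n",
    x$kind, x$config$width, x$config$n_layers, x$config$n_heads,
    x$config$vocab_size,
    if (is.null(x$params)) ", untrained" else ""))
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  pretrained %d epochs; final loss %.4f (gen %.4f, disc %.4f)\n",
                nrow(x$log), last$loss, last$loss_gen, last$loss_disc))
  }
  invisible(x)
}

#' Sample generator predictions at masked positions
#'
#' Runs the generator on a masked sequence and samples one token per
#' selected position from its output distribution (categorical,
#' temperature 1), so the prediction may or may not equal the original
#' token.
#'
#' @param encoder A trained (or freshly initialized) `electra_encoder`.
#' @param ids Zero-based id vector of the original sequence.
#' @param selected Logical vector of positions to fill.
#' @param seed Optional seed for the categorical draw.
#' @return Integer vector of sampled ids, one per selected position.
#' @export
generator_fill <- function(encoder, ids, selected, seed = NULL) {
  stopifnot(inherits(encoder, "electra_encoder"), !is.null(encoder$params))
  ids <- as.integer(ids)
  run <- function() {
    res <- electra_losses(encoder$params, encoder$config,
                          matrix(ids, 1L), matrix(selected, 1L),
                          grads = FALSE)
    res$repl
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Per-position replacement probabilities from the discriminator
#'
#' @param encoder An `electra_encoder` with parameters.
#' @param x A string, `token_seq` or zero-based id vector (length at most
#'   `max_positions`).
#' @return Numeric vector of probabilities in `[0, 1]`, `NA` at padding
#'   positions.
#' @export
discriminate <- function(encoder, x) {
  stopifnot(inherits(encoder, "electra_encoder"), !is.null(encoder$params))
  ids <- encoder_ids(encoder, x)
  if (length(ids) > encoder$config$max_positions) {
    stop(sprintf("sequence length %d exceeds max_positions %d; truncate first",
                 length(ids), encoder$config$max_positions), call. = FALSE)
  }
  res <- electra_losses(encoder$params, encoder$config, matrix(ids, 1L),
                        matrix(FALSE, 1L, length(ids)), repl = integer(0),
                        grads = FALSE)
  p <- res$probs
  p[ids == 0L] <- NA_real_
  p
}

#' Held-out replaced-token-detection AUC
#'
#' Corrupts held-out strings exactly as in pretraining (mask at
#' `mask_prob`, fill with generator samples) and scores the
#' discriminator's ability to rank replaced above untouched positions.
#' An untrained encoder scores about 0.5.
#'
#' @param encoder An `electra_encoder`.
#' @param corpus Character vector of held-out strings.
#' @param mask_prob Masking probability (defaults to the config's).
#' @param seed Seed for masking and generator sampling.
#' @return List with `auc` and `n_positions`.
#' @export
evaluate_rtd <- function(encoder, corpus, mask_prob = NULL, seed = 1L) {
  stopifnot(inherits(encoder, "electra_encoder"), !is.null(encoder$params))
  mask_prob <- mask_prob %||% encoder$config$mask_prob
  id_list <- corpus_to_ids(encoder, corpus)
  id_list <- id_list[lengths(id_list) > 0L]
  with_seed(seed, {
    flags_all <- logical(0)
    probs_all <- numeric(0)
    starts <- seq(1L, length(id_list), by = 64L)
    for (s in starts) {
      take <- s:min(s + 63L, length(id_list))
      ids <- pad_id_matrix(id_list[take])
      sel <- matrix(stats::runif(length(ids)) < mask_prob,
                    nrow(ids), ncol(ids))
      res <- electra_losses(encoder$params, encoder$config, ids, sel,
                            grads = FALSE)
      keep <- !res$pad
      flags_all <- c(flags_all, res$flags[keep])
      probs_all <- c(probs_all, res$probs[keep])
    }
    list(auc = classification_metrics(flags_all, probs_all)$auc,
         n_positions = length(flags_all))
  })
}

#' Save / load an encoder checkpoint directory
#'
#' The checkpoint holds the configuration and vocabulary as JSON, the
#' numeric parameters as an RDS blob, and the training log as CSV.
#' Reloading reproduces forward outputs bit-identically.
#'
#' @param encoder An `electra_encoder`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_encoder`: `dir` invisibly; `load_encoder`: the restored
#'   `electra_encoder`.
#' @export
save_encoder <- function(encoder, dir) {
  stopifnot(inherits(encoder, "electra_encoder"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- encoder$config
  class(meta) <- NULL
  meta$kind <- encoder$kind
  meta$tokenize_mode <- encoder$tokenize_mode
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_vocabulary(encoder$vocab, file.path(dir, "vocab.json"))
  saveRDS(encoder$params, file.path(dir, "params.rds"))
  if (!is.null(encoder$log)) {
    utils::write.csv(encoder$log, file.path(dir, "log.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- encoder_config(meta$vocab_size, meta$width, meta$n_layers,
                           meta$n_heads, meta$max_positions,
                           meta$generator_fraction, meta$mask_prob,
                           meta$ffn_mult, meta$disc_weight)
  enc <- structure(
    list(config = config, vocab = read_vocabulary(file.path(dir, "vocab.json")),
         params = readRDS(file.path(dir, "params.rds")),
         kind = meta$kind, tokenize_mode = meta$tokenize_mode),
    class = "electra_encoder")
  log_path <- file.path(dir, "log.csv")
  if (file.exists(log_path)) enc$log <- utils::read.csv(log_path)
  enc
}
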