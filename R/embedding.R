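# Turning token sequences into fixed-size contextual matrices for the
# affinity model, plus the one-hot ablation encoder.
#
# Orientation: matrices are (positions x dims) throughout the package;
# the field also writes the transposed W x N form -- a pure transpose.

# discriminator-encoder hidden states for a padded id matrix (B x T);
# returns per-layer post-residual states (the states averaged by
# layer_pool = "mean") -- the final layer norm is part of the pretraining
# head only and is not applied to embeddings
encoder_states <- function(encoder, ids) {
  params <- encoder$params
  B <- nrow(ids); T <- ncol(ids)
  ids_vec <- as.vector(t(ids))
  pad <- ids_vec == 0L
  X0 <- params$tok_emb[ids_vec + 1L, , drop = FALSE] +
    params$pos_emb[rep(seq_len(T), B), , drop = FALSE]
  tf_forward(params, "d.", X0, B, T, pad, encoder$config$width,
             encoder$config$n_heads, encoder$config$n_layers)
}

#' Encode a sequence as a fixed-size contextual matrix
#'
#' Runs the (frozen) discriminator encoder over the token sequence and
#' takes, per position, either the arithmetic mean of the hidden states
#' across all transformer layers (`layer_pool = "mean"`, the default) or
#' the last layer's state.  The result is padded/truncated to
#' `(max_len, width)`; rows at padding positions are exactly zero, so the
#' matrix norm does not depend on the amount of trailing padding.  For a
#' one-layer encoder the two pooling strategies coincide.
#'
#' @param encoder A trained `electra_encoder`.
#' @param seq A string, `token_seq`, or zero-based id vector (tokens must
#'   belong to the encoder's vocabulary).
#' @param max_len Output length (e.g. 100 for SMILES, 1000 for proteins
#'   at benchmark scale).
#' @param layer_pool `"mean"` (mean over all layers) or `"last"`.
#' @return A numeric `(max_len, width)` matrix with attribute `kind`.
#' @export
encode_sequence <- function(encoder, seq, max_len,
                            layer_pool = c("mean", "last")) {
  layer_pool <- match.arg(layer_pool)
  stopifnot(inherits(encoder, "electra_encoder"), !is.null(encoder$params))
  ids <- encoder_ids(encoder, seq)
  out <- encode_id_batch(encoder, list(ids), max_len, layer_pool)[[1L]]
  out
}

# batched encoding of a list of id vectors (shared padded length)
encode_id_batch <- function(encoder, id_list, max_len, layer_pool) {
  W <- encoder$config$width
  id_list <- lapply(id_list, function(v) {
    v <- as.integer(v)
    if (length(v) > max_len) v <- v[seq_len(max_len)]
    if (length(v) > encoder$config$max_positions) {
      stop(sprintf("sequence length %d exceeds max_positions %d",
                   length(v), encoder$config$max_positions), call. = FALSE)
    }
    v
  })
  T <- max(lengths(id_list), 1L)
  ids <- do.call(rbind, lapply(id_list, function(v) {
    c(v, rep(0L, T - length(v)))
  }))
  if (all(ids == 0L)) {
    # all-padding batch: zero embeddings by contract
    return(lapply(id_list, function(v) {
      m <- matrix(0, max_len, W)
      attr(m, "kind") <- encoder$kind
      m
    }))
  }
  fw <- encoder_states(encoder, ids)
  E <- if (layer_pool == "mean") {
    Reduce(`+`, fw$states) / length(fw$states)
  } else {
    fw$states[[length(fw$states)]]
  }
  lapply(seq_len(nrow(ids)), function(b) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    m <- matrix(0, max_len, W)
    keep <- which(ids[b, ] != 0L)
    if (length(keep)) m[keep, ] <- E[rows[keep], , drop = FALSE]
    attr(m, "kind") <- encoder$kind
    m
  })
}

#' Encode a set of entities, batched
#'
#' Convenience wrapper embedding many sequences with one encoder; used to
#' precompute per-entity embeddings once before affinity training
#' (entities are reused across many interaction pairs).
#'
#' @param encoder A trained `electra_encoder`.
#' @param entities Named character vector of SMILES or sequences.
#' @param max_len Output length per entity.
#' @param layer_pool See [encode_sequence()].
#' @param batch_size Sequences per forward pass.
#' @return Named list of `(max_len, width)` matrices.
#' @export
encode_entities <- function(encoder, entities, max_len,
                            layer_pool = c("mean", "last"),
                            batch_size = 32L) {
  layer_pool <- match.arg(layer_pool)
  stopifnot(inherits(encoder, "electra_encoder"), !is.null(encoder$params))
  id_list <- lapply(seq_along(entities),
                    function(i) encoder_ids(encoder, entities[[i]]))
  out <- vector("list", length(entities))
  for (s in seq(1L, length(entities), by = batch_size)) {
    take <- s:min(s + batch_size - 1L, length(entities))
    out[take] <- encode_id_batch(encoder, id_list[take], max_len,
                                 layer_pool)
  }
  names(out) <- names(entities)
  out
}

#' One-hot ablation encoder
#'
#' Encodes a token sequence as indicator rows (row `i` is the indicator
#' vector of token `i`, width = vocabulary size); padding rows are
#' all-zero.  This is the ablation baseline that replaces the pretrained
#' contextual embedding.
#'
#' @param seq A `token_seq`, string-free id vector, or character vector of
#'   tokens.
#' @param vocab The `dta_vocabulary` defining ids.
#' @param max_len Output length.
#' @return A numeric `(max_len, vocab$size)` matrix.
#' @export
encode_onehot <- function(seq, vocab, max_len) {
  stopifnot(inherits(vocab, "dta_vocabulary"))
  ids <- if (inherits(seq, "token_seq")) {
    if (!is.null(seq$ids)) seq$ids else encode_tokens(vocab, seq$tokens)
  } else if (is.numeric(seq)) {
    as.integer(seq)
  } else {
    encode_tokens(vocab, as.character(seq))
  }
  if (any(ids < 0L | ids >= vocab$size)) {
    stop("id out of range for vocabulary", call. = FALSE)
  }
  if (length(ids) > max_len) ids <- ids[seq_len(max_len)]
  m <- matrix(0, max_len, vocab$size)
  nonpad <- which(ids != 0L)
  if (length(nonpad)) m[cbind(nonpad, ids[nonpad] + 1L)] <- 1
  m
}
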