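tiny_corpus <- function(n = 10L, seed = 70) {
  spec <- synthetic_spec(corpus_n = n, corpus_length = c(8L, 14L))
  gen_corpus(spec, "compound", seed, n = n)
}

tiny_encoder <- function(corpus = tiny_corpus(), epochs = 1L, seed = 1L,
                         ...) {
  v <- build_vocabulary(lapply(corpus, tokenize_smiles), "compound")
  cfg <- encoder_config(v$size, width = 16L, n_layers = 1L, n_heads = 2L,
                        max_positions = 16L, ...)
  pretrain_electra(corpus, "compound", vocab = v, config = cfg,
                   epochs = epochs, batch = 8L, lr = 1e-3, seed = seed)
}

test_that("masking selects non-pad positions at the requested rate", {
  ids <- c(2L, 3L, 4L, 0L, 0L)
  none <- mask_tokens(ids, 0)
  expect_identical(none$masked_ids, ids)
  expect_false(any(none$selected))
  # mask_prob -> 1: every non-pad position selected
  all_sel <- mask_tokens(rep(5L, 10L), 0.999, seed = 1)
  expect_true(all(all_sel$selected))
  expect_true(all(all_sel$masked_ids == 1L))
  # pad positions are never selected
  m <- mask_tokens(ids, 0.999, seed = 2)
  expect_false(any(m$selected[ids == 0L]))
  expect_error(mask_tokens(ids, 1.2), "mask_prob")
  expect_error(mask_tokens(integer(0), 0.5), "empty")
  # binomial expectation: 1000 seeded draws on 100 tokens at 0.15
  counts <- vapply(1:1000, function(s) {
    sum(mask_tokens(rep(3L, 100L), 0.15, seed = s)$selected)
  }, numeric(1))
  se <- sqrt(0.15 * 0.85 * 100 / 1000)
  expect_lt(abs(mean(counts) - 15), 3 * se)
})

test_that("corruption flags are exactly the elementwise id inequality", {
  ids <- c(2L, 3L, 4L, 5L)
  sel <- c(FALSE, TRUE, TRUE, FALSE)
  # generator sampling the true token yields a FALSE flag
  out <- corrupt_ids(ids, sel, predictions = c(3L, 9L))
  expect_identical(out$corrupted_ids, c(2L, 3L, 9L, 5L))
  expect_identical(out$replaced_flags, out$corrupted_ids != ids)
  none <- corrupt_ids(ids, rep(FALSE, 4), integer(0))
  expect_identical(none$corrupted_ids, ids)
  expect_false(any(none$replaced_flags))
  set.seed(71)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    ids <- sample(2:9, n, replace = TRUE)
    sel <- runif(n) < 0.4
    pred <- sample(2:9, sum(sel), replace = TRUE)
    out <- corrupt_ids(ids, sel, pred)
    expect_identical(out$replaced_flags, out$corrupted_ids != ids)
    expect_identical(out$corrupted_ids[!sel], ids[!sel])
  }
})

test_that("pretraining runs, reproduces with the seed, and reports a descending loss", {
  corp <- tiny_corpus(30)
  e1 <- tiny_encoder(corp, epochs = 3, seed = 5)
  e2 <- tiny_encoder(corp, epochs = 3, seed = 5)
  expect_equal(e1$params, e2$params)
  expect_identical(e1$log, e2$log)
  e3 <- tiny_encoder(corp, epochs = 3, seed = 6)
  expect_false(identical(e1$params, e3$params))
  expect_equal(nrow(e1$log), 3L)
})

test_that("discriminator outputs are probabilities, deterministic, and length-guarded", {
  enc <- tiny_encoder()
  s <- "CC(=O)NC"
  p1 <- discriminate(enc, s)
  p2 <- discriminate(enc, s)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_length(p1, nchar(s))
  expect_error(discriminate(enc, strrep("C", 40)), "max_positions")
})

test_that("an untrained discriminator scores near-chance replaced-token AUC", {
  ns <- asNamespace("dtalearn")
  corp <- tiny_corpus(60, seed = 77)
  enc <- tiny_encoder(corp)        # vocabulary + structure only
  set.seed(8)
  enc$params <- ns$electra_init_params(enc$config)
  r <- evaluate_rtd(enc, corp, mask_prob = 0.3, seed = 3)
  expect_gt(r$n_positions, 400)
  expect_lt(abs(r$auc - 0.5), 0.1)
})

test_that("padding contributes to neither loss", {
  ns <- asNamespace("dtalearn")
  enc <- tiny_encoder()
  cfg <- enc$config
  ids <- matrix(c(2L, 3L, 4L), 1L)
  ids_pad <- matrix(c(2L, 3L, 4L, 0L, 0L, 0L), 1L)
  sel <- matrix(c(FALSE, TRUE, FALSE), 1L)
  sel_pad <- matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE), 1L)
  r1 <- ns$electra_losses(enc$params, cfg, ids, sel, repl = 5L,
                          grads = FALSE)
  r2 <- ns$electra_losses(enc$params, cfg, ids_pad, sel_pad, repl = 5L,
                          grads = FALSE)
  expect_equal(r1$loss, r2$loss, tolerance = 1e-10)
  # hand-computed discriminator loss on the 3-token example
  probs <- r1$probs
  flags <- c(FALSE, TRUE, FALSE)
  bce <- mean(-(flags * log(probs) + (1 - flags) * log(1 - probs)))
  expect_equal(r1$loss_disc, bce, tolerance = 1e-8)
})

test_that("checkpoints reload with bit-identical forward outputs", {
  enc <- tiny_encoder()
  dir <- withr::local_tempdir()
  save_encoder(enc, dir)
  back <- load_encoder(dir)
  expect_identical(back$vocab$tokens, enc$vocab$tokens)
  s <- "CCOC(=O)C"
  expect_identical(discriminate(back, s), discriminate(enc, s))
  expect_identical(encode_sequence(back, s, 12),
                   encode_sequence(enc, s, 12))
})

test_that("generator sampling is seeded and lands on selected positions only", {
  enc <- tiny_encoder()
  ids <- encode_tokens(enc$vocab, tokenize_smiles("CCOCC")$tokens)
  sel <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  p1 <- generator_fill(enc, ids, sel, seed = 4)
  p2 <- generator_fill(enc, ids, sel, seed = 4)
  expect_identical(p1, p2)
  expect_length(p1, 2L)
  expect_true(all(p1 >= 2L))     # specials are never sampled
  out <- corrupt_ids(ids, sel, p1)
  expect_identical(out$corrupted_ids[!sel], ids[!sel])
})
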