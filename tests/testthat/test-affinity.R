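test_that("SE block: identity at unit gate, contraction, hand-computed squeeze", {
  set.seed(91)
  X <- matrix(rnorm(8 * 3), 8, 3)
  forced <- se_block(X, out_channels = 4L, reduction = 2L, seed = 9,
                     gate_override = rep(1, 4))
  expect_equal(forced$output, forced$U)
  free <- se_block(X, out_channels = 4L, reduction = 2L,
                   params = forced$params)
  expect_true(all(free$gate >= 0 & free$gate <= 1))
  expect_true(all(abs(free$output) <= abs(free$U) + 1e-12))
  # squeeze descriptor on a tiny 4 x 2 map equals explicit channel means
  tiny <- se_block(matrix(rnorm(4 * 2), 4, 2), out_channels = 2L,
                   reduction = 1L, seed = 10)
  expect_equal(tiny$descriptor,
               c(mean(tiny$U[, 1]), mean(tiny$U[, 2])), tolerance = 1e-12)
  expect_error(se_block(matrix(c(1, NA, 2, 3), 2), 2L), "non-finite")
})

test_that("highway layer: pure carry at gate 0, pure transform at gate 1, closed form", {
  set.seed(92)
  x <- rnorm(6)
  carry <- highway_layer(x, seed = 3, gate_override = 0)
  expect_equal(carry$y, x)
  transform <- highway_layer(x, seed = 3, gate_override = 1)
  expect_equal(transform$y, transform$transform)
  # explicit formula with known weights
  hw <- highway_layer(x, params = carry$params)
  tg <- 1 / (1 + exp(-(as.vector(x %*% carry$params$Wt) +
                         carry$params$bt)))
  h <- pmax(as.vector(x %*% carry$params$Wh) + carry$params$bh, 0)
  expect_equal(hw$y, tg * h + (1 - tg) * x, tolerance = 1e-6)
})

test_that("global max pooling matches the explicit per-channel maximum", {
  set.seed(93)
  U <- matrix(rnorm(7 * 4), 7, 4)
  expect_equal(global_max_pool(U),
               c(max(U[, 1]), max(U[, 2]), max(U[, 3]), max(U[, 4])))
})

mini_setup <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      spec <- synthetic_spec(n_compounds = 12L, n_proteins = 6L,
                             n_families = 2L,
                             protein_length = c(20L, 30L),
                             smiles_atoms = c(5L, 10L))
      ds <- gen_dataset(spec, seed = 94)
      ctoks <- lapply(ds$compounds, tokenize_smiles)
      ptoks <- lapply(ds$proteins, tokenize_protein)
      cvoc <- build_vocabulary(ctoks, "compound")
      pvoc <- build_vocabulary(ptoks, "protein")
      Ec <- lapply(ctoks, encode_onehot, vocab = cvoc, max_len = 20L)
      Ep <- lapply(ptoks, encode_onehot, vocab = pvoc, max_len = 36L)
      names(Ec) <- names(ds$compounds)
      names(Ep) <- names(ds$proteins)
      cfg <- dta_config(cvoc$size, pvoc$size, 20L, 36L,
                        preset = "miniature", conv_channels = c(8L, 12L),
                        fc_sizes = c(16L, 1L), epochs = 3L, batch = 16L)
      env <<- list(ds = ds, Ec = Ec, Ep = Ep, cfg = cfg)
    }
    env
  }
})

test_that("feature extraction returns the contracted vector and rejects bad shapes", {
  m <- mini_setup()
  fit <- dta_train(m$ds$interactions, m$Ec, m$Ep, m$cfg, val = 0.2,
                   seed = 1)
  v <- feature_extract(m$Ec[[1L]], fit, branch = "compound")
  expect_length(v, m$cfg$conv_channels[2L])
  expect_true(all(is.finite(v)))
  expect_error(feature_extract(matrix(0, 5, 5), fit, "compound"),
               "matrix")
})

test_that("training is seed-reproducible and prediction deterministic in eval mode", {
  m <- mini_setup()
  f1 <- dta_train(m$ds$interactions, m$Ec, m$Ep, m$cfg, val = 0.2,
                  seed = 42)
  f2 <- dta_train(m$ds$interactions, m$Ec, m$Ep, m$cfg, val = 0.2,
                  seed = 42)
  expect_equal(f1$log, f2$log)
  expect_equal(f1$params, f2$params)
  p1 <- predict(f1, m$ds$interactions[1:10, ], m$Ec, m$Ep)
  p2 <- predict(f1, m$ds$interactions[1:10, ], m$Ec, m$Ep)
  expect_identical(p1, p2)
})

test_that("batch prediction equals per-item prediction", {
  m <- mini_setup()
  fit <- dta_train(m$ds$interactions, m$Ec, m$Ep, m$cfg, val = 0.2,
                   seed = 7)
  pairs <- m$ds$interactions[1:9, ]
  batched <- predict(fit, pairs, m$Ec, m$Ep, batch = 9L)
  singles <- vapply(1:9, function(i) {
    predict(fit, pairs[i, , drop = FALSE], m$Ec, m$Ep)
  }, numeric(1))
  expect_equal(batched, singles, tolerance = 1e-5)
})

test_that("a zero learning rate freezes the parameters across epochs", {
  m <- mini_setup()
  cfg0 <- m$cfg
  cfg0$lr <- 0
  cfg0$dropout <- 0
  cfg0$epochs <- 2L
  fit <- dta_train(m$ds$interactions, m$Ec, m$Ep, cfg0, val = 0.2,
                   seed = 3)
  # params never move, so both epochs see the identical loss surface
  expect_equal(fit$log$train_loss[1L], fit$log$train_loss[2L],
               tolerance = 1e-12)
  expect_equal(fit$log$val_loss[1L], fit$log$val_loss[2L],
               tolerance = 1e-12)
})

test_that("training validates its inputs", {
  m <- mini_setup()
  bad <- m$ds$interactions
  bad$affinity <- bad$affinity[1L]
  expect_error(dta_train(bad, m$Ec, m$Ep, m$cfg), "identical")
  expect_error(dta_train(m$ds$interactions[0, ], m$Ec, m$Ep, m$cfg),
               "nrow")
  missing <- m$Ec[-1L]
  expect_error(dta_train(m$ds$interactions, missing, m$Ep, m$cfg),
               "missing embeddings")
})

test_that("classification mode yields probabilities and honours labels", {
  m <- mini_setup()
  cfgc <- m$cfg
  cfgc$task <- "classification"
  pairs <- m$ds$interactions
  pairs$affinity <- as.numeric(pairs$affinity >=
                                 stats::median(pairs$affinity))
  fit <- dta_train(pairs, m$Ec, m$Ep, cfgc, val = 0.2, seed = 5)
  p <- predict(fit, pairs[1:12, ], m$Ec, m$Ep)
  expect_true(all(p > 0 & p < 1))
})

test_that("permuting all-pad rows leaves branch features unchanged", {
  m <- mini_setup()
  fit <- dta_train(m$ds$interactions, m$Ec, m$Ep, m$cfg, val = 0.2,
                   seed = 9)
  lens <- vapply(m$Ec, function(E) sum(rowSums(abs(E)) > 0), numeric(1))
  E <- m$Ec[[which.min(lens)]]          # entity with the most padding
  n_real <- min(lens)
  perm <- c(seq_len(n_real), rev((n_real + 1):nrow(E)))
  expect_equal(feature_extract(E[perm, ], fit, "compound"),
               feature_extract(E, fit, "compound"), tolerance = 1e-12)
})
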