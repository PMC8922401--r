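test_that("generators are pure functions of spec and seed", {
  spec <- synthetic_spec(n_compounds = 8L, n_proteins = 6L,
                         n_families = 2L, corpus_n = 20L)
  expect_identical(gen_proteins(spec, 3), gen_proteins(spec, 3))
  expect_identical(gen_smiles(spec, 3), gen_smiles(spec, 3))
  expect_identical(gen_corpus(spec, "compound", 3),
                   gen_corpus(spec, "compound", 3))
  p <- gen_proteins(spec, 3)
  s <- gen_smiles(spec, 3)
  expect_identical(gen_affinities(s, p, spec, 3),
                   gen_affinities(s, p, spec, 3))
  expect_false(identical(gen_proteins(spec, 3), gen_proteins(spec, 4)))
})

test_that("zero mutation rate collapses families to identical sequences", {
  spec <- synthetic_spec(n_proteins = 6L, n_families = 2L,
                         mutation_rate = 0)
  p <- gen_proteins(spec, 5)
  fam <- attr(p, "family")
  for (f in unique(fam)) {
    members <- p[fam == f]
    expect_true(all(members == members[1L]))
    expect_equal(protein_distance(members[1L], members[2L]), 0)
  }
})

test_that("within-family distances are smaller than between-family distances", {
  spec <- synthetic_spec(n_proteins = 30L, n_families = 5L,
                         mutation_rate = 0.05)
  p <- gen_proteins(spec, 8)
  fam <- attr(p, "family")
  d <- distance_matrix(stats::setNames(as.character(p), names(p)),
                       "protein")
  same <- outer(fam, fam, "==") & upper.tri(d)
  diff <- outer(fam, fam, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
  expect_lt(max(d[same]), min(d[diff]))   # clean cluster separation
})

test_that("generated SMILES are grammar-balanced and fingerprintable", {
  spec <- synthetic_spec(n_compounds = 120L)
  sm <- gen_smiles(spec, 12)
  for (s in sm) {
    chars <- strsplit(s, "")[[1L]]
    expect_equal(sum(chars == "("), sum(chars == ")"))
    digits <- chars[chars %in% as.character(1:9)]
    if (length(digits)) {
      expect_true(all(table(digits) %% 2 == 0))
    }
  }
  fps <- lapply(seq_along(sm),
                function(i) morgan_fingerprint(sm[[i]], id = names(sm)[i]))
  expect_true(all(lengths(fps) > 0L))
})

test_that("planted affinities take exactly two values when noiseless with one weight", {
  spec <- synthetic_spec(n_compounds = 20L, n_proteins = 8L,
                         n_families = 2L, motifs = "WYWKH",
                         substructures = "C(=O)O", weights = 2,
                         noise_sd = 0)
  pr <- gen_proteins(spec, 21)
  sm <- gen_smiles(spec, 21)
  tab <- gen_affinities(sm, pr, spec, 21)
  vals <- sort(unique(tab$affinity))
  expect_lte(length(vals), 2L)
  expect_true(all(vals %in% c(spec$baseline, spec$baseline + 2)))
})

test_that("injected duplicates and conflicts are exactly what refine reports", {
  spec <- synthetic_spec(n_compounds = 12L, n_proteins = 5L,
                         n_families = 2L, n_duplicates = 7L,
                         n_conflicts = 4L)
  ds <- gen_dataset(spec, 33)
  rep <- refinement_report(refine_dataset(ds))
  expect_equal(rep$n_duplicate_keys, 7L)
  expect_equal(rep$n_conflict_keys, 4L)
  expect_equal(rep$n_records_in - rep$n_records_out,
               7L + 2L * 4L)   # dup keys lose 1 record, conflict keys 2
})

test_that("the corpus follows its 3-gram grammar better than a unigram fit", {
  spec <- synthetic_spec(corpus_n = 300L)
  corp <- gen_corpus(spec, "compound", 7)
  expect_length(corp, 300L)
  g <- attr(corp, "grammar")
  A <- length(g$alphabet)
  train <- corp[1:200]
  held <- corp[201:300]
  # unigram fit on the training lines
  counts <- table(factor(unlist(strsplit(train, "")),
                         levels = g$alphabet)) + 1
  uni <- counts / sum(counts)
  nll_uni <- 0; nll_tri <- 0; n_tok <- 0
  for (s in held) {
    ids <- match(strsplit(s, "")[[1L]], g$alphabet)
    for (t in seq_along(ids)) {
      nll_uni <- nll_uni - log(uni[ids[t]])
      if (t >= 3) {
        ctx <- (ids[t - 2L] - 1L) * A + ids[t - 1L]
        k <- match(ids[t], g$successors[ctx, ])
        nll_tri <- nll_tri - log(g$probs[k])
      } else {
        nll_tri <- nll_tri - log(1 / A)
      }
      n_tok <- n_tok + 1
    }
  }
  expect_lt(exp(nll_tri / n_tok), exp(nll_uni / n_tok))
})

test_that("protein-kind corpora draw from the residue alphabet", {
  spec <- synthetic_spec(corpus_n = 30L)
  corp <- gen_corpus(spec, "protein", 4)
  expect_true(all(vapply(corp, function(s) {
    length(tokenize_protein(s)$tokens) == nchar(s)
  }, logical(1))))
})
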