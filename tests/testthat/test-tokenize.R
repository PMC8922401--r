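test_that("char-mode SMILES tokenization splits every character", {
  expect_identical(tokenize_smiles("CC(=)OC1=C", mode = "char")$tokens,
                   c("C", "C", "(", "=", ")", "O", "C", "1", "=", "C"))
  expect_identical(tokenize_smiles("", mode = "char")$tokens, character(0))
  expect_identical(tokenize_smiles("", mode = "atom")$tokens, character(0))
})

test_that("atom-mode tokenization emits multi-character atoms as single tokens", {
  expect_identical(tokenize_smiles("ClCBr", mode = "atom")$tokens,
                   c("Cl", "C", "Br"))
  expect_identical(tokenize_smiles("C[nH]1cc1", mode = "atom")$tokens,
                   c("C", "[nH]", "1", "c", "c", "1"))
  expect_identical(tokenize_smiles("CSi(F)Se", mode = "atom")$tokens,
                   c("C", "Si", "(", "F", ")", "Se"))
  expect_error(tokenize_smiles("CC[nH", mode = "atom"), "offset 3")
})

test_that("tokenization is lossless: concatenation reproduces the input", {
  set.seed(101)
  alphabet <- c("C", "N", "O", "S", "F", "l", "B", "r", "c", "n", "1",
                "2", "3", "(", ")", "=", "#", "[", "]", "H", "+", "-")
  for (i in 1:50) {
    s <- paste(sample(alphabet, sample(1:30, 1), replace = TRUE),
               collapse = "")
    expect_identical(paste(tokenize_smiles(s, "char")$tokens,
                           collapse = ""), s)
    atom <- tryCatch(tokenize_smiles(s, "atom"), error = function(e) NULL)
    if (!is.null(atom)) {
      expect_identical(paste(atom$tokens, collapse = ""), s)
    }
  }
})

test_that("protein tokenization is 1-mer with case folding and strict alphabet", {
  expect_identical(tokenize_protein("MKV")$tokens, c("M", "K", "V"))
  expect_identical(tokenize_protein("mkv")$tokens, c("M", "K", "V"))
  expect_identical(tokenize_protein("")$tokens, character(0))
  expect_error(tokenize_protein("MK*V"), "'\\*' at position 3")
  expect_error(tokenize_protein("M2V"), "position 2")
})

test_that("vocabulary construction is deterministic, order-independent and complete", {
  s1 <- tokenize_smiles("CN")
  s2 <- tokenize_smiles("NO")
  v <- build_vocabulary(list(s1, s2), "compound")
  expect_identical(v$tokens, c("<PAD>", "<MASK>", "C", "N", "O"))
  expect_equal(v$size, 5L)
  expect_identical(encode_tokens(v, "<PAD>"), 0L)
  expect_identical(encode_tokens(v, "<MASK>"), 1L)
  # single-sequence corpus
  v1 <- build_vocabulary(list(tokenize_smiles("CC")), "compound")
  expect_equal(v1$size, 3L)
  # shuffling the corpus changes nothing
  v_rev <- build_vocabulary(list(s2, s1), "compound")
  expect_identical(v, v_rev)
  # set-union oracle on random corpora
  set.seed(5)
  for (i in 1:10) {
    strs <- replicate(5, paste(sample(LETTERS[1:6], 8, replace = TRUE),
                               collapse = ""))
    corp <- lapply(strs, tokenize_protein)
    v <- build_vocabulary(corp, "protein")
    expect_setequal(setdiff(v$tokens, c("<PAD>", "<MASK>")),
                    unique(unlist(strsplit(strs, ""))))
  }
  expect_error(build_vocabulary(list(), "compound"), "empty")
  expect_error(encode_tokens(v, "zz"), "not in vocabulary")
})

test_that("pad_or_truncate gives exact lengths and is idempotent", {
  v <- build_vocabulary(list(tokenize_smiles("CNO")), "compound")
  s <- tokenize_smiles("CC", vocab = v)
  p <- pad_or_truncate(s, 4)
  expect_identical(p$tokens, c("C", "C", "<PAD>", "<PAD>"))
  expect_identical(p$ids, c(2L, 2L, 0L, 0L))
  long <- tokenize_smiles(strrep("C", 120), vocab = v)
  expect_length(pad_or_truncate(long, 100)$tokens, 100L)
  expect_identical(pad_or_truncate(long, 100)$tokens,
                   long$tokens[1:100])
  # identity at own length, idempotence at fixed max_len
  expect_identical(pad_or_truncate(s, 2), s)
  expect_identical(pad_or_truncate(p, 4), p)
})

test_that("corpus statistics match an independent recount", {
  corp <- list(tokenize_smiles("CC"), tokenize_smiles("CNCO"))
  st <- corpus_stats(corp)
  expect_equal(st$mean_length, 3)
  expect_equal(st$min_length, 2)
  expect_equal(st$n_sequences, 2)
  one <- corpus_stats(list(tokenize_protein("MKVLAWY")))
  expect_equal(one$mean_length, 7)
  expect_equal(one$min_length, 7)
  # random corpus vs hand recount
  set.seed(11)
  strs <- replicate(100, paste(sample(c("C", "N", "O", "(", ")", "="),
                                      sample(2:20, 1), replace = TRUE),
                               collapse = ""))
  corp <- lapply(strs, tokenize_smiles)
  st <- corpus_stats(corp)
  lens <- nchar(strs)
  expect_equal(st$mean_length, mean(lens))
  expect_equal(st$min_length, min(lens))
  expect_equal(st$vocab_size, length(unique(unlist(strsplit(strs, "")))))
  expect_error(corpus_stats(list()), "empty")
})
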