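# Independent oracles used across the suite.  These are deliberately
# naive transcriptions (double loops, explicit set arithmetic, textbook
# dynamic programming) kept separate from the package's implementations.

# O(n^2) brute-force concordance index
ci_oracle <- function(y, b) {
  num <- 0
  Z <- 0
  n <- length(y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y[i] > y[j]) {
        Z <- Z + 1
        d <- b[i] - b[j]
        num <- num + (d > 0) + 0.5 * (d == 0)
      }
    }
  }
  num / Z
}

# Mann-Whitney pair-count AUC (ties count half)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive all-cutpoints precision-recall area (step-wise summation)
pr_oracle <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  area <- 0
  prev_rec <- 0
  for (th in ths) {
    predset <- scores >= th
    tp <- sum(labels[predset])
    prec <- tp / sum(predset)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# textbook Gotoh local alignment (affine gaps; a gap of length L costs
# open + L * ext, matching the package's alignment configuration)
sw_oracle <- function(a, b, mat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# connected components of the strict-threshold graph via transitive
# closure of the adjacency matrix (independent of the union-find code)
components_oracle <- function(d, threshold) {
  adj <- (d < threshold) | diag(nrow(d)) == 1
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                 "Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

# small fully assembled synthetic dataset for split/refine tests
make_test_dataset <- function(seed = 1, ...) {
  spec <- synthetic_spec(...)
  gen_dataset(spec, seed)
}
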