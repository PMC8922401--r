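# Seeded synthetic-data generators: protein families with planted motifs,
# grammar-valid SMILES with planted substructures, planted-signal affinity
# tables, and 3-gram-grammar pretraining corpora.  Everything is a pure
# function of (spec, seed), so fixtures are rebuilt identically at test
# time and nothing is shipped on disk.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic drug-target affinity study
#'
#' Collects the knobs of the synthetic generators.  The defaults define a
#' desk-scale study: 100 compounds by 20 proteins (2000 interaction pairs),
#' proteins in 5 sequence families produced by mutating family ancestors,
#' and affinities driven by three planted motif-substructure interactions
#' plus Gaussian noise.
#'
#' @param n_compounds,n_proteins Entity counts.
#' @param n_families Number of protein families; family members share an
#'   ancestor and hence small normalized alignment distances.
#' @param protein_length Length range of family ancestors.
#' @param mutation_rate Per-residue substitution probability applied to
#'   each family member.
#' @param smiles_atoms Range of backbone atom counts per generated SMILES.
#' @param motifs Protein k-mers planted per family (guaranteed present in
#'   every member of a carrying family).
#' @param substructures SMILES fragments appended to carrying compounds.
#' @param weights Affinity contribution of each motif x substructure
#'   interaction.
#' @param baseline Affinity intercept (pKd-like scale).
#' @param noise_sd Gaussian noise standard deviation on affinities.
#' @param n_duplicates,n_conflicts Numbers of exact-duplicate and
#'   conflicting-label records injected into the interaction table (to
#'   exercise [refine_dataset()]).
#' @param corpus_n,corpus_length Pretraining corpus size and string-length
#'   range for [gen_corpus()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 100L, n_proteins = 20L,
                           n_families = 5L,
                           protein_length = c(50L, 80L),
                           mutation_rate = 0.05,
                           smiles_atoms = c(8L, 25L),
                           motifs = c("WYWKH", "DDFGE", "HHCCY"),
                           substructures = c("C(=O)O", "C#N", "S(=O)C"),
                           weights = c(1.5, 1.2, 1.0),
                           baseline = 5, noise_sd = 0.3,
                           n_duplicates = 0L, n_conflicts = 0L,
                           corpus_n = 2000L, corpus_length = c(20L, 40L)) {
  stopifnot(n_compounds >= 1L, n_proteins >= 1L, n_families >= 1L,
            noise_sd >= 0, length(motifs) == length(substructures),
            length(weights) == length(motifs))
  structure(list(n_compounds = n_compounds, n_proteins = n_proteins,
                 n_families = n_families, protein_length = protein_length,
                 mutation_rate = mutation_rate, smiles_atoms = smiles_atoms,
                 motifs = motifs, substructures = substructures,
                 weights = weights, baseline = baseline,
                 noise_sd = noise_sd, n_duplicates = n_duplicates,
                 n_conflicts = n_conflicts, corpus_n = corpus_n,
                 corpus_length = corpus_length),
            class = "synthetic_spec")
}

#' Generate family-structured protein sequences
#'
#' Draws `n_families` random ancestors, derives members by per-residue
#' substitution at `mutation_rate`, and embeds each planted motif carried
#' by the family into every member at a random position.  Within-family
#' normalized alignment distances are therefore small and between-family
#' distances large, giving the cold-split machinery real cluster structure.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return Named character vector of sequences (`protein1`, ...) with
#'   attributes `family` (integer vector) and `has_motif` (protein x motif
#'   logical matrix as realised in the sequences).
#' @export
gen_proteins <- function(spec, seed = 1L) {
  with_seed(seed, {
    per_family <- ceiling(spec$n_proteins / spec$n_families)
    # which families carry which motifs
    carries <- matrix(stats::runif(spec$n_families * length(spec$motifs)) < 0.5,
                      spec$n_families, length(spec$motifs))
    seqs <- character(0)
    family <- integer(0)
    for (f in seq_len(spec$n_families)) {
      len <- sample(spec$protein_length[1L]:spec$protein_length[2L], 1L)
      ancestor <- sample(AMINO_ACIDS, len, replace = TRUE)
      # family-fixed motif positions (one per non-overlapping block), so
      # members of a family stay alignable; motifs are re-imposed after
      # mutation so their presence is guaranteed in every carrier
      n_mot <- length(spec$motifs)
      block <- len %/% max(n_mot, 1L)
      motif_pos <- vapply(seq_len(n_mot), function(k) {
        lo <- (k - 1L) * block + 1L
        hi <- min(k * block, len) - nchar(spec$motifs[k])
        sample(lo:max(hi, lo), 1L)
      }, integer(1))
      for (m in seq_len(per_family)) {
        if (length(seqs) >= spec$n_proteins) break
        member <- ancestor
        mut <- stats::runif(len) < spec$mutation_rate
        member[mut] <- sample(AMINO_ACIDS, sum(mut), replace = TRUE)
        for (k in seq_len(n_mot)) {
          if (!carries[f, k]) next
          motif <- strsplit(spec$motifs[k], "")[[1L]]
          member[motif_pos[k]:(motif_pos[k] + length(motif) - 1L)] <- motif
        }
        seqs <- c(seqs, paste(member, collapse = ""))
        family <- c(family, f)
      }
    }
    names(seqs) <- sprintf("protein%d", seq_along(seqs))
    has <- sapply(spec$motifs, function(m) grepl(m, seqs, fixed = TRUE))
    attr(seqs, "family") <- family
    attr(seqs, "has_motif") <- matrix(has, nrow = length(seqs),
                                      dimnames = list(names(seqs),
                                                      spec$motifs))
    seqs
  })
}

# one grammar-valid SMILES string: chains, branches, paired ring closures
random_smiles <- function(n_atoms) {
  atoms <- c("C", "C", "C", "C", "N", "O", "S", "F", "Cl", "Br")
  out <- character(0)
  open_ring <- integer(0)
  next_digit <- 1L
  depth <- 0L
  atoms_left <- n_atoms
  emitted <- 0L
  while (atoms_left > 0L) {
    if (emitted > 0L && stats::runif(1) < 0.10) out <- c(out, "=")
    out <- c(out, sample(atoms, 1L))
    emitted <- emitted + 1L
    atoms_left <- atoms_left - 1L
    # maybe open a ring at this atom
    if (next_digit <= 9L && length(open_ring) == 0L &&
        atoms_left > 2L && stats::runif(1) < 0.15) {
      out <- c(out, as.character(next_digit))
      open_ring <- c(open_ring, next_digit)
      next_digit <- next_digit + 1L
    } else if (length(open_ring) && stats::runif(1) < 0.25) {
      out <- c(out, as.character(open_ring[1L]))
      open_ring <- open_ring[-1L]
    }
    # branches
    if (depth > 0L && stats::runif(1) < 0.30) {
      out <- c(out, ")")
      depth <- depth - 1L
    }
    if (atoms_left > 1L && depth < 3L && stats::runif(1) < 0.15) {
      out <- c(out, "(")
      depth <- depth + 1L
    }
  }
  while (depth > 0L) {           # a '(' must not be empty: pad with C
    out <- c(out, "C", ")")
    depth <- depth - 1L
  }
  if (length(open_ring)) {       # close pending rings on a final atom
    out <- c(out, "C", as.character(open_ring))
  }
  paste(out, collapse = "")
}

#' Generate grammar-valid SMILES strings
#'
#' Stochastic chains with branches and paired ring closures over
#' `{C, N, O, S, F, Cl, Br}`.  Planted substructure fragments from the
#' spec are appended to a random half of the compounds.  Strings are
#' syntactically balanced (paired parentheses, paired ring digits) and
#' parseable by [parse_smiles()], but no chemical valence is enforced.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return Named character vector of SMILES (`compound1`, ...) with
#'   attribute `has_substructure` (compound x fragment logical matrix as
#'   realised in the strings).
#' @export
gen_smiles <- function(spec, seed = 1L) {
  with_seed(seed + 1000L, {
    # backbone length is shortened to offset planted fragments, so the
    # total string length is (near-)independent of fragment presence --
    # otherwise sequence length alone would leak the planted signal
    frag_cost <- round(nchar(spec$substructures) / 1.5)
    smiles <- vapply(seq_len(spec$n_compounds), function(i) {
      carry <- stats::runif(length(spec$substructures)) < 0.5
      n_atoms <- sample(spec$smiles_atoms[1L]:spec$smiles_atoms[2L], 1L)
      n_backbone <- max(3L, n_atoms - sum(frag_cost[carry]))
      s <- random_smiles(n_backbone)
      paste0(s, paste(spec$substructures[carry], collapse = ""))
    }, character(1))
    names(smiles) <- sprintf("compound%d", seq_along(smiles))
    has <- sapply(spec$substructures,
                  function(x) grepl(x, smiles, fixed = TRUE))
    attr(smiles, "has_substructure") <-
      matrix(has, nrow = length(smiles),
             dimnames = list(names(smiles), spec$substructures))
    smiles
  })
}

#' Generate a planted-signal affinity table
#'
#' For every compound-protein pair, the affinity is
#' `baseline + sum_k weight_k * substructure_k(compound) * motif_k(protein)
#' + N(0, noise_sd)`: an interaction term fires only when the compound
#' carries fragment `k` and the protein carries motif `k`.  A capable model
#' can therefore recover the planted signal from the sequences alone.
#' Optionally injects exact-duplicate and conflicting-label records on
#' disjoint pair keys (counts from the spec) to exercise refinement.
#'
#' @param compounds Named SMILES vector (from [gen_smiles()]).
#' @param proteins Named sequence vector (from [gen_proteins()]).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return Data.frame `compound_id`, `protein_id`, `affinity`, with
#'   attribute `injection` = list(n_duplicates, n_conflicts).
#' @export
gen_affinities <- function(compounds, proteins, spec, seed = 1L) {
  with_seed(seed + 2000L, {
    sub <- sapply(spec$substructures,
                  function(x) grepl(x, compounds, fixed = TRUE))
    mot <- sapply(spec$motifs, function(m) grepl(m, proteins, fixed = TRUE))
    sub <- matrix(sub, nrow = length(compounds))
    mot <- matrix(mot, nrow = length(proteins))
    signal <- sub %*% diag(spec$weights, length(spec$weights)) %*% t(mot)
    grid <- expand.grid(ci = seq_along(compounds), pi = seq_along(proteins))
    aff <- spec$baseline + signal[cbind(grid$ci, grid$pi)] +
      stats::rnorm(nrow(grid), sd = spec$noise_sd)
    tab <- data.frame(compound_id = names(compounds)[grid$ci],
                      protein_id = names(proteins)[grid$pi],
                      affinity = aff, stringsAsFactors = FALSE)
    n_inj <- spec$n_duplicates + spec$n_conflicts
    if (n_inj > 0L) {
      pick <- sample.int(nrow(tab), n_inj)
      dup <- pick[seq_len(spec$n_duplicates)]
      conf <- pick[spec$n_duplicates + seq_len(spec$n_conflicts)]
      extra <- tab[c(dup, conf), , drop = FALSE]
      if (length(conf)) {
        shift <- seq_len(spec$n_conflicts)
        extra$affinity[spec$n_duplicates + shift] <-
          extra$affinity[spec$n_duplicates + shift] + 1
      }
      tab <- rbind(tab, extra)
      rownames(tab) <- NULL
    }
    attr(tab, "injection") <- list(n_duplicates = spec$n_duplicates,
                                   n_conflicts = spec$n_conflicts)
    tab
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: [gen_proteins()] + [gen_smiles()] +
#' [gen_affinities()] assembled into a [dta_dataset()].
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `dta_dataset`.
#' @export
gen_dataset <- function(spec, seed = 1L) {
  proteins <- gen_proteins(spec, seed)
  compounds <- gen_smiles(spec, seed)
  tab <- gen_affinities(compounds, proteins, spec, seed)
  ds <- dta_dataset(as.character(compounds) |> stats::setNames(names(compounds)),
                    as.character(proteins) |> stats::setNames(names(proteins)),
                    tab)
  attr(ds, "protein_family") <- attr(proteins, "family")
  ds
}

#' Generate a 3-gram-grammar pretraining corpus
#'
#' Builds a fixed sparse 3-gram grammar over a small token alphabet (each
#' context `(t1, t2)` allows three successors with probabilities 0.6, 0.3,
#' 0.1) and samples one string per line from it.  Replaced-token detection
#' is learnable on such a corpus because random replacements break the
#' 3-gram structure, while a unigram model cannot capture it.
#'
#' @param spec A [synthetic_spec()] (uses `corpus_n`, `corpus_length`).
#' @param kind `"compound"` (SMILES-like alphabet) or `"protein"`
#'   (residue alphabet).
#' @param seed Integer seed (fixes both the grammar and the sample).
#' @param n Number of strings (default `spec$corpus_n`).
#' @return Character vector of strings with attribute `grammar` = list
#'   (`alphabet`, `successors` (A^2 x 3 index matrix), `probs`).
#' @export
gen_corpus <- function(spec, kind = c("compound", "protein"), seed = 1L,
                       n = NULL) {
  kind <- match.arg(kind)
  n <- n %||% spec$corpus_n
  alphabet <- if (kind == "compound") {
    c("C", "N", "O", "S", "F", "c", "n", "o", "1", "2", "(", ")", "=", "#")
  } else {
    AMINO_ACIDS
  }
  A <- length(alphabet)
  probs <- c(0.6, 0.3, 0.1)
  with_seed(seed + 3000L, {
    successors <- t(vapply(seq_len(A * A), function(i) {
      sample.int(A, 3L)
    }, integer(3)))
    lens <- sample(spec$corpus_length[1L]:spec$corpus_length[2L], n,
                   replace = TRUE)
    strings <- vapply(lens, function(len) {
      ids <- integer(len)
      ids[1L] <- sample.int(A, 1L)
      if (len >= 2L) ids[2L] <- sample.int(A, 1L)
      if (len >= 3L) {
        for (t in 3:len) {
          ctx <- (ids[t - 2L] - 1L) * A + ids[t - 1L]
          ids[t] <- sample(successors[ctx, ], 1L, prob = probs)
        }
      }
      paste(alphabet[ids], collapse = "")
    }, character(1))
    attr(strings, "grammar") <- list(alphabet = alphabet,
                                     successors = successors,
                                     probs = probs)
    strings
  })
}
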