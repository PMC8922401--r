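# Morgan-style circular fingerprints over a minimal SMILES molecular graph.
#
# The parser covers the lexical subset the package generates and the common
# organic subset: one/two-letter element symbols, aromatic lowercase atoms,
# bracket atoms, bond symbols - = # : / \, branches, dot disconnections and
# single-digit ring closures.  No valence or aromaticity perception is done;
# the graph is purely structural, which is sufficient for substructure
# fingerprinting.

AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")

# deterministic 31-bit mixing hash of an integer vector
hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

element_code <- function(element) {
  chars <- utf8ToInt(element)
  sum(chars * 256L^(seq_along(chars) - 1L)) %% 2147483647
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A SMILES string.
#' @param id Optional compound id used in error messages.
#' @return A list with `atoms` (data.frame: element, aromatic) and `bonds`
#'   (data.frame: from, to, order).
#' @export
parse_smiles <- function(smiles, id = NULL) {
  label <- if (is.null(id)) sprintf("'%s'", smiles) else sprintf("'%s'", id)
  fail <- function(msg) {
    stop(sprintf("cannot parse SMILES for compound %s: %s", label, msg),
         call. = FALSE)
  }
  toks <- tryCatch(tokenize_smiles(smiles, mode = "atom")$tokens,
                   error = function(e) fail(conditionMessage(e)))
  elements <- character(0)
  aromatic <- logical(0)
  bonds_from <- integer(0)
  bonds_to <- integer(0)
  bonds_order <- numeric(0)
  prev <- NA_integer_
  pending <- NA_real_
  stack <- integer(0)
  ring_open <- list()

  add_atom <- function(element, arom) {
    elements[length(elements) + 1L] <<- element
    aromatic[length(aromatic) + 1L] <<- arom
    cur <- length(elements)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending
             else if (arom && aromatic[prev]) 1.5 else 1
      bonds_from <<- c(bonds_from, prev)
      bonds_to <<- c(bonds_to, cur)
      bonds_order <<- c(bonds_order, ord)
    }
    pending <<- NA_real_
    prev <<- cur
  }

  for (tok in toks) {
    if (tok %in% c("-", "/", "\\")) {
      pending <- 1
    } else if (tok == "=") {
      pending <- 2
    } else if (tok == "#") {
      pending <- 3
    } else if (tok == ":") {
      pending <- 1.5
    } else if (tok == "(") {
      if (is.na(prev)) fail("branch opened before any atom")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) fail("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending <- NA_real_
    } else if (grepl("^[0-9]$", tok)) {
      if (is.na(prev)) fail("ring closure digit before any atom")
      if (is.null(ring_open[[tok]])) {
        ring_open[[tok]] <- list(atom = prev, order = pending)
      } else {
        opened <- ring_open[[tok]]
        ord <- if (!is.na(pending)) pending
               else if (!is.na(opened$order)) opened$order
               else if (aromatic[prev] && aromatic[opened$atom]) 1.5 else 1
        bonds_from <- c(bonds_from, opened$atom)
        bonds_to <- c(bonds_to, prev)
        bonds_order <- c(bonds_order, ord)
        ring_open[[tok]] <- NULL
      }
      pending <- NA_real_
    } else if (grepl("^\\[", tok)) {
      m <- regmatches(tok, regexec("^\\[[0-9]*([A-Za-z][a-z]?)", tok))[[1L]]
      if (length(m) < 2L) fail(sprintf("bracket atom '%s'", tok))
      el <- m[2L]
      arom <- el %in% AROMATIC_ATOMS
      add_atom(if (arom) toupper(el) else el, arom)
    } else if (grepl("^[A-Z][a-z]?$", tok)) {
      add_atom(tok, FALSE)
    } else if (tok %in% AROMATIC_ATOMS) {
      add_atom(toupper(tok), TRUE)
    } else {
      fail(sprintf("unsupported token '%s'", tok))
    }
  }
  if (length(stack)) fail("unbalanced '('")
  if (length(ring_open)) {
    fail(sprintf("unclosed ring closure digit(s) %s",
                 paste(names(ring_open), collapse = ", ")))
  }
  if (length(elements) == 0L) fail("no atoms")
  list(atoms = data.frame(element = elements, aromatic = aromatic,
                          stringsAsFactors = FALSE),
       bonds = data.frame(from = bonds_from, to = bonds_to,
                          order = bonds_order))
}

#' Morgan-style circular fingerprint of a SMILES string
#'
#' Computes iterated circular-substructure identifiers in the Morgan/ECFP
#' style: each atom starts from an invariant built from its element,
#' aromaticity, degree and total bond order; for `radius` rounds every
#' atom's invariant is rehashed together with its (bond order, neighbour
#' invariant) pairs in sorted order.  All identifiers from all rounds are
#' folded into `nbits` bits; the fingerprint is the set of occupied bit
#' positions.
#'
#' @param smiles A SMILES string (or a pre-parsed graph from
#'   [parse_smiles()]).
#' @param radius Number of neighbourhood-expansion rounds (default 2,
#'   ECFP4-like).
#' @param nbits Fold size (default 2048).
#' @param id Optional compound id for error messages.
#' @return Sorted integer vector of occupied bit positions in
#'   `[0, nbits)`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, nbits = 2048L,
                               id = NULL) {
  mol <- if (is.list(smiles) && !is.null(smiles$atoms)) smiles
         else parse_smiles(smiles, id = id)
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    o <- as.integer(round(mol$bonds$order[k] * 2))
    nb[[i]] <- rbind(nb[[i]], c(j, o))
    nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  deg <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bsum <- vapply(nb, function(x) if (is.null(x)) 0L else sum(x[, 2L]),
                 integer(1))
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(element_code(mol$atoms$element[i]),
                as.integer(mol$atoms$aromatic[i]), deg[i], bsum[i]))
  }, integer(1))
  all_ids <- inv
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(hash_ints(c(inv[i], 0L)))
        codes <- nb[[i]][, 2L] * 2147483647 + inv[nb[[i]][, 1L]]
        ord <- order(codes)
        hash_ints(c(inv[i],
                    as.vector(t(cbind(nb[[i]][ord, 2L], inv[nb[[i]][ord, 1L]])))))
      }, integer(1))
      all_ids <- c(all_ids, inv)
    }
  }
  sort(unique(as.integer(all_ids %% nbits)))
}
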