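# Entity-level similarity distances and single-linkage clustering.
#
# Protein distance: 1 - SW(p, q) / sqrt(SW(p, p) * SW(q, q)), with SW the
# Smith-Waterman local-alignment score.  Compound distance: 1 - Jaccard of
# the Morgan-style fingerprint bit sets.  Both are bounded in [0, 1],
# symmetric and zero on identical inputs; the triangle inequality is not
# guaranteed and not relied upon.

sw_score_matrix <- function(scoring = "BLOSUM62") {
  if (is.matrix(scoring)) return(scoring)
  get(utils::data(list = scoring, package = "Biostrings",
                  envir = environment()))
}

sw_score <- function(a, b, scoring = "BLOSUM62", gap_open = 10,
                     gap_extend = 1) {
  mat <- sw_score_matrix(scoring)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Normalized Smith-Waterman distance between two proteins
#'
#' `1 - SW(p_i, p_j) / sqrt(SW(p_i, p_i) * SW(p_j, p_j))` with `SW` the
#' local-alignment score under the configured scheme (default BLOSUM62,
#' gap opening 10, gap extension 1).  The normalization bounds the distance
#' in `[0, 1]` for any non-negative scoring of the cross alignment; the
#' distance of a sequence to itself is exactly 0.
#'
#' @param p_i,p_j Residue sequences (single strings).
#' @param scoring Substitution matrix name (from Biostrings) or an explicit
#'   matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Distance in `[0, 1]`.
#' @export
protein_distance <- function(p_i, p_j, scoring = "BLOSUM62", gap_open = 10,
                             gap_extend = 1) {
  stopifnot(nchar(p_i) > 0L, nchar(p_j) > 0L)
  sii <- sw_score(p_i, p_i, scoring, gap_open, gap_extend)
  sjj <- sw_score(p_j, p_j, scoring, gap_open, gap_extend)
  if (sii <= 0 || sjj <= 0) {
    stop("sequence with non-positive self-alignment score", call. = FALSE)
  }
  sij <- sw_score(p_i, p_j, scoring, gap_open, gap_extend)
  1 - max(sij, 0) / sqrt(sii * sjj)
}

#' Fingerprint Jaccard distance between two compounds
#'
#' `1 - |FP_i intersect FP_j| / |FP_i union FP_j|` over circular-
#' substructure fingerprint bit sets (see [morgan_fingerprint()]).
#' Fingerprints may also be supplied directly as integer sets, bypassing
#' SMILES parsing.
#'
#' @param c_i,c_j SMILES strings, or (when `fp = TRUE`) integer vectors of
#'   fingerprint bits.
#' @param radius,nbits Fingerprint parameters, see [morgan_fingerprint()].
#' @param fp Set `TRUE` when `c_i`/`c_j` already are fingerprint bit sets.
#' @param id_i,id_j Optional compound ids for error messages.
#' @return Distance in `[0, 1]`.
#' @export
compound_distance <- function(c_i, c_j, radius = 2L, nbits = 2048L,
                              fp = FALSE, id_i = NULL, id_j = NULL) {
  if (!fp) {
    c_i <- morgan_fingerprint(c_i, radius, nbits, id = id_i)
    c_j <- morgan_fingerprint(c_j, radius, nbits, id = id_j)
  }
  u <- length(union(c_i, c_j))
  if (u == 0L) return(0)
  1 - length(intersect(c_i, c_j)) / u
}

#' Pairwise distance matrix for a set of proteins or compounds
#'
#' @param entities Named character vector of sequences (`kind = "protein"`)
#'   or SMILES (`kind = "compound"`).
#' @param kind `"protein"` or `"compound"`.
#' @param ... Passed to [protein_distance()] / [compound_distance()].
#' @return Symmetric numeric matrix with zero diagonal and dimnames from
#'   `entities`.
#' @export
distance_matrix <- function(entities, kind = c("protein", "compound"), ...) {
  kind <- match.arg(kind)
  n <- length(entities)
  ids <- names(entities)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (kind == "compound") {
    fps <- lapply(seq_len(n), function(i) {
      morgan_fingerprint(entities[[i]], id = ids[i], ...)
    })
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        d[i, j] <- d[j, i] <- compound_distance(fps[[i]], fps[[j]], fp = TRUE)
      }
    }
  } else {
    self <- vapply(entities, function(s) sw_score(s, s, ...), numeric(1))
    if (any(self <= 0)) {
      stop("sequence with non-positive self-alignment score", call. = FALSE)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        sij <- sw_score(entities[[i]], entities[[j]], ...)
        d[i, j] <- d[j, i] <- 1 - max(sij, 0) / sqrt(self[i] * self[j])
      }
    }
  }
  d
}

#' Single-linkage clusters at a distance threshold
#'
#' Clusters are the connected components of the graph with an edge between
#' two entities whenever their distance is below the threshold (strict `<`
#' by default).  This is exactly single-linkage clustering with the
#' dendrogram cut at the threshold: any two entities closer than the
#' threshold end up in the same cluster, transitively (chaining).
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param threshold Clustering threshold (default 0.3).
#' @param strict Use strict `<` for edges (default); `FALSE` uses `<=`.
#' @return A `cluster_assignment` object: list with `cluster` (named
#'   integer vector entity -> cluster id, ids consecutive from 1),
#'   `threshold`, `strict`.
#' @export
single_linkage_clusters <- function(d, threshold = 0.3, strict = TRUE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  # union-find over the strict-threshold graph
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      linked <- if (strict) d[i, j] < threshold else d[i, j] <= threshold
      if (linked) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, unique(roots))
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  names(cluster) <- ids
  structure(list(cluster = cluster, threshold = threshold, strict = strict),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d entities in %d clusters (threshold %g, %s)>\n",
              length(x$cluster), length(unique(x$cluster)), x$threshold,
              if (x$strict) "strict <" else "<="))
  invisible(x)
}
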