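# Train/validation/test split schemes: random cross-validation folds,
# cluster-level cold-drug / cold-target splits, and the blind 3x3 grid in
# which neither test proteins nor test compounds share a similarity
# cluster with the training set.

new_split_plan <- function(scheme, train, val, test, clusters, seed,
                           extra = list()) {
  structure(c(list(scheme = scheme, train = sort(train), val = sort(val),
                   test = sort(test), clusters = clusters, seed = seed),
              extra),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n <- length(x$train) + length(x$val) + length(x$test)
  cat(sprintf("<split_plan %s: %d/%d/%d interactions (train/val/test), seed %s>\n",
              x$scheme, length(x$train), length(x$val), length(x$test),
              format(x$seed)))
  if (n > 0) {
    cat(sprintf("  ratios: %.3f / %.3f / %.3f\n", length(x$train) / n,
                length(x$val) / n, length(x$test) / n))
  }
  invisible(x)
}

#' Random interaction-level folds
#'
#' Partitions the interactions into `n_parts` near-equal folds (the usual
#' scheme: one fold held out as the independent test set, the remaining
#' folds rotated for cross-validation).
#'
#' @param dataset A `dta_dataset`.
#' @param n_parts Number of folds (default 6).
#' @param seed Integer seed; the same seed reproduces the same folds.
#' @return List with `folds` (list of disjoint index vectors covering all
#'   interactions), `n_parts`, `seed`.
#' @export
random_split <- function(dataset, n_parts = 6L, seed = 1L) {
  stopifnot(inherits(dataset, "dta_dataset"))
  n <- nrow(dataset$interactions)
  if (n < n_parts) {
    stop(sprintf("%d interactions cannot fill %d folds", n, n_parts),
         call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(n_parts), length.out = n)
  folds <- split(perm, fold_of)
  names(folds) <- NULL
  list(folds = lapply(folds, sort), n_parts = n_parts, seed = seed)
}

# interactions per cluster for the cold entity kind
cluster_interaction_index <- function(interactions, clusters, kind) {
  col <- if (kind == "compound") "compound_id" else "protein_id"
  ents <- interactions[[col]]
  missing <- setdiff(unique(ents), names(clusters$cluster))
  if (length(missing)) {
    stop(sprintf("no cluster assignment for: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  split(seq_len(nrow(interactions)), clusters$cluster[ents])
}

# greedy largest-cluster-first allocation onto the partition furthest
# below its interaction-count target; ties among equal-sized clusters are
# broken by a seeded shuffle
allocate_clusters <- function(sizes, targets, seed) {
  ord <- with_seed(seed, order(sizes + stats::runif(length(sizes)) * 0.5,
                               decreasing = TRUE))
  assign <- integer(length(sizes))
  filled <- numeric(length(targets))
  for (k in ord) {
    deficit <- targets - filled
    p <- which.max(deficit)
    assign[k] <- p
    filled[p] <- filled[p] + sizes[k]
  }
  assign
}

#' Cold-drug / cold-target split
#'
#' Allocates whole similarity clusters of the cold entity kind to the
#' train/validation/test partitions, targeting the given interaction-count
#' ratios (approximately 7:1:2 by default).  All interactions of an entity
#' follow its cluster, and no cluster appears in more than one partition,
#' so every test-set drug (target) is dissimilar -- at the clustering
#' threshold -- from every training and validation drug (target).
#'
#' @param dataset A `dta_dataset`.
#' @param mode `"cold_drug"` (clusters compounds) or `"cold_target"`.
#' @param clusters A `cluster_assignment` for the cold entity kind (from
#'   [single_linkage_clusters()]).
#' @param ratios Target train/val/test interaction proportions.
#' @param seed Integer seed for tie-breaking among equal-sized clusters.
#' @return A `split_plan` with disjoint interaction index sets.
#' @export
cold_split <- function(dataset, mode = c("cold_drug", "cold_target"),
                       clusters, ratios = c(7, 1, 2), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "dta_dataset"),
            inherits(clusters, "cluster_assignment"), length(ratios) == 3L)
  kind <- if (mode == "cold_drug") "compound" else "protein"
  by_cluster <- cluster_interaction_index(dataset$interactions, clusters,
                                          kind)
  sizes <- lengths(by_cluster)
  total <- sum(sizes)
  targets <- total * ratios / sum(ratios)
  if (max(sizes) > targets[3L] * 2 && length(sizes) > 3L) {
    warning("a single cluster exceeds twice the test budget; ",
            "allocation is best-effort", call. = FALSE)
  }
  assign <- allocate_clusters(sizes, targets, seed)
  part <- function(p) unlist(by_cluster[assign == p], use.names = FALSE)
  new_split_plan(mode, part(1L), part(2L), part(3L), clusters, seed,
                 extra = list(ratios = ratios, kind = kind))
}

#' Blind nine-fold split over a 3x3 cluster grid
#'
#' Protein clusters are allocated to three folds and compound clusters to
#' three folds (balanced by interaction counts), placing every interaction
#' in a 3x3 grid cell.  For each of the nine choices of test cell, the
#' four cells sharing the test cell's protein fold or compound fold are
#' discarded and the remaining four cells form the training set, so no
#' protein or compound cluster is shared between training and test.
#'
#' @param dataset A `dta_dataset`.
#' @param protein_clusters,compound_clusters `cluster_assignment` objects.
#' @param seed Integer seed.
#' @return A list of nine `split_plan` objects (scheme `"blind"`, empty
#'   validation sets), with the grid cell of each plan in `$grid`.
#' @export
blind_split <- function(dataset, protein_clusters, compound_clusters,
                        seed = 1L) {
  stopifnot(inherits(dataset, "dta_dataset"))
  ia <- dataset$interactions
  p_by <- cluster_interaction_index(ia, protein_clusters, "protein")
  c_by <- cluster_interaction_index(ia, compound_clusters, "compound")
  if (length(p_by) < 3L || length(c_by) < 3L) {
    stop("need at least 3 protein clusters and 3 compound clusters",
         call. = FALSE)
  }
  p_fold_of_cluster <- allocate_clusters(lengths(p_by), rep(sum(lengths(p_by)) / 3, 3),
                                         seed)
  c_fold_of_cluster <- allocate_clusters(lengths(c_by), rep(sum(lengths(c_by)) / 3, 3),
                                         seed + 1L)
  # per-interaction fold membership
  p_fold <- integer(nrow(ia))
  for (k in seq_along(p_by)) p_fold[p_by[[k]]] <- p_fold_of_cluster[k]
  c_fold <- integer(nrow(ia))
  for (k in seq_along(c_by)) c_fold[c_by[[k]]] <- c_fold_of_cluster[k]

  plans <- list()
  for (i in 1:3) {
    for (j in 1:3) {
      test <- which(p_fold == i & c_fold == j)
      train <- which(p_fold != i & c_fold != j)
      plans[[length(plans) + 1L]] <- new_split_plan(
        "blind", train, integer(0), test,
        list(protein = protein_clusters, compound = compound_clusters),
        seed,
        extra = list(grid = c(protein_fold = i, compound_fold = j),
                     protein_fold_of = p_fold, compound_fold_of = c_fold))
    }
  }
  plans
}

#' Independently verify a split plan's exclusion guarantees
#'
#' Re-checks, from nothing but the plan, the interaction table and the
#' cluster assignment(s): (1) the train/val/test index sets are disjoint;
#' (2) for cold splits, no cluster of the cold entity kind occurs in two
#' partitions; (3) for blind splits, no protein or compound cluster is
#' shared between train and test.
#'
#' @param plan A `split_plan`.
#' @param dataset The `dta_dataset` the plan indexes into.
#' @return `TRUE` invisibly; violations raise an error.
#' @export
verify_split_plan <- function(plan, dataset) {
  stopifnot(inherits(plan, "split_plan"))
  ia <- dataset$interactions
  parts <- list(train = plan$train, val = plan$val, test = plan$test)
  all_idx <- unlist(parts, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    stop("split partitions overlap", call. = FALSE)
  }
  clusters_of <- function(idx, clusters, kind) {
    col <- if (kind == "compound") "compound_id" else "protein_id"
    unique(clusters$cluster[ia[[col]][idx]])
  }
  if (plan$scheme %in% c("cold_drug", "cold_target")) {
    kind <- if (plan$scheme == "cold_drug") "compound" else "protein"
    cl <- lapply(parts, clusters_of, clusters = plan$clusters, kind = kind)
    for (a in 1:2) {
      for (b in (a + 1):3) {
        shared <- intersect(cl[[a]], cl[[b]])
        if (length(shared)) {
          stop(sprintf("%s: cluster(s) %s shared between %s and %s",
                       plan$scheme, paste(shared, collapse = ","),
                       names(parts)[a], names(parts)[b]), call. = FALSE)
        }
      }
    }
  } else if (plan$scheme == "blind") {
    for (kind in c("protein", "compound")) {
      tr <- clusters_of(plan$train, plan$clusters[[kind]], kind)
      te <- clusters_of(plan$test, plan$clusters[[kind]], kind)
      shared <- intersect(tr, te)
      if (length(shared)) {
        stop(sprintf("blind: %s cluster(s) %s shared between train and test",
                     kind, paste(shared, collapse = ",")), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
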