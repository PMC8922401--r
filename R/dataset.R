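# The interaction dataset container, the duplicate/conflict refinement
# rule, and per-entity interaction statistics.

#' Construct a drug-target affinity dataset
#'
#' Bundles compound SMILES, protein sequences and an interaction table.
#' Every interaction must reference an existing entity.
#'
#' @param compounds Named character vector: compound id -> SMILES.
#' @param proteins Named character vector: protein id -> residue sequence.
#' @param interactions Data.frame with columns `compound_id`, `protein_id`,
#'   `affinity`.
#' @return A `dta_dataset` object.
#' @export
dta_dataset <- function(compounds, proteins, interactions) {
  stopifnot(is.character(compounds), !is.null(names(compounds)),
            is.character(proteins), !is.null(names(proteins)),
            is.data.frame(interactions),
            all(c("compound_id", "protein_id", "affinity") %in%
                  names(interactions)))
  bad_c <- setdiff(interactions$compound_id, names(compounds))
  bad_p <- setdiff(interactions$protein_id, names(proteins))
  if (length(bad_c) || length(bad_p)) {
    stop(sprintf("interactions reference unknown entities: %s",
                 paste(utils::head(c(bad_c, bad_p), 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(interactions$affinity)) {
    stop("affinity column must be numeric", call. = FALSE)
  }
  rownames(interactions) <- NULL
  structure(list(compounds = compounds, proteins = proteins,
                 interactions = interactions),
            class = "dta_dataset")
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat(sprintf("<dta_dataset: %d compounds x %d proteins, %d interactions>\n",
              length(x$compounds), length(x$proteins),
              nrow(x$interactions)))
  invisible(x)
}

#' @export
summary.dta_dataset <- function(object, ...) {
  s <- dataset_stats(object)
  cat(sprintf(
    paste0("Drug-target affinity dataset\n",
           "  proteins               : %d\n",
           "  compounds              : %d\n",
           "  interactions           : %d\n",
           "  interactions / protein : %.2f\n",
           "  interactions / compound: %.2f\n",
           "  affinity range         : [%.3g, %.3g]\n"),
    s$n_proteins, s$n_compounds, s$n_interactions,
    s$interactions_per_protein, s$interactions_per_compound,
    min(object$interactions$affinity), max(object$interactions$affinity)))
  invisible(s)
}

#' Refine a dataset: collapse duplicates, drop conflicting labels
#'
#' Repeated measurements of the same (compound, protein) pair with an
#' identical affinity collapse to a single record.  Pairs measured with
#' different affinities are removed entirely, since contradictory labels
#' on the same input harm supervised training.  Entities left without any
#' interaction are dropped from the entity tables.  The refinement is
#' idempotent.
#'
#' @param dataset A `dta_dataset`.
#' @param by `"id"` (default) keys pairs on entity ids; `"sequence"` keys
#'   on the SMILES/sequence strings themselves, which additionally
#'   collapses distinct ids with identical representations.
#' @return A `refined_dta_dataset`: the refined `dta_dataset` with an
#'   attached `report` listing, per removed or collapsed key, the reason
#'   (`"duplicate"` or `"conflict"`) and the number of raw records
#'   involved, plus summary counts.
#' @export
refine_dataset <- function(dataset, by = c("id", "sequence")) {
  by <- match.arg(by)
  stopifnot(inherits(dataset, "dta_dataset"))
  ia <- dataset$interactions
  ckey <- if (by == "id") ia$compound_id else
    unname(dataset$compounds[ia$compound_id])
  pkey <- if (by == "id") ia$protein_id else
    unname(dataset$proteins[ia$protein_id])
  key <- paste(ckey, pkey, sep = "\r")
  groups <- split(seq_len(nrow(ia)), key)

  keep <- logical(nrow(ia))
  rep_key <- character(0)
  rep_reason <- character(0)
  rep_n <- integer(0)
  for (g in groups) {
    affs <- ia$affinity[g]
    if (length(g) == 1L) {
      keep[g] <- TRUE
    } else if (length(unique(affs)) == 1L) {
      keep[g[1L]] <- TRUE              # exact duplicates: keep one
      rep_key <- c(rep_key, paste(ia$compound_id[g[1L]],
                                  ia$protein_id[g[1L]], sep = "|"))
      rep_reason <- c(rep_reason, "duplicate")
      rep_n <- c(rep_n, length(g))
    } else {                           # conflicting labels: drop all
      rep_key <- c(rep_key, paste(ia$compound_id[g[1L]],
                                  ia$protein_id[g[1L]], sep = "|"))
      rep_reason <- c(rep_reason, "conflict")
      rep_n <- c(rep_n, length(g))
    }
  }
  refined <- ia[keep, , drop = FALSE]
  rownames(refined) <- NULL
  compounds <- dataset$compounds[names(dataset$compounds) %in%
                                   refined$compound_id]
  proteins <- dataset$proteins[names(dataset$proteins) %in%
                                 refined$protein_id]
  report <- list(
    removed = data.frame(key = rep_key, reason = rep_reason,
                         n_records = rep_n, stringsAsFactors = FALSE),
    n_duplicate_keys = sum(rep_reason == "duplicate"),
    n_conflict_keys = sum(rep_reason == "conflict"),
    n_records_in = nrow(ia), n_records_out = nrow(refined))
  out <- dta_dataset(compounds, proteins, refined)
  attr(out, "report") <- report
  class(out) <- c("refined_dta_dataset", class(out))
  out
}

#' @export
print.refined_dta_dataset <- function(x, ...) {
  r <- attr(x, "report")
  NextMethod()
  cat(sprintf("  refined: %d -> %d records (%d duplicate keys collapsed, %d conflicting keys dropped)\n",
              r$n_records_in, r$n_records_out, r$n_duplicate_keys,
              r$n_conflict_keys))
  invisible(x)
}

#' Refinement report accessor
#'
#' @param dataset A `refined_dta_dataset` from [refine_dataset()].
#' @return The removal report (see [refine_dataset()]).
#' @export
refinement_report <- function(dataset) {
  r <- attr(dataset, "report")
  if (is.null(r)) stop("dataset carries no refinement report", call. = FALSE)
  r
}

#' Dataset size and per-entity interaction statistics
#'
#' @param dataset A `dta_dataset`.
#' @return A list with `n_proteins`, `n_compounds`, `n_interactions`,
#'   `interactions_per_protein` and `interactions_per_compound` (totals
#'   divided by entity counts).
#' @export
dataset_stats <- function(dataset) {
  stopifnot(inherits(dataset, "dta_dataset"))
  n_i <- nrow(dataset$interactions)
  if (n_i == 0L) stop("dataset has no interactions", call. = FALSE)
  list(n_proteins = length(dataset$proteins),
       n_compounds = length(dataset$compounds),
       n_interactions = n_i,
       interactions_per_protein = n_i / length(dataset$proteins),
       interactions_per_compound = n_i / length(dataset$compounds))
}
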