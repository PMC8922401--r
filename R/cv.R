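# Multi-fold training/evaluation orchestration and fold aggregation
# (mean and standard deviation per metric, the "0.892 (0.002)" reporting
# convention).

#' Aggregate per-fold metric reports
#'
#' @param reports List of metric lists (e.g. `dta_metrics` objects) with
#'   identical numeric fields.
#' @param std `"sample"` (n-1 denominator, the common fold-reporting
#'   convention) or `"population"`.
#' @return A data.frame with one row per metric: `metric`, `mean`, `sd`,
#'   `n_folds`.
#' @export
aggregate_metrics <- function(reports, std = c("sample", "population")) {
  std <- match.arg(std)
  stopifnot(length(reports) >= 1L)
  fields <- names(reports[[1L]])
  fields <- fields[vapply(reports[[1L]], is.numeric, logical(1))]
  rows <- lapply(fields, function(f) {
    v <- vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))
    s <- if (length(v) < 2L) 0 else if (std == "sample") stats::sd(v) else
      sqrt(mean((v - mean(v))^2))
    data.frame(metric = f, mean = mean(v), sd = s,
               n_folds = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-validated training and evaluation
#'
#' Implements the usual benchmark protocol: the interactions are split
#' into `n_parts` near-equal folds, one fold is held out as the
#' independent test set, and each of the remaining folds in turn serves
#' as the validation set while the others train the model.  Each rotation
#' yields a full metric panel on the test fold; the aggregate reports
#' mean and standard deviation per metric.
#'
#' @param dataset A `dta_dataset` (typically refined).
#' @param compound_emb,protein_emb Named embedding lists covering the
#'   dataset's entities.
#' @param config A [dta_config()].
#' @param n_parts Number of folds (default 6: one test fold + 5-fold CV).
#' @param n_rotations How many validation rotations to run (default all
#'   `n_parts - 1`; smaller values save time).
#' @param threshold Optional affinity threshold for AUPR.
#' @param seed Integer seed (folds, initialization, batching).
#' @return A `dta_cv` object: list with `per_fold` (list of
#'   `dta_metrics`), `aggregate` (data.frame), `folds`, `seed`.
#' @export
run_cv <- function(dataset, compound_emb, protein_emb, config,
                   n_parts = 6L, n_rotations = n_parts - 1L,
                   threshold = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "dta_dataset"))
  sp <- random_split(dataset, n_parts, seed)
  test_idx <- sp$folds[[1L]]
  rest <- sp$folds[-1L]
  pairs <- dataset$interactions
  reports <- list()
  for (r in seq_len(min(n_rotations, length(rest)))) {
    val_idx <- rest[[r]]
    train_idx <- unlist(rest[-r], use.names = FALSE)
    fit <- dta_train(pairs[c(train_idx, val_idx), , drop = FALSE],
                     compound_emb, protein_emb, config,
                     val = length(train_idx) + seq_along(val_idx),
                     seed = seed + r)
    pred <- predict(fit, pairs[test_idx, , drop = FALSE], compound_emb,
                    protein_emb)
    reports[[r]] <- evaluate_predictions(pairs$affinity[test_idx], pred,
                                         threshold = threshold)
  }
  structure(list(per_fold = reports,
                 aggregate = aggregate_metrics(reports),
                 folds = sp, seed = seed),
            class = "dta_cv")
}

#' @export
print.dta_cv <- function(x, ...) {
  cat(sprintf("<dta_cv: %d rotations>\n", length(x$per_fold)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-9s %.3f (%.3f)\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}
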