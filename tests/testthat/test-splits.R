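singleton_clusters <- function(ids) {
  structure(list(cluster = stats::setNames(seq_along(ids), ids),
                 threshold = 0.3, strict = TRUE),
            class = "cluster_assignment")
}

test_that("random folds partition the interactions evenly and reproducibly", {
  ds <- make_test_dataset(seed = 2, n_compounds = 10L, n_proteins = 6L,
                          n_families = 2L)
  ds$interactions <- ds$interactions[1:60, ]
  sp <- random_split(ds, n_parts = 6L, seed = 4)
  expect_equal(lengths(sp$folds), rep(10L, 6L))
  all_idx <- unlist(sp$folds)
  expect_equal(sort(all_idx), 1:60)
  sp2 <- random_split(ds, n_parts = 6L, seed = 4)
  expect_identical(sp$folds, sp2$folds)
  expect_false(identical(sp$folds,
                         random_split(ds, n_parts = 6L, seed = 5)$folds))
  tiny <- ds
  tiny$interactions <- tiny$interactions[1:3, ]
  expect_error(random_split(tiny, n_parts = 6L), "cannot fill")
})

test_that("cold splits allocate whole singleton clusters at the target ratio", {
  # 10 compounds, one cluster each, equal interaction counts
  compounds <- stats::setNames(rep("CCO", 10), paste0("d", 1:10))
  proteins <- c(t1 = "MKVLAW")
  tab <- data.frame(compound_id = rep(names(compounds), each = 2),
                    protein_id = "t1",
                    affinity = rnorm(20, 6), stringsAsFactors = FALSE)
  ds <- dta_dataset(compounds, proteins, tab)
  cl <- singleton_clusters(names(compounds))
  plan <- cold_split(ds, "cold_drug", cl, seed = 3)
  n_entities <- function(idx) length(unique(tab$compound_id[idx]))
  expect_equal(n_entities(plan$train), 7L)
  expect_equal(n_entities(plan$val), 1L)
  expect_equal(n_entities(plan$test), 2L)
  expect_true(verify_split_plan(plan, ds))
})

test_that("cold splits keep chained clusters together and exclude test clusters exhaustively", {
  ds <- make_test_dataset(seed = 6, n_compounds = 30L, n_proteins = 12L,
                          n_families = 4L)
  pd <- distance_matrix(ds$proteins, "protein")
  pcl <- single_linkage_clusters(pd, 0.3)
  plan <- cold_split(ds, "cold_target", pcl, seed = 11)
  expect_true(verify_split_plan(plan, ds))
  # exhaustive manual check of the defining guarantee
  ia <- ds$interactions
  for (a in c("train", "val")) {
    cl_a <- unique(pcl$cluster[ia$protein_id[plan[[a]]]])
    cl_t <- unique(pcl$cluster[ia$protein_id[plan$test]])
    expect_length(intersect(cl_a, cl_t), 0L)
  }
  # every interaction of an entity follows its cluster: entities never
  # straddle partitions
  part_of <- integer(nrow(ia))
  part_of[plan$train] <- 1L; part_of[plan$val] <- 2L
  part_of[plan$test] <- 3L
  expect_true(all(tapply(part_of, ia$protein_id,
                         function(x) length(unique(x))) == 1))
})

test_that("blind nine-fold grid excludes shared clusters between train and test", {
  # 3 protein clusters x 3 compound clusters, one interaction per cell
  compounds <- stats::setNames(rep("CCO", 3), paste0("d", 1:3))
  proteins <- stats::setNames(rep("MKVLAW", 3), paste0("t", 1:3))
  tab <- expand.grid(compound_id = names(compounds),
                     protein_id = names(proteins),
                     stringsAsFactors = FALSE)
  tab$affinity <- rnorm(9, 6)
  ds <- dta_dataset(compounds, proteins, tab)
  plans <- blind_split(ds, singleton_clusters(names(proteins)),
                       singleton_clusters(names(compounds)), seed = 2)
  expect_length(plans, 9L)
  for (p in plans) {
    expect_length(p$test, 1L)
    expect_length(p$train, 4L)          # 9 cells - test row - test col
    expect_length(p$val, 0L)
    expect_true(verify_split_plan(p, ds))
    # brute-force grid recomputation from the plan's fold assignments
    i <- p$grid["protein_fold"]; j <- p$grid["compound_fold"]
    expect_identical(sort(p$test),
                     which(p$protein_fold_of == i & p$compound_fold_of == j))
    expect_identical(sort(p$train),
                     which(p$protein_fold_of != i & p$compound_fold_of != j))
  }
  two_clusters <- structure(
    list(cluster = stats::setNames(c(1L, 1L, 2L), names(proteins)),
         threshold = 0.3, strict = TRUE),
    class = "cluster_assignment")
  expect_error(blind_split(ds, two_clusters,
                           singleton_clusters(names(compounds)), seed = 1),
               "at least 3")
})

test_that("blind splits hold on family-structured synthetic data", {
  ds <- make_test_dataset(seed = 9, n_compounds = 24L, n_proteins = 12L,
                          n_families = 4L)
  pcl <- single_linkage_clusters(distance_matrix(ds$proteins, "protein"),
                                 0.3)
  ccl <- single_linkage_clusters(distance_matrix(ds$compounds, "compound"),
                                 0.3)
  plans <- blind_split(ds, pcl, ccl, seed = 13)
  for (p in plans) expect_true(verify_split_plan(p, ds))
  # grid cells cover all interactions exactly once across the 3x3 grid
  tests <- unlist(lapply(plans, `[[`, "test"))
  expect_equal(sort(tests), seq_len(nrow(ds$interactions)))
})

test_that("the verifier actually rejects contaminated plans", {
  ds <- make_test_dataset(seed = 2, n_compounds = 10L, n_proteins = 4L,
                          n_families = 2L)
  cl <- singleton_clusters(names(ds$compounds))
  plan <- cold_split(ds, "cold_drug", cl, seed = 1)
  broken <- plan
  broken$train <- c(plan$train, plan$test[1L])
  expect_error(verify_split_plan(broken, ds), "overlap")
  # move one interaction of a test compound into train while its cluster
  # keeps other interactions in the test partition
  broken2 <- plan
  broken2$test <- plan$test[-1L]
  broken2$train <- c(plan$train, plan$test[1L])
  expect_error(verify_split_plan(broken2, ds), "shared")
})
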