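test_that("concordance index handles the defining cases", {
  expect_equal(concordance_index(c(1, 2, 3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(concordance_index(c(1, 2), c(5, 5)), 0.5)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(1, 3, 2, 4)), 5 / 6)
  expect_error(concordance_index(c(2, 2, 2), c(1, 2, 3)), "all y_true")
})

test_that("concordance index equals the brute-force pair-count oracle", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(3:50, 1)
    y <- sample(1:6, n, replace = TRUE)      # heavy tie patterns
    if (length(unique(y)) < 2) y[1] <- y[1] + 1
    b <- round(rnorm(n), 1)                  # prediction ties too
    expect_identical(concordance_index(y, b), ci_oracle(y, b))
  }
})

test_that("CI is invariant under strictly monotone transforms and has exact limits", {
  set.seed(22)
  y <- rnorm(30)
  b <- rnorm(30)
  ci <- concordance_index(y, b)
  expect_equal(concordance_index(y, exp(b)), ci)
  expect_equal(concordance_index(y, 3 * b - 7), ci)
  expect_equal(concordance_index(y, y), 1)
  expect_equal(concordance_index(y, -y), 0)
})

test_that("mse and pearson match naive two-pass formulas", {
  set.seed(23)
  y <- rnorm(40); b <- rnorm(40)
  expect_equal(mse(y, y), 0)
  expect_equal(pearson(y, y), 1)
  yc <- y - mean(y)
  expect_equal(pearson(yc, -yc), -1)
  expect_equal(mse(y, b), sum((y - b)^2) / 40, tolerance = 1e-10)
  r_naive <- sum((y - mean(y)) * (b - mean(b))) /
    sqrt(sum((y - mean(y))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(y, b), r_naive, tolerance = 1e-10)
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("r_m^2 limits and transcription hold", {
  y <- c(1, 2, 3, 5)
  r <- rm2_index(y, y)
  expect_equal(r$rm2, 1)
  expect_equal(r$r2, 1)
  expect_equal(r$r02, 1)
  # through-origin-perfect predictions: r2 = r02 so rm2 = r2
  r2 <- rm2_index(2 * y, y)
  expect_equal(r2$rm2, r2$r2)
  # symbol-by-symbol recomputation on random vectors, both orientations
  set.seed(24)
  for (i in 1:20) {
    yt <- rnorm(10); yp <- rnorm(10)
    r <- rm2_index(yt, yp)
    k <- sum(yt * yp) / sum(yp^2)
    r02 <- 1 - sum((yt - k * yp)^2) / sum((yt - mean(yt))^2)
    r2 <- cor(yt, yp)^2
    expect_equal(r$r02, r02, tolerance = 1e-12)
    expect_equal(r$rm2, r2 * (1 - sqrt(max(r2 - r02, 0))),
                 tolerance = 1e-12)
    expect_lte(r$rm2, r$r2 + 1e-12)
    ro <- rm2_index(yt, yp, orientation = "pred_on_obs")
    ko <- sum(yp * yt) / sum(yt^2)
    expect_equal(ro$r02,
                 1 - sum((yp - ko * yt)^2) / sum((yp - mean(yp))^2),
                 tolerance = 1e-12)
  }
})

test_that("AUPR matches the exhaustive all-cutpoints construction", {
  # perfectly separating predictions
  expect_equal(aupr_by_threshold(c(1, 2, 8, 9), c(.1, .2, .8, .9), 5), 1)
  expect_error(aupr_by_threshold(c(8, 9), c(.1, .2), 5), "single class")
  set.seed(25)
  for (i in 1:30) {
    n <- 20
    y <- rnorm(n, mean = 7)
    b <- rnorm(n, mean = 7)
    if (length(unique(y >= 7)) < 2) next
    expect_equal(aupr_by_threshold(y, b, 7),
                 pr_oracle(as.integer(y >= 7), b), tolerance = 1e-9)
    # with tied scores
    bt <- round(b, 0)
    expect_equal(aupr_by_threshold(y, bt, 7),
                 pr_oracle(as.integer(y >= 7), bt), tolerance = 1e-9)
  }
})

test_that("classification metrics match the confusion matrix and Mann-Whitney AUC", {
  perfect <- classification_metrics(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_equal(unlist(perfect), c(sen = 1, acc = 1, f1 = 1, prec = 1,
                                  auc = 1))
  # TP = FP = FN = TN = 1
  sym <- classification_metrics(c(1, 1, 0, 0), c(.9, .1, .9, .1))
  expect_equal(unlist(sym[c("prec", "sen", "acc", "f1")]),
               c(prec = .5, sen = .5, acc = .5, f1 = .5))
  expect_error(classification_metrics(c(1, 1), c(.2, .3)), "single-class")
  set.seed(26)
  for (i in 1:25) {
    lab <- c(rep(1, 7), rep(0, 8))
    p <- round(runif(15), 1)                 # ties included
    expect_equal(classification_metrics(lab, p)$auc, auc_oracle(lab, p))
  }
})

test_that("the evaluation panel assembles all metrics coherently", {
  set.seed(27)
  y <- rnorm(50, 7); b <- y + rnorm(50, sd = .5)
  rep <- evaluate_predictions(y, b, threshold = 7)
  expect_s3_class(rep, "dta_metrics")
  expect_equal(rep$ci, concordance_index(y, b))
  expect_equal(rep$mse, mse(y, b))
  expect_equal(rep$rm2, rm2_index(y, b)$rm2)
  expect_equal(rep$aupr, aupr_by_threshold(y, b, 7))
  expect_true(rep$ci >= 0 && rep$ci <= 1)
  expect_true(rep$mse >= 0)
  expect_output(print(rep), "CI")
})
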