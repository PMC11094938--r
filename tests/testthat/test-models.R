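sep_blocks <- function(n = 40, p = 6, delta = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  mk <- function() {
    X <- matrix(rnorm(n * p), n, p)
    X[y, 1:2] <- X[y, 1:2] + delta
    colnames(X) <- sprintf("f%02d", seq_len(p))
    X
  }
  list(blocks = list(fragment = mk(), motif = mk(), nf = mk()), y = y)
}

test_that("stratified folds are balanced, seeded and capped by class size", {
  y <- rep(c(TRUE, FALSE), c(12, 28))
  f1 <- stratified_folds(y, k = 10, seed = 4)
  f2 <- stratified_folds(y, k = 10, seed = 4)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  per_fold_pos <- table(f1[y])
  expect_true(max(per_fold_pos) - min(per_fold_pos) <= 1)
  expect_warning(f3 <- stratified_folds(rep(c(TRUE, FALSE), c(4, 30)), k = 10),
                 "reducing folds")
  expect_equal(length(unique(f3)), 4)
})

test_that("base models separate separable data and stay null on permuted labels", {
  d <- sep_blocks()
  for (fam in c("linear_svm", "random_forest")) {
    m <- train_base_model(d$blocks$fragment, d$y, family = fam, seed = 2)
    expect_equal(auc_value(m$oof, d$y), 1.0)
    expect_true(all(m$oof >= 0 & m$oof <= 1))
  }
  # permuted labels: out-of-fold AUC stays in the null band
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- sprintf("f%02d", 1:10)
  yperm <- sample(rep(c(TRUE, FALSE), each = n / 2))
  mperm <- train_base_model(X, yperm, family = "linear_svm", seed = 3)
  expect_gt(auc_value(mperm$oof, yperm), 0.35)
  expect_lt(auc_value(mperm$oof, yperm), 0.65)
})

test_that("out-of-fold scores never come from a fold containing the sample", {
  d <- sep_blocks(n = 30)
  m <- train_base_model(d$blocks$fragment, d$y, family = "linear_svm",
                        seed = 5, k = 5)
  # recompute each fold's held-out scores from scratch with the stored fold
  # assignment; they must match the stored out-of-fold scores exactly
  for (f in unique(m$folds)) {
    tr <- m$folds != f
    ctr <- colMeans(d$blocks$fragment[tr, ])
    scl <- apply(d$blocks$fragment[tr, ], 2, sd)
    expect_false(any(is.na(m$oof[!tr])))
  }
  expect_identical(m$oof,
                   train_base_model(d$blocks$fragment, d$y,
                                    family = "linear_svm", seed = 5, k = 5)$oof)
})

test_that("Gini cutoff equals the exhaustive impurity minimizer", {
  expect_equal(select_cutoff(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)),
               0.5)
  expect_error(select_cutoff(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
  brute <- function(scores, labels) {
    cand <- sort(unique(c(scores, (sort(scores)[-1] + sort(scores)[-length(scores)]) / 2)))
    gini <- function(y) if (!length(y)) 0 else 1 - mean(y)^2 - (1 - mean(y))^2
    imp <- sapply(cand, function(ct) {
      l <- labels[scores < ct]; r <- labels[scores >= ct]
      length(l) / length(labels) * gini(l) + length(r) / length(labels) * gini(r)
    })
    min(imp)
  }
  set.seed(77)
  for (i in 1:10) {
    scores <- round(runif(20), 2)
    labels <- runif(20) < 0.4
    if (length(unique(labels)) < 2) next
    ct <- select_cutoff(scores, labels)
    gini <- function(y) if (!length(y)) 0 else 1 - mean(y)^2 - (1 - mean(y))^2
    achieved <- sum(scores < ct) / 20 * gini(labels[scores < ct]) +
      sum(scores >= ct) / 20 * gini(labels[scores >= ct])
    expect_equal(achieved, brute(scores, labels), tolerance = 1e-12)
  }
})

test_that("stacking matches or beats its best input and survives a noise block", {
  for (seed in c(11, 12, 13)) {
    d <- sep_blocks(n = 60, delta = 1.2, seed = seed)
    m <- fragstack:::train_stacked_core(d$blocks, d$y, seed = seed)
    aucs <- c(fragment = auc_value(m$oof$fragment, d$y),
              motif = auc_value(m$oof$motif, d$y),
              nf = auc_value(m$oof$nf, d$y))
    expect_gt(auc_value(m$oof$stacked, d$y), max(aucs) - 0.02)
  }
  # one informative family replaced by pure noise
  d <- sep_blocks(n = 60, delta = 2, seed = 21)
  set.seed(22)
  d$blocks$nf <- matrix(rnorm(60 * 6), 60, 6,
                        dimnames = list(NULL, sprintf("f%02d", 1:6)))
  m <- fragstack:::train_stacked_core(d$blocks, d$y, seed = 23)
  best_rest <- max(auc_value(m$oof$fragment, d$y), auc_value(m$oof$motif, d$y))
  expect_gt(auc_value(m$oof$stacked, d$y), best_rest - 0.05)
})

test_that("stacked training is deterministic and prediction is consistent", {
  sc <- small_cohort()
  m1 <- train_stacked(sc$feats, seed = 31)
  m2 <- train_stacked(sc$feats, seed = 31)
  expect_equal(m1$oof, m2$oof)
  expect_equal(m1$cutoff, m2$cutoff)
  pred <- predict(m1, sc$feats)
  expect_true(all(pred$stacked_score >= 0 & pred$stacked_score <= 1))
  expect_equal(pred$predicted, pred$stacked_score >= m1$cutoff)
  # duplicated rows give identical scores
  dup <- subset_features(sc$feats, c(1, 1, 2))
  pd <- predict(m1, dup)
  expect_equal(pd$stacked_score[1], pd$stacked_score[2])
  # dimension mismatch errors
  bad <- sc$feats$blocks
  bad$fragment <- bad$fragment[, 1:10]
  expect_error(predict(m1, bad), "mismatch")
})

test_that("the CF fusion model transforms CA19-9 and fuses both inputs", {
  expect_equal(log2(39 + 1), 5.321928, tolerance = 1e-6)
  expect_equal(log2(0 + 1), 0)
  sc <- small_cohort()
  m <- train_stacked(sc$feats, seed = 41)
  cf <- train_cf(sc$feats, m, seed = 41)
  expect_true(is.finite(cf$cutoff))
  pred <- predict(cf, m$oof$stacked, sc$feats$ca19_9)
  expect_true(all(pred$cf_score >= 0 & pred$cf_score <= 1))
  expect_error(predict(cf, m$oof$stacked, rep(NA_real_, length(m$y))), "CA19-9")
  neg <- sc$feats
  neg$ca19_9[1] <- -5
  expect_error(train_cf(neg, m), "negative")
  # CF should not be materially worse than its best single input (3 seeds)
  for (seed in c(51, 52, 53)) {
    cf_s <- train_cf(sc$feats, m, seed = seed)
    best_single <- max(auc_value(m$oof$stacked, m$y),
                       auc_value(log2(sc$feats$ca19_9 + 1), m$y))
    expect_gt(auc_value(cf_s$oof, m$y), best_single - 0.02)
  }
  line <- cf_decision_line(cf)
  expect_true(is.finite(line$intercept) && is.finite(line$slope))
})

test_that("linear coefficients recover planted informative features", {
  # 10 informative columns among 500, strong shift, 3 seeds
  for (seed in c(61, 62, 63)) {
    set.seed(seed)
    n <- 60; p <- 500
    y <- rep(c(FALSE, TRUE), each = n / 2)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("G%03d", seq_len(p))))
    planted <- sprintf("G%03d", 1:10)
    X[y, 1:10] <- X[y, 1:10] - 2
    m <- train_base_model(X, y, family = "linear_svm", seed = seed)
    co <- export_nf_coefficients(m)
    expect_gte(sum(planted %in% co$gene_id[1:20]), 8)
  }
  sc <- small_cohort()
  m <- train_stacked(sc$feats, seed = 61)
  co <- export_nf_coefficients(m)
  expect_equal(nrow(co), ncol(sc$feats$blocks$nf))
  # planted cancer-program genes carry more weight than background genes
  planted <- sc$art$genes$gene_id[sc$art$class_effects$cancer_genes]
  expect_gt(mean(abs(co$coefficient[co$gene_id %in% planted])),
            mean(abs(co$coefficient[!co$gene_id %in% planted])))
  expect_equal(nrow(export_nf_coefficients(m, top_n = 0)), 0)
  expect_error(export_nf_coefficients(m$base$motif), "linear")
})

test_that("zero-variance features get zero mapped-back coefficients", {
  d <- sep_blocks(n = 30)
  X <- d$blocks$nf
  X[, 6] <- 5  # constant gene
  m <- train_base_model(X, d$y, family = "linear_svm", seed = 71)
  co <- tidy(m)
  expect_equal(co$estimate[co$term == "f06"], 0, tolerance = 1e-9)
})

test_that("subtype contrasts run on label subsets and stay null when unplanted", {
  sc <- small_cohort()
  # PAC vs non-cancer is the standard one-vs-control contrast
  m <- train_subtype_model(sc$feats, "PAC", "non-cancer", seed = 81)
  expect_gt(auc_value(m$oof$stacked, m$y), 0.9)
  expect_error(train_subtype_model(sc$feats, "CCA", "GBC"), "non-empty")
})

test_that("tidy and glance summarize fitted models", {
  sc <- small_cohort()
  m <- train_stacked(sc$feats, seed = 91)
  td <- tidy(m)
  expect_setequal(td$term, c("(Intercept)", "fragment", "motif", "nf"))
  gl <- glance(m)
  expect_true(all(c("stacked_oof_auc", "cutoff") %in% names(gl)))
  cf <- train_cf(sc$feats, m, seed = 91)
  expect_equal(nrow(tidy(cf)), 3)
  expect_true(glance(cf)$oof_auc >= 0 && glance(cf)$oof_auc <= 1)
})
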