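#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

BASE_FAMILIES <- c(fragment = "linear_svm", motif = "random_forest",
                   nf = "linear_svm")

#' Stratified cross-validation fold assignment
#'
#' @param y Logical class vector.
#' @param k Requested fold count; silently reduced (with a warning) to the
#'   minority-class count when larger.
#' @param seed Integer seed.
#' @return Integer fold id per sample, in `1..k`.
#' @export
stratified_folds <- function(y, k = 10, seed = 1L) {
  y <- as.logical(y)
  n_min <- min(sum(y), sum(!y))
  if (n_min < 2) abort("need at least 2 samples in each class")
  if (k > n_min) {
    warn(sprintf("reducing folds from %d to %d (minority class size)", k, n_min))
    k <- n_min
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

fit_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# Platt-style margin -> probability map: logistic fit on smoothed targets so
# perfectly separated folds stay finite.
fit_platt <- function(margin, y) {
  n1 <- sum(y); n0 <- sum(!y)
  t <- ifelse(y, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  fit <- suppressWarnings(stats::glm(t ~ margin, family = stats::quasibinomial()))
  co <- stats::coef(fit)
  if (anyNA(co)) co[is.na(co)] <- 0
  co
}

apply_platt <- function(co, margin) stats::plogis(co[1] + co[2] * margin)

svm_margin <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  drop(attr(pr, "decision.values"))
}

fit_linear_svm <- function(X, y) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = 1, scale = FALSE)
  m <- svm_margin(fit, X)
  # orient margins so larger = more cancer-like, whatever libsvm's label order
  flip <- mean(m[y]) < mean(m[!y])
  list(fit = fit, flip = flip)
}

learner_fit <- function(X, y, family, seed) {
  if (family == "linear_svm") {
    sv <- fit_linear_svm(X, y)
    m <- svm_margin(sv$fit, X) * ifelse(sv$flip, -1, 1)
    platt <- fit_platt(m, y)
    list(family = family, fit = sv$fit, flip = sv$flip, platt = platt)
  } else if (family == "random_forest") {
    rf <- withr::with_seed(seed, randomForest::randomForest(
      x = X, y = factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")),
      ntree = 500))
    list(family = family, fit = rf)
  } else {
    abort(sprintf("unknown learner family: %s", family))
  }
}

learner_score <- function(learner, X) {
  if (learner$family == "linear_svm") {
    m <- svm_margin(learner$fit, X) * ifelse(learner$flip, -1, 1)
    unname(apply_platt(learner$platt, m))
  } else {
    unname(stats::predict(learner$fit, X, type = "prob")[, "pos"])
  }
}

#' Train one per-family base model with out-of-fold scoring
#'
#' Stratified k-fold cross-validation in which standardization, the learner
#' and (for the max-margin learner) the margin-to-probability calibration are
#' all fit on the training portion of each fold only, so every sample's
#' out-of-fold score comes from a model that never saw it. The returned
#' model is refit on all the data for use at prediction time.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Logical outcome (TRUE = cancer / positive group).
#' @param family `"linear_svm"` (fragment-size and NF features) or
#'   `"random_forest"` (end-motif features).
#' @param k Folds (default 10).
#' @param seed Integer seed for folds and forest.
#' @param folds Optional precomputed fold assignment (shared across the
#'   three families by the stacked trainer).
#' @return Object of class `fs_base_model` with elements `oof` (out-of-fold
#'   scores in `[0, 1]`), `folds`, `std`, `learner`, `family`.
#' @export
train_base_model <- function(X, y, family = "linear_svm", k = 10, seed = 1L,
                             folds = NULL) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) abort("single-class input")
  folds <- folds %||% stratified_folds(y, k, seed)
  oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    std <- fit_standardizer(X[tr, , drop = FALSE])
    lf <- learner_fit(apply_standardizer(std, X[tr, , drop = FALSE]), y[tr],
                      family, seed = derive_seed(seed, f))
    oof[!tr] <- learner_score(lf, apply_standardizer(std, X[!tr, , drop = FALSE]))
  }
  std <- fit_standardizer(X)
  learner <- learner_fit(apply_standardizer(std, X), y, family,
                         seed = derive_seed(seed, 0L))
  structure(list(family = family, std = std, learner = learner,
                 folds = folds, oof = oof, y = y,
                 feature_names = colnames(X)),
            class = "fs_base_model")
}

#' @export
predict.fs_base_model <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$feature_names)) {
    if (!setequal(colnames(newdata), object$feature_names)) {
      abort("feature dimension/name mismatch with trained base model")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  learner_score(object$learner, apply_standardizer(object$std, newdata))
}

#' Gini-impurity decision cutoff
#'
#' Scans the midpoints between consecutive sorted unique scores and returns
#' the threshold minimizing the size-weighted mean Gini impurity
#' `n_left/n * Gini(left) + n_right/n * Gini(right)` with
#' `Gini(g) = 1 - p^2 - (1-p)^2`; ties break toward the larger cutoff
#' (higher specificity).
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive class).
#' @return The cutoff; predicted positive means `score >= cutoff`.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("both classes required to place a cutoff")
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  gini <- function(y) {
    if (length(y) == 0) return(0)
    p <- mean(y)
    1 - p^2 - (1 - p)^2
  }
  n <- length(scores)
  imp <- vapply(cand, function(ct) {
    left <- scores < ct
    sum(left) / n * gini(labels[left]) + sum(!left) / n * gini(labels[!left])
  }, numeric(1))
  best <- imp <= min(imp) + 1e-12
  max(cand[best])
}

train_stacked_core <- function(blocks, y, k = 10, seed = 1L) {
  stopifnot(all(c("fragment", "motif", "nf") %in% names(blocks)))
  folds <- stratified_folds(y, k, seed)
  base <- purrr::imap(blocks, function(X, nm) {
    train_base_model(X, y, family = BASE_FAMILIES[[nm]], seed = seed,
                     folds = folds)
  })
  oof <- tibble(fragment = base$fragment$oof, motif = base$motif$oof,
                nf = base$nf$oof)
  meta <- suppressWarnings(stats::glm(y ~ fragment + motif + nf,
                                      family = stats::binomial(),
                                      data = cbind(oof, y = y)))
  stacked_oof <- unname(stats::predict(meta, newdata = oof, type = "response"))
  cutoff <- select_cutoff(stacked_oof, y)
  structure(list(base = base, meta = meta, cutoff = cutoff, folds = folds,
                 oof = mutate(oof, stacked = stacked_oof), y = y, seed = seed),
            class = "fs_stacked_model")
}

#' Train the stacked detection model
#'
#' Fits the three per-family base models (linear max-margin classifiers for
#' the fragment-size and nucleosome-footprint blocks, a 500-tree random
#' forest for the end-motif block) with shared stratified ten-fold CV, then a
#' logistic-regression meta-learner on the three out-of-fold score columns.
#' The decision cutoff minimizes Gini impurity over the out-of-fold stacked
#' scores.
#'
#' @param features A `cohort_features` (training cohort).
#' @param y Optional logical outcome; defaults to cancer vs non-cancer.
#' @param k Folds.
#' @param seed Integer seed.
#' @return Object of class `fs_stacked_model`.
#' @export
train_stacked <- function(features, y = NULL, k = 10, seed = 1L) {
  y <- y %||% features$cancer
  mod <- train_stacked_core(features$blocks, y, k = k, seed = seed)
  mod$sample_id <- features$sample_id
  mod
}

#' @export
print.fs_stacked_model <- function(x, ...) {
  cat(sprintf("<fs_stacked_model> %d samples, cutoff %.3f\n",
              length(x$y), x$cutoff))
  invisible(x)
}

#' Score samples with a stacked model
#'
#' @param object An `fs_stacked_model`.
#' @param newdata A `cohort_features` or a named list of feature matrices.
#' @param ... Unused.
#' @return Tibble `sample_id`, per-family scores, `stacked_score`,
#'   `predicted` (logical at the stored cutoff).
#' @export
predict.fs_stacked_model <- function(object, newdata, ...) {
  blocks <- if (inherits(newdata, "cohort_features")) newdata$blocks else newdata
  sids <- if (inherits(newdata, "cohort_features")) newdata$sample_id
          else rownames(blocks[[1]]) %||% as.character(seq_len(nrow(blocks[[1]])))
  scores <- purrr::imap(object$base, function(bm, nm) {
    predict(bm, blocks[[nm]])
  })
  df <- tibble(fragment = scores$fragment, motif = scores$motif,
               nf = scores$nf)
  stacked <- unname(stats::predict(object$meta, newdata = df,
                                   type = "response"))
  tibble(sample_id = sids,
         fragment_score = df$fragment, motif_score = df$motif,
         nf_score = df$nf, stacked_score = stacked,
         predicted = stacked >= object$cutoff)
}

#' Train the CA19-9 + fragmentomics fusion model
#'
#' The final detection model: a linear max-margin classifier on two inputs,
#' the ten-fold cross-validated stacked cancer score and
#' `log2(CA19-9 + 1)`, both standardized on the training cohort. Its own
#' ten-fold CV produces out-of-fold fusion scores from which the Gini cutoff
#' is chosen; the stored model is refit on all training samples.
#'
#' @param features Training `cohort_features` (CA19-9 required, values >= 0).
#' @param stacked An `fs_stacked_model` trained on the same cohort (its
#'   out-of-fold stacked scores are the fragmentomics input).
#' @param k Folds.
#' @param seed Integer seed.
#' @return Object of class `fs_cf_model`.
#' @export
train_cf <- function(features, stacked, k = 10, seed = 1L) {
  ca <- features$ca19_9
  if (anyNA(ca)) abort("CA19-9 required for every sample")
  if (any(ca < 0)) abort("negative CA19-9 value")
  y <- features$cancer
  X <- cbind(stacked_score = stacked$oof$stacked, ca19_9_log2 = log2(ca + 1))
  folds <- stratified_folds(y, k, seed)
  oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    std <- fit_standardizer(X[tr, , drop = FALSE])
    lf <- learner_fit(apply_standardizer(std, X[tr, , drop = FALSE]), y[tr],
                      "linear_svm", seed = derive_seed(seed, f))
    oof[!tr] <- learner_score(lf, apply_standardizer(std, X[!tr, , drop = FALSE]))
  }
  std <- fit_standardizer(X)
  learner <- learner_fit(apply_standardizer(std, X), y, "linear_svm",
                         seed = derive_seed(seed, 0L))
  structure(list(std = std, learner = learner, cutoff = select_cutoff(oof, y),
                 oof = oof, y = y, folds = folds),
            class = "fs_cf_model")
}

#' Score samples with a CF fusion model
#'
#' @param object An `fs_cf_model`.
#' @param stacked_score Stacked cancer scores of the new samples (from
#'   [predict.fs_stacked_model()]).
#' @param ca19_9 CA19-9 values in U/mL.
#' @param ... Unused.
#' @return Tibble `stacked_score`, `ca19_9`, `cf_score`, `predicted`.
#' @export
predict.fs_cf_model <- function(object, stacked_score, ca19_9, ...) {
  if (anyNA(ca19_9)) abort("CA19-9 required for CF prediction")
  X <- cbind(stacked_score = stacked_score, ca19_9_log2 = log2(ca19_9 + 1))
  sc <- learner_score(object$learner, apply_standardizer(object$std, X))
  tibble(stacked_score = stacked_score, ca19_9 = ca19_9, cf_score = sc,
         predicted = sc >= object$cutoff)
}

#' Linear decision boundary of a CF model in the 2-D feature plane
#'
#' @param object An `fs_cf_model`.
#' @return List `intercept`, `slope` describing the decision line in the
#'   (log2(CA19-9 + 1), stacked score) plane.
#' @export
cf_decision_line <- function(object) {
  w <- linear_svm_weights(object$learner, object$std)
  # w1 * stacked + w2 * ca_log2 + b = 0  ->  stacked = -(b + w2 * ca)/w1
  list(intercept = -w$b / w$w[["stacked_score"]],
       slope = -w$w[["ca19_9_log2"]] / w$w[["stacked_score"]])
}

# weights of a linear svm mapped back through standardization
linear_svm_weights <- function(learner, std) {
  fit <- learner$fit
  w_std <- drop(t(fit$coefs) %*% fit$SV)
  b_std <- -fit$rho
  if (learner$flip) {
    w_std <- -w_std
    b_std <- -b_std
  }
  w <- w_std / std$scale
  b <- b_std - sum(w_std * std$center / std$scale)
  list(w = w, b = b)
}

#' Train a subtype-contrast stacked model
#'
#' Runs the full stacking machinery with group membership as the outcome:
#' one cancer type against another (`"PAC"` vs `"CCA"`), against a composite
#' (`"PAC"` vs `c("CCA", "GBC")`), or a cancer type against non-cancer
#' controls only.
#'
#' @param features A `cohort_features`.
#' @param class_a,class_b Character vectors of labels forming the positive
#'   (`class_a`) and negative group.
#' @param k,seed As in [train_stacked()].
#' @return An `fs_stacked_model` fit on the subset, with attribute
#'   `contrast`.
#' @export
train_subtype_model <- function(features, class_a, class_b, k = 10, seed = 1L) {
  keep <- features$label %in% c(class_a, class_b)
  if (!any(features$label %in% class_a) || !any(features$label %in% class_b)) {
    abort("both contrast groups must be non-empty")
  }
  sub <- subset_features(features, keep)
  mod <- train_stacked(sub, y = sub$label %in% class_a, k = k, seed = seed)
  attr(mod, "contrast") <- list(positive = class_a, negative = class_b)
  mod
}

#' Ranked gene coefficients of the NF base model
#'
#' Extracts the linear weights of the nucleosome-footprint max-margin
#' learner, maps them back through the feature standardization (so a
#' zero-variance gene gets weight 0 on the original scale), and ranks genes
#' by absolute coefficient.
#'
#' @param model An `fs_stacked_model` (its `nf` base model is used) or an
#'   `fs_base_model` with a linear learner.
#' @param top_n Rows returned (default all).
#' @return Tibble `gene_id`, `coefficient`, `rank`.
#' @export
export_nf_coefficients <- function(model, top_n = Inf) {
  bm <- if (inherits(model, "fs_stacked_model")) model$base$nf else model
  if (!inherits(bm, "fs_base_model") || bm$family != "linear_svm") {
    abort("NF coefficients require a linear base model")
  }
  w <- linear_svm_weights(bm$learner, bm$std)$w
  out <- tibble(gene_id = bm$feature_names, coefficient = unname(w)) |>
    arrange(dplyr::desc(abs(.data$coefficient))) |>
    mutate(rank = row_number())
  utils::head(out, top_n)
}

#' @export
tidy.fs_base_model <- function(x, ...) {
  if (x$family == "linear_svm") {
    w <- linear_svm_weights(x$learner, x$std)$w
    tibble(term = x$feature_names, estimate = unname(w))
  } else {
    imp <- randomForest::importance(x$learner$fit)
    tibble(term = rownames(imp), estimate = unname(imp[, 1]))
  }
}

#' @export
glance.fs_base_model <- function(x, ...) {
  tibble(family = x$family, n = length(x$y), k_folds = length(unique(x$folds)),
         oof_auc = auc_value(x$oof, x$y))
}

#' @export
tidy.fs_stacked_model <- function(x, ...) {
  co <- stats::coef(x$meta)
  tibble(term = names(co), estimate = unname(co))
}

#' @export
glance.fs_stacked_model <- function(x, ...) {
  tibble(n = length(x$y), k_folds = length(unique(x$folds)),
         fragment_oof_auc = auc_value(x$oof$fragment, x$y),
         motif_oof_auc = auc_value(x$oof$motif, x$y),
         nf_oof_auc = auc_value(x$oof$nf, x$y),
         stacked_oof_auc = auc_value(x$oof$stacked, x$y),
         cutoff = x$cutoff)
}

#' @export
tidy.fs_cf_model <- function(x, ...) {
  w <- linear_svm_weights(x$learner, x$std)
  tibble(term = c(names(w$w), "(intercept)"),
         estimate = c(unname(w$w), w$b))
}

#' @export
glance.fs_cf_model <- function(x, ...) {
  tibble(n = length(x$y), oof_auc = auc_value(x$oof, x$y), cutoff = x$cutoff)
}
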