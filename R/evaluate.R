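#' Area under the ROC curve
#'
#' Rank-based AUC with half credit for tied scores — identical to the
#' normalized Mann-Whitney U statistic `U / (n1 * n0)` and to the trapezoid
#' area over the empirical ROC with simultaneous steps at ties.
#'
#' @param scores Numeric scores (larger = more positive-like).
#' @param labels Logical (TRUE = positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_value <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and summary metrics
#'
#' Computes the empirical ROC (thresholds at every distinct score, ties
#' stepped simultaneously), the trapezoid AUC, sensitivity at the target
#' specificity, and — when a decision cutoff is given — the confusion counts
#' at that cutoff.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive).
#' @param target_specificity Specificity floor for the reported sensitivity.
#' @param cutoff Optional decision cutoff (predict positive at
#'   `score >= cutoff`).
#' @return List of class `eval_report`: `roc` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `sensitivity_at_spec`, `spec_target`, `threshold_at_spec`
#'   and, with a cutoff, `confusion` (tibble `tp`, `fp`, `tn`, `fn`).
#' @export
roc_auc <- function(scores, labels, target_specificity = 0.95, cutoff = NULL) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes required for ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  sas <- sensitivity_at_specificity(scores, labels, target_specificity)
  out <- list(roc = tibble(threshold = thr, fpr = fpr, tpr = tpr),
              auc = auc,
              sensitivity_at_spec = sas$sensitivity,
              spec_target = target_specificity,
              threshold_at_spec = sas$threshold)
  if (!is.null(cutoff)) {
    pred <- scores >= cutoff
    out$confusion <- tibble(tp = sum(pred & labels), fp = sum(pred & !labels),
                            tn = sum(!pred & !labels), fn = sum(!pred & labels))
    out$cutoff <- cutoff
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f; sensitivity %.3f at specificity >= %.2f\n",
              x$auc, x$sensitivity_at_spec, x$spec_target))
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(auc = x$auc, sensitivity_at_spec = x$sensitivity_at_spec,
         spec_target = x$spec_target, threshold_at_spec = x$threshold_at_spec)
}

#' Sensitivity at a fixed specificity
#'
#' Chooses the smallest threshold whose specificity on the negative class is
#' at least `target` (thereby maximizing sensitivity under the constraint)
#' and reports the sensitivity there.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive).
#' @param target Specificity floor in `[0, 1]`.
#' @return List `sensitivity`, `threshold`, `specificity`.
#' @export
sensitivity_at_specificity <- function(scores, labels, target = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) abort("both classes required")
  neg <- scores[!labels]
  cand <- sort(unique(c(scores, max(scores) + 1)))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  ok <- which(spec >= target)
  t_star <- cand[ok[1]]
  list(sensitivity = mean(scores[labels] >= t_star), threshold = t_star,
       specificity = spec[ok[1]])
}

#' Pairwise Mann-Whitney U comparison of score groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests between every pair of
#' groups, exact for small tie-free samples and normal-approximated with tie
#' correction otherwise ([stats::wilcox.test()] semantics). The U statistic
#' is reported for the first group of each pair.
#'
#' @param scores Numeric scores.
#' @param grouping Group label per score.
#' @return Tibble `group1`, `group2`, `n1`, `n2`, `u`, `p_value`.
#' @export
compare_groups <- function(scores, grouping) {
  grouping <- as.character(grouping)
  gs <- unique(grouping)
  if (any(table(grouping) < 1)) abort("every group needs at least one score")
  if (length(gs) < 2) abort("need at least two groups")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- scores[grouping == pr[1]]
    y <- scores[grouping == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = (length(x) +
                                                               length(y)) <= 20))
    tibble(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
           u = unname(wt$statistic), p_value = wt$p.value)
  })
}

#' Fold-wise cross-validated AUC quantile interval
#'
#' AUC computed within each CV fold from the out-of-fold scores, summarized
#' by its mean and percentile interval. (The interval construction for the
#' published CV AUCs is unstated; fold-wise percentiles are reported here and
#' labelled as such.)
#'
#' @param oof Out-of-fold scores.
#' @param y Logical labels.
#' @param folds Fold assignment.
#' @param level Interval coverage.
#' @return Tibble `auc`, `ci_lo`, `ci_hi`, `n_folds` (folds lacking a class
#'   are skipped).
#' @export
fold_auc_summary <- function(oof, y, folds, level = 0.95) {
  per <- purrr::map_dbl(sort(unique(folds)), function(f) {
    yy <- y[folds == f]
    if (length(unique(yy)) < 2) return(NA_real_)
    auc_value(oof[folds == f], yy)
  })
  per <- per[!is.na(per)]
  a <- (1 - level) / 2
  tibble(auc = auc_value(oof, y),
         ci_lo = unname(stats::quantile(per, a)),
         ci_hi = unname(stats::quantile(per, 1 - a)),
         n_folds = length(per))
}

#' CA19-9-stratified classification report
#'
#' Splits samples at the clinical CA19-9 cutoff (boundary value assigned to
#' the negative stratum, `<= cutoff`) and reports, within each stratum, the
#' model's confusion counts, sensitivity and specificity at the model's
#' decision threshold.
#'
#' @param scores Model scores.
#' @param labels Logical (TRUE = cancer).
#' @param ca19_9 CA19-9 in U/mL.
#' @param model_cutoff Model decision threshold.
#' @param cutoff_u_per_ml Clinical CA19-9 positivity cutoff (default 39).
#' @return Tibble, one row per stratum: `stratum`, `n`, `n_cancer`, `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
ca19_9_stratified_report <- function(scores, labels, ca19_9, model_cutoff,
                                     cutoff_u_per_ml = 39) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), length(ca19_9) == length(labels))
  stratum <- ifelse(ca19_9 <= cutoff_u_per_ml, "ca19_9_negative",
                    "ca19_9_positive")
  pred <- scores >= model_cutoff
  purrr::map_dfr(c("ca19_9_negative", "ca19_9_positive"), function(st) {
    i <- stratum == st
    tp <- sum(pred[i] & labels[i]); fp <- sum(pred[i] & !labels[i])
    tn <- sum(!pred[i] & !labels[i]); fn <- sum(!pred[i] & labels[i])
    tibble(stratum = st, n = sum(i), n_cancer = sum(labels[i]),
           tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
}

#' Coverage-downsampling experiment
#'
#' For each retention fraction: thins every sample's fragments, re-extracts
#' all three feature families, retrains the full stacked model on the
#' training cohort from scratch, and evaluates the per-family and stacked
#' models on the validation cohort. Mirrors the depth-robustness analysis in
#' which the size-profile model degrades least and the nucleosome-footprint
#' model most.
#'
#' @param training,validation `synthetic_cohort` objects sharing artifacts.
#' @param fractions Retention fractions in `(0, 1]`.
#' @param seed Integer seed (downsampling and model training).
#' @param motif_cfg,bounds Featurizer settings.
#' @param k CV folds.
#' @param min_presence NF gene presence threshold; relaxed below the strict
#'   default because extreme thinning leaves some reference windows empty in
#'   some samples.
#' @return Tibble, one row per (fraction, model family): `fraction`,
#'   `family`, `validation_auc`, `training_oof_auc`.
#' @export
downsampling_experiment <- function(training, validation, fractions,
                                    seed = 1L,
                                    motif_cfg = motif_config(umi_offset = 0),
                                    bounds = size_bounds(), k = 10,
                                    min_presence = 0.5) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must lie in (0, 1]")
  purrr::map_dfr(fractions, function(f) {
    tr <- featurize_cohort(training, motif_cfg = motif_cfg, bounds = bounds,
                           min_presence = min_presence,
                           downsample_to = f, downsample_seed = derive_seed(seed, 1))
    va <- featurize_cohort(validation, motif_cfg = motif_cfg, bounds = bounds,
                           nf_fit = tr$nf_fit, downsample_to = f,
                           downsample_seed = derive_seed(seed, 2))
    mod <- train_stacked(tr, k = k, seed = seed)
    pred <- predict(mod, va)
    fam_scores <- list(fragment = pred$fragment_score,
                       motif = pred$motif_score, nf = pred$nf_score,
                       stacked = pred$stacked_score)
    oof <- c(as.list(mod$oof))
    purrr::imap_dfr(fam_scores, function(sc, nm) {
      tibble(fraction = f, family = nm,
             validation_auc = auc_value(sc, va$cancer),
             training_oof_auc = auc_value(oof[[nm]], mod$y))
    })
  })
}
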