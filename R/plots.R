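#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a fragment length distribution
#'
#' @param fragments Fragment tibble, optionally with a `group` column
#'   (e.g. class label) for overlaid curves.
#' @param range Length range displayed.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(fragments, range = c(90, 400)) {
  if ("group" %in% names(fragments)) {
    d <- purrr::map_dfr(split(fragments, fragments$group),
                        size_distribution, range = range, .id = "group")
    p <- ggplot(d, aes(x = .data$length, y = .data$frequency,
                       colour = .data$group))
  } else {
    d <- size_distribution(fragments, range)
    p <- ggplot(d, aes(x = .data$length, y = .data$frequency))
  }
  p + geom_line() +
    labs(x = "fragment length (bp)", y = "frequency") +
    theme_minimal()
}

#' Plot TSS coverage profiles
#'
#' @param coverage Tibble from [coverage_around_tss()]; profiles are
#'   averaged within `group` if such a column is present (e.g. expression
#'   tier), otherwise per gene.
#' @return A ggplot.
#' @export
plot_tss_coverage <- function(coverage) {
  key <- if ("group" %in% names(coverage)) "group" else "gene_id"
  d <- coverage |>
    group_by(.data[[key]], .data$offset) |>
    summarise(coverage = mean(.data$coverage), .groups = "drop")
  ggplot(d, aes(x = .data$offset, y = .data$coverage,
                colour = .data[[key]])) +
    geom_line() +
    labs(x = "position relative to TSS (bp)", y = "mean fragment coverage") +
    theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot the CF model decision plane
#'
#' Samples in the (log2(CA19-9 + 1), stacked score) plane with the linear
#' decision boundary of the fusion model.
#'
#' @param cf An `fs_cf_model`.
#' @param stacked_score,ca19_9,labels Sample coordinates and class.
#' @return A ggplot.
#' @export
plot_cf_plane <- function(cf, stacked_score, ca19_9, labels) {
  line <- cf_decision_line(cf)
  d <- tibble(ca = log2(ca19_9 + 1), stacked = stacked_score,
              class = ifelse(as.logical(labels), "cancer", "non-cancer"))
  ggplot(d, aes(x = .data$ca, y = .data$stacked, colour = .data$class)) +
    geom_point(alpha = 0.8) +
    geom_abline(intercept = line$intercept, slope = line$slope) +
    labs(x = "log2(CA19-9 + 1)", y = "stacked cancer score") +
    theme_minimal()
}
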