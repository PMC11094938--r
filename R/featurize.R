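#' Extract the three feature families for one sample
#'
#' Runs the fragment-size, codon end-motif and nucleosome-footprint
#' featurizers on one qualified fragment set. The size feature applies its
#' own length window (`bounds`) inside the otherwise-qualified fragments;
#' motif and NF features use the fragments as given.
#'
#' @param fragments Qualified fragment tibble.
#' @param genome A `genome_bundle`.
#' @param bins Bin tibble for the size profile.
#' @param genes TSS annotation tibble.
#' @param motif_cfg A [motif_config()].
#' @param bounds A [size_bounds()].
#' @return List with `fragment` (named numeric, `2 * B`), `motif` (named
#'   numeric, 192 at defaults) and `nf` ([nf_profile()] tibble).
#' @export
featurize_sample <- function(fragments, genome, bins, genes,
                             motif_cfg = motif_config(), bounds = size_bounds()) {
  list(fragment = fragment_size_features(fragments, bins, bounds),
       motif = end_motif_features(fragments, genome, motif_cfg),
       nf = nf_profile(fragments, genes))
}

#' Build a cohort feature matrix
#'
#' Featurizes every sample of a cohort and assembles the per-family blocks.
#' The NF block is either fit here (gene presence filter + imputation means;
#' training use) or projected onto a training fit (`nf_fit`; validation use),
#' so no validation information leaks into feature assembly.
#'
#' @param cohort A `synthetic_cohort`, or a named list of fragment tibbles
#'   plus a `truth` tibble passed separately.
#' @param genome,bins,genes Scaffolds (defaulted from the cohort's artifacts
#'   when present).
#' @param truth Metadata tibble with `sample_id`, `label`, optional `ca19_9`.
#' @param motif_cfg,bounds Featurizer settings.
#' @param min_presence NF gene presence threshold (training fit).
#' @param nf_fit Optional list `genes`, `impute_means` from a training
#'   feature matrix.
#' @param downsample_to,downsample_seed Optional per-sample fragment thinning
#'   applied before featurization (depth experiments).
#' @return Object of class `cohort_features`: `sample_id`, `label`,
#'   `cancer` (logical), `ca19_9`, `blocks` (named list of numeric matrices
#'   `fragment`, `motif`, `nf`), `nf_fit`.
#' @export
featurize_cohort <- function(cohort, genome = NULL, bins = NULL, genes = NULL,
                             truth = NULL, motif_cfg = motif_config(umi_offset = 0),
                             bounds = size_bounds(), min_presence = 1.0,
                             nf_fit = NULL, downsample_to = 1.0,
                             downsample_seed = 1L) {
  if (inherits(cohort, "synthetic_cohort")) {
    genome <- genome %||% cohort$artifacts$genome
    bins <- bins %||% cohort$artifacts$bins
    genes <- genes %||% cohort$artifacts$genes
    truth <- truth %||% cohort$truth
    samples <- cohort$samples
  } else {
    samples <- cohort
  }
  stopifnot(!is.null(genome), !is.null(bins), !is.null(genes), !is.null(truth))
  sids <- names(samples)
  truth <- truth[match(sids, truth$sample_id), , drop = FALSE]

  feats <- purrr::imap(samples, function(frag, sid) {
    if (downsample_to < 1) {
      frag <- downsample_fragments(frag, downsample_to,
                                   seed = derive_seed(downsample_seed,
                                                      match(sid, sids)))
    }
    featurize_sample(frag, genome, bins, genes, motif_cfg, bounds)
  })
  frag_mat <- do.call(rbind, purrr::map(feats, "fragment"))
  motif_mat <- do.call(rbind, purrr::map(feats, "motif"))
  rownames(frag_mat) <- rownames(motif_mat) <- sids
  nf_profiles <- purrr::map(feats, "nf")
  if (is.null(nf_fit)) {
    nf <- assemble_nf_features(nf_profiles, min_presence = min_presence)
    nf_mat <- nf$matrix
    nf_fit <- list(genes = nf$genes, impute_means = nf$impute_means)
  } else {
    nf_mat <- apply_nf_features(nf_profiles, nf_fit$genes, nf_fit$impute_means)
  }
  structure(list(sample_id = sids, label = truth$label,
                 cancer = truth$label != "non-cancer",
                 ca19_9 = truth$ca19_9 %||% rep(NA_real_, length(sids)),
                 blocks = list(fragment = frag_mat, motif = motif_mat,
                               nf = nf_mat),
                 nf_fit = nf_fit),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("<cohort_features> %d samples (%d cancer)\n",
              length(x$sample_id), sum(x$cancer)))
  for (nm in names(x$blocks)) {
    cat(sprintf("  %-9s %d features\n", nm, ncol(x$blocks[[nm]])))
  }
  invisible(x)
}

#' Subset a cohort feature matrix by sample
#'
#' @param x A `cohort_features`.
#' @param keep Logical or integer sample index.
#' @return A `cohort_features` restricted to `keep`.
#' @export
subset_features <- function(x, keep) {
  structure(list(sample_id = x$sample_id[keep], label = x$label[keep],
                 cancer = x$cancer[keep], ca19_9 = x$ca19_9[keep],
                 blocks = purrr::map(x$blocks, ~ .x[keep, , drop = FALSE]),
                 nf_fit = x$nf_fit),
            class = "cohort_features")
}

#' Feature matrix as a tibble
#'
#' Long/wide tidy view of a `cohort_features` object: one row per sample,
#' metadata columns first, then all feature columns of the requested blocks.
#'
#' @param x A `cohort_features`.
#' @param blocks Which blocks to include.
#' @return A tibble.
#' @export
features_tbl <- function(x, blocks = names(x$blocks)) {
  mat <- do.call(cbind, x$blocks[blocks])
  dplyr::bind_cols(tibble(sample_id = x$sample_id, label = x$label,
                          cancer = x$cancer, ca19_9 = x$ca19_9),
                   as_tibble(mat))
}
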