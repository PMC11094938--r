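#' Position-wise fragment coverage around transcription start sites
#'
#' For each gene, counts at every strand-oriented offset in
#' `[-flank, +flank]` the number of fragments whose interval covers that
#' position (whole-fragment coverage: the sequenced molecule protects the
#' DNA, so nucleosome footprints are a fragment-level signal). Offsets are
#' mirrored for minus-strand genes so positive offsets always point
#' downstream of transcription.
#'
#' @param fragments Fragment tibble.
#' @param genes Annotation tibble from [gene_annotation()] /
#'   [load_gene_annotation()].
#' @param flank Half-width of the profiled window (default 2000, i.e. 4001
#'   positions).
#' @return Tibble `gene_id`, `offset`, `coverage`.
#' @export
coverage_around_tss <- function(fragments, genes, flank = 2000) {
  assert_fragments(fragments)
  if (nrow(genes) == 0) abort("`genes` must be non-empty")
  offs <- seq(-flank, flank)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    win_lo <- g$tss - flank          # genomic positions tss-flank .. tss+flank
    near <- fragments$chrom == g$chrom &
      fragments$end > win_lo & fragments$start <= g$tss + flank
    frag <- fragments[near, , drop = FALSE]
    cov <- integer(2 * flank + 2)    # diff array over window positions
    a <- pmax(frag$start - win_lo, 0) + 1
    b <- pmin(frag$end - win_lo, 2 * flank + 1)
    for (k in seq_along(a)) {
      cov[a[k]] <- cov[a[k]] + 1L
      cov[b[k] + 1L] <- cov[b[k] + 1L] - 1L
    }
    cov <- cumsum(cov)[seq_len(2 * flank + 1)]
    if (g$strand == "-") cov <- rev(cov)
    tibble(gene_id = g$gene_id, offset = offs, coverage = cov)
  })
}

#' Nucleosome footprint from TSS coverage profiles
#'
#' NF of a gene = mean coverage over the central window
#' `[-halfwidth, +halfwidth]` (501 positions at the 250-bp default) divided
#' by mean coverage over the flanking reference windows
#' `[-2000, -1000]` and `[1000, 2000]` (closed intervals, strand-oriented).
#' Low NF means nucleosome depletion around the TSS, the signature of an
#' actively transcribed gene. NF is missing where the reference mean is 0.
#'
#' @param coverage Tibble from [coverage_around_tss()].
#' @param central_halfwidth Central window half-width in bp.
#' @param ref_offsets Two-row matrix of closed reference-window offset
#'   intervals.
#' @return Tibble `gene_id`, `central_mean`, `reference_mean`, `nf`.
#' @export
nucleosome_footprint <- function(coverage, central_halfwidth = 250,
                                 ref_offsets = rbind(c(-2000, -1000),
                                                     c(1000, 2000))) {
  stopifnot(all(c("gene_id", "offset", "coverage") %in% names(coverage)))
  in_central <- abs(coverage$offset) <= central_halfwidth
  in_ref <- rep(FALSE, nrow(coverage))
  for (r in seq_len(nrow(ref_offsets))) {
    in_ref <- in_ref | (coverage$offset >= ref_offsets[r, 1] &
                        coverage$offset <= ref_offsets[r, 2])
  }
  cov <- coverage |>
    mutate(.central = in_central, .ref = in_ref) |>
    group_by(.data$gene_id) |>
    summarise(central_mean = mean(.data$coverage[.data$.central]),
              reference_mean = mean(.data$coverage[.data$.ref]),
              .groups = "drop")
  cov$nf <- ifelse(cov$reference_mean > 0,
                   cov$central_mean / cov$reference_mean, NA_real_)
  cov
}

# Mean whole-fragment coverage over a closed genomic interval [lo, hi]
# equals (sum over fragments of overlap width with [lo, hi+1)) / (hi-lo+1).
window_mean_cov <- function(frag_start, frag_end, lo, hi) {
  ov <- pmin(frag_end, hi + 1) - pmax(frag_start, lo)
  sum(pmax(ov, 0)) / (hi - lo + 1)
}

#' Per-gene nucleosome footprint directly from fragments
#'
#' Fast path equivalent to [coverage_around_tss()] followed by
#' [nucleosome_footprint()]: window mean coverages are computed from
#' fragment-overlap widths without materializing position-wise arrays.
#' The central and reference windows are symmetric around the TSS, so the
#' ratio is strand-independent even though profiles are strand-oriented.
#'
#' @param fragments Fragment tibble.
#' @param genes Annotation tibble; window geometry is taken from its
#'   attributes (see [gene_annotation()]).
#' @return Tibble `gene_id`, `central_mean`, `reference_mean`, `nf`.
#' @export
nf_profile <- function(fragments, genes) {
  assert_fragments(fragments)
  chw <- attr(genes, "central_halfwidth") %||% 250
  ro <- attr(genes, "ref_offsets") %||% rbind(c(-2000, -1000), c(1000, 2000))
  # per-chromosome start-sorted index so each gene touches only nearby rows
  by_chrom <- purrr::map(split(tibble(start = fragments$start,
                                      end = fragments$end),
                               fragments$chrom),
                         function(d) d[order(d$start), , drop = FALSE])
  max_len <- if (nrow(fragments) > 0) max(fragments$end - fragments$start) else 0
  ng <- nrow(genes)
  central <- numeric(ng); refm <- numeric(ng)
  for (i in seq_len(ng)) {
    tss <- genes$tss[i]
    lo_all <- tss + min(ro, -chw)
    hi_all <- tss + max(ro, chw)
    d <- by_chrom[[genes$chrom[i]]]
    if (is.null(d)) {
      fs <- numeric(0); fe <- numeric(0)
    } else {
      a <- findInterval(lo_all - max_len, d$start) + 1
      b <- findInterval(hi_all, d$start)
      sl <- if (b >= a) a:b else integer(0)
      near <- sl[d$end[sl] > lo_all]
      fs <- d$start[near]; fe <- d$end[near]
    }
    sgn <- if (genes$strand[i] == "-") -1 else 1
    central[i] <- window_mean_cov(fs, fe, tss - chw, tss + chw)
    ref_w <- 0; ref_s <- 0
    for (r in seq_len(nrow(ro))) {
      lo <- tss + sgn * ro[r, 1]; hi <- tss + sgn * ro[r, 2]
      if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
      w <- hi - lo + 1
      ref_s <- ref_s + window_mean_cov(fs, fe, lo, hi) * w
      ref_w <- ref_w + w
    }
    refm[i] <- ref_s / ref_w
  }
  tibble(gene_id = genes$gene_id, central_mean = central,
         reference_mean = refm,
         nf = ifelse(refm > 0, central / refm, NA_real_))
}

#' Assemble the cross-sample nucleosome-footprint feature block
#'
#' Keeps genes whose NF is non-missing in at least `min_presence` of the
#' samples (default: all of them), imputes any remaining missing value with
#' the gene's cross-sample mean, and returns a deterministic,
#' annotation-ordered feature matrix. The returned object also carries the
#' per-gene imputation means so a validation cohort can be transformed with
#' training-fit parameters only.
#'
#' @param profiles Named list (by sample) of [nf_profile()] tibbles, or one
#'   long tibble with a `sample_id` column.
#' @param min_presence Minimum fraction of samples with observed NF.
#' @return List of class `nf_features`: `genes` (character), `matrix`
#'   (samples x genes), `impute_means` (named numeric).
#' @export
assemble_nf_features <- function(profiles, min_presence = 1.0) {
  if (is.data.frame(profiles)) {
    stopifnot("sample_id" %in% names(profiles))
    profiles <- split(profiles[, c("gene_id", "nf")], profiles$sample_id)
  }
  stopifnot(length(profiles) >= 1)
  gene_order <- profiles[[1]]$gene_id
  mat <- do.call(rbind, purrr::map(profiles, function(p) {
    p$nf[match(gene_order, p$gene_id)]
  }))
  rownames(mat) <- names(profiles)
  colnames(mat) <- gene_order
  presence <- colMeans(!is.na(mat))
  keep <- presence >= min_presence
  if (!any(keep)) abort("no gene passes the NF presence filter")
  mat <- mat[, keep, drop = FALSE]
  means <- colMeans(mat, na.rm = TRUE)
  for (j in which(colSums(is.na(mat)) > 0)) {
    mat[is.na(mat[, j]), j] <- means[j]
  }
  structure(list(genes = colnames(mat), matrix = mat, impute_means = means),
            class = "nf_features")
}

#' Project per-sample NF profiles onto a fixed gene list
#'
#' Used for validation cohorts: genes and imputation means come from the
#' training-cohort [assemble_nf_features()] fit.
#'
#' @param profiles As in [assemble_nf_features()].
#' @param genes Character vector of training genes.
#' @param impute_means Named numeric of training imputation means.
#' @return Samples x genes matrix.
#' @export
apply_nf_features <- function(profiles, genes, impute_means) {
  if (is.data.frame(profiles)) {
    profiles <- split(profiles[, c("gene_id", "nf")], profiles$sample_id)
  }
  mat <- do.call(rbind, purrr::map(profiles, function(p) {
    p$nf[match(genes, p$gene_id)]
  }))
  rownames(mat) <- names(profiles)
  colnames(mat) <- genes
  for (j in seq_along(genes)) {
    mat[is.na(mat[, j]), j] <- impute_means[[genes[j]]]
  }
  mat
}
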