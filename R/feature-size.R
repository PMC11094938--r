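#' Short/long fragment length classes
#'
#' The published intervals ("short [130,177], long [177,237]") overlap at
#' 177 bp; they are resolved here to short = [130, 177) and long = [177, 237]
#' so the classes partition and no fragment is double-counted.
#'
#' @param short_min,short_max Short class: `short_min <= length < short_max`.
#' @param long_max Long class: `short_max <= length <= long_max`.
#' @return A list of class `size_bounds`.
#' @export
size_bounds <- function(short_min = 130, short_max = 177, long_max = 237) {
  stopifnot(short_min < short_max, short_max <= long_max)
  structure(list(short_min = short_min, short_max = short_max,
                 long_max = long_max), class = "size_bounds")
}

#' Per-bin short and long fragment counts
#'
#' Assigns each fragment to at most one genomic bin by its midpoint (so
#' straddlers are never double-counted) and at most one length class per
#' [size_bounds()]; fragments outside both classes or outside every bin are
#' ignored.
#'
#' @param fragments Fragment tibble.
#' @param bins Bin tibble from [tile_bins()], [load_bins()] or [delfi_bins()].
#' @param bounds A [size_bounds()].
#' @return Tibble with one row per bin: `bin`, `chrom`, `start`, `end`,
#'   `short`, `long`, `total`.
#' @export
count_size_classes <- function(fragments, bins, bounds = size_bounds()) {
  assert_fragments(fragments)
  if (!is.data.frame(bins) || nrow(bins) == 0) abort("`bins` must be non-empty")
  len <- frag_lengths(fragments)
  is_short <- len >= bounds$short_min & len < bounds$short_max
  is_long <- len >= bounds$short_max & len <= bounds$long_max
  keep <- is_short | is_long
  mid <- floor((fragments$start + fragments$end) / 2)[keep]
  chrom <- fragments$chrom[keep]
  is_short <- is_short[keep]

  bin_of <- rep(NA_integer_, length(mid))
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    on_ch <- which(chrom == ch)
    if (length(on_ch) == 0) next
    idx <- findInterval(mid[on_ch], b$start)
    inside <- idx >= 1 & idx <= nrow(b) & mid[on_ch] < b$end[pmax(idx, 1)]
    bin_of[on_ch[inside]] <- b$bin[idx[inside]]
  }
  hit <- !is.na(bin_of)
  short_ct <- tabulate(bin_of[hit & is_short] + 1L, nbins = nrow(bins))
  long_ct <- tabulate(bin_of[hit & !is_short] + 1L, nbins = nrow(bins))
  out <- bins[, c("bin", "chrom", "start", "end")]
  out$short <- short_ct[out$bin + 1L]
  out$long <- long_ct[out$bin + 1L]
  out$total <- out$short + out$long
  out
}

zstd <- function(x) {
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) rep(0, length(x)) else (x - mu) / sd_pop
}

#' Z-scored fragmentation feature vector
#'
#' Standardizes the short and total per-bin coverage vectors independently
#' within the sample (population SD across bins) and concatenates them,
#' yielding a `2 * B` feature vector — 1008 features on the shipped 504-bin
#' scaffold. Per-sample standardization is what makes the feature usable on
#' a single sample at prediction time and invariant to sequencing depth.
#'
#' @param profile Output of [count_size_classes()].
#' @return Named numeric vector `short_z_<bin>`, `total_z_<bin>`.
#' @export
zscore_profile <- function(profile) {
  stopifnot(all(c("bin", "short", "total") %in% names(profile)))
  if (nrow(profile) < 2) abort("need at least 2 bins to standardize")
  prof <- arrange(profile, .data$bin)
  stats::setNames(c(zstd(prof$short), zstd(prof$total)),
                  c(sprintf("short_z_%04d", prof$bin),
                    sprintf("total_z_%04d", prof$bin)))
}

#' Fragment-size feature vector for one sample
#'
#' Convenience wrapper: counts size classes over `bins` and returns the
#' z-scored concatenated feature vector. Fragment-length bounds for this
#' feature (`[130, 237]` within otherwise-qualified fragments) are applied by
#' `bounds`, independent of the global insert-size QC rule.
#'
#' @inheritParams count_size_classes
#' @return Named numeric vector of length `2 * nrow(bins)`.
#' @export
fragment_size_features <- function(fragments, bins, bounds = size_bounds()) {
  zscore_profile(count_size_classes(fragments, bins, bounds))
}

#' Fragment length frequency distribution
#'
#' Empirical length distribution of (diagnostic-range) fragments, the raw
#' material of the size-profile figures: modal peak near 166 bp and the
#' ~10-bp sub-nucleosomal comb below 160 bp.
#'
#' @param fragments Fragment tibble.
#' @param range Inclusive length range retained for the diagnostic
#'   (default `c(90, 600)`, wider than the strict QC floor so sub-150-bp
#'   structure stays visible).
#' @return Tibble `length`, `n`, `frequency` over every length in `range`.
#' @export
size_distribution <- function(fragments, range = c(90, 600)) {
  assert_fragments(fragments)
  len <- frag_lengths(fragments)
  len <- len[len >= range[1] & len <= range[2]]
  grid <- seq(range[1], range[2])
  n <- tabulate(match(len, grid), nbins = length(grid))
  tibble(length = grid, n = n,
         frequency = if (sum(n) > 0) n / sum(n) else rep(0, length(n)))
}

#' Modal fragment length
#'
#' @param fragments Fragment tibble.
#' @param range Length range searched (default mono-nucleosome neighborhood).
#' @return The most frequent fragment length (smallest on ties).
#' @export
modal_length <- function(fragments, range = c(90, 600)) {
  d <- size_distribution(fragments, range)
  d$length[which.max(d$n)]
}
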