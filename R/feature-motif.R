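#' End-motif extraction settings
#'
#' The codon end motif reads three 3-bp motifs at 1-based offsets 1, 4 and 7
#' of the informative part of each fragment 5' end. `umi_offset` skips bases
#' whose apparent sequence is perturbed by UMI library chemistry: the study
#' design makes the 6th base the 1st informative position, i.e. an offset of
#' 5; UMI-free libraries (including the synthetic cohorts generated here)
#' use 0.
#'
#' @param umi_offset Bases skipped at each 5' end (>= 0).
#' @param positions 1-based motif start offsets within the informative window.
#' @param width Motif width in bp.
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(umi_offset = 5, positions = c(1, 4, 7), width = 3) {
  stopifnot(umi_offset >= 0, width >= 1, all(positions >= 1))
  structure(list(umi_offset = umi_offset, positions = positions, width = width),
            class = "motif_config")
}

motif_alphabet <- function(width) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), width),
                              stringsAsFactors = FALSE)[, width:1, drop = FALSE])
}

# Both 5'-end windows of each fragment, read 5'->3' on their own strands:
# left = reference[start, start+window), right = revcomp(reference[end-window, end)).
# Fragments whose windows leave the chromosome are dropped (count attached).
end_windows <- function(fragments, genome, window_bp) {
  clen <- chrom_length(genome, fragments$chrom)
  ok <- fragments$start + window_bp <= clen & fragments$end - window_bp >= 0 &
    fragments$end <= clen & fragments$start >= 0
  frag <- fragments[ok, , drop = FALSE]
  left <- fetch_ranges(genome, frag$chrom, frag$start, frag$start + window_bp)
  right <- Biostrings::reverseComplement(
    fetch_ranges(genome, frag$chrom, frag$end - window_bp, frag$end))
  list(left = left, right = right, keep = ok, n_skipped = sum(!ok))
}

#' 5'-end sequences of a fragment
#'
#' Returns the two 5'-end windows of each fragment read from the reference:
#' the left end as-is and the right end reverse-complemented, both 5'->3' on
#' their respective strands. Fragments whose windows would cross a
#' chromosome edge are skipped, with the count in attribute `n_skipped`.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_bundle`.
#' @param window_bp Window width in bp.
#' @return Tibble `chrom`, `start`, `end`, `left`, `right`.
#' @export
fragment_end_sequences <- function(fragments, genome, window_bp) {
  assert_fragments(fragments)
  ew <- end_windows(fragments, genome, window_bp)
  kept <- fragments[ew$keep, , drop = FALSE]
  out <- tibble(chrom = kept$chrom, start = kept$start, end = kept$end,
                left = unname(as.character(ew$left)),
                right = unname(as.character(ew$right)))
  attr(out, "n_skipped") <- ew$n_skipped
  out
}

count_motifs_at <- function(ends, offset0, width, alphabet) {
  m <- substr(ends, offset0 + 1, offset0 + width)
  m <- m[!grepl("[^ACGT]", m)]
  ct <- tabulate(match(m, alphabet), nbins = length(alphabet))
  stats::setNames(ct, alphabet)
}

#' Codon end-motif profile
#'
#' Counts, at each configured position of both 5' ends of every fragment,
#' the `width`-bp reference motif after skipping `umi_offset` bases, and
#' normalizes counts to frequencies independently within each position block
#' (three separate 64-simplexes at defaults, 192 features in total). Motifs
#' containing non-ACGT bases are skipped per position.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_bundle`.
#' @param cfg A [motif_config()].
#' @return Tibble `position` (1-based block start), `motif`, `count`,
#'   `frequency`, ordered by (position, motif); `frequency` sums to 1 within
#'   each position block when any motif was counted.
#' @export
count_codon_motifs <- function(fragments, genome, cfg = motif_config()) {
  assert_fragments(fragments)
  window <- cfg$umi_offset + max(cfg$positions) + cfg$width - 1
  ew <- end_windows(fragments, genome, window)
  ends <- c(as.character(ew$left), as.character(ew$right))
  alphabet <- motif_alphabet(cfg$width)
  purrr::map_dfr(cfg$positions, function(p) {
    ct <- count_motifs_at(ends, cfg$umi_offset + p - 1, cfg$width, alphabet)
    tot <- sum(ct)
    tibble(position = p, motif = alphabet, count = as.integer(ct),
           frequency = if (tot > 0) unname(ct / tot) else rep(0, length(ct)))
  })
}

#' Codon end-motif feature vector
#'
#' @inheritParams count_codon_motifs
#' @return Named numeric frequency vector (`pos<k>_<motif>`), length
#'   `length(positions) * 4^width` (192 at defaults).
#' @export
end_motif_features <- function(fragments, genome, cfg = motif_config()) {
  prof <- count_codon_motifs(fragments, genome, cfg)
  stats::setNames(prof$frequency, sprintf("pos%d_%s", prof$position, prof$motif))
}

#' Plain k-mer end-motif frequencies
#'
#' The single-motif alternative (4-bp and 6-bp end motifs in the wider
#' literature): one k-mer read at the first informative position of both 5'
#' ends, normalized to a `4^k` frequency vector.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_bundle`.
#' @param k Motif width (1-8).
#' @param umi_offset Bases skipped at each end.
#' @return Tibble `motif`, `count`, `frequency` with `4^k` rows.
#' @export
count_kmer_end_motifs <- function(fragments, genome, k = 4, umi_offset = 0) {
  stopifnot(k >= 1, k <= 8)
  assert_fragments(fragments)
  ew <- end_windows(fragments, genome, umi_offset + k)
  ends <- c(as.character(ew$left), as.character(ew$right))
  alphabet <- motif_alphabet(k)
  ct <- count_motifs_at(ends, umi_offset, k, alphabet)
  tot <- sum(ct)
  tibble(motif = alphabet, count = as.integer(ct),
         frequency = if (tot > 0) unname(ct / tot) else rep(0, length(ct)))
}

#' Per-position GC content of fragment 5' ends
#'
#' Fraction of fragment ends carrying G or C at each of the first `max_pos`
#' positions of the 5'-end sequence — the diagnostic that shows how far into
#' the fragment the end-composition bias extends.
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_bundle`.
#' @param max_pos Number of end positions profiled.
#' @return Tibble `position` (1-based), `gc_fraction`.
#' @export
end_gc_content <- function(fragments, genome, max_pos = 20) {
  stopifnot(max_pos >= 1)
  assert_fragments(fragments)
  ew <- end_windows(fragments, genome, max_pos)
  ends <- c(as.character(ew$left), as.character(ew$right))
  mat <- matrix(unlist(strsplit(ends, "")), ncol = max_pos, byrow = TRUE)
  gc <- colMeans(mat == "G" | mat == "C")
  tibble(position = seq_len(max_pos), gc_fraction = gc)
}

#' Cross-sample correlation of base occurrence around fragment starts
#'
#' For each sample, computes the frequency of each base at reference
#' positions `-flank .. +flank` relative to the fragment 5' start (position 0
#' = first fragment base, negative positions upstream on the reference), then
#' returns the Pearson correlation matrix of those frequencies across
#' samples, averaged over the four bases. Adjacent positions correlating more
#' strongly than distant ones is what motivates splitting a long end motif
#' into short adjacent blocks.
#'
#' @param fragments_by_sample Fragment tibble with a `sample_id` column, or a
#'   named list of fragment tibbles.
#' @param genome A `genome_bundle`.
#' @param flank Positions profiled on each side of the start.
#' @return A `(2*flank+1) x (2*flank+1)` correlation matrix with position
#'   labels; entries are `NA` where a position has zero variance.
#' @export
base_occurrence_correlation <- function(fragments_by_sample, genome, flank = 10) {
  if (is.data.frame(fragments_by_sample)) {
    stopifnot("sample_id" %in% names(fragments_by_sample))
    fragments_by_sample <- split(fragments_by_sample,
                                 fragments_by_sample$sample_id)
  }
  stopifnot(length(fragments_by_sample) >= 2)
  positions <- seq(-flank, flank)
  freq <- purrr::map(fragments_by_sample, function(frag) {
    clen <- chrom_length(genome, frag$chrom)
    ok <- frag$start - flank >= 0 & frag$start + flank + 1 <= clen
    frag <- frag[ok, , drop = FALSE]
    seqs <- as.character(fetch_ranges(genome, frag$chrom, frag$start - flank,
                                      frag$start + flank + 1))
    mat <- matrix(unlist(strsplit(seqs, "")), ncol = length(positions),
                  byrow = TRUE)
    vapply(c("A", "C", "G", "T"),
           function(b) colMeans(mat == b),
           numeric(length(positions)))  # positions x base
  })
  # per base: samples x positions matrix -> correlation across samples
  cors <- purrr::map(1:4, function(bi) {
    m <- do.call(rbind, purrr::map(freq, ~ .x[, bi]))
    suppressWarnings(stats::cor(m))
  })
  avg <- Reduce(`+`, purrr::map(cors, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, purrr::map(cors, function(m) (!is.na(m)) * 1))
  dimnames(avg) <- list(positions, positions)
  avg
}
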