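# One-chromosome genome with a known sequence for hand-checkable motifs.
seq_genome <- function(s, name = "chr1") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), s), fa)
  load_genome(fa)
}

test_that("fragment end sequences read 5'->3' on each strand", {
  g <- seq_genome("GTTACAGGCT")
  frag <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  es <- fragment_end_sequences(frag, g, 3)
  expect_equal(es$left, "GTT")
  expect_equal(es$right, "AGC")  # revcomp of GCT
  # palindromic end windows give identical left/right reads
  gp <- seq_genome("ACGTTTTTACGT")
  esp <- fragment_end_sequences(tibble::tibble(chrom = "chr1", start = 0,
                                               end = 12), gp, 4)
  expect_equal(esp$left, esp$right)
  # window past the chromosome edge skips the fragment with a tally
  es2 <- fragment_end_sequences(tibble::tibble(chrom = "chr1", start = 8,
                                               end = 10), g, 3)
  expect_equal(nrow(es2), 0)
  expect_equal(attr(es2, "n_skipped"), 1)
})

test_that("codon motifs are read at offsets 1, 4, 7 with the UMI offset applied", {
  # left end GTTACAGGC...; make the right end identical by reverse-complement
  left9 <- "GTTACAGGC"
  g <- seq_genome(paste0(left9, "AAAAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(left9)))))
  frag <- tibble::tibble(chrom = "chr1", start = 0, end = 23)
  prof <- count_codon_motifs(frag, g, motif_config(umi_offset = 0))
  expect_equal(nrow(prof), 192)
  expect_equal(prof$frequency[prof$position == 1 & prof$motif == "GTT"], 1)
  expect_equal(prof$frequency[prof$position == 4 & prof$motif == "ACA"], 1)
  expect_equal(prof$frequency[prof$position == 7 & prof$motif == "GGC"], 1)
  expect_equal(sum(prof$frequency), 3)

  # a 5-bp UMI prefix at both ends leaves the offset-5 profile unchanged
  g2 <- seq_genome(paste0("NNNNN", left9, "AAAAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(left9))), "NNNNN"))
  prof2 <- count_codon_motifs(tibble::tibble(chrom = "chr1", start = 0,
                                             end = 33),
                              g2, motif_config(umi_offset = 5))
  expect_equal(prof2$frequency, prof$frequency)
})

test_that("profiles of pooled fragment sets are count-weighted averages", {
  g <- toy_genome()
  set.seed(11)
  mk <- function(n) {
    start <- sample(100:5000, n)
    tibble::tibble(chrom = "chr1", start = start, end = start + 166)
  }
  a <- mk(40); b <- mk(60)
  cfg <- motif_config(umi_offset = 0)
  pa <- count_codon_motifs(a, g, cfg)
  pb <- count_codon_motifs(b, g, cfg)
  pab <- count_codon_motifs(dplyr::bind_rows(a, b), g, cfg)
  expect_equal(pab$count, pa$count + pb$count)
  block_tot <- rep(as.numeric(tapply(pab$count, pab$position, sum)), each = 64)
  expect_equal(pab$frequency, pab$count / block_tot)
  # per-position blocks each sum to 1
  expect_equal(as.numeric(tapply(pab$frequency, pab$position, sum)), rep(1, 3))
})

test_that("left and right motif counts agree on a revcomp-closed fragment set", {
  g <- toy_genome()
  set.seed(5)
  start <- sample(100:4000, 20)
  frag <- tibble::tibble(chrom = "chr1", start = start, end = start + 180)
  # the set is closed under reverse complement by construction of the
  # extractor: brute-force compare left-end counts with right-end counts of
  # the mirrored set (same fragments; right end of f is left end of revcomp(f))
  es <- fragment_end_sequences(frag, g, 3)
  left_counts <- table(substr(es$left, 1, 3))
  right_counts <- table(substr(es$right, 1, 3))
  both <- count_codon_motifs(frag, g, motif_config(umi_offset = 0,
                                                   positions = 1))
  expected <- rep(0L, 64)
  names(expected) <- both$motif
  expected[names(left_counts)] <- expected[names(left_counts)] + left_counts
  expected[names(right_counts)] <- expected[names(right_counts)] + right_counts
  expect_equal(both$count, unname(as.integer(expected)))
})

test_that("plain k-mer motifs normalize and match the codon position-1 block", {
  g <- toy_genome()
  set.seed(6)
  start <- sample(100:4000, 30)
  frag <- tibble::tibble(chrom = "chr1", start = start, end = start + 170)
  k4 <- count_kmer_end_motifs(frag, g, k = 4)
  expect_equal(nrow(k4), 256)
  expect_equal(sum(k4$frequency), 1)
  k3 <- count_kmer_end_motifs(frag, g, k = 3)
  codon <- count_codon_motifs(frag, g, motif_config(umi_offset = 0))
  expect_equal(k3$frequency, codon$frequency[codon$position == 1])
})

test_that("end GC content flags composition bias confined to the biased window", {
  sc <- small_cohort()
  g <- sc$art$genome
  frag <- sc$cohort$samples[[1]]
  gc <- end_gc_content(frag, g, max_pos = 12)
  expect_equal(nrow(gc), 12)
  expect_true(all(gc$gc_fraction > 0.2 & gc$gc_fraction < 0.65))
  # all-G genome gives GC fraction 1 everywhere
  gg <- seq_genome(strrep("G", 2000))
  frag2 <- tibble::tibble(chrom = "chr1", start = c(100, 300), end = c(260, 470))
  expect_equal(end_gc_content(frag2, gg, 5)$gc_fraction, rep(1, 5))
})

test_that("base occurrence correlations are strongest at adjacent positions", {
  sc <- small_cohort()
  m <- base_occurrence_correlation(sc$cohort$samples[1:8], sc$art$genome,
                                   flank = 6)
  expect_equal(dim(m), c(13, 13))
  expect_equal(unname(diag(m)), rep(1, 13), tolerance = 1e-9)
  expect_equal(m, t(m), tolerance = 1e-12)
  off <- row(m) - col(m)
  adj <- mean(m[abs(off) == 1])
  far <- mean(m[abs(off) >= 5])
  expect_gt(adj, far)
})

test_that("planted differential motifs come out elevated in the cancer mean profile", {
  sc <- small_cohort()
  cfgm <- motif_config(umi_offset = 0)
  profs <- purrr::imap(sc$cohort$samples, function(s, id) {
    p <- count_codon_motifs(s, sc$art$genome, cfgm)
    p$sample_id <- id
    p
  })
  long <- dplyr::bind_rows(profs)
  long$cancer <- sc$cohort$truth$label[match(long$sample_id,
                                             sc$cohort$truth$sample_id)] != "non-cancer"
  mean_freq <- function(pos, motif, cancer) {
    mean(long$frequency[long$position == pos & long$motif == motif &
                          long$cancer == cancer])
  }
  for (m in list(c(7, "ACA"), c(4, "ATG"), c(1, "AAG"))) {
    expect_gt(mean_freq(as.integer(m[1]), m[2], TRUE),
              mean_freq(as.integer(m[1]), m[2], FALSE))
  }
  for (m in list(c(1, "GTT"), c(1, "GTC"), c(7, "GTC"))) {
    expect_lt(mean_freq(as.integer(m[1]), m[2], TRUE),
              mean_freq(as.integer(m[1]), m[2], FALSE))
  }
})
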