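test_that("genome simulation is seeded, bounded and composition-faithful", {
  cfg <- cohort_config(seed = 7, n_genes = 100, chrom_length = 3e5)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  a1 <- simulate_genome(cfg, dir = d1)
  a2 <- simulate_genome(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  # annotation windows all in bounds with non-overlapping +/-2 kb regions
  genes <- a1$genes
  expect_true(all(genes$tss - 2000 >= 0 &
                    genes$tss + 2000 < chrom_length(a1$genome, genes$chrom)))
  by_ch <- split(genes, genes$chrom)
  expect_true(all(vapply(by_ch, function(g) {
    all(diff(sort(g$tss)) > 4000)
  }, logical(1))))
  # stationary GC close to the configured value (3 sigma on 600 kb)
  seqs <- get_sequence(a1$genome, "chr1", 0, 3e5)
  gc <- mean(strsplit(seqs, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - cfg$gc), 3 * sqrt(0.25 / 3e5) / 0.9 + 0.01)
  # reloading the written FASTA reproduces the in-memory genome
  g2 <- load_genome(file.path(d1, "genome.fa"))
  expect_equal(get_sequence(g2, "chr1", 100, 200),
               get_sequence(a1$genome, "chr1", 100, 200))
})

test_that("per-sample simulation is deterministic and class-aware", {
  sc <- small_cohort()
  s1 <- simulate_sample(sc$art, "non-cancer", sc$cfg, seed = 123, n = 3000)
  s2 <- simulate_sample(sc$art, "non-cancer", sc$cfg, seed = 123, n = 3000)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 3000)
  expect_true(all(s1$end <= chrom_length(sc$art$genome, s1$chrom)))
  expect_error(simulate_sample(sc$art, "lung", sc$cfg, seed = 1), "unknown class")
})

test_that("control samples peak at the configured mono-nucleosome mode", {
  sc <- small_cohort()
  s <- simulate_sample(sc$art, "non-cancer", sc$cfg, seed = 400, n = 50000)
  expect_lte(abs(modal_length(s) - 166), 2)
  # pooled controls agree
  pooled <- dplyr::bind_rows(
    sc$cohort$samples[sc$cohort$truth$label == "non-cancer"])
  expect_lte(abs(modal_length(pooled) - 166), 2)
})

test_that("the sub-nucleosomal comb spaces local maxima about 10 bp apart", {
  sc <- small_cohort()
  pooled <- dplyr::bind_rows(sc$cohort$samples)
  d <- size_distribution(pooled, range = c(90, 170))
  peaks <- comb_peaks(d)
  expect_gte(length(peaks), 3)
  expect_true(all(abs(diff(peaks) - 10) <= 1))
})

test_that("cancer size shift and TSS depletion limit behave as planted", {
  sc <- small_cohort()
  # a 0.2 short-fraction boost against a 0 control, other effects unchanged
  cfg <- cohort_config(seed = sc$cfg$seed, n_per_class = sc$cfg$n_per_class,
                       short_boost = 0.2)
  ctrl <- simulate_sample(sc$art, "non-cancer", cfg, seed = 55, n = 15000)
  canc <- simulate_sample(sc$art, "PAC", cfg, seed = 56, n = 15000)
  # directional: boosted short fraction drags the mean down (3 sigma apart)
  se <- sqrt(var(ctrl$length) / 15000 + var(canc$length) / 15000)
  expect_lt(mean(canc$length), mean(ctrl$length) - 3 * se)
  # full depletion kills central coverage
  cfg_full <- cohort_config(seed = cfg$seed, depletion_depth = 1,
                            n_per_class = cfg$n_per_class)
  art_full <- sc$art
  s <- simulate_sample(art_full, "non-cancer", cfg_full, seed = 60, n = 20000)
  expr <- art_full$expression[["non-cancer"]]
  strong <- which(expr >= 0.99)
  if (length(strong) > 0) {
    nf <- nf_profile(s, art_full$genes)
    expect_lt(mean(nf$central_mean[strong]), 0.2 * mean(nf$reference_mean[strong]))
  }
})

test_that("cohort simulation reproduces shape, CA19-9 strata and determinism", {
  cfg <- cohort_config(seed = 13,
                       n_per_class = c("non-cancer" = 3, CCA = 2, GBC = 2,
                                       PAC = 2),
                       fragments_per_sample = 500)
  co1 <- simulate_cohort(cfg, prefix = "t")
  expect_equal(nrow(co1$truth), 9)
  expect_equal(as.integer(table(co1$truth$label)[c("non-cancer", "CCA", "GBC",
                                                   "PAC")]),
               c(3L, 2L, 2L, 2L))
  co2 <- simulate_cohort(cfg, prefix = "t")
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$samples, co2$samples)

  # Lewis-negative probability 0 with a far-above-cutoff mean puts every
  # cancer over the clinical threshold
  cfg_hi <- cohort_config(seed = 13,
                          n_per_class = c("non-cancer" = 2, PAC = 20),
                          fragments_per_sample = 200,
                          ca19_9_meanlog = c("non-cancer" = log(5),
                                             CCA = log(5000), GBC = log(5000),
                                             PAC = log(5000)),
                          ca19_9_sdlog = c("non-cancer" = 0.3, CCA = 0.3,
                                           GBC = 0.3, PAC = 0.3),
                          lewis_negative_prob = 0)
  co3 <- simulate_cohort(cfg_hi, prefix = "h")
  expect_true(all(co3$truth$ca19_9[co3$truth$label == "PAC"] > 39))
})
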