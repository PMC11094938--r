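# Shared fixtures, built once per test run and cached.
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Deterministic toy genome: chr1 10 kb with an N-run at [6000, 6050),
# chr2 8 kb, chrX 2 kb (non-autosome), written to FASTA once per run.
toy_genome <- function() {
  fixture("toy_genome", function() {
    set.seed(20240501)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    chr1 <- mk(10000)
    substr(chr1, 6001, 6050) <- strrep("N", 50)
    seqs <- c(chr1 = chr1, chr2 = mk(8000), chrX = mk(2000))
    fa <- file.path(tempdir(), "toy_genome.fa")
    writeLines(unlist(lapply(names(seqs), function(ch) c(paste0(">", ch), seqs[[ch]]))),
               fa)
    load_genome(fa)
  })
}

# 50 read pairs spanning every QC rule, written as SAM and converted to BAM.
# Returns the BAM path and the per-pair truth table used by the brute-force
# oracle in the QC tests.
sam_fixture <- function() {
  fixture("sam_fixture", function() {
    g <- toy_genome()
    set.seed(99)
    n <- 50
    category <- sample(c("good", "low_mapq", "short", "long", "improper",
                         "sex_chrom", "n_run", "duplicate"),
                       n, replace = TRUE,
                       prob = c(0.4, 0.1, 0.08, 0.08, 0.1, 0.08, 0.08, 0.08))
    rl <- 60L
    truth <- lapply(seq_len(n), function(i) {
      cat_i <- category[i]
      chrom <- if (cat_i == "sex_chrom") "chrX" else sample(c("chr1", "chr2"), 1)
      L <- switch(cat_i,
                  short = sample(100:149, 1),
                  long = sample(601:700, 1),
                  sample(150:450, 1))
      lim <- c(chr1 = 10000, chr2 = 8000, chrX = 2000)[[chrom]]
      start <- if (cat_i == "n_run") {
        chrom <- "chr1"
        sample(5980:5999, 1)           # interval overlaps the N-run
      } else if (chrom == "chr1") {
        sample(c(0:5300, 6100:(lim - L - 1)), 1)  # avoid the N-run
      } else {
        sample(0:(lim - L - 1), 1)
      }
      mapq <- if (cat_i == "low_mapq") sample(c(0, 10, 20), 2, TRUE)
              else sample(30:60, 2, TRUE)
      list(qname = sprintf("p%03d", i), chrom = chrom, start = start, L = L,
           mapq1 = mapq[1], mapq2 = mapq[2],
           proper = cat_i != "improper", dup = cat_i == "duplicate")
    })
    sam <- file.path(tempdir(), "fixture.sam")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             "@SQ\tSN:chr1\tLN:10000", "@SQ\tSN:chr2\tLN:8000",
             "@SQ\tSN:chrX\tLN:2000")
    recs <- unlist(lapply(truth, function(p) {
      f1 <- 0x1 + 0x20 + 0x40 + if (p$proper) 0x2 else 0
      f2 <- 0x1 + 0x10 + 0x80 + if (p$proper) 0x2 else 0
      if (p$dup) { f1 <- f1 + 0x400; f2 <- f2 + 0x400 }
      p1 <- p$start + 1
      p2 <- p$start + p$L - rl + 1
      seqq <- strrep("A", rl); qual <- strrep("I", rl)
      c(paste(p$qname, f1, p$chrom, p1, p$mapq1, paste0(rl, "M"), "=",
              p2, p$L, seqq, qual, sep = "\t"),
        paste(p$qname, f2, p$chrom, p2, p$mapq2, paste0(rl, "M"), "=",
              p1, -p$L, seqq, qual, sep = "\t"))
    }))
    writeLines(c(hdr, recs), sam)
    bam <- Rsamtools::asBam(sam, file.path(tempdir(), "fixture"),
                            overwrite = TRUE)
    list(bam = bam,
         truth = dplyr::bind_rows(lapply(truth, tibble::as_tibble)))
  })
}

# Small cohort with strong default effects: 10 non-cancer vs 10 PAC,
# featurized; shared by model and evaluation unit tests.
small_cohort <- function() {
  fixture("small_cohort", function() {
    cfg <- cohort_config(seed = 7,
                         n_per_class = c("non-cancer" = 10, PAC = 10),
                         fragments_per_sample = 12000)
    art <- simulate_genome(cfg)
    cohort <- simulate_cohort(cfg, art, prefix = "s")
    feats <- featurize_cohort(cohort)
    list(cfg = cfg, art = art, cohort = cohort, feats = feats)
  })
}

# Full-shape strong-effect study (89 training / 129 validation) with trained
# stacked and CF models; the expensive fixture behind the signal-recovery
# and phenomenology acceptance checks.
strong_study <- function() {
  fixture("strong_study", function() {
    cfg <- cohort_config(seed = 101)
    study <- simulate_study(cfg)
    ftr <- featurize_cohort(study$training)
    fva <- featurize_cohort(study$validation, nf_fit = ftr$nf_fit)
    stacked <- train_stacked(ftr, seed = 101)
    cf <- train_cf(ftr, stacked, seed = 101)
    pred_va <- predict(stacked, fva)
    list(cfg = cfg, study = study, ftr = ftr, fva = fva,
         stacked = stacked, cf = cf, pred_va = pred_va)
  })
}

# Local maxima of a length histogram over a +/-3 bp neighborhood, above a
# small prominence floor — robust to shot noise on the mono-nucleosome
# shoulder.
comb_peaks <- function(dist, below = 160, window = 3, floor_frac = 0.02) {
  n <- dist$n
  is_peak <- vapply(seq_along(n), function(i) {
    lo <- max(1, i - window); hi <- min(length(n), i + window)
    n[i] == max(n[lo:hi]) && sum(n[lo:hi] == n[i]) == 1 &&
      n[i] > max(n) * floor_frac
  }, logical(1))
  peaks <- dist$length[is_peak]
  peaks[peaks < below]
}

null_config <- function(seed = 42) {
  cohort_config(seed = seed,
                n_per_class = c("non-cancer" = 60, CCA = 20, GBC = 20, PAC = 20),
                short_boost = 0, bin_amplitude = 0, cnv_amplitude = 0,
                motif_effect = 0, nf_effect = 0, subtype_nf_effect = 0)
}
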