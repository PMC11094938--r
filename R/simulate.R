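CANCER_CLASSES <- c("CCA", "GBC", "PAC")
ALL_CLASSES <- c("non-cancer", CANCER_CLASSES)

#' Synthetic-cohort generative settings
#'
#' One object holds every per-class generative parameter of the simulator:
#' the genome (size, base composition, first-order base dependence), the
#' fragment-length mixture (mono-nucleosome peak at 166 bp, a sub-nucleosomal
#' component with a 10-bp comb below 160 bp, a small di-nucleosome shoulder),
#' the planted class effects in each feature family, and the per-class
#' CA19-9 model with a Lewis-negative cancer subset whose secretion is forced
#' low. Defaults mirror the study conditions: training cohort of 89 samples
#' (31 non-cancer, 16 CCA, 14 GBC, 28 PAC), per-sample depth of 20,000
#' fragments on a 1.2-Mb two-chromosome genome (about 2.8x coverage, the
#' order of the study's low-coverage sequencing), and "strong" effects in all
#' three families.
#'
#' Class effects, all zeroable for null cohorts:
#' * `short_boost` — extra sub-nucleosomal mixture weight in cancer (global
#'   leftward size shift);
#' * `bin_amplitude` — bin-structured modulation of the short-fragment weight
#'   (a fixed per-class regional fragmentation profile; the within-sample
#'   z-scoring of the size feature removes purely global shifts, so regional
#'   structure is what that feature detects);
#' * `cnv_amplitude` — bin-structured modulation of fragment density
#'   (copy-number-like signal in the total-coverage vector);
#' * `motif_effect` — log-scale acceptance weights planting six signature
#'   end motifs (1-GTT, 1-GTC, 7-GTC down; 7-ACA, 4-ATG, 1-AAG up in cancer);
#' * `nf_effect` — expression level given to a cancer-specific gene program
#'   (silent in non-cancer), depleting TSS coverage via `depletion_depth`.
#'   The default (0.75, about a 35-50% NF reduction at planted genes) keeps
#'   per-gene effects moderate, as in real nucleosome-footprint data, which
#'   is what makes the NF feature family the most depth-sensitive one;
#' * `subtype_nf_effect` — expression of per-subtype gene sets, the planted
#'   tissue-of-origin signal.
#'
#' @param seed Root seed; all randomness derives from it.
#' @param n_per_class Named integer vector over
#'   `c("non-cancer", "CCA", "GBC", "PAC")`.
#' @param fragments_per_sample Qualified fragments generated per sample.
#' @param n_chroms,chrom_length,gc,markov_strength Genome shape: chromosome
#'   count and length (bp), stationary GC fraction, and probability that a
#'   base copies its left neighbor (drives adjacent-position base
#'   correlation).
#' @param n_genes,expressed_fraction,depletion_depth TSS annotation size,
#'   fraction of genes expressed in all classes, and maximal central-window
#'   thinning probability for a fully expressed gene.
#' @param n_cancer_genes,nf_effect Size and expression level of the
#'   pan-cancer gene program.
#' @param n_subtype_genes,subtype_nf_effect Size and expression level of each
#'   cancer subtype's private gene set.
#' @param mono_mean,mono_sd,sub_weight,comb_period,comb_sd,di_weight,di_mean,di_sd
#'   Fragment-length mixture parameters (bp).
#' @param short_boost,bin_amplitude,cnv_amplitude,motif_effect Class effect
#'   magnitudes (see above), applied to cancer classes only.
#' @param size_bin_width Width of the naive genomic bins tiled on the
#'   synthetic genome for the size feature.
#' @param ca19_9_meanlog,ca19_9_sdlog Named per-class log-normal parameters
#'   (U/mL scale).
#' @param lewis_negative_prob Probability that a cancer sample is
#'   Lewis-antigen negative (CA19-9 drawn low regardless of class).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    seed = 1L,
    n_per_class = c("non-cancer" = 31, CCA = 16, GBC = 14, PAC = 28),
    fragments_per_sample = 20000,
    n_chroms = 2, chrom_length = 6e5, gc = 0.41, markov_strength = 0.25,
    n_genes = 120, expressed_fraction = 0.5, depletion_depth = 0.7,
    n_cancer_genes = 10, nf_effect = 0.75,
    n_subtype_genes = 8, subtype_nf_effect = 0.45,
    mono_mean = 166, mono_sd = 9, sub_weight = 0.13,
    comb_period = 10, comb_sd = 1.5,
    di_weight = 0.03, di_mean = 332, di_sd = 25,
    short_boost = 0.06, bin_amplitude = 0.5, cnv_amplitude = 0.08,
    motif_effect = 0.4,
    size_bin_width = 5e4,
    ca19_9_meanlog = c("non-cancer" = log(8), CCA = log(70),
                       GBC = log(150), PAC = log(180)),
    ca19_9_sdlog = c("non-cancer" = 0.8, CCA = 1.6, GBC = 1.5, PAC = 1.6),
    lewis_negative_prob = 0.08) {
  stopifnot(all(names(n_per_class) %in% ALL_CLASSES),
            all(n_per_class >= 0), fragments_per_sample > 0,
            markov_strength >= 0, markov_strength < 1,
            depletion_depth >= 0, depletion_depth <= 1,
            sub_weight + di_weight + short_boost < 1,
            lewis_negative_prob >= 0, lewis_negative_prob <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

# First-order Markov sequence: with prob `s` a base copies its left
# neighbor, otherwise it is an iid draw from the stationary composition.
markov_sequence <- function(n, p, s) {
  iid <- sample.int(4, n, replace = TRUE, prob = p)
  if (s > 0) {
    copy <- stats::runif(n) < s
    copy[1] <- FALSE
    anchor <- cummax(seq_len(n) * (!copy))
    iid <- iid[anchor]
  }
  c("A", "C", "G", "T")[iid]
}

#' Generate the synthetic genome, bins, annotation and truth expression
#'
#' Builds the shared coordinate scaffolds of a synthetic study: a seeded
#' Markov genome, naive fixed-width bins, a TSS annotation with
#' non-overlapping +/-2-kb windows, per-gene truth expression, and the fixed
#' per-class effect profiles (regional fragmentation/CNV bin profiles, motif
#' acceptance weights, class gene programs). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @param dir Optional directory; when given, FASTA (+ .fai), bins BED and
#'   annotation/expression TSVs are written there.
#' @return List of class `synthetic_genome`: `genome`, `bins`, `genes`,
#'   `expression` (tibble `gene_id`, per-class expression columns),
#'   `class_effects`.
#' @export
simulate_genome <- function(cfg, dir = NULL) {
  p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- withr::with_seed(derive_seed(cfg$seed, 1), {
    Biostrings::DNAStringSet(vapply(chrom_names, function(ch) {
      paste(markov_sequence(cfg$chrom_length, p, cfg$markov_strength),
            collapse = "")
    }, character(1)))
  })
  names(seqs) <- chrom_names
  genome <- structure(
    list(chroms = tibble(chrom = chrom_names,
                         length = Biostrings::width(seqs)),
         src = seqs, path = NA_character_),
    class = "genome_bundle")
  bins <- tile_bins(genome, cfg$size_bin_width)

  # non-overlapping TSS windows: fixed spacing with jitter
  margin <- 2100
  genes <- withr::with_seed(derive_seed(cfg$seed, 2), {
    per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
    purrr::map2_dfr(chrom_names, per_chrom, function(ch, k) {
      if (k == 0) return(tibble())
      usable <- cfg$chrom_length - 2 * margin
      spacing <- floor(usable / k)
      if (spacing < 2 * margin + 200) {
        abort("genome too small for requested gene count")
      }
      base <- margin + (seq_len(k) - 1) * spacing
      tss <- base + sample.int(spacing - 2 * margin, k, replace = TRUE)
      tibble(chrom = ch, tss = tss,
             strand = sample(c("+", "-"), k, replace = TRUE))
    }) |>
      mutate(gene_id = sprintf("G%04d", row_number())) |>
      select("gene_id", "chrom", "tss", "strand")
  })
  genes <- gene_annotation(genes, genome)

  effects <- withr::with_seed(derive_seed(cfg$seed, 3), {
    base_level <- ifelse(stats::runif(nrow(genes)) < cfg$expressed_fraction,
                         stats::runif(nrow(genes), 0.5, 1), 0)
    silent <- which(base_level == 0)
    need <- cfg$n_cancer_genes + 3 * cfg$n_subtype_genes
    if (length(silent) < need) {
      abort("not enough silent genes to host the class gene programs")
    }
    picks <- sample(silent, need)
    cancer_genes <- picks[seq_len(cfg$n_cancer_genes)]
    subtype_genes <- split(picks[-seq_len(cfg$n_cancer_genes)],
                           rep(CANCER_CLASSES, each = cfg$n_subtype_genes))
    program_level <- stats::runif(nrow(genes), 0.7, 1)

    # one regional fragmentation / copy-number profile shared by all cancer
    # classes: subtype differences live in the NF gene programs only, so the
    # size feature separates cancer from control but not subtype from subtype
    bin_profile <- stats::runif(nrow(bins), -1, 1)
    cnv_profile <- stats::runif(nrow(bins), -1, 1)
    list(base_level = base_level, cancer_genes = cancer_genes,
         subtype_genes = subtype_genes, program_level = program_level,
         bin_profile = bin_profile, cnv_profile = cnv_profile)
  })

  expression <- tibble(gene_id = genes$gene_id)
  for (cl in ALL_CLASSES) {
    lvl <- effects$base_level
    if (cl %in% CANCER_CLASSES) {
      lvl[effects$cancer_genes] <- cfg$nf_effect *
        effects$program_level[effects$cancer_genes]
      sg <- effects$subtype_genes[[cl]]
      lvl[sg] <- cfg$subtype_nf_effect * effects$program_level[sg]
    }
    expression[[cl]] <- pmin(lvl, 1)
  }

  # six signature motifs, planted via 5'-end acceptance weights (3 blocks x 64)
  beta <- matrix(0, nrow = 3, ncol = 64,
                 dimnames = list(NULL, motif_alphabet(3)))
  up <- list(c(3, "ACA"), c(2, "ATG"), c(1, "AAG"))
  down <- list(c(1, "GTT"), c(1, "GTC"), c(3, "GTC"))
  for (m in up) beta[as.integer(m[1]), m[2]] <- cfg$motif_effect
  for (m in down) beta[as.integer(m[1]), m[2]] <- -cfg$motif_effect

  art <- structure(list(genome = genome, bins = bins, genes = genes,
                        expression = expression,
                        class_effects = c(effects, list(motif_beta = beta))),
                   class = "synthetic_genome")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(seqs, fa)
    Rsamtools::indexFa(fa)
    art$genome$path <- fa
    readr::write_tsv(bins[, c("chrom", "start", "end")],
                     file.path(dir, "bins.bed"), col_names = FALSE)
    ann <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                  tss = genes$tss + 1, strand = genes$strand)
    readr::write_tsv(ann, file.path(dir, "genes.tsv"))
    readr::write_tsv(expression, file.path(dir, "expression.tsv"))
  }
  art
}

# Per-class expression lookup vector for thinning
class_expression <- function(artifacts, class) {
  stats::setNames(artifacts$expression[[class]], artifacts$expression$gene_id)
}

draw_lengths <- function(n, w_sub, cfg) {
  # component: 1 = mono, 2 = sub-nucleosomal comb, 3 = di-nucleosome
  u <- stats::runif(n)
  comp <- 1L + (u < w_sub + cfg$di_weight) + (u < cfg$di_weight)
  # comp: 3 if u < di, 2 if di <= u < di+sub, else 1
  len <- numeric(n)
  mono <- comp == 1L
  len[mono] <- stats::rnorm(sum(mono), cfg$mono_mean, cfg$mono_sd)
  sub <- comp == 2L
  if (any(sub)) {
    k <- sample.int(7, sum(sub), replace = TRUE, prob = exp(-(1:7 - 1) / 2.5))
    len[sub] <- stats::rnorm(sum(sub), cfg$mono_mean - cfg$comb_period * k,
                             cfg$comb_sd)
  }
  di <- comp == 3L
  len[di] <- stats::rnorm(sum(di), cfg$di_mean, cfg$di_sd)
  pmax(round(len), 60)
}

#' Simulate one sample's fragment set
#'
#' Draws aligned fragment intervals for a sample of the given class:
#' positions uniform over the genome modulated by the class CNV bin profile,
#' lengths from the class size mixture with the bin-structured short-fragment
#' weight, 5'-end composition reweighted by acceptance sampling toward the
#' class motif signature (keeping reference-based motif extraction honest —
#' the genome sequence is never rewritten), and central-TSS-window midpoints
#' rejection-thinned in proportion to `depletion_depth` times the class
#' expression of the gene. Deterministic given `seed`.
#'
#' @param artifacts A `synthetic_genome` from [simulate_genome()].
#' @param class One of `"non-cancer"`, `"CCA"`, `"GBC"`, `"PAC"`.
#' @param cfg The [cohort_config()] used to build `artifacts`.
#' @param seed Integer seed for this sample.
#' @param n Number of fragments (default `cfg$fragments_per_sample`).
#' @return Fragment tibble `chrom`, `start`, `end`, `length`, `mapq` (60).
#' @export
simulate_sample <- function(artifacts, class, cfg, seed,
                            n = cfg$fragments_per_sample) {
  if (!class %in% ALL_CLASSES) abort(sprintf("unknown class: %s", class))
  genome <- artifacts$genome
  bins <- artifacts$bins
  is_cancer <- class %in% CANCER_CLASSES
  eff <- artifacts$class_effects
  bin_r <- if (is_cancer) eff$bin_profile else numeric(nrow(bins))
  cnv_r <- if (is_cancer) eff$cnv_profile else numeric(nrow(bins))
  boost <- if (is_cancer) cfg$short_boost else 0
  amp <- if (is_cancer) cfg$bin_amplitude else 0
  cnv_amp <- if (is_cancer) cfg$cnv_amplitude else 0
  beta <- if (is_cancer) eff$motif_beta else 0 * eff$motif_beta
  expr <- class_expression(artifacts, class)

  # central TSS windows, sorted per chromosome, for midpoint thinning
  chw <- attr(artifacts$genes, "central_halfwidth") %||% 250
  wins <- split(artifacts$genes, artifacts$genes$chrom)
  wins <- purrr::map(wins, function(g) {
    g <- arrange(g, .data$tss)
    list(lo = g$tss - chw, hi = g$tss + chw, gene = g$gene_id)
  })
  clens <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
  chrom_prob <- clens / sum(clens)
  wmax <- exp(sum(pmax(apply(beta, 1, max), 0)))

  withr::with_seed(seed, {
    out <- vector("list", 0)
    got <- 0L
    while (got < n) {
      m <- max(2000L, ceiling((n - got) * 1.8))
      chrom <- sample(names(clens), m, replace = TRUE, prob = chrom_prob)
      len_cap <- clens[chrom]
      start <- floor(stats::runif(m) * (len_cap - 700))
      # bin of the candidate (by start; bins are >> fragment length)
      bin_idx <- rep(NA_integer_, m)
      for (ch in unique(bins$chrom)) {
        b <- bins[bins$chrom == ch, ]
        sel <- chrom == ch
        bi <- findInterval(start[sel], b$start)
        bi[bi < 1 | bi > nrow(b)] <- NA
        bin_idx[sel] <- b$bin[bi] + 1L
      }
      in_bin <- !is.na(bin_idx)
      # CNV-like density modulation
      dens <- ifelse(in_bin, 1 + cnv_amp * cnv_r[ifelse(in_bin, bin_idx, 1L)], 1)
      keep <- stats::runif(m) < dens / (1 + abs(cnv_amp))
      # length from the bin-modulated mixture
      w_sub <- pmin(pmax(cfg$sub_weight + boost +
                           ifelse(in_bin, amp * cfg$sub_weight *
                                    bin_r[ifelse(in_bin, bin_idx, 1L)], 0),
                         0.01), 0.9)
      len <- draw_lengths(m, w_sub, cfg)
      end <- start + len
      keep <- keep & end <= clens[chrom]
      # motif acceptance on the left 5' end (9 informative bases)
      idx <- which(keep)
      if (length(idx) > 0 && any(beta != 0)) {
        nine <- as.character(fetch_ranges(genome, chrom[idx], start[idx],
                                          start[idx] + 9))
        lw <- beta[1, substr(nine, 1, 3)] + beta[2, substr(nine, 4, 6)] +
          beta[3, substr(nine, 7, 9)]
        acc <- stats::runif(length(idx)) < exp(lw) / wmax
        keep[idx[!acc]] <- FALSE
      }
      # TSS-central thinning by class expression
      idx <- which(keep)
      if (length(idx) > 0 && cfg$depletion_depth > 0) {
        mid <- floor((start[idx] + end[idx]) / 2)
        p_rej <- numeric(length(idx))
        for (ch in names(wins)) {
          w <- wins[[ch]]
          sel <- chrom[idx] == ch
          if (!any(sel)) next
          wi <- findInterval(mid[sel], w$lo)
          inside <- wi >= 1 & mid[sel] <= w$hi[pmax(wi, 1)]
          g <- w$gene[wi[inside]]
          p <- cfg$depletion_depth * expr[g]
          tmp <- numeric(sum(sel))
          tmp[inside] <- p
          p_rej[sel] <- tmp
        }
        rej <- stats::runif(length(idx)) < p_rej
        keep[idx[rej]] <- FALSE
      }
      ok <- which(keep)
      if (length(ok) > 0) {
        take <- ok[seq_len(min(length(ok), n - got))]
        out[[length(out) + 1L]] <- tibble(
          chrom = chrom[take], start = start[take], end = end[take],
          length = len[take], mapq = 60)
        got <- got + length(take)
      }
    }
    arrange(bind_rows(out), match(.data$chrom, names(clens)), .data$start)
  })
}

draw_ca19_9 <- function(class, cfg, n) {
  lewis <- if (class %in% CANCER_CLASSES) {
    stats::runif(n) < cfg$lewis_negative_prob
  } else rep(FALSE, n)
  val <- stats::rlnorm(n, cfg$ca19_9_meanlog[[class]], cfg$ca19_9_sdlog[[class]])
  # Lewis-negative individuals barely secrete CA19-9 whatever the tumor does
  val[lewis] <- stats::rlnorm(sum(lewis), log(2), 0.7)
  list(value = round(val, 1), lewis_negative = lewis)
}

#' Simulate a labeled cohort
#'
#' Generates `n_per_class` samples per label on shared genome artifacts,
#' with per-sample derived seeds (any sample is reproducible in isolation),
#' per-class CA19-9 draws and a truth table.
#'
#' @param cfg A [cohort_config()].
#' @param artifacts Optional `synthetic_genome`; built from `cfg` if missing.
#' @param n_per_class Optional override of `cfg$n_per_class`.
#' @param prefix Sample-id prefix (also offsets the per-sample seed stream so
#'   cohorts with different prefixes are independent).
#' @param dir Optional output directory for per-sample fragment TSVs and a
#'   `metadata.tsv`.
#' @return List of class `synthetic_cohort`: `samples` (named list of
#'   fragment tibbles), `truth` (tibble `sample_id`, `label`, `ca19_9`,
#'   `lewis_negative`), `artifacts`.
#' @export
simulate_cohort <- function(cfg, artifacts = NULL, n_per_class = NULL,
                            prefix = "s", dir = NULL) {
  artifacts <- artifacts %||% simulate_genome(cfg)
  n_per_class <- n_per_class %||% cfg$n_per_class
  offset <- utils::head(utf8ToInt(prefix), 1) * 1000L
  samples <- list()
  truth <- list()
  i <- 0L
  for (cl in names(n_per_class)) {
    k <- n_per_class[[cl]]
    if (k == 0) next
    ca <- withr::with_seed(derive_seed(cfg$seed, offset + 999L + match(cl, ALL_CLASSES)),
                           draw_ca19_9(cl, cfg, k))
    for (j in seq_len(k)) {
      i <- i + 1L
      sid <- sprintf("%s_%s_%02d", prefix, gsub("[^A-Za-z]", "", cl), j)
      frag <- simulate_sample(artifacts, cl, cfg,
                              seed = derive_seed(cfg$seed, offset + i))
      samples[[sid]] <- frag
      truth[[sid]] <- tibble(sample_id = sid, label = cl,
                             ca19_9 = ca$value[j],
                             lewis_negative = ca$lewis_negative[j])
    }
  }
  truth <- bind_rows(truth)
  out <- structure(list(samples = samples, truth = truth,
                        artifacts = artifacts),
                   class = "synthetic_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(truth, file.path(dir, "metadata.tsv"))
    for (sid in names(samples)) {
      readr::write_tsv(samples[[sid]], file.path(dir, paste0(sid, ".tsv")))
    }
  }
  out
}

#' Simulate a paired training/validation study
#'
#' Two cohorts over shared genome artifacts, shaped by default like the
#' study design (89 training, 129 validation samples).
#'
#' @param cfg A [cohort_config()].
#' @param validation_n_per_class Validation cohort shape.
#' @return List with `training`, `validation` (each a `synthetic_cohort`)
#'   and `artifacts`.
#' @export
simulate_study <- function(cfg,
                           validation_n_per_class = c("non-cancer" = 40,
                                                      CCA = 39, GBC = 16,
                                                      PAC = 34)) {
  artifacts <- simulate_genome(cfg)
  training <- simulate_cohort(cfg, artifacts, prefix = "train")
  validation <- simulate_cohort(cfg, artifacts,
                                n_per_class = validation_n_per_class,
                                prefix = "valid")
  list(training = training, validation = validation, artifacts = artifacts)
}
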