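mini_genes <- function(genome, tss, strand = "+", ids = NULL) {
  ids <- ids %||% sprintf("g%d", seq_along(tss))
  gene_annotation(tibble::tibble(gene_id = ids, chrom = "chr1", tss = tss,
                                 strand = strand), genome)
}

test_that("TSS coverage matches brute-force per-position overlap counting", {
  g <- toy_genome()
  genes <- mini_genes(g, tss = c(3000, 5000), strand = c("+", "-"))
  set.seed(21)
  start <- sample(500:7000, 30)
  frag <- tibble::tibble(chrom = "chr1", start = start,
                         end = start + sample(150:350, 30, TRUE))
  cov <- coverage_around_tss(frag, genes, flank = 400)
  for (i in 1:2) {
    tss <- genes$tss[i]
    brute <- vapply(seq(-400, 400), function(p) {
      gpos <- if (genes$strand[i] == "-") tss - p else tss + p
      sum(frag$start <= gpos & frag$end > gpos)
    }, numeric(1))
    expect_equal(cov$coverage[cov$gene_id == genes$gene_id[i]], brute)
  }
})

test_that("single fragments produce the expected oriented coverage blocks", {
  g <- toy_genome()
  frag <- tibble::tibble(chrom = "chr1", start = 2900, end = 3100)
  plus <- coverage_around_tss(frag, mini_genes(g, 3000, "+"), flank = 200)
  expect_equal(plus$coverage[plus$offset %in% -100:99], rep(1, 200))
  expect_equal(sum(plus$coverage), 200)
  minus <- coverage_around_tss(frag, mini_genes(g, 3000, "-"), flank = 200)
  expect_equal(minus$coverage[minus$offset %in% -99:100], rep(1, 200))
  # stacking two identical fragments doubles coverage
  two <- coverage_around_tss(dplyr::bind_rows(frag, frag),
                             mini_genes(g, 3000, "+"), flank = 200)
  expect_equal(max(two$coverage), 2)
})

test_that("nucleosome footprint is the central/reference coverage ratio", {
  # flat coverage -> NF = 1
  flat <- tidyr::expand_grid(gene_id = "g1", offset = -2000:2000)
  flat$coverage <- 4
  expect_equal(nucleosome_footprint(flat)$nf, 1)
  # central 5, reference 10 -> NF = 0.5
  prof <- tidyr::expand_grid(gene_id = "g1", offset = -2000:2000)
  prof$coverage <- ifelse(abs(prof$offset) <= 250, 5,
                          ifelse(abs(prof$offset) >= 1000, 10, 7))
  expect_equal(nucleosome_footprint(prof)$nf, 0.5)
  # zero reference coverage -> missing
  zero <- dplyr::mutate(flat, coverage = ifelse(abs(offset) <= 250, 2, 0))
  expect_true(is.na(nucleosome_footprint(zero)$nf))
})

test_that("fast fragment-level NF equals the coverage-array route", {
  sc <- small_cohort()
  genes <- sc$art$genes[seq(1, 20), ]
  frag <- sc$cohort$samples[[1]]
  via_cov <- nucleosome_footprint(coverage_around_tss(frag, genes))
  direct <- nf_profile(frag, genes)
  expect_equal(direct$nf, via_cov$nf)
  expect_equal(direct$central_mean, via_cov$central_mean)
  expect_equal(direct$reference_mean, via_cov$reference_mean)
})

test_that("NF is invariant to uniform depth scaling", {
  g <- toy_genome()
  genes <- mini_genes(g, 3000)
  set.seed(31)
  start <- sample(500:6000, 200, TRUE)
  frag <- tibble::tibble(chrom = "chr1", start = start, end = start + 180)
  nf1 <- nf_profile(frag, genes)$nf
  nf3 <- nf_profile(dplyr::bind_rows(frag, frag, frag), genes)$nf
  expect_equal(nf1, nf3)
})

test_that("expressed genes show lower NF than silent genes in synthetic samples", {
  sc <- small_cohort()
  expr <- sc$art$expression[["non-cancer"]]
  nf <- nf_profile(sc$cohort$samples[[1]], sc$art$genes)
  expect_lt(mean(nf$nf[expr > 0]), mean(nf$nf[expr == 0]))
  # cancer program genes are depleted in cancer, not in controls
  ca_sample <- sc$cohort$samples[[which(sc$cohort$truth$label == "PAC")[1]]]
  nf_ca <- nf_profile(ca_sample, sc$art$genes)
  cg <- sc$art$class_effects$cancer_genes
  expect_lt(mean(nf_ca$nf[cg]), mean(nf$nf[cg]))
})

test_that("NF feature assembly filters by presence and imputes with gene means", {
  p <- function(nf) tibble::tibble(gene_id = c("a", "b", "c"), nf = nf)
  profiles <- list(s1 = p(c(1, 2, NA)), s2 = p(c(3, NA, NA)),
                   s3 = p(c(5, 4, 6)))
  strict <- assemble_nf_features(profiles, min_presence = 1.0)
  expect_equal(strict$genes, "a")
  relaxed <- assemble_nf_features(profiles, min_presence = 0.6)
  expect_equal(relaxed$genes, c("a", "b"))
  expect_equal(unname(relaxed$matrix[, "b"]), c(2, 3, 4))  # NA -> mean(2, 4)
  expect_error(assemble_nf_features(profiles, min_presence = 2), "presence")

  # validation projection uses training genes and means only
  proj <- apply_nf_features(list(v1 = p(c(NA, 7, 8))), relaxed$genes,
                            relaxed$impute_means)
  expect_equal(unname(proj[1, ]), c(3, 7))
})

test_that("downsampling inflates the spread of NF estimates", {
  sc <- small_cohort()
  genes <- sc$art$genes
  nf_full <- purrr::map(sc$cohort$samples[1:6],
                        function(s) nf_profile(s, genes)$nf)
  nf_half <- purrr::imap(sc$cohort$samples[1:6], function(s, id) {
    nf_profile(downsample_fragments(s, 0.3, seed = match(id, names(sc$cohort$samples))),
               genes)$nf
  })
  var_full <- mean(apply(do.call(rbind, nf_full), 2, var), na.rm = TRUE)
  var_half <- mean(apply(do.call(rbind, nf_half), 2, var), na.rm = TRUE)
  expect_gt(var_half, var_full)
})
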