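#' Read-qualification settings
#'
#' Bundles the filters applied to aligned read pairs before featurization:
#' (1) autosomal alignment, (2) mapping quality strictly greater than
#' `min_mapq` for both mates, (3) insert size within
#' `[min_insert, max_insert]` (inclusive), (4) proper pairing, and
#' (5) a reference region free of degenerate (non-ACGT) bases. Rules are
#' applied in that fixed order and a rejected pair is tallied against the
#' first rule it fails.
#'
#' The size-profile diagnostic and the short/long featurizer look at
#' sub-150-bp structure, so the insert-range rule can be overridden per use
#' via the `insert_override` argument of the consumers; the strict
#' `[150, 600]` default governs everything else.
#'
#' @param min_mapq Minimum mapping quality; pairs must exceed it strictly.
#' @param min_insert,max_insert Inclusive insert-size bounds in bp.
#' @param autosomes_only Keep only fragments on chr1-chr22 (either naming
#'   dialect). Set `FALSE` for synthetic genomes with other names.
#' @param require_proper_pair Drop pairs without the proper-pair flag.
#' @param exclude_degenerate_reference Drop fragments whose reference
#'   interval contains a non-ACGT base (requires a genome).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_mapq = 20, min_insert = 150, max_insert = 600,
                      autosomes_only = TRUE, require_proper_pair = TRUE,
                      exclude_degenerate_reference = TRUE) {
  stopifnot(min_insert > 0, min_insert <= max_insert, min_mapq >= 0)
  structure(list(min_mapq = min_mapq, min_insert = min_insert,
                 max_insert = max_insert, autosomes_only = autosomes_only,
                 require_proper_pair = require_proper_pair,
                 exclude_degenerate_reference = exclude_degenerate_reference),
            class = "qc_config")
}

new_qc_report <- function(total_in, tallies, kept) {
  structure(list(total_in = total_in, failed = tallies, kept = kept),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d in, %d kept\n", x$total_in, x$kept))
  for (nm in names(x$failed)) cat(sprintf("  %-28s %d\n", nm, x$failed[[nm]]))
  invisible(x)
}

#' @export
#' @rdname qc_report_json
write_qc_report <- function(report, path) {
  jsonlite::write_json(list(total_in = report$total_in, kept = report$kept,
                            failed = as.list(report$failed)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a QC report
#'
#' @param report A `qc_report` as attached to fragment tables.
#' @param path Output JSON path.
#' @name qc_report_json
NULL

#' Extract the QC report attached to a fragment table
#' @param fragments A fragment tibble returned by [read_fragments()] or
#'   [read_fragment_table()].
#' @return The `qc_report`, or `NULL`.
#' @export
qc_report <- function(fragments) attr(fragments, "qc_report")

rule_names <- c("not_primary_or_duplicate", "not_autosomal", "low_mapq",
                "insert_size_out_of_range", "not_proper_pair",
                "degenerate_reference")

# Vectorized rule engine shared by the BAM and table readers. `checks` is a
# named list of logical "fails this rule" vectors, in application order.
apply_rules <- function(frag, checks) {
  n <- nrow(frag)
  failed_at <- rep(NA_integer_, n)
  for (i in seq_along(checks)) {
    hit <- checks[[i]] & is.na(failed_at)
    failed_at[hit] <- i
  }
  tallies <- stats::setNames(
    vapply(seq_along(checks), function(i) sum(failed_at == i, na.rm = TRUE), 0L),
    names(checks))
  kept <- frag[is.na(failed_at), , drop = FALSE]
  attr(kept, "qc_report") <- new_qc_report(n, tallies, nrow(kept))
  kept
}

degenerate_interval <- function(genome, chrom, start, end) {
  seqs <- fetch_ranges(genome, chrom, start, end)
  freq <- Biostrings::alphabetFrequency(seqs)
  rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]) < Biostrings::width(seqs)
}

#' Read qualified cfDNA fragments from a BAM file
#'
#' Emits one fragment per qualified read pair: the outer interval spanned by
#' the two mates, recomputed from the mate coordinates and CIGARs rather than
#' trusting TLEN (whose sign/extent conventions vary by aligner). Coordinates
#' are 0-based half-open; `length = end - start` is the insert size.
#' Unmapped, secondary, supplementary and duplicate-flagged records are
#' discarded first, then the five qualification rules of [qc_config()] run in
#' order, with a per-rule first-failure tally attached as a [qc_report()].
#'
#' @param bam_path Coordinate-sorted, indexed, paired-end BAM.
#' @param qc A [qc_config()].
#' @param genome A `genome_bundle`; required for the degenerate-reference
#'   rule and for chromosome-name harmonization.
#' @return Tibble `chrom`, `start`, `end`, `length`, `mapq` (min of the pair),
#'   with attribute `qc_report`.
#' @export
read_fragments <- function(bam_path, qc = qc_config(), genome = NULL) {
  if (!file.exists(bam_path)) abort(sprintf("BAM not found: %s", bam_path))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  recs <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  if (length(recs$qname) == 0) {
    return(apply_rules(tibble(chrom = character(), start = double(),
                              end = double(), length = double(),
                              mapq = double()),
                       stats::setNames(rep(list(logical(0)), 6), rule_names)))
  }
  paired_flag <- bitwAnd(recs$flag, 1L) > 0
  if (!all(paired_flag)) abort("BAM contains unpaired (single-end) records")
  rec <- tibble(
    qname = recs$qname,
    flag = recs$flag,
    chrom = as.character(recs$rname),
    pos0 = recs$pos - 1,
    end0 = recs$pos - 1 +
      GenomicAlignments::cigarWidthAlongReferenceSpace(recs$cigar),
    mapq = as.numeric(recs$mapq),
    proper = bitwAnd(recs$flag, 2L) > 0,
    duplicate = bitwAnd(recs$flag, 1024L) > 0)

  # pair mates by query name; keep only complete same-chromosome pairs
  rec <- arrange(rec, .data$qname, .data$pos0)
  grp <- match(rec$qname, unique(rec$qname))
  cnt <- tabulate(grp)
  rec <- rec[cnt[grp] == 2, , drop = FALSE]
  first <- seq(1, nrow(rec), by = 2)
  second <- first + 1
  same_chrom <- rec$chrom[first] == rec$chrom[second]
  frag <- tibble(
    chrom = rec$chrom[first],
    start = rec$pos0[first],
    end = pmax(rec$end0[first], rec$end0[second]),
    mapq = pmin(rec$mapq[first], rec$mapq[second]),
    proper = rec$proper[first] & rec$proper[second] & same_chrom,
    duplicate = rec$duplicate[first] | rec$duplicate[second])
  frag$length <- frag$end - frag$start

  if (!is.null(genome)) {
    mapped <- match_chrom_style(frag$chrom, genome$chroms$chrom)
    frag$chrom <- ifelse(is.na(mapped), frag$chrom, mapped)
  }
  autosomes <- if (!is.null(genome)) autosome_names(genome$chroms$chrom)
               else paste0("chr", 1:22)

  degen <- rep(FALSE, nrow(frag))
  if (qc$exclude_degenerate_reference) {
    if (is.null(genome)) abort("degenerate-reference rule requires `genome`")
    candidate <- frag$chrom %in% genome$chroms$chrom
    candidate[candidate] <- frag$end[candidate] <=
      chrom_length(genome, frag$chrom[candidate])
    if (any(candidate)) {
      degen[candidate] <- degenerate_interval(
        genome, frag$chrom[candidate], frag$start[candidate], frag$end[candidate])
    }
  }
  checks <- list(
    not_primary_or_duplicate = frag$duplicate,
    not_autosomal = if (qc$autosomes_only) !(frag$chrom %in% autosomes)
                    else rep(FALSE, nrow(frag)),
    low_mapq = !(frag$mapq > qc$min_mapq),
    insert_size_out_of_range = frag$length < qc$min_insert |
      frag$length > qc$max_insert,
    not_proper_pair = if (qc$require_proper_pair) !frag$proper
                      else rep(FALSE, nrow(frag)),
    degenerate_reference = degen)
  out <- apply_rules(frag, checks)
  rep_attr <- attr(out, "qc_report")
  out <- out[, c("chrom", "start", "end", "length", "mapq"), drop = FALSE]
  attr(out, "qc_report") <- rep_attr
  out
}

#' Read qualified fragments from a plain table
#'
#' Accepts a TSV (or in-memory data frame) with columns `chrom`, `start`,
#' `end` and optional `mapq`, in 0-based half-open coordinates, and applies
#' the same qualification semantics as [read_fragments()] minus the rules
#' that need BAM flags (proper pairing, duplicate flags). The
#' degenerate-reference rule runs only when a genome is supplied.
#'
#' @param path TSV path, or a data frame taken as already parsed.
#' @param qc A [qc_config()].
#' @param genome Optional `genome_bundle` for name harmonization and the
#'   degenerate-reference rule.
#' @return Tibble as for [read_fragments()], with attribute `qc_report`.
#' @export
read_fragment_table <- function(path, qc = qc_config(), genome = NULL) {
  frag <- if (is.data.frame(path)) as_tibble(path)
          else readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_fragments(frag, "path")
  frag$start <- as.numeric(frag$start)
  frag$end <- as.numeric(frag$end)
  if (anyNA(frag$start) || anyNA(frag$end)) abort("malformed fragment row")
  if (any(frag$start >= frag$end)) abort("fragment rows with start >= end")
  if (!"mapq" %in% names(frag)) frag$mapq <- Inf
  frag$length <- frag$end - frag$start

  if (!is.null(genome)) {
    mapped <- match_chrom_style(frag$chrom, genome$chroms$chrom)
    frag$chrom <- ifelse(is.na(mapped), frag$chrom, mapped)
  }
  autosomes <- if (!is.null(genome)) autosome_names(genome$chroms$chrom)
               else paste0("chr", 1:22)
  degen <- rep(FALSE, nrow(frag))
  if (qc$exclude_degenerate_reference && !is.null(genome)) {
    candidate <- frag$chrom %in% genome$chroms$chrom
    candidate[candidate] <- frag$end[candidate] <=
      chrom_length(genome, frag$chrom[candidate])
    if (any(candidate)) {
      degen[candidate] <- degenerate_interval(
        genome, frag$chrom[candidate], frag$start[candidate], frag$end[candidate])
    }
  }
  checks <- list(
    not_primary_or_duplicate = rep(FALSE, nrow(frag)),
    not_autosomal = if (qc$autosomes_only) !(frag$chrom %in% autosomes)
                    else rep(FALSE, nrow(frag)),
    low_mapq = !(frag$mapq > qc$min_mapq),
    insert_size_out_of_range = frag$length < qc$min_insert |
      frag$length > qc$max_insert,
    not_proper_pair = rep(FALSE, nrow(frag)),
    degenerate_reference = degen)
  out <- apply_rules(frag, checks)
  rep_attr <- attr(out, "qc_report")
  out <- out[, c("chrom", "start", "end", "length", "mapq"), drop = FALSE]
  attr(out, "qc_report") <- rep_attr
  out
}

#' Randomly thin a fragment set to emulate lower sequencing depth
#'
#' Keeps each fragment independently with probability `keep_fraction`;
#' deterministic for a given seed, so downsampling experiments are exactly
#' reproducible.
#'
#' @param fragments Fragment tibble.
#' @param keep_fraction Probability in (0, 1] of retaining each fragment.
#' @param seed Integer seed.
#' @return The thinned fragment tibble.
#' @export
downsample_fragments <- function(fragments, keep_fraction, seed = 1L) {
  assert_fragments(fragments)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must lie in (0, 1]")
  }
  if (keep_fraction == 1) return(fragments)
  keep <- withr::with_seed(seed, stats::runif(nrow(fragments)) < keep_fraction)
  fragments[keep, , drop = FALSE]
}
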