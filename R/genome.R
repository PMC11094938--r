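#' Load a reference genome from FASTA
#'
#' Wraps an indexed FASTA as a light "genome bundle": an ordered table of
#' chromosome lengths plus a sequence accessor. All coordinates exposed by the
#' bundle are 0-based, half-open (the BAM/BED convention); `get_sequence()`
#' returns exactly `end - start` bases.
#'
#' @param fasta_path Path to a FASTA file. A `.fai` index is created with
#'   [Rsamtools::indexFa()] if absent.
#' @param in_memory Load sequences into memory (a [Biostrings::DNAStringSet])
#'   rather than querying the indexed file. Sensible for the small synthetic
#'   genomes used throughout; keep `FALSE` for a real reference.
#' @return An object of class `genome_bundle` with elements `chroms`
#'   (tibble of `chrom`, `length`) and a sequence source.
#' @export
load_genome <- function(fasta_path, in_memory = TRUE) {
  if (!file.exists(fasta_path)) {
    abort(sprintf("FASTA not found: %s", fasta_path))
  }
  if (in_memory) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    chroms <- tibble(chrom = names(seqs), length = Biostrings::width(seqs))
    src <- seqs
  } else {
    if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
    fa <- Rsamtools::FaFile(fasta_path)
    si <- Rsamtools::seqinfo(fa)
    chroms <- tibble(chrom = GenomeInfoDb::seqnames(si),
                     length = GenomeInfoDb::seqlengths(si))
    src <- fa
  }
  if (anyDuplicated(chroms$chrom)) abort("duplicate chromosome names in FASTA")
  structure(list(chroms = chroms, src = src, path = fasta_path),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosomes, %s bp total\n",
              nrow(x$chroms), format(sum(as.double(x$chroms$length)),
                                     big.mark = ",")))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$chrom)
  if (anyNA(i)) abort(sprintf("unknown chromosome: %s",
                              paste(unique(chrom[is.na(i)]), collapse = ", ")))
  genome$chroms$length[i]
}

# Batch sequence fetch for 0-based half-open ranges -> DNAStringSet.
fetch_ranges <- function(genome, chrom, start, end) {
  clen <- chrom_length(genome, chrom)
  if (any(start < 0) || any(end > clen) || any(start > end)) {
    abort("sequence query outside chromosome bounds")
  }
  if (methods::is(genome$src, "DNAStringSet")) {
    # XStringSet subsetting shares storage, so this is cheap at any scale
    Biostrings::subseq(genome$src[chrom], start = start + 1, end = end)
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    Biostrings::getSeq(genome$src, gr)
  }
}

#' Extract reference sequence for one interval
#'
#' @param genome A `genome_bundle`.
#' @param chrom,start,end Interval in 0-based, half-open coordinates.
#' @return A character scalar of length `end - start`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "GTTACAGGCT"), fa)
#' g <- load_genome(fa)
#' get_sequence(g, "chr1", 0, 3)
get_sequence <- function(genome, chrom, start, end) {
  unname(as.character(fetch_ranges(genome, chrom, start, end)))
}

#' Tile chromosomes into fixed-width genomic bins
#'
#' Splits each included chromosome into consecutive windows of `width_bp`;
#' a trailing window shorter than `width_bp` is dropped so every bin has the
#' same width and coverage stays comparable across bins. Bin indices are
#' 0-based and contiguous in (chromosome, start) order.
#'
#' @param genome A `genome_bundle`.
#' @param width_bp Window width in bp (> 0). The published fragmentation
#'   profile uses 5e6.
#' @param include_chroms Chromosomes to tile; default all in the genome.
#' @return A tibble with columns `chrom`, `start`, `end`, `bin`
#'   (0-based half-open coordinates).
#' @export
tile_bins <- function(genome, width_bp, include_chroms = NULL) {
  if (!is_count(width_bp) || width_bp <= 0) abort("`width_bp` must be a positive integer")
  include_chroms <- include_chroms %||% genome$chroms$chrom
  lens <- chrom_length(genome, include_chroms)
  bins <- purrr::map2_dfr(include_chroms, lens, function(ch, len) {
    k <- floor(len / width_bp)
    if (k == 0) return(tibble(chrom = character(), start = double(), end = double()))
    start <- (seq_len(k) - 1) * width_bp
    tibble(chrom = ch, start = start, end = start + width_bp)
  })
  bins$bin <- seq_len(nrow(bins)) - 1L
  bins
}

#' Read a genomic bin set from BED
#'
#' @param path BED3(+) file; coordinates are taken as 0-based half-open
#'   (BED native).
#' @param genome Optional `genome_bundle` whose chromosome-name dialect the
#'   bins are rewritten to; bins on chromosomes absent from the genome error.
#' @return Bin tibble as from [tile_bins()].
#' @export
load_bins <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  bins <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr))
  if (!is.null(genome)) {
    mapped <- match_chrom_style(bins$chrom, genome$chroms$chrom)
    if (anyNA(mapped)) {
      abort(sprintf("bins on chromosomes absent from genome: %s",
                    paste(unique(bins$chrom[is.na(mapped)]), collapse = ", ")))
    }
    bins$chrom <- mapped
  }
  bins <- arrange(bins, match(.data$chrom, unique(.data$chrom)), .data$start)
  bins$bin <- seq_len(nrow(bins)) - 1L
  bins
}

#' The shipped 5-Mb autosome bin set (synthetic stand-in)
#'
#' Returns the packaged 504-bin, 5-Mb hg19 autosome scaffold. The published
#' 504-bin set descends from DELFI's filtered tiling, whose exclusion mask is
#' not public; this asset is a synthetic reconstruction (naive 5-Mb tiling of
#' the 22 autosomes with the 63 bins nearest centromeres/telomeres removed)
#' that reproduces the bin count and geometry, not the exact mask.
#'
#' @param genome Optional `genome_bundle` used to harmonize chromosome names.
#' @return Bin tibble with 504 rows.
#' @export
delfi_bins <- function(genome = NULL) {
  load_bins(system.file("extdata", "hg19_5mb_bins_synthetic.bed",
                        package = "fragstack"),
            genome = genome)
}

#' Load a TSS annotation table
#'
#' Reads a tab-delimited annotation (`gene_id`, `chrom`, `tss`, `strand`,
#' with or without a header) and validates it against a genome. The TSS
#' column is interpreted as a 1-based position and converted to 0-based
#' internally. Genes whose central window (`tss` +/- `central_halfwidth`) or
#' flanking reference windows (strand-aware offsets `ref_offsets`) would
#' extend beyond the chromosome are dropped, with a message giving the count.
#'
#' @param path Tab-delimited file.
#' @param genome A `genome_bundle`.
#' @param central_halfwidth Half-width of the central TSS window in bp.
#' @param ref_offsets Two-column matrix-like of upstream/downstream reference
#'   window offsets relative to the TSS, in transcription orientation.
#' @return A tibble `gene_id`, `chrom`, `tss` (0-based), `strand`, carrying
#'   the window geometry as attributes `central_halfwidth` and `ref_offsets`.
#' @export
load_gene_annotation <- function(path, genome,
                                 central_halfwidth = 250,
                                 ref_offsets = rbind(c(-2000, -1000),
                                                     c(1000, 2000))) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 4) abort("annotation needs >= 4 columns: gene_id, chrom, tss, strand")
  first_tss <- suppressWarnings(as.numeric(raw[[3]][1]))
  if (is.na(first_tss)) raw <- raw[-1, , drop = FALSE]  # header row
  genes <- tibble(gene_id = as.character(raw[[1]]),
                  chrom = as.character(raw[[2]]),
                  tss = suppressWarnings(as.numeric(raw[[3]])) - 1,
                  strand = as.character(raw[[4]]))
  if (anyNA(genes$tss)) abort("malformed TSS column in annotation")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every gene")
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids in annotation")
  mapped <- match_chrom_style(genes$chrom, genome$chroms$chrom)
  if (anyNA(mapped)) {
    abort(sprintf("genes on chromosomes absent from genome: %s",
                  paste(unique(genes$chrom[is.na(mapped)]), collapse = ", ")))
  }
  genes$chrom <- mapped
  gene_annotation(genes, genome, central_halfwidth = central_halfwidth,
                  ref_offsets = ref_offsets)
}

#' Build a TSS annotation from a tibble
#'
#' Programmatic counterpart of [load_gene_annotation()]: takes an in-memory
#' table with 0-based TSS positions, applies the same bounds filter, and
#' attaches the window geometry.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @inheritParams load_gene_annotation
#' @return Annotation tibble (see [load_gene_annotation()]).
#' @export
gene_annotation <- function(genes, genome, central_halfwidth = 250,
                            ref_offsets = rbind(c(-2000, -1000),
                                                c(1000, 2000))) {
  max_ext <- max(abs(range(ref_offsets)), central_halfwidth)
  clen <- chrom_length(genome, genes$chrom)
  ok <- genes$tss - max_ext >= 0 & genes$tss + max_ext < clen
  dropped <- sum(!ok)
  if (dropped > 0) {
    inform(sprintf("dropped %d gene(s) whose TSS windows exceed chromosome bounds",
                   dropped))
  }
  out <- as_tibble(genes[ok, c("gene_id", "chrom", "tss", "strand")])
  attr(out, "central_halfwidth") <- central_halfwidth
  attr(out, "ref_offsets") <- ref_offsets
  attr(out, "n_dropped") <- dropped
  out
}
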