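#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number across all_of
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Strip a leading "chr" so "chr1" and "1" compare equal across dialects.
chrom_core <- function(x) sub("^chr", "", as.character(x))

#' Harmonize chromosome names against a reference set
#'
#' Sequencing artifacts mix the "chr1" (hg19/UCSC) and "1" (g1k/Ensembl)
#' dialects. `match_chrom_style()` rewrites `x` to whichever spelling the
#' `target` set uses, matching on the name with any "chr" prefix removed.
#' Names with no counterpart in `target` are returned as `NA`.
#'
#' @param x Character vector of chromosome names to rewrite.
#' @param target Character vector of reference chromosome names.
#' @return Character vector, same length as `x`.
#' @export
#' @examples
#' match_chrom_style(c("1", "chr2", "MT"), c("chr1", "chr2"))
match_chrom_style <- function(x, target) {
  target <- as.character(target)
  idx <- match(chrom_core(x), chrom_core(target))
  target[idx]
}

autosome_names <- function(target) {
  target[chrom_core(target) %in% as.character(1:22)]
}

# Deterministic child seeds from one root seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + 7919 * as.double(index)) %% 2147483629L)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 &&
  x == floor(x)

assert_fragments <- function(fragments, arg = "fragments") {
  if (!is.data.frame(fragments) ||
      !all(c("chrom", "start", "end") %in% names(fragments))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end", arg))
  }
  invisible(fragments)
}

frag_lengths <- function(fragments) {
  if ("length" %in% names(fragments)) fragments$length
  else fragments$end - fragments$start
}
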