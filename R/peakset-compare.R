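# Comparison of consensus enhancers with external peak sets and compartment
# size summaries.

#' Compare a peak set with an external peak set by reciprocal overlap
#'
#' The external set is merged first (overlapping and bookended intervals
#' unified, as multi-sample peak files routinely contain duplicates); the
#' query set is then filtered by reciprocal overlap at `min_fraction` of
#' each interval's length. `one_to_one` counts query intervals with exactly
#' one reciprocal match.
#'
#' @param starr_peaks Query `GRanges` (e.g. consensus enhancers), compared
#'   as-is (not merged).
#' @param external `GRanges` of external peaks (ChIP-seq, ATAC-seq,
#'   predictions).
#' @param min_fraction Reciprocal overlap fraction (default 0.1).
#' @param names Optional length-2 character vector of set labels.
#' @return List of class `OverlapReport`: `names`, `n_a`, `n_b_raw`,
#'   `n_b_merged`, `n_a_overlapping`, `fraction`, `percent`, `one_to_one`.
#' @export
compare_peak_sets <- function(starr_peaks, external, min_fraction = 0.1,
                              names = c("query", "external")) {
  chr_a <- unique(as.character(seqnames(starr_peaks)))
  chr_b <- unique(as.character(seqnames(external)))
  if (length(intersect(chr_a, chr_b)) == 0L && length(chr_a) && length(chr_b))
    warning("no shared chromosome names between peak sets (",
            paste(head(chr_a, 3), collapse = ","), " ... vs ",
            paste(head(chr_b, 3), collapse = ","), " ...)")
  merged <- merge_intervals(external)
  hits <- reciprocal_overlap(starr_peaks, merged, min_fraction,
                             return_hits = TRUE)
  match_counts <- table(queryHits(hits))
  n_over <- length(match_counts)
  structure(list(names = names, n_a = length(starr_peaks),
                 n_b_raw = length(external), n_b_merged = length(merged),
                 n_a_overlapping = n_over,
                 fraction = if (length(starr_peaks))
                   n_over / length(starr_peaks) else 0,
                 percent = round_half_up(
                   100 * if (length(starr_peaks))
                     n_over / length(starr_peaks) else 0, 1L),
                 one_to_one = sum(match_counts == 1L)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: %d/%d query peaks with reciprocal match (%.1f%%), %d one-to-one;\n  external %d -> %d after merge\n",
    x$names[1], x$names[2], x$n_a_overlapping, x$n_a, x$percent,
    x$one_to_one, x$n_b_raw, x$n_b_merged))
  invisible(x)
}

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Total size of the enhancer compartment
#'
#' Total bases covered by the merged enhancer intervals and the percentage
#' of the genome they occupy (one decimal, rounded half away from zero).
#'
#' @param enhancers A `GRanges`.
#' @param genome_length Total genome length in bases (a number), or a
#'   [Genome] whose sequence lengths are summed.
#' @return List with `total_bases`, `genome_length`, `percent`.
#' @export
compartment_summary <- function(enhancers, genome_length) {
  if (is(genome_length, "Genome"))
    genome_length <- sum(as.numeric(genome_length$lengths))
  total <- sum(as.numeric(width(merge_intervals(enhancers))))
  list(total_bases = total, genome_length = genome_length,
       percent = round_half_up(100 * total / genome_length, 1L))
}

#' Convert log2 enrichment to fold change
#' @param x Log2 enrichment value(s).
#' @return `2^x`.
#' @examples
#' log2_to_fold(2) # 4-fold
#' @export
log2_to_fold <- function(x) 2^x
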