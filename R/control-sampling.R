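# Size- and locus-matched non-enhancer control sets built by constrained
# rejection sampling: same chromosome, same length, start within 0.5 Mb of
# the paired enhancer, no exon or candidate-peak overlap, <= 1% N.

#' Sample one matched control window
#'
#' Draws starts uniformly from the feasible band (enhancer start +/- `band`,
#' clipped to the chromosome) until a window is found that overlaps no exon
#' and no candidate peak and contains at most `max_n_fraction` N bases.
#'
#' @param enhancer Single-interval `GRanges`.
#' @param genome A [Genome].
#' @param exons `GRanges` of exon intervals (all exon bases, UTR included).
#' @param peaks `GRanges` of candidate enhancer peaks to avoid.
#' @param band Maximum |control start - enhancer start| (default 5e5).
#' @param max_n_fraction Maximum tolerated N fraction (default 0.01).
#' @param max_attempts Attempts before giving up.
#' @return Single-interval `GRanges` with an `attempts` metadata column.
#' @export
sample_matched_control <- function(enhancer, genome, exons, peaks,
                                   band = 5e5, max_n_fraction = 0.01,
                                   max_attempts = 1000L) {
  got <- sample_control_batch(enhancer, genome, exons, peaks, band,
                              max_n_fraction, max_attempts)
  if (is.na(got$start))
    stop("sampling exhausted after ", max_attempts,
         " attempts for enhancer ",
         if (!is.null(mcols(enhancer)$name)) mcols(enhancer)$name else "",
         " at ", as.character(seqnames(enhancer)), ":", start(enhancer))
  out <- GRanges(as.character(seqnames(enhancer)),
                 IRanges(got$start, width = width(enhancer)))
  mcols(out)$attempts <- got$attempts
  out
}

# vectorized core: one rejection round for a set of enhancers at a time;
# returns start positions (NA on failure) and attempts used
sample_control_batch <- function(enhancers, genome, exons, peaks,
                                 band, max_n_fraction, max_attempts) {
  n <- length(enhancers)
  chr <- as.character(seqnames(enhancers))
  len <- width(enhancers)
  lo <- pmax(1, start(enhancers) - band)
  hi <- pmin(genome$lengths[chr] - len + 1, start(enhancers) + band)
  if (any(hi < lo))
    stop("no feasible start band for ", sum(hi < lo), " enhancer(s)")
  ngaps <- n_gap_ranges(genome)
  gap_gr <- suppressWarnings(do.call(c, c(list(GRanges()),
    lapply(names(ngaps), function(ch)
      if (length(ngaps[[ch]])) GRanges(ch, ngaps[[ch]]) else GRanges()))))
  avoid <- suppressWarnings(c(granges(exons), granges(peaks)))
  starts <- rep(NA_real_, n)
  attempts <- rep(0L, n)
  todo <- seq_len(n)
  for (round in seq_len(max_attempts)) {
    if (length(todo) == 0L) break
    cand_start <- floor(runif(length(todo), lo[todo], hi[todo] + 1))
    cand_start <- pmin(cand_start, hi[todo])  # guard the open edge
    cand <- GRanges(chr[todo], IRanges(cand_start, width = len[todo]))
    attempts[todo] <- attempts[todo] + 1L
    bad <- countOverlaps(cand, avoid, ignore.strand = TRUE) > 0L
    if (length(gap_gr)) {
      hits <- findOverlaps(cand, gap_gr, ignore.strand = TRUE)
      if (length(hits)) {
        nw <- width(pintersect(cand[queryHits(hits)],
                               gap_gr[subjectHits(hits)],
                               ignore.strand = TRUE))
        nbases <- tapply(nw, queryHits(hits), sum)
        idx <- as.integer(names(nbases))
        bad[idx] <- bad[idx] |
          (as.numeric(nbases) / len[todo][idx] > max_n_fraction)
      }
    }
    ok <- !bad
    starts[todo[ok]] <- cand_start[ok]
    todo <- todo[!ok]
  }
  list(start = starts, attempts = attempts)
}

#' Build the ten matched control sets
#'
#' For each enhancer and each of `n_sets` sets, draws one matched control
#' window ([sample_matched_control()] constraints). Per-set RNG streams are
#' derived from `seed` so the collection is reproducible. Controls may
#' overlap one another and may overlap introns or other non-exonic gene
#' parts; only exons, candidate peaks and N-rich windows are excluded.
#'
#' @param enhancers `GRanges` of consensus enhancers (with optional `name`).
#' @param genome A [Genome].
#' @param ann A [GeneAnnotation] (its exon table is the exclusion set).
#' @param peaks `GRanges` of candidate peaks to avoid (default: the
#'   enhancers themselves).
#' @param n_sets Number of control sets (default 10).
#' @param band,max_n_fraction,max_attempts See [sample_matched_control()].
#' @param seed Integer seed.
#' @return List of class `ControlSetCollection`: `sets` (list of `GRanges`,
#'   each parallel to `enhancers`), `attempts` (matrix), `seed`.
#' @export
build_control_sets <- function(enhancers, genome, ann, peaks = enhancers,
                               n_sets = 10L, band = 5e5,
                               max_n_fraction = 0.01, max_attempts = 1000L,
                               seed = 1L) {
  stopifnot(length(enhancers) > 0)
  sets <- vector("list", n_sets)
  attempts <- matrix(0L, nrow = length(enhancers), ncol = n_sets)
  for (s in seq_len(n_sets)) {
    got <- with_seed(seed + 1009L * s,
      sample_control_batch(enhancers, genome, ann$exons, peaks, band,
                           max_n_fraction, max_attempts))
    fail <- which(is.na(got$start))
    if (length(fail))
      stop("sampling exhausted in control set ", s, " for enhancer(s) ",
           paste(head(fail, 5L), collapse = ", "))
    gr <- GRanges(as.character(seqnames(enhancers)),
                  IRanges(got$start, width = width(enhancers)))
    mcols(gr)$enhancer <- if (!is.null(mcols(enhancers)$name))
      mcols(enhancers)$name else as.character(seq_along(enhancers))
    mcols(gr)$set <- s
    sets[[s]] <- gr
    attempts[, s] <- got$attempts
  }
  structure(list(sets = sets, attempts = attempts, seed = seed),
            class = "ControlSetCollection")
}

#' @export
print.ControlSetCollection <- function(x, ...) {
  cat(sprintf(
    "ControlSetCollection: %d sets x %d controls (mean attempts %.2f)\n",
    length(x$sets), length(x$sets[[1L]]), mean(x$attempts)))
  invisible(x)
}

#' Extract sequences for a set of intervals
#'
#' @param gr A `GRanges`.
#' @param genome A [Genome].
#' @return Character vector of forward-strand sequences.
#' @export
interval_sequences <- function(gr, genome) {
  vapply(seq_along(gr), function(i)
    as.character(subseq(genome$seq[[as.character(seqnames(gr))[i]]],
                        start(gr)[i], end(gr)[i])),
    "")
}

#' Write control sets as BED files
#'
#' One BED per set (`control_set_01.bed`, ...) plus a pairing TSV.
#'
#' @param collection A [build_control_sets()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_control_sets <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- list()
  for (s in seq_along(collection$sets)) {
    gr <- collection$sets[[s]]
    out <- granges(gr)
    mcols(out)$name <- mcols(gr)$enhancer
    write_bed(out, file.path(dir, sprintf("control_set_%02d.bed", s)))
    pair[[s]] <- data.frame(enhancer = mcols(gr)$enhancer, set = s,
                            chrom = as.character(seqnames(gr)),
                            start0 = start(gr) - 1L, end0 = end(gr),
                            attempts = collection$attempts[, s])
  }
  write.table(do.call(rbind, pair), file.path(dir, "control_pairing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
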