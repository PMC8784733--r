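#' @import methods
#' @importFrom stats median quantile setNames aov anova chisq.test fisher.test
#'   kruskal.test wilcox.test pbinom runif sd var
#' @importFrom utils read.table write.table head tail
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue runLength DataFrame
#' @importFrom IRanges IRanges ranges width start end slice Views
#' @importFrom GenomicRanges GRanges seqnames granges findOverlaps countOverlaps
#'   pintersect reduce coverage distance follow precede strand strand<- sort
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   letterFrequency reverseComplement subseq subseq<- matchPattern vmatchPattern
#' @importFrom BiocGenerics unlist width start end sort
NULL

# Internal convention: all intervals are GRanges, 1-based closed (the native
# Bioconductor convention).  BED files (0-based half-open) are converted at the
# read/write boundary, so BED round trips are bit-exact on coordinates.

#' Genome object
#'
#' A genome is a `DNAStringSet` of chromosome sequences plus the set of
#' chromosome names excluded from analysis (e.g. Y, unplaced and mitochondrial
#' sequences, which are dropped from fragment libraries before peak calling).
#'
#' @param seq A named `DNAStringSet` over the alphabet A, C, G, T, N.
#' @param excluded Character vector of chromosome names to exclude from
#'   analysis. Must be a subset of `names(seq)`.
#' @return An object of class `Genome` with elements `seq`, `lengths` and
#'   `excluded`.
#' @examples
#' g <- Genome(Biostrings::DNAStringSet(c(chr1 = "ACGTACGT", Mt = "ACGT")),
#'             excluded = "Mt")
#' genome_lengths(g)
#' @export
Genome <- function(seq, excluded = character()) {
  if (!is(seq, "DNAStringSet")) seq <- DNAStringSet(seq)
  if (is.null(names(seq)) || anyNA(names(seq)) || any(names(seq) == ""))
    stop("all genome sequences must be named")
  if (anyDuplicated(names(seq)))
    stop("duplicated chromosome names in genome")
  if (!all(excluded %in% names(seq)))
    stop("excluded chromosomes not present in genome: ",
         paste(setdiff(excluded, names(seq)), collapse = ", "))
  if (sum(as.numeric(width(seq))) <= 0) stop("genome has zero total length")
  structure(list(seq = seq,
                 lengths = setNames(width(seq), names(seq)),
                 excluded = as.character(excluded)),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x$seq), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  if (length(x$excluded))
    cat("  excluded from analysis:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `Genome`.
#' @param analysed If `TRUE`, drop excluded chromosomes.
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome, analysed = FALSE) {
  len <- genome$lengths
  if (analysed && length(genome$excluded))
    len <- len[setdiff(names(len), genome$excluded)]
  len
}

#' Per-chromosome N-gap ranges
#'
#' @param genome A `Genome`.
#' @return Named list of `IRanges`, one per chromosome, covering all N bases.
#' @export
n_gap_ranges <- function(genome) {
  res <- lapply(seq_along(genome$seq), function(i) {
    m <- matchPattern("N", genome$seq[[i]])
    reduce(as(m, "IRanges"))
  })
  names(res) <- names(genome$seq)
  res
}

#' Non-N genome length
#'
#' Total number of called (non-N) bases, optionally restricted to
#' non-excluded chromosomes. Used as the effective genome length for the
#' model-1 binomial null and as the denominator of coverage summaries.
#'
#' @param genome A `Genome`.
#' @param analysed Drop excluded chromosomes first.
#' @return Named numeric vector of non-N lengths per chromosome.
#' @export
effective_lengths <- function(genome, analysed = TRUE) {
  keep <- names(genome$seq)
  if (analysed) keep <- setdiff(keep, genome$excluded)
  n <- vapply(keep, function(ch)
    sum(letterFrequency(genome$seq[[ch]], "N")), numeric(1))
  genome$lengths[keep] - n
}

#' Read a genome FASTA file
#'
#' Sequences are uppercased and every character outside A/C/G/T is stored
#' as N.
#'
#' @param path FASTA file.
#' @param excluded Chromosome names to mark as excluded from analysis.
#' @return A [Genome].
#' @export
read_genome_fasta <- function(path, excluded = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("FASTA format error at line 1: empty file: ", path)
  if (!startsWith(first, ">"))
    stop("FASTA format error at line 1: expected '>' header, got: ", first)
  seqs <- readBStringSet(path)
  # keep only the first word of each header, like most genome tools
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  x <- toupper(as.character(seqs))
  x <- gsub("[^ACGT]", "N", x)
  Genome(DNAStringSet(x), excluded = intersect(excluded, names(x)))
}

#' Write a genome FASTA file
#' @param genome A [Genome].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed.
#' Columns 4 and 5 are stored as `name` and `score`, column 6 as strand, and
#' any further columns as `V7`, `V8`, ... so that [write_bed()] round trips
#' coordinates and attributes bit-exactly.
#'
#' @param path BED file (tab-separated, 3+ columns).
#' @param genome Optional [Genome]; if given, intervals are validated against
#'   its chromosome names and lengths.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED format error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  ncol <- min(nf)
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_chr))
  e <- suppressWarnings(as.numeric(e_chr))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad))
    stop("BED format error at line ", which(bad)[1L],
         ": non-integer coordinates")
  if (any(s < 0))
    stop("BED format error at line ", which(s < 0)[1L],
         ": negative start")
  if (any(s >= e))
    stop("BED format error at line ", which(s >= e)[1L],
         ": start >= end")
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  if (ncol >= 4L) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (ncol >= 5L) mcols(gr)$score <- vapply(fields, `[[`, "", 5L)
  if (ncol >= 6L) {
    st <- vapply(fields, `[[`, "", 6L)
    st[!st %in% c("+", "-")] <- "*"
    strand(gr) <- st
  }
  if (ncol >= 7L) for (j in 7:ncol)
    mcols(gr)[[paste0("V", j)]] <- vapply(fields, `[[`, "", j)
  if (!is.null(genome)) validate_intervals(gr, genome)
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of [read_bed()]: 1-based closed `GRanges` coordinates become
#' 0-based half-open BED coordinates. `name`, `score`, strand and `V7`...
#' metadata columns are written back in order; later BED columns are only
#' written when all earlier ones are present.
#'
#' @param gr A `GRanges`.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  cols <- list(as.character(seqnames(gr)),
               format(start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE))
  mc <- mcols(gr)
  if (!is.null(mc$name)) {
    cols <- c(cols, list(as.character(mc$name)))
    if (!is.null(mc$score)) {
      cols <- c(cols, list(as.character(mc$score)))
      st <- as.character(strand(gr))
      has_strand <- any(st != "*")
      extra <- grep("^V[0-9]+$", colnames(mc), value = TRUE)
      if (has_strand || length(extra)) {
        st[st == "*"] <- "."
        cols <- c(cols, list(st))
        for (v in extra[order(as.integer(sub("V", "", extra)))])
          cols <- c(cols, list(as.character(mc[[v]])))
      }
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Validate intervals against a genome
#'
#' @param gr A `GRanges`.
#' @param genome A [Genome].
#' @return `gr`, invisibly; errors if any interval falls on an unknown
#'   chromosome or outside its bounds.
#' @export
validate_intervals <- function(gr, genome) {
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(genome$lengths))
  if (length(unknown))
    stop("intervals on chromosomes absent from genome: ",
         paste(unknown, collapse = ", "))
  too_far <- end(gr) > genome$lengths[chr] | start(gr) < 1
  if (any(too_far))
    stop(sum(too_far), " interval(s) outside chromosome bounds")
  invisible(gr)
}

#' Merge intervals (bedtools-merge semantics)
#'
#' Overlapping and bookended intervals (end of one equals start of the next
#' in 0-based terms) are unified; output is sorted and pairwise disjoint.
#'
#' @param gr A `GRanges`.
#' @return Merged `GRanges`, strand ignored.
#' @examples
#' merge_intervals(GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(10, 20))))
#' @export
merge_intervals <- function(gr) {
  if (length(gr) == 0L) return(GRanges())
  # reduce() default min.gapwidth = 1 unifies bookended ranges, matching
  # `bedtools merge` default parameters
  reduce(granges(gr), ignore.strand = TRUE)
}

#' Reciprocal-overlap filter (bedtools intersect -f x -r -u semantics)
#'
#' Returns the subset of `a` for which at least one interval of `b` overlaps
#' by at least `min_fraction` of the length of *each* of the two intervals.
#' Each `a` interval is reported at most once.
#'
#' @param a,b `GRanges`.
#' @param min_fraction Reciprocal overlap fraction in (0, 1].
#' @param return_hits If `TRUE`, return the qualifying `Hits` object instead
#'   of the subset (used for one-to-one accounting).
#' @return Subset of `a` (or a `Hits`).
#' @export
reciprocal_overlap <- function(a, b, min_fraction = 0.1, return_hits = FALSE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- width(pintersect(granges(a)[queryHits(hits)],
                           granges(b)[subjectHits(hits)],
                           ignore.strand = TRUE))
    keep <- ov >= min_fraction * width(a)[queryHits(hits)] &
            ov >= min_fraction * width(b)[subjectHits(hits)]
    hits <- hits[keep]
  }
  if (return_hits) return(hits)
  a[sort(unique(queryHits(hits)))]
}

#' Closest feature to the left and right of each query interval
#'
#' For each query, reports the nearest feature wholly to its left and to its
#' right, with the gap in bases between them (0 means touching). A feature
#' overlapping the query is reported on both sides with distance 0. Ties are
#' broken by lowest feature start, then lexicographic `name`.
#'
#' @param query A `GRanges`.
#' @param features A `GRanges`, ideally with a `name` metadata column
#'   (feature/gene ids).
#' @return A `data.frame` with one row per query: `left_name`, `left_distance`,
#'   `right_name`, `right_distance` (`NA` when no feature exists on that side
#'   of the query on its chromosome).
#' @export
closest_feature <- function(query, features) {
  nm <- mcols(features)$name
  if (is.null(nm)) nm <- as.character(seq_along(features))
  o <- order(start(features), nm)
  features <- granges(features)[o]
  nm <- nm[o]
  res <- data.frame(left_name = rep(NA_character_, length(query)),
                    left_distance = rep(NA_real_, length(query)),
                    right_name = NA_character_, right_distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(features) == 0L || length(query) == 0L) return(res)
  # overlapping features: distance 0 on both sides; select first hit in
  # (start, name) order for determinism
  hits <- findOverlaps(query, features, ignore.strand = TRUE)
  if (length(hits)) {
    first <- !duplicated(queryHits(hits))
    qi <- queryHits(hits)[first]
    si <- subjectHits(hits)[first]
    res$left_name[qi] <- res$right_name[qi] <- nm[si]
    res$left_distance[qi] <- res$right_distance[qi] <- 0
  }
  todo <- which(is.na(res$left_name))
  if (length(todo) == 0L) return(res)
  fchr <- as.character(seqnames(features))
  qchr <- as.character(seqnames(query))
  for (ch in unique(qchr[todo])) {
    qi <- todo[qchr[todo] == ch]
    fi <- which(fchr == ch)
    if (length(fi) == 0L) next
    fs <- start(features)[fi]; fe <- end(features)[fi]
    # left: nearest feature end strictly left of the query start; among
    # equal ends, fi is already in (start, name) order so the first wins
    ue <- sort(unique(fe))
    best_for_end <- vapply(ue, function(e) fi[fe == e][1L], integer(1))
    pos <- findInterval(start(query)[qi] - 1L, ue)
    has <- pos >= 1L
    res$left_name[qi[has]] <- nm[best_for_end[pos[has]]]
    res$left_distance[qi[has]] <-
      start(query)[qi[has]] - ue[pos[has]] - 1L
    # right: nearest feature start strictly right of the query end
    us <- sort(unique(fs))
    best_for_start <- vapply(us, function(s) fi[fs == s][1L], integer(1))
    pos <- findInterval(end(query)[qi], us) + 1L
    has <- pos <= length(us)
    res$right_name[qi[has]] <- nm[best_for_start[pos[has]]]
    res$right_distance[qi[has]] <-
      us[pos[has]] - end(query)[qi[has]] - 1L
  }
  res
}
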