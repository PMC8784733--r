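# PWM-based transcription-factor-binding-site scanning and the ten-control
# consensus enrichment criterion.

#' Position weight matrix
#'
#' Wraps a 4 x L base-count matrix (rows A, C, G, T) together with the
#' background base frequencies and the derived log2-odds scoring matrix.
#' The pseudocount (default 0.8 total per column, the JASPAR community
#' convention) is split across bases in proportion to the background.
#'
#' @param id Motif identifier.
#' @param counts 4 x L numeric matrix with rownames A, C, G, T.
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Total pseudocount per column.
#' @return An object of class `pwm` with elements `id`, `counts`,
#'   `background`, `log_odds`, `max_score`.
#' @export
pwm <- function(id, counts, background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T): ", id)
  if (ncol(counts) < 4L) stop("motif too short (L < 4): ", id)
  if (any(colSums(counts) <= 0)) stop("zero column count sum in motif ", id)
  rownames(counts) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  prob <- sweep(counts, 2, colSums(counts) + pseudocount, "/") +
    pseudocount * background / rep(colSums(counts) + pseudocount,
                                   each = 4L)
  lo <- log2(prob / background)
  structure(list(id = id, counts = counts, background = background,
                 log_odds = lo, max_score = sum(apply(lo, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, consensus %s\n", x$id, ncol(x$counts),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM
#' @param x A [pwm].
#' @return Character string of the per-column max-count bases.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read motifs in JASPAR PFM format
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four
#' labelled count rows `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path JASPAR PFM file.
#' @param background Base frequencies for the log-odds transform.
#' @param pseudocount Total pseudocount per column.
#' @return List of [pwm] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no motif headers in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1L]][1L]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("JASPAR format error in motif ", id, ": expected 4 count rows, got ",
           length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR format error in motif ", id, ": row length mismatch")
    out[[i]] <- pwm(id, do.call(rbind, rows), background, pseudocount)
  }
  out
}

#' Write motifs in JASPAR PFM format
#' @param pwms List of [pwm] objects.
#' @param path Output file.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

encode_dna <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1L]]
  m <- match(v, c("A", "C", "G", "T"))
  m
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands with the motif's log2-odds matrix and
#' reports the windows scoring at least `threshold` times the motif's maximum
#' attainable score. Windows containing N are skipped. Minus-strand matches
#' are reported in forward-strand coordinates.
#'
#' @param x A [pwm].
#' @param sequence Character string (A/C/G/T/N).
#' @param threshold Fraction of the maximum log-odds score, in (0, 1].
#' @return `data.frame` with `start`, `end` (1-based, inclusive), `strand`,
#'   `score`; zero rows when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(x, sequence, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  enc <- encode_dna(sequence)
  L <- ncol(x$log_odds)
  n <- length(enc) - L + 1L
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric())
  if (n < 1L) return(empty)
  score_with <- function(m) {
    s <- numeric(n)
    bad <- logical(n)
    for (j in seq_len(L)) {
      b <- enc[j:(j + n - 1L)]
      na <- is.na(b)
      bad <- bad | na
      b[na] <- 1L
      s <- s + m[cbind(b, j)]
    }
    s[bad] <- -Inf
    s
  }
  # minus strand: scoring the forward sequence with the reverse-complemented
  # matrix equals scoring the reverse complement at the mirrored position
  rc <- x$log_odds[4:1, L:1]
  cut <- threshold * x$max_score
  fw <- score_with(x$log_odds)
  rv <- score_with(rc)
  hits_f <- which(fw >= cut)
  hits_r <- which(rv >= cut)
  out <- data.frame(
    start = c(hits_f, hits_r),
    end = c(hits_f, hits_r) + L - 1L,
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    score = c(fw[hits_f], rv[hits_r]))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Sequence-level motif presence
#'
#' @param x A [pwm].
#' @param sequences Character vector.
#' @param threshold Relative score threshold (see [scan_sequence()]).
#' @return Logical vector: does each sequence contain >= 1 match?
#' @export
motif_presence <- function(x, sequences, threshold = 0.8) {
  vapply(sequences, function(s) nrow(scan_sequence(x, s, threshold)) > 0,
         logical(1), USE.NAMES = FALSE)
}

#' Fisher test of motif presence in enhancers vs one control set
#'
#' One-sided Fisher exact test on the 2 x 2 table of sequence-level motif
#' presence (>= 1 match) in enhancers versus controls.
#'
#' @param x A [pwm].
#' @param enhancer_seqs,control_seqs Character vectors of sequences.
#' @param threshold Relative score threshold.
#' @param presence_enh Optional precomputed presence vector for the
#'   enhancers (avoids rescanning across the 10 control comparisons).
#' @return List with `p_value` (one-sided, enrichment in enhancers),
#'   `enhancer_fraction`, `control_fraction`, `direction` (+1 enhancer-high).
#' @export
motif_enrichment_test <- function(x, enhancer_seqs, control_seqs,
                                  threshold = 0.8, presence_enh = NULL) {
  stopifnot(length(enhancer_seqs) > 0, length(control_seqs) > 0)
  pe <- if (is.null(presence_enh)) motif_presence(x, enhancer_seqs, threshold)
        else presence_enh
  pc <- motif_presence(x, control_seqs, threshold)
  tab <- matrix(c(sum(pe), sum(!pe), sum(pc), sum(!pc)), nrow = 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(p_value = p, enhancer_fraction = mean(pe),
       control_fraction = mean(pc),
       direction = sign(mean(pe) - mean(pc)))
}

#' Consensus motif enrichment over the ten control sets
#'
#' Tests each motif against each control set and calls a motif enriched when
#' it is significantly enriched (one-sided Fisher `p < alpha` with the
#' enhancer fraction higher) in at least `min_sets` of the comparisons.
#'
#' @param pwms List of [pwm] objects.
#' @param enhancer_seqs Character vector of enhancer sequences.
#' @param control_seq_sets List of character vectors (one per control set).
#' @param threshold Relative score threshold.
#' @param alpha Per-comparison significance level.
#' @param min_sets Minimum number of enriched comparisons (default 8 of 10).
#' @return `data.frame`: `motif`, `n_enriched`, `consensus`, and one
#'   p-value/flag pair per control set in list columns `p_values`, `flags`.
#' @export
consensus_motif_enrichment <- function(pwms, enhancer_seqs, control_seq_sets,
                                       threshold = 0.8, alpha = 0.05,
                                       min_sets = 8L) {
  res <- lapply(pwms, function(p) {
    pe <- motif_presence(p, enhancer_seqs, threshold)
    tests <- lapply(control_seq_sets, function(ctrl)
      motif_enrichment_test(p, enhancer_seqs, ctrl, threshold,
                            presence_enh = pe))
    pv <- vapply(tests, `[[`, numeric(1), "p_value")
    flags <- pv < alpha &
      vapply(tests, `[[`, numeric(1), "direction") > 0
    data.frame(motif = p$id, n_enriched = sum(flags),
               consensus = sum(flags) >= min_sets,
               p_values = I(list(pv)), flags = I(list(flags)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Repeat content of merged motif matches
#'
#' Per sequence, overlapping motif-match intervals are merged and the
#' fraction of matched bases that fall inside perfect-repeat runs is
#' computed. Sequences without any matched base are excluded (`NA`).
#'
#' @param match_list List (per sequence) of `data.frame`s with `start`,`end`
#'   match coordinates (e.g. rbind of [scan_sequence()] results).
#' @param repeat_list List (per sequence) of `data.frame`s with `start`,`end`
#'   repeat-run coordinates (see [find_perfect_repeats()]).
#' @return Numeric vector: per-sequence repetitive fraction of matched bases.
#' @export
motif_repeat_overlap <- function(match_list, repeat_list) {
  stopifnot(length(match_list) == length(repeat_list))
  vapply(seq_along(match_list), function(i) {
    m <- match_list[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NA_real_)
    mr <- reduce(IRanges(m$start, m$end))
    r <- repeat_list[[i]]
    if (is.null(r) || nrow(r) == 0L) return(0)
    rr <- reduce(IRanges(r$start, r$end))
    sum(width(IRanges::intersect(mr, rr))) / sum(width(mr))
  }, numeric(1))
}
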