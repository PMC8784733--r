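# Peak calling: binomial enrichment of cDNA reporter fragments over plasmid
# input, fixed-width candidate windows on coverage maxima, and replicate
# consensus by minimum mutual overlap.

#' Fragment library
#'
#' A per-replicate, per-channel collection of mapped fragment intervals.
#'
#' @param fragments A `GRanges` of mapped fragment intervals.
#' @param replicate Replicate identifier (integer or string).
#' @param channel `"cdna"` (reporter transcripts) or `"input"` (plasmid pool).
#' @return An object of class `FragmentLibrary` with elements `fragments`,
#'   `replicate`, `channel`, `total_count`.
#' @export
FragmentLibrary <- function(fragments, replicate, channel = c("cdna", "input")) {
  channel <- match.arg(channel)
  structure(list(fragments = granges(fragments), replicate = replicate,
                 channel = channel, total_count = length(fragments)),
            class = "FragmentLibrary")
}

#' @export
print.FragmentLibrary <- function(x, ...) {
  cat(sprintf("FragmentLibrary: replicate %s, channel %s, %s fragments\n",
              x$replicate, x$channel, format(x$total_count, big.mark = ",")))
  invisible(x)
}

#' Peak-calling parameters
#'
#' Defaults follow the standard STARR-seq peak-calling configuration:
#' coverage quantile 0.99, 500-bp fixed-width peaks, binomial p-value cutoff
#' 0.001 under model 2 (input-proportion null), fold-enrichment cutoff 3, and
#' a 250-bp minimum mutual overlap for the replicate consensus.
#'
#' @param min_quantile Quantile of positive per-base cDNA coverage used as
#'   the candidate-window floor.
#' @param peak_width Fixed peak width in bases.
#' @param max_pval Binomial p-value threshold.
#' @param model 2 = null success probability from the input counts
#'   (`k_input / N_input`); 1 = `peak_width / effective genome length`.
#' @param min_enrichment Minimum library-size-normalized cDNA/input fold.
#' @param min_consensus_overlap Minimum pairwise overlap (bases) between
#'   supporting replicate peaks.
#' @param deduplicate Drop duplicate fragment intervals inside the caller
#'   (off by default; duplicates are normally removed upstream when
#'   sequencing runs are merged).
#' @return A list of class `PeakCallParams`.
#' @export
peak_call_params <- function(min_quantile = 0.99, peak_width = 500L,
                             max_pval = 0.001, model = 2L,
                             min_enrichment = 3, min_consensus_overlap = 250L,
                             deduplicate = FALSE) {
  stopifnot(min_quantile > 0, min_quantile < 1, peak_width > 0,
            model %in% c(1L, 2L), min_consensus_overlap <= peak_width)
  structure(list(min_quantile = min_quantile,
                 peak_width = as.integer(peak_width), max_pval = max_pval,
                 model = as.integer(model), min_enrichment = min_enrichment,
                 min_consensus_overlap = as.integer(min_consensus_overlap),
                 deduplicate = deduplicate),
            class = "PeakCallParams")
}

#' Drop fragments on excluded chromosomes
#'
#' Removes fragments mapped to the genome's excluded chromosomes (e.g. Y,
#' unplaced scaffolds and the mitochondrion) and updates the library total.
#'
#' @param library A [FragmentLibrary].
#' @param genome A [Genome] with its `excluded` set populated.
#' @return The filtered [FragmentLibrary].
#' @export
filter_chromosomes <- function(library, genome) {
  keep <- !as.character(seqnames(library$fragments)) %in% genome$excluded
  FragmentLibrary(library$fragments[keep], library$replicate, library$channel)
}

# coverage over a fixed chromosome set, independent of the seqlevels the
# fragments happen to carry
fragment_coverage <- function(frags, lengths) {
  keep <- as.character(seqnames(frags)) %in% names(lengths)
  frags <- frags[keep]
  gr <- GRanges(factor(as.character(seqnames(frags)),
                       levels = names(lengths)), ranges(frags))
  coverage(gr, width = lengths)
}

# Weighted (type-1) quantile of an integer coverage distribution given as a
# value/count table; used instead of decoding whole-genome coverage vectors.
weighted_quantile <- function(values, counts, prob) {
  o <- order(values)
  values <- values[o]
  counts <- as.numeric(counts[o])
  cum <- cumsum(counts)
  target <- prob * cum[length(cum)]
  values[which(cum >= target)[1L]]
}

#' Candidate windows from cDNA coverage maxima
#'
#' Computes per-base cDNA fragment coverage, thresholds it at the
#' `min_quantile` quantile of the positive coverage values (genome-wide),
#' and selects fixed-width windows centered on coverage maxima greedily by
#' descending coverage (ties to the lowest position); windows overlapping an
#' already-selected window are suppressed. Windows are shifted, if needed,
#' to lie fully on their chromosome.
#'
#' @param cdna A [FragmentLibrary] (cDNA channel).
#' @param genome A [Genome].
#' @param params A [peak_call_params()] list.
#' @return Sorted, pairwise non-overlapping `GRanges` of width
#'   `params$peak_width`.
#' @export
candidate_windows <- function(cdna, genome, params = peak_call_params()) {
  frags <- cdna$fragments
  if (params$deduplicate) frags <- unique(frags)
  chroms <- setdiff(names(genome$lengths), genome$excluded)
  frags <- frags[as.character(seqnames(frags)) %in% chroms]
  if (length(frags) == 0L) return(GRanges())
  cov <- fragment_coverage(frags, genome$lengths[chroms])
  # genome-wide quantile of positive coverage values from run-length tables
  vals <- unlist(lapply(cov, runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, runLength), use.names = FALSE)
  pos <- vals > 0
  if (!any(pos)) return(GRanges())
  thr <- weighted_quantile(vals[pos], lens[pos], params$min_quantile)
  w <- params$peak_width
  half <- w %/% 2L
  out <- list()
  for (ch in chroms) {
    sl <- slice(cov[[ch]], lower = thr)
    if (length(sl) == 0L) next
    rng <- as(sl, "IRanges")
    pos_v <- sequence(width(rng), from = start(rng))
    val_v <- as.integer(cov[[ch]][pos_v])
    ord <- order(-val_v, pos_v)
    alive <- rep(TRUE, length(pos_v))
    centers <- integer(0)
    for (i in ord) {
      if (!alive[i]) next
      c0 <- pos_v[i]
      centers <- c(centers, c0)
      # suppress every position whose window would overlap this one
      lo <- findInterval(c0 - w, pos_v) + 1L
      hi <- findInterval(c0 + w - 1L, pos_v)
      if (hi >= lo) alive[lo:hi] <- FALSE
    }
    if (length(centers)) {
      st <- pmin(pmax(centers - half, 1L), genome$lengths[[ch]] - w + 1L)
      # clipping near chromosome ends can re-introduce overlaps between
      # windows whose centers were > peak_width apart; drop later-selected
      # windows that collide with an earlier (higher-coverage) one
      clipped <- which(st != centers - half)
      drop <- logical(length(st))
      for (i in clipped) {
        prior <- which(!drop & seq_along(st) < i)
        if (any(abs(st[prior] - st[i]) < w)) drop[i] <- TRUE
      }
      st <- st[!drop]
      out[[ch]] <- GRanges(ch, IRanges(st, width = w))
    }
  }
  if (length(out) == 0L) return(GRanges())
  sort(suppressWarnings(unname(do.call(c, unname(out)))),
       ignore.strand = TRUE)
}

#' Binomial enrichment test for one window
#'
#' Upper-tail binomial test of the cDNA fragment count against the null
#' success probability: model 2 uses the input proportion
#' `p0 = k_input / N_input` (floored at `1/N_input` when `k_input` is 0,
#' with a flag); model 1 uses `p0 = peak_width / effective_length`. The
#' p-value is `P(X >= k_cdna)` for `X ~ Binomial(N_cdna, p0)`. Enrichment is
#' the library-size-normalized fold
#' `(k_cdna/N_cdna) / (max(k_input, 1)/N_input)`.
#'
#' @param k_cdna,n_cdna cDNA fragment count in the window and library total.
#' @param k_input,n_input Same for the input channel.
#' @param params A [peak_call_params()] list.
#' @param effective_length Effective (non-N, non-excluded) genome length;
#'   required for model 1.
#' @return `data.frame` with `p_value`, `enrichment`, `flagged` (vectorized
#'   over the count arguments).
#' @export
binomial_peak_test <- function(k_cdna, n_cdna, k_input, n_input,
                               params = peak_call_params(),
                               effective_length = NULL) {
  stopifnot(all(n_cdna > 0), all(n_input > 0),
            all(k_cdna <= n_cdna), all(k_input <= n_input))
  if (params$model == 2L) {
    flagged <- k_input == 0
    p0 <- pmax(k_input, 1) / n_input
  } else {
    if (is.null(effective_length))
      stop("model 1 requires effective_length")
    flagged <- rep(FALSE, length(k_cdna))
    p0 <- rep(params$peak_width / effective_length, length(k_cdna))
  }
  p <- pbinom(k_cdna - 1, n_cdna, p0, lower.tail = FALSE)
  p[k_cdna == 0] <- 1
  # single division of exact integer products so the >= min_enrichment
  # filter is exact at its boundary
  enr <- (as.numeric(k_cdna) * n_input) / (pmax(as.numeric(k_input), 1) * n_cdna)
  data.frame(p_value = p, enrichment = enr, flagged = flagged)
}

#' Call candidate peaks for one replicate
#'
#' Counts fragments overlapping (by >= 1 bp) each candidate window in both
#' channels, applies [binomial_peak_test()], and keeps windows with
#' `p_value <= max_pval` and `enrichment >= min_enrichment`.
#'
#' @param cdna,input [FragmentLibrary] objects for the replicate (already
#'   chromosome-filtered).
#' @param genome A [Genome].
#' @param params A [peak_call_params()] list.
#' @return Sorted `GRanges` of peaks with metadata `k_cdna`, `k_input`,
#'   `p_value`, `enrichment`, `flagged`, `replicate`.
#' @export
call_peaks <- function(cdna, input, genome, params = peak_call_params()) {
  stopifnot(cdna$channel == "cdna", input$channel == "input")
  win <- candidate_windows(cdna, genome, params)
  if (length(win) == 0L) return(empty_peaks())
  k_cdna <- countOverlaps(win, cdna$fragments, ignore.strand = TRUE)
  k_input <- countOverlaps(win, input$fragments, ignore.strand = TRUE)
  eff <- if (params$model == 1L)
    sum(effective_lengths(genome, analysed = TRUE)) else NULL
  bt <- binomial_peak_test(k_cdna, cdna$total_count, k_input,
                           input$total_count, params, eff)
  keep <- bt$p_value <= params$max_pval & bt$enrichment >= params$min_enrichment
  peaks <- win[keep]
  mcols(peaks) <- DataFrame(k_cdna = k_cdna[keep], k_input = k_input[keep],
                            p_value = bt$p_value[keep],
                            enrichment = bt$enrichment[keep],
                            flagged = bt$flagged[keep],
                            replicate = rep(cdna$replicate, sum(keep)))
  sort(peaks, ignore.strand = TRUE)
}

empty_peaks <- function() {
  g <- GRanges()
  mcols(g) <- DataFrame(k_cdna = integer(), k_input = integer(),
                        p_value = numeric(), enrichment = numeric(),
                        flagged = logical(), replicate = character())
  g
}

#' Replicate-consensus enhancers
#'
#' A consensus enhancer exists wherever one peak from every replicate
#' mutually overlaps pairwise by at least `min_consensus_overlap` bases
#' (for intervals, the minimum pairwise overlap of a tuple equals the width
#' of its common intersection). The consensus interval is that common
#' intersection; its activity is the mean over replicates of the supporting
#' peaks' log2 enrichment.
#'
#' @param peak_lists List (length >= 2) of per-replicate peak `GRanges` as
#'   returned by [call_peaks()].
#' @param params A [peak_call_params()] list.
#' @return `GRanges` of consensus enhancers with metadata `activity` (mean
#'   log2 enrichment), an `enrichment` matrix column (one column per
#'   replicate) and a `support` matrix column of supporting peak indices.
#' @export
consensus_peaks <- function(peak_lists, params = peak_call_params()) {
  stopifnot(length(peak_lists) >= 2L)
  n_rep <- length(peak_lists)
  # running join: tuples of (current intersection, supporting indices)
  cur <- granges(peak_lists[[1L]])
  support <- matrix(seq_along(cur), ncol = 1L)
  for (r in 2:n_rep) {
    nxt <- granges(peak_lists[[r]])
    hits <- findOverlaps(cur, nxt, ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty_consensus(n_rep))
    cur <- granges(pintersect(cur[queryHits(hits)], nxt[subjectHits(hits)],
                              ignore.strand = TRUE))
    support <- cbind(support[queryHits(hits), , drop = FALSE],
                     subjectHits(hits))
  }
  keep <- width(cur) >= params$min_consensus_overlap
  cur <- cur[keep]
  support <- support[keep, , drop = FALSE]
  if (length(cur) == 0L) return(empty_consensus(n_rep))
  enr <- vapply(seq_len(n_rep), function(r)
    mcols(peak_lists[[r]])$enrichment[support[, r]], numeric(length(cur)))
  enr <- matrix(enr, nrow = length(cur))
  o <- order(as.character(seqnames(cur)), start(cur), end(cur))
  cur <- cur[o]
  support <- support[o, , drop = FALSE]
  enr <- enr[o, , drop = FALSE]
  dup <- duplicated(paste(as.character(seqnames(cur)), start(cur), end(cur)))
  cur <- cur[!dup]
  mcols(cur) <- DataFrame(activity = rowMeans(log2(enr))[!dup],
                          enrichment = I(enr[!dup, , drop = FALSE]),
                          support = I(support[!dup, , drop = FALSE]))
  names(mcols(cur)) <- c("activity", "enrichment", "support")
  mcols(cur)$name <- sprintf("enh_%04d", seq_along(cur))
  cur
}

empty_consensus <- function(n_rep) {
  g <- GRanges()
  mcols(g) <- DataFrame(activity = numeric(),
                        enrichment = I(matrix(numeric(), 0, n_rep)),
                        support = I(matrix(integer(), 0, n_rep)),
                        name = character())
  names(mcols(g)) <- c("activity", "enrichment", "support", "name")
  g
}

#' Median per-base fragment coverage
#'
#' Median of per-base coverage over the non-N positions of the analysed
#' (non-excluded) chromosomes; a quality-control summary of genome
#' representation in a library.
#'
#' @param library A [FragmentLibrary].
#' @param genome A [Genome].
#' @return List with `global` median and per-chromosome medians.
#' @export
coverage_median <- function(library, genome) {
  chroms <- setdiff(names(genome$lengths), genome$excluded)
  cov <- fragment_coverage(library$fragments, genome$lengths[chroms])
  ngaps <- n_gap_ranges(genome)
  per_tab <- lapply(chroms, function(ch) {
    v <- cov[[ch]]
    gaps <- ngaps[[ch]]
    tab <- data.frame(value = runValue(v), n = as.numeric(runLength(v)))
    if (length(gaps)) {
      # subtract N positions from the run-length table
      gtab <- table(unlist(lapply(Views(v, gaps), as.integer)))
      for (val in names(gtab)) {
        i <- which(tab$value == as.integer(val))
        tab$n[i] <- tab$n[i] - as.numeric(gtab[[val]])
      }
      tab <- tab[tab$n > 0, , drop = FALSE]
    }
    tab
  })
  names(per_tab) <- chroms
  med <- function(tab) {
    if (nrow(tab) == 0L) return(NA_real_)
    weighted_quantile(tab$value, tab$n, 0.5)
  }
  all_tab <- do.call(rbind, per_tab)
  agg <- tapply(all_tab$n, all_tab$value, sum)
  global <- weighted_quantile(as.numeric(names(agg)), as.numeric(agg), 0.5)
  list(global = global,
       per_chromosome = vapply(per_tab, med, numeric(1)))
}
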