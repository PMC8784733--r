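# Independent brute-force oracles used to pin down the interval algebra,
# the binomial/Fisher tails and the repeat finder. These deliberately use
# different mechanisms (quadratic sweeps, direct pmf summation, the base-R
# regex engine) than the implementations they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# quadratic interval union: repeatedly fuse any overlapping/bookended pair
oracle_merge <- function(df) {
  repeat {
    fused <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] &&
            df$start[i] <= df$end[j] + 1 && df$end[i] >= df$start[j] - 1) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          fused <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!fused) break
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

# exhaustive pairwise reciprocal-overlap check; returns indices of a kept
oracle_reciprocal <- function(a, b, f) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
      if (ov <= 0) next
      la <- a$end[i] - a$start[i] + 1
      lb <- b$end[j] - b$start[j] + 1
      if (ov >= f * la && ov >= f * lb) { keep[i] <- TRUE; break }
    }
  }
  which(keep)
}

# linear-scan closest feature left/right of one query (1-based closed)
oracle_closest <- function(q, feats) {
  same <- feats[feats$chrom == q$chrom, , drop = FALSE]
  res <- list(left_name = NA_character_, left_distance = NA_real_,
              right_name = NA_character_, right_distance = NA_real_)
  if (nrow(same) == 0) return(res)
  ov <- same[same$start <= q$end & same$end >= q$start, , drop = FALSE]
  if (nrow(ov)) {
    ov <- ov[order(ov$start, ov$name), , drop = FALSE]
    res$left_name <- res$right_name <- ov$name[1]
    res$left_distance <- res$right_distance <- 0
    return(res)
  }
  left <- same[same$end < q$start, , drop = FALSE]
  if (nrow(left)) {
    d <- q$start - left$end - 1
    best <- which(d == min(d))
    best <- best[order(left$start[best], left$name[best])][1]
    res$left_name <- left$name[best]
    res$left_distance <- min(d)
  }
  right <- same[same$start > q$end, , drop = FALSE]
  if (nrow(right)) {
    d <- right$start - q$end - 1
    best <- which(d == min(d))
    best <- best[order(right$start[best], right$name[best])][1]
    res$right_name <- right$name[best]
    res$right_distance <- min(d)
  }
  res
}

# upper-tail binomial probability by direct pmf summation in log space
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# one-sided Fisher p by hypergeometric tail summation:
# P(X >= k) for X ~ Hypergeom(white = k1 + k2 present, drawn = n1)
oracle_fisher_greater <- function(k1, n1, k2, n2) {
  white <- k1 + k2
  total <- n1 + n2
  i <- k1:min(white, n1)
  sum(exp(lchoose(white, i) + lchoose(total - white, n1 - i) -
            lchoose(total, n1)))
}

# regex-based perfect-repeat oracle: for every concrete non-periodic unit,
# find greedy full-unit matches, then keep only left-maximal ones (the base
# immediately before the match must not extend the same-phase chain)
oracle_repeats <- function(seq, k, masked = NULL) {
  v <- strsplit(seq, "")[[1L]]
  if (!is.null(masked) && length(masked)) v[masked] <- "N"
  seq <- paste(v, collapse = "")
  bases <- c("A", "C", "G", "T")
  units <- switch(k,
    bases,
    {u <- as.vector(outer(bases, bases, paste0)); u[substr(u,1,1) != substr(u,2,2)]},
    {u <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
     u[vapply(u, function(x) length(unique(strsplit(x, "")[[1]])) > 1, TRUE)]})
  min_units <- c(6L, 3L, 2L)[k]
  out <- list()
  for (u in units) {
    # lookahead + capture finds overlapping greedy matches (maximal runs of
    # the same unit may share up to k-1 boundary bases)
    m0 <- gregexpr(sprintf("(?=((?:%s){%d,}))", u, min_units), seq,
                   perl = TRUE)[[1L]]
    if (m0[1L] == -1L) next
    m <- as.vector(attr(m0, "capture.start"))
    len <- as.vector(attr(m0, "capture.length"))
    for (idx in seq_along(m)) {
      a <- m[idx]
      run_len <- (len[idx] %/% k) * k
      # left-maximality in the same phase: v[a-1] must not equal v[a-1+k]
      if (a > 1L && a - 1L + k <= nchar(seq) &&
          v[a - 1L] %in% bases && v[a - 1L] == v[a - 1L + k]) next
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = a + run_len - 1L, unit = substr(seq, a, a + k - 1L),
        n_units = run_len %/% k, run_length = run_len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      n_units = integer(), run_length = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_intervals_df <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                                max_len = 300) {
  st <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = st,
             end = st + sample.int(max_len, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  if (!is.null(df$name)) mcols(gr)$name <- df$name
  gr
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

# canonical row order for set comparisons (GRanges sort by seqlevels order,
# the oracles by alphabetical chromosome -- normalize both)
sort_df <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
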