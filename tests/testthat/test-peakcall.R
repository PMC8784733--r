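toy_genome <- function(len = 10000, chroms = "c1", gc = 0.5, seed = 1) {
  set.seed(seed)
  Genome(Biostrings::DNAStringSet(
    setNames(vapply(chroms, function(ch) random_dna(len, gc), ""), chroms)))
}

stack_frags <- function(chrom, start, end, n) {
  GRanges(chrom, IRanges(rep(start, n), rep(end, n)))
}

test_that("binomial tail p-values match direct pmf summation to 1e-12", {
  params <- peak_call_params()
  for (n in c(10, 50, 100, 500)) {
    for (p0 in c(0.001, 0.01, 0.1, 0.5)) {
      ks <- unique(pmin(n, c(0, 1, 2, 5, round(n * p0), round(n * p0) + 3,
                             round(2 * n * p0), n)))
      n_input <- 1e6
      got <- binomial_peak_test(ks, n, round(p0 * n_input), n_input, params)
      want <- vapply(ks, oracle_binom_tail, numeric(1), n = n, p = p0)
      want[ks == 0] <- 1
      expect_lt(max(abs(got$p_value - want)), 1e-12)
    }
  }
})

test_that("binomial test handles degenerate counts and is monotone in k", {
  r <- binomial_peak_test(0, 1000, 10, 1000)
  expect_equal(r$p_value, 1)
  expect_equal(r$enrichment, 0)
  # equal proportions give enrichment exactly 1
  expect_equal(binomial_peak_test(10, 1000, 10, 1000)$enrichment, 1)
  # zero input count: floored null, flagged, pseudocount denominator
  r0 <- binomial_peak_test(5, 1000, 0, 1000)
  expect_true(r0$flagged)
  expect_equal(r0$enrichment, 5)
  # monotone non-increasing p in k_cdna
  p <- binomial_peak_test(0:50, 100, 10, 1000)$p_value
  expect_true(all(diff(p) <= 1e-15))
  # model 1 uses the effective genome length
  p1 <- peak_call_params(model = 1)
  r1 <- binomial_peak_test(8, 1000, 0, 1000, p1, effective_length = 5e5)
  expect_equal(r1$p_value, oracle_binom_tail(8, 1000, 500 / 5e5),
               tolerance = 1e-12)
})

test_that("candidate windows sit on coverage maxima with greedy suppression", {
  g <- toy_genome()
  # triangular pileup: nested fragments sharing midpoint 5000
  frags <- GRanges("c1", IRanges(5000 - 10 * (1:20), 5000 + 10 * (1:20)))
  lib <- FragmentLibrary(frags, 1, "cdna")
  win <- candidate_windows(lib, g, peak_call_params(min_quantile = 0.5))
  expect_length(win, 1)
  # independent per-base coverage argmax
  cover <- numeric(10000)
  for (i in seq_along(frags))
    cover[start(frags)[i]:end(frags)[i]] <-
      cover[start(frags)[i]:end(frags)[i]] + 1
  expect_true(start(win) <= which.max(cover) &&
                end(win) >= which.max(cover))

  # two pileups farther apart than the peak width: two windows
  frags2 <- c(stack_frags("c1", 2000, 2080, 20),
              stack_frags("c1", 6000, 6080, 20))
  win2 <- candidate_windows(FragmentLibrary(frags2, 1, "cdna"), g,
                            peak_call_params(min_quantile = 0.5))
  expect_length(win2, 2)

  # two maxima 300 bp apart (< peak width): the higher one wins
  frags3 <- c(stack_frags("c1", 4975, 5025, 30),
              stack_frags("c1", 5275, 5325, 20))
  win3 <- candidate_windows(FragmentLibrary(frags3, 1, "cdna"), g,
                            peak_call_params(min_quantile = 0.5))
  expect_length(win3, 1)
  expect_true(countOverlaps(win3, GRanges("c1", IRanges(4975, 5025))) == 1)

  # all-zero coverage
  expect_length(candidate_windows(
    FragmentLibrary(GRanges(), 1, "cdna"), g), 0)
})

test_that("call_peaks applies the p-value and enrichment filters at their boundaries", {
  g <- toy_genome(len = 1e6, chroms = c("cA", "cB"), seed = 2)
  build <- function(k_cdna) {
    set.seed(33)
    bg_n <- 20000 - k_cdna
    bg <- GRanges("cB", IRanges(sample.int(1e6 - 900, bg_n), width = 900))
    cdna <- FragmentLibrary(
      suppressWarnings(c(stack_frags("cA", 5000, 5400, k_cdna), bg)),
      1, "cdna")
    bgi <- GRanges("cB", IRanges(sample.int(1e6 - 900, 19900), width = 900))
    input <- FragmentLibrary(
      suppressWarnings(c(stack_frags("cA", 5000, 5400, 100), bgi)),
      1, "input")
    call_peaks(cdna, input, g)
  }
  pk_lo <- build(299)   # enrichment 2.99: rejected by the >= 3 rule
  expect_equal(sum(as.character(seqnames(pk_lo)) == "cA"), 0)
  pk_hi <- build(300)   # enrichment 3.00 at p << 0.001: retained
  on_a <- pk_hi[as.character(seqnames(pk_hi)) == "cA"]
  expect_length(on_a, 1)
  expect_equal(mcols(on_a)$enrichment, 3)
  expect_equal(mcols(on_a)$k_cdna, 300)

  # significant but weakly enriched or enriched but insignificant both fail
  bt <- binomial_peak_test(c(29, 3), 10000, c(10, 1), 10000)
  expect_true(bt$p_value[1] < 0.001 && bt$enrichment[1] < 3)
  expect_true(bt$enrichment[2] >= 3 && bt$p_value[2] > 0.001)
})

test_that("excluded chromosomes are dropped from libraries and never yield peaks", {
  g <- Genome(Biostrings::DNAStringSet(c(c1 = random_dna(5000),
                                         Mt = random_dna(2000))),
              excluded = "Mt")
  frags <- suppressWarnings(
    c(stack_frags("c1", 100, 600, 7), stack_frags("Mt", 10, 500, 3)))
  lib <- FragmentLibrary(frags, 1, "cdna")
  filt <- filter_chromosomes(lib, g)
  expect_equal(filt$total_count, 7)
  expect_true(all(as.character(seqnames(filt$fragments)) == "c1"))
  # empty excluded set: identity
  g2 <- Genome(g$seq)
  expect_equal(filter_chromosomes(lib, g2)$total_count, 10)
  # per-chromosome accounting on simulated libraries
  sim <- simulate_genome(simulation_config(
    seed = 2, chrom_lengths = c(a = 3e5, b = 3e5), mt_length = 5000,
    n_genes = 10, n_enhancers = 5, n_fragments_input = 5000,
    n_fragments_cdna = 5000))
  libs <- simulate_fragments(sim$genome, sim$truth, sim$truth$config)
  tab <- table(as.character(seqnames(libs[[1]]$input$fragments)))
  filt <- filter_chromosomes(libs[[1]]$input, sim$genome)
  expect_equal(filt$total_count, sum(tab[setdiff(names(tab), "Mt")]))
})

test_that("consensus requires >= 250 bp mutual overlap across all replicates", {
  mk <- function(starts, enr = 8) {
    gr <- GRanges("c1", IRanges(starts, width = 500))
    mcols(gr) <- DataFrame(k_cdna = 100L, k_input = 10L, p_value = 1e-9,
                           enrichment = enr, flagged = FALSE, replicate = 1L)
    gr
  }
  # three identical peaks: one consensus of full width
  cons <- consensus_peaks(list(mk(1000), mk(1000), mk(1000)))
  expect_length(cons, 1)
  expect_equal(width(cons), 500)
  expect_equal(mcols(cons)$activity, log2(8))

  # staggered by 251 bp: pairwise overlap 249 -> no consensus
  expect_length(consensus_peaks(list(mk(1000), mk(1251), mk(1000))), 0)
  # staggered by 250 bp: pairwise overlap 250 -> consensus at the boundary
  cons250 <- consensus_peaks(list(mk(1000), mk(1250), mk(1000)))
  expect_length(cons250, 1)
  expect_equal(width(cons250), 250)

  # random staggered peaks against an exhaustive triple-enumeration oracle
  set.seed(21)
  for (rep in 1:5) {
    starts <- lapply(1:3, function(r)
      sort(sample(seq(1, 20000, by = 120), 25)))
    reps <- lapply(starts, mk)
    got <- consensus_peaks(reps)
    want <- list()
    for (i in seq_along(starts[[1]])) for (j in seq_along(starts[[2]]))
      for (k in seq_along(starts[[3]])) {
        s <- c(starts[[1]][i], starts[[2]][j], starts[[3]][k])
        lo <- max(s); hi <- min(s) + 499
        if (hi - lo + 1 >= 250)
          want[[length(want) + 1]] <- c(lo, hi)
      }
    want <- unique(do.call(rbind, c(list(matrix(numeric(), 0, 2)), want)))
    got_df <- unique(cbind(start(got), end(got)))
    expect_equal(nrow(got_df), if (is.null(nrow(want))) 0 else nrow(want))
    if (!is.null(nrow(want)) && nrow(want))
      expect_setequal(paste(got_df[, 1], got_df[, 2]),
                      paste(want[, 1], want[, 2]))
  }
})

test_that("coverage medians summarize non-N depth", {
  g <- Genome(Biostrings::DNAStringSet(c(c1 = strrep("A", 100))))
  lib <- FragmentLibrary(GRanges("c1", IRanges(1, 100)), 1, "input")
  expect_equal(coverage_median(lib, g)$global, 1)
  expect_equal(coverage_median(FragmentLibrary(GRanges(), 1, "input"),
                               g)$global, 0)
  # N positions are excluded from the median
  gN <- Genome(Biostrings::DNAStringSet(
    c(c1 = paste0(strrep("A", 40), strrep("N", 60)))))
  libN <- FragmentLibrary(GRanges("c1", IRanges(1, 40)), 1, "input")
  expect_equal(coverage_median(libN, gN)$global, 1)

  # uniform library: median within 10% of n * mean_len / genome_len
  cfg <- simulation_config(seed = 6, chrom_lengths = c(a = 5e5),
                           mt_length = 0, n_genes = 8, n_enhancers = 4,
                           enhancer_fold = 1, n_fragments_input = 30000,
                           n_fragments_cdna = 1000, n_replicates = 1)
  sim <- simulate_genome(cfg)
  libs <- simulate_fragments(sim$genome, sim$truth, cfg)
  med <- coverage_median(libs[[1]]$input, sim$genome)$global
  expected <- 30000 * 900 / 5e5
  expect_lt(abs(med - expected) / expected, 0.1)
})
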