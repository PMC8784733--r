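test_that("gc_content excludes N from numerator and denominator", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGN"), 2 / 3)
  expect_true(is.na(gc_content("NNNN")))
  set.seed(3)
  s <- random_dna(500)
  at <- 1 - gc_content(s)
  expect_equal(gc_content(s) + at, 1)
})

test_that("perfect repeat runs follow the unit-count thresholds and leftmost phase", {
  r <- find_perfect_repeats("AAAAAA", 1)
  expect_equal(r$unit, "A")
  expect_equal(r$n_units, 6)
  expect_equal(find_perfect_repeats("AAAAA", 1)$unit, character()) # 5 < 6

  r2 <- find_perfect_repeats("ATATAT", 2)
  expect_equal(r2$unit, "AT")
  expect_equal(r2$n_units, 3)
  expect_equal(nrow(find_perfect_repeats("ATATAT", 1)), 0)

  r3 <- find_perfect_repeats("ATCATC", 3)
  expect_equal(r3$unit, "ATC")
  expect_equal(r3$n_units, 2)
  expect_equal(nrow(find_perfect_repeats("ATCAT", 3)), 0)  # 5 bp < 6

  # trailing partial unit is not counted; unit read at leftmost phase
  r4 <- find_perfect_repeats("ATATATA", 2)
  expect_equal(r4$unit, "AT")
  expect_equal(r4$run_length, 6)
  expect_equal(r4$start, 1)
  r5 <- find_perfect_repeats("CACACAC", 2)
  expect_equal(r5$unit, "CA")
  expect_equal(r5$start, 1)

  # periodic units are never reported at larger unit lengths
  expect_equal(nrow(find_perfect_repeats("AAAAAAAA", 2)), 0)
  expect_equal(nrow(find_perfect_repeats("AAAAAAAAA", 3)), 0)
  # N breaks runs
  expect_equal(nrow(find_perfect_repeats("ATANATAT", 2)), 0)
})

test_that("hierarchical exclusion masks smaller-unit runs before larger scans", {
  s <- paste0("CCCCCCC", "ATATATAT", "GGG")
  sr <- scan_repeats(s)
  expect_equal(sr$mono$unit, "C")
  expect_equal(sr$mono$end, 7)
  expect_equal(sr$di$unit, "AT")
  expect_equal(sr$di$start, 8)  # the mono run does not seed the AT run
  # a mono run bleeding into the following bases is masked before di scan
  sr2a <- scan_repeats(paste0("AAAAAAA", "ATATATAT"))
  expect_equal(sr2a$mono$end, 8)        # the eighth A extends the mono run
  expect_equal(sr2a$di$start, 9)        # di scan starts after the mask
  expect_equal(sr2a$di$unit, "TA")
  # a dinucleotide run is masked before the trinucleotide scan
  s2 <- strrep("CACACA", 2)  # CA run of 12, also matchable as period-3 ACA
  sr2 <- scan_repeats(s2)
  expect_equal(nrow(sr2$tri), 0)
  expect_equal(sr2$di$run_length, 12)
})

test_that("the repeat finder matches the regex oracle on random sequences", {
  set.seed(101)
  for (i in 1:100) {
    # AT-skewed alphabet so that runs are frequent
    s <- paste(sample(c("A", "T", "C", "G", "A", "T"), 1000, TRUE),
               collapse = "")
    for (k in 1:3) {
      got <- find_perfect_repeats(s, k)
      want <- oracle_repeats(s, k)
      expect_equal(got[order(got$start), c("start", "end", "unit")],
                   want[, c("start", "end", "unit")], ignore_attr = TRUE,
                   label = sprintf("seq %d unit length %d", i, k))
    }
  }
})

test_that("repeat profiles summarize presence, counts and sequence fraction", {
  p <- repeat_profile(c("AAAAAACCCCCC", "ACGTACGTACGT"), 1)
  expect_equal(p$table$n_runs, c(2, 0))
  expect_equal(p$table$fraction, c(1, 0))
  expect_true(p$presence[1, "A"] && p$presence[1, "C"])
  expect_false(any(p$presence[2, ]))
  # planted synthetic enhancers carry their configured repeat unit
  sim <- simulate_genome(simulation_config(
    seed = 5, chrom_lengths = c(a = 4e5), mt_length = 0, n_genes = 8,
    n_enhancers = 10, n_fragments_input = 1000, n_fragments_cdna = 1000,
    planted_repeat_units = "CA"))
  seqs <- interval_sequences(sim$truth$enhancers, sim$genome)
  pres <- repeat_profile(seqs, 2)$presence
  expect_true(all(pres[, "CA"] | pres[, "AC"]))
})

test_that("the gatekeeping consensus procedure issues correct verdicts", {
  set.seed(6)
  base <- rnorm(300)
  controls <- lapply(1:10, function(i) rnorm(300))
  # identical distributions: not significant
  r <- consensus_compare(rnorm(300), controls)
  expect_equal(r$verdict, "not_significant")
  # extreme separation: enriched with all ten tests agreeing
  r2 <- consensus_compare(base + 3, lapply(1:10, function(i) rnorm(300)))
  expect_equal(r2$verdict, "enriched_in_enhancers")
  expect_true(all(r2$mwu_p < 0.001))
  expect_true(all(r2$directions == 1))
  r3 <- consensus_compare(base - 3, lapply(1:10, function(i) rnorm(300)))
  expect_equal(r3$verdict, "depleted_in_enhancers")
  # heterogeneous controls trip the gate before any comparison
  het <- c(lapply(1:9, function(i) rnorm(300)), list(rnorm(300) + 2))
  r4 <- consensus_compare(base, het)
  expect_equal(r4$verdict, "controls_heterogeneous")
  expect_true(is.na(r4$omnibus_kw_p))
  # all-10 rule: nine significant post-hoc tests are not enough
  expect_equal(starrscout:::posthoc_verdict(
    c(rep(1e-6, 9), 0.5), rep(1, 10)), "not_significant")
  expect_equal(starrscout:::posthoc_verdict(rep(1e-6, 10), rep(1, 10)),
               "enriched_in_enhancers")
  # direction unanimity: one control shifting the other way blocks a verdict
  expect_equal(starrscout:::posthoc_verdict(
    rep(1e-6, 10), c(rep(1, 9), -1)), "not_significant")
  expect_error(consensus_compare(1:10, list(1:5)), "set size")
})

test_that("dinucleotide class enrichment computes log2 FE with its invariances", {
  # identical sets: log2 FE exactly 0
  set.seed(8)
  seqs <- vapply(1:50, function(i)
    paste0(random_dna(200), if (i <= 20) "CACACACA" else "",
           random_dna(100)), "")
  d0 <- suppressWarnings(
    dinucleotide_enrichment(seqs, lapply(1:10, function(i) seqs)))
  expect_true(all(d0$log2_fe_mean[d0$n_sets_used > 0] == 0))

  # enhancer fraction 0.42 vs control 0.21 in every set: log2 FE = 1 +- 0
  mk <- function(frac, n = 100) vapply(seq_len(n), function(i)
    if (i <= frac * n) paste0("GGTTGG", "CACACA", "GGTTGG")
    else "GGTTGGTTGGTTGGTTGG", "")
  d1 <- suppressWarnings(
    dinucleotide_enrichment(mk(0.42), lapply(1:10, function(i) mk(0.21))))
  ca <- d1[d1$class == "CA", ]
  expect_equal(ca$log2_fe_mean, 1)
  expect_equal(ca$log2_fe_sd, 0)

  # antisymmetry under swapping enhancer and control roles
  a <- vapply(1:60, function(i) random_dna(300, gc = 0.6), "")
  b0 <- vapply(1:60, function(j) random_dna(300, gc = 0.3), "")
  b <- lapply(1:10, function(i) b0)
  d_ab <- suppressWarnings(dinucleotide_enrichment(a, b))
  d_ba <- suppressWarnings(
    dinucleotide_enrichment(b0, lapply(1:10, function(i) a)))
  for (cl in c("CA", "GA", "GC", "TA")) {
    x <- d_ab[d_ab$class == cl, ]
    y <- d_ba[d_ba$class == cl, ]
    if (x$n_sets_used == 10 && y$n_sets_used == 10)
      expect_equal(x$log2_fe_mean, -y$log2_fe_mean, tolerance = 1e-9)
  }

  # reverse-complementing every sequence leaves class fractions unchanged
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  d_fwd <- suppressWarnings(dinucleotide_enrichment(a, b))
  d_rc <- suppressWarnings(
    dinucleotide_enrichment(vapply(a, rc, ""),
                            lapply(b, function(s) vapply(s, rc, ""))))
  expect_equal(d_fwd$enhancer_fraction, d_rc$enhancer_fraction)
  expect_equal(d_fwd$log2_fe_mean, d_rc$log2_fe_mean)
})
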