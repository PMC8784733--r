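test_that("FASTA reading normalizes case and ambiguity codes and round trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  g <- read_genome_fasta(f)
  expect_equal(unname(genome_lengths(g)), 4)
  expect_equal(as.character(g$seq[["chr1"]]), "ACGT")

  writeLines(c(">chr1 description text", "acgn", "ryswkd"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g$seq[["chr1"]]), "ACGNNNNNNN")

  writeLines(character(), f)
  expect_error(read_genome_fasta(f), "format error")
  writeLines(c("ACGT"), f)
  expect_error(read_genome_fasta(f), "expected '>'")

  # round trip through the writer
  set.seed(11)
  g0 <- Genome(Biostrings::DNAStringSet(
    c(a = random_dna(3000), b = random_dna(1234))))
  write_genome_fasta(g0, f)
  g1 <- read_genome_fasta(f)
  expect_identical(as.character(g1$seq), as.character(g0$seq))
})

test_that("BED round trips are bit-exact and malformed lines are rejected", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t500", f)
  gr <- read_bed(f)
  expect_equal(width(gr), 500)
  expect_equal(start(gr), 1)  # 0-based BED -> 1-based internal

  set.seed(42)
  df <- random_intervals_df(1000, max_pos = 1e6)
  gr0 <- df_to_gr(df)
  mcols(gr0)$name <- sprintf("iv%04d", seq_along(gr0))
  mcols(gr0)$score <- as.character(sample(0:1000, 1000, TRUE))
  write_bed(gr0, f)
  raw1 <- readLines(f)
  gr1 <- read_bed(f)
  write_bed(gr1, f)
  expect_identical(readLines(f), raw1)
  expect_equal(start(gr1), start(gr0))
  expect_equal(end(gr1), end(gr0))
  expect_equal(mcols(gr1)$name, mcols(gr0)$name)

  writeLines(c("chr1\t0\t10", "chr1\t10\t5"), f)
  expect_error(read_bed(f), "line 2.*start >= end")
  writeLines("chr1\t1.5\t10", f)
  expect_error(read_bed(f), "non-integer")
  writeLines("chr1\t5", f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("merge_intervals matches bedtools default semantics and a quadratic oracle", {
  gr <- df_to_gr(data.frame(chrom = "c", start = c(1, 6), end = c(10, 15)))
  expect_equal(gr_to_df(merge_intervals(gr)),
               data.frame(chrom = "c", start = 1, end = 15))
  # bookended intervals (end == next start in 0-based terms) are unified
  gr <- df_to_gr(data.frame(chrom = "c", start = c(1, 11), end = c(10, 20)))
  expect_equal(gr_to_df(merge_intervals(gr))$end, 20)

  set.seed(7)
  for (rep in 1:3) {
    df <- random_intervals_df(500)
    m <- merge_intervals(df_to_gr(df))
    o <- oracle_merge(df)
    expect_equal(sort_df(gr_to_df(m)), sort_df(o), ignore_attr = TRUE)
    # idempotence and covered-base conservation
    expect_equal(gr_to_df(merge_intervals(m)), gr_to_df(m))
    covered <- sum(width(reduce(df_to_gr(df))))
    expect_equal(sum(width(m)), covered)
  }
})

test_that("reciprocal_overlap enforces the fraction on both intervals", {
  # overlap of 10 is 10% of the 100-bp query but ~1% of the 910-bp subject
  a <- df_to_gr(data.frame(chrom = "c", start = 1, end = 100))
  b <- df_to_gr(data.frame(chrom = "c", start = 91, end = 1000))
  expect_length(reciprocal_overlap(a, b, 0.1), 0)
  b2 <- df_to_gr(data.frame(chrom = "c", start = 51, end = 150))
  expect_length(reciprocal_overlap(a, b2, 0.1), 1)

  set.seed(99)
  for (rep in 1:3) {
    da <- random_intervals_df(200)
    db <- random_intervals_df(200)
    got <- reciprocal_overlap(df_to_gr(da), df_to_gr(db), 0.1)
    expect_equal(sort_df(gr_to_df(got)),
                 sort_df(da[oracle_reciprocal(da, db, 0.1), ]),
                 ignore_attr = TRUE)
  }
  # symmetric membership for equal-length intervals
  set.seed(5)
  da <- random_intervals_df(100); da$end <- da$start + 99
  db <- random_intervals_df(100); db$end <- db$start + 99
  ga <- df_to_gr(da); gb <- df_to_gr(db)
  expect_equal(length(reciprocal_overlap(ga, gb, 0.3)) > 0,
               length(reciprocal_overlap(gb, ga, 0.3)) > 0)
})

test_that("closest_feature reports gap distances with deterministic ties", {
  # 0-based peak (100,200), gene (150,400): overlap -> distance 0
  q <- df_to_gr(data.frame(chrom = "c", start = 101, end = 200))
  feats <- df_to_gr(data.frame(chrom = "c", start = 151, end = 400,
                               name = "g1"))
  r <- closest_feature(q, feats)
  expect_equal(r$left_distance, 0)
  expect_equal(r$left_name, "g1")

  # 0-based genes (0,50) and (300,400): left gap 50, right gap 100
  feats <- df_to_gr(data.frame(chrom = "c", start = c(1, 301),
                               end = c(50, 400), name = c("gl", "gr")))
  r <- closest_feature(q, feats)
  expect_equal(r$left_distance, 50)
  expect_equal(r$right_distance, 100)
  expect_equal(r$right_name, "gr")

  # no feature on the chromosome -> absent sides
  r <- closest_feature(df_to_gr(data.frame(chrom = "other", start = 5,
                                           end = 10)), feats)
  expect_true(is.na(r$left_name) && is.na(r$right_name))

  set.seed(13)
  for (rep in 1:3) {
    fdf <- random_intervals_df(60)
    fdf$name <- sprintf("f%02d", seq_len(nrow(fdf)))
    qdf <- random_intervals_df(40)
    got <- closest_feature(df_to_gr(qdf), df_to_gr(fdf))
    for (i in seq_len(nrow(qdf))) {
      o <- oracle_closest(qdf[i, ], fdf)
      expect_equal(got$left_distance[i], o$left_distance)
      expect_equal(got$right_distance[i], o$right_distance)
      expect_equal(got$left_name[i], o$left_name)
      expect_equal(got$right_name[i], o$right_name)
    }
  }
})

make_two_exon_tx <- function(strand, utr_first_exon = TRUE) {
  # two exons [1,100], [201,300]; CDS confined to one exon so the single
  # intron sits between a UTR-only exon and the first coding exon
  genes <- df_to_gr(data.frame(chrom = "c", start = 1, end = 300,
                               name = "g"))
  tx <- df_to_gr(data.frame(chrom = "c", start = 1, end = 300, name = "t"))
  mcols(tx)$gene <- "g"
  strand(genes) <- strand(tx) <- strand
  ex <- df_to_gr(data.frame(chrom = "c", start = c(1, 201),
                            end = c(100, 300)))
  mcols(ex)$tx <- "t"
  if ((strand == "+") == utr_first_exon) {
    u5 <- ex[1]; cds <- ex[2]
  } else {
    u5 <- ex[2]; cds <- ex[1]
  }
  GeneAnnotation(genes, tx, exons = ex, cds = cds, utr5 = u5)
}

test_that("derive_introns labels ordinals strand-aware, 5'UTR intron included", {
  ann <- make_two_exon_tx("+")
  ann <- derive_introns(ann)
  expect_equal(start(ann$introns), 101)
  expect_equal(end(ann$introns), 200)
  expect_equal(mcols(ann$introns)$label, "5utr_intron")

  # minus-strand mirror: the same (rightmost-UTR) gap gets the same label
  annm <- derive_introns(make_two_exon_tx("-"))
  expect_equal(mcols(annm$introns)$label, "5utr_intron")
  expect_equal(start(annm$introns), 101)

  # CDS in both exons: the gap is the first coding intron
  ann2 <- make_two_exon_tx("+")
  mcols_cds <- ann2$exons
  ann2$cds <- mcols_cds
  ann2 <- derive_introns(ann2)
  expect_equal(mcols(ann2$introns)$label, "intron_1")

  # overlapping exons are an annotation error
  bad <- make_two_exon_tx("+")
  bad$exons <- df_to_gr(data.frame(chrom = "c", start = c(1, 50),
                                   end = c(100, 300)))
  mcols(bad$exons)$tx <- "t"
  expect_error(derive_introns(bad), "overlapping exons")

  # single-exon transcripts yield no introns
  single <- make_two_exon_tx("+")
  single$exons <- single$exons[1]
  single <- derive_introns(single)
  expect_length(single$introns, 0)
})

test_that("exons and introns tile the transcript span without overlap", {
  sim <- simulate_genome(simulation_config(
    seed = 3, chrom_lengths = c(a = 3e5, b = 3e5), mt_length = 0,
    n_genes = 12, n_enhancers = 4, n_fragments_input = 1000,
    n_fragments_cdna = 1000))
  ann <- sim$annotation
  for (t in mcols(ann$transcripts)$name) {
    ex <- ann$exons[mcols(ann$exons)$tx == t]
    intr <- ann$introns[mcols(ann$introns)$tx == t]
    expect_equal(sum(countOverlaps(intr, ex)), 0)
    span <- range(c(granges(ex), granges(intr)), ignore.strand = TRUE)
    tx <- ann$transcripts[mcols(ann$transcripts)$name == t]
    expect_equal(start(span), start(tx))
    expect_equal(end(span), end(tx))
    expect_equal(sum(width(ex)) + sum(width(intr)), width(tx))
  }
})
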