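# Deterministic synthetic study generator: toy multi-chromosome genome with
# N-gaps, single-isoform gene models with explicit UTRs, planted enhancers
# (elevated GC, planted dinucleotide repeats and motif instances), and
# per-replicate STARR-seq fragment libraries with configurable cDNA
# enrichment over the planted enhancers.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Built-in demonstration motifs
#'
#' Six deterministic synthetic PFMs (not derived from any motif database;
#' the ids carry a `syn` prefix). The first two are the default planted
#' motifs of the simulator; the rest serve as non-planted decoys in
#' enrichment tests.
#'
#' @return List of [pwm] objects.
#' @export
demo_motifs <- function() {
  consensi <- c(synCRE = "TGACGTCA", synEBOX = "CACGTGAC",
                synGATA = "GATAAGAT", synPOU = "TTATGCAA",
                synETS = "CCGGAAGT", synZIC = "AGGGTATA")
  lapply(names(consensi), function(id) {
    b <- match(strsplit(consensi[[id]], "")[[1L]], c("A", "C", "G", "T"))
    counts <- matrix(5, nrow = 4, ncol = length(b))
    counts[cbind(b, seq_along(b))] <- 85
    pwm(id, counts)
  })
}

#' Simulation configuration
#'
#' The defaults are the package's reference study conditions: a 5-Mb toy
#' genome of five 1-Mb chromosome arms plus a small excluded mitochondrial
#' sequence, background GC 0.44 with a +0.06 GC shift inside enhancers
#' (mirroring the direction and size of the enhancer/control GC contrast the
#' assay is designed to detect), 60 genes, 60 planted enhancers of
#' 600-1000 bp (about 12 per Mb, the genome-wide density a saturating
#' screen reports) at 8-fold cDNA enrichment, fragments of 800-1000 bp,
#' 380,000 fragments per channel per replicate -- about 68x median genome
#' coverage, the depth a genome-wide STARR-seq screen attains after
#' cloning -- and three biological replicates.
#'
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the seed.
#' @param chrom_lengths Named integer vector of analysed chromosome lengths.
#' @param mt_length Length of the additional excluded `Mt` chromosome
#'   (0 = none).
#' @param background_gc Background GC fraction.
#' @param gc_shift GC added inside planted enhancers.
#' @param n_genes,n_enhancers Feature counts.
#' @param enhancer_length_range,fragment_length_range Length ranges (bases).
#' @param enhancer_fold Multiplicative cDNA fragment-rate enrichment over
#'   planted enhancers (1 = null screen).
#' @param n_fragments_input,n_fragments_cdna Fragments per replicate.
#' @param n_replicates Biological replicates.
#' @param planted_repeat_units Dinucleotide units planted in enhancers.
#' @param planted_motifs List of [pwm]s planted in every enhancer
#'   (default: first two of [demo_motifs()]).
#' @param n_fraction Fraction of N-gap bases per chromosome.
#' @param class_mix Probabilities of placing an enhancer in intergenic vs
#'   intronic space.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c("2R" = 1e6, "2L" = 1e6,
                                                "3R" = 1e6, "3L" = 1e6,
                                                "X" = 1e6),
                              mt_length = 15000L,
                              background_gc = 0.44, gc_shift = 0.06,
                              n_genes = 60L, n_enhancers = 60L,
                              enhancer_length_range = c(600L, 1000L),
                              enhancer_fold = 8,
                              fragment_length_range = c(800L, 1000L),
                              n_fragments_input = 380000L,
                              n_fragments_cdna = 380000L,
                              n_replicates = 3L,
                              planted_repeat_units = c("CA", "GC"),
                              planted_motifs = NULL,
                              n_fraction = 0.005,
                              class_mix = c(intergenic = 0.53,
                                            intronic = 0.47)) {
  if (is.null(planted_motifs)) planted_motifs <- demo_motifs()[1:2]
  cfg <- structure(list(seed = as.integer(seed),
                        chrom_lengths = chrom_lengths, mt_length = mt_length,
                        background_gc = background_gc, gc_shift = gc_shift,
                        n_genes = as.integer(n_genes),
                        n_enhancers = as.integer(n_enhancers),
                        enhancer_length_range = enhancer_length_range,
                        enhancer_fold = enhancer_fold,
                        fragment_length_range = fragment_length_range,
                        n_fragments_input = as.integer(n_fragments_input),
                        n_fragments_cdna = as.integer(n_fragments_cdna),
                        n_replicates = as.integer(n_replicates),
                        planted_repeat_units = planted_repeat_units,
                        planted_motifs = planted_motifs,
                        n_fraction = n_fraction,
                        class_mix = class_mix / sum(class_mix)),
                   class = "SimulationConfig")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(all(cfg$chrom_lengths > 0), cfg$n_genes > 0, cfg$n_enhancers > 0,
            cfg$n_replicates >= 1, cfg$enhancer_fold >= 1,
            cfg$background_gc >= 0, cfg$background_gc <= 1,
            cfg$background_gc + cfg$gc_shift <= 1,
            cfg$n_fraction >= 0, cfg$n_fraction < 1,
            cfg$n_fragments_input > 0, cfg$n_fragments_cdna > 0,
            diff(cfg$enhancer_length_range) >= 0,
            diff(cfg$fragment_length_range) >= 0)
  if (cfg$fragment_length_range[2] >= min(cfg$chrom_lengths))
    stop("fragment length range exceeds the shortest chromosome")
  invisible(cfg)
}

# uniform non-overlapping placement with a margin, by rejection; intervals
# are tracked as a plain data.frame to keep the inner loop cheap
df_overlaps <- function(chrom, start, end, df, margin = 0L) {
  if (nrow(df) == 0L) return(FALSE)
  same <- df$chrom == chrom
  any(same & df$start <= end + margin & df$end >= start - margin)
}

place_intervals <- function(n, lengths_of, chrom_lengths, occupied,
                            margin = 0L, end_buffer = 0L,
                            max_attempts = 200L) {
  placed <- occupied[0, , drop = FALSE]
  for (i in seq_len(n)) {
    len <- lengths_of(i)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ch <- sample(names(chrom_lengths), 1L,
                   prob = as.numeric(chrom_lengths))
      lo <- 1L + end_buffer
      hi <- chrom_lengths[[ch]] - len - end_buffer + 1L
      if (hi < lo) next
      st <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      if (!df_overlaps(ch, st, st + len - 1L, occupied, margin) &&
          !df_overlaps(ch, st, st + len - 1L, placed, margin)) {
        placed <- rbind(placed,
                        data.frame(chrom = ch, start = st,
                                   end = st + len - 1L,
                                   stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("sizing error: could not place interval ", i, " of ", n,
           " (genome too crowded for the requested configuration)")
  }
  placed
}

empty_df <- function()
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)

#' Simulate a genome, annotation and planted-enhancer truth table
#'
#' Generates chromosome sequences at the configured background GC, places
#' single-isoform gene models (3-6 exons with explicit 5'/3' UTRs), plants
#' non-overlapping enhancers in intergenic or intronic space according to
#' `class_mix`, rewrites each enhancer's sequence at `background_gc +
#' gc_shift` with one planted dinucleotide repeat run and one instance of
#' each planted motif, and inserts N-gap blocks outside genes and enhancers.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with elements `genome` ([Genome]), `annotation`
#'   ([GeneAnnotation]) and `truth` (list: `enhancers` `GRanges` with `fold`,
#'   `class`, `repeat_unit`; `repeats` and `motifs` `GRanges` of planted
#'   instances; `config`).
#' @export
simulate_genome <- function(config = simulation_config()) {
  validate_config(config)
  with_seed(config$seed, {
    cl <- config$chrom_lengths
    seqs <- vapply(names(cl), function(ch)
      rand_dna(cl[[ch]], config$background_gc), "")

    # --- gene models ---------------------------------------------------
    gene_structures <- lapply(seq_len(config$n_genes), function(i) {
      n_ex <- sample(3:6, 1L)
      ex_len <- sample(150:450, n_ex, replace = TRUE)
      in_len <- sample(300:1500, n_ex - 1L, replace = TRUE)
      # half the genes get a UTR-only first exon (CDS starting in exon 2),
      # so the annotation exercises the 5'UTR-intron class
      list(n_ex = n_ex, ex_len = ex_len, in_len = in_len,
           utr5 = sample(100:140, 1L), utr3 = sample(100:140, 1L),
           u5_full = runif(1) < 0.5,
           span = sum(ex_len) + sum(in_len))
    })
    buf <- config$fragment_length_range[2]
    gene_df <- place_intervals(
      config$n_genes, function(i) gene_structures[[i]]$span, cl,
      empty_df(), margin = 500L, end_buffer = buf)
    gene_spans <- GRanges(gene_df$chrom, IRanges(gene_df$start, gene_df$end))
    strand(gene_spans) <- sample(c("+", "-"), config$n_genes, replace = TRUE)

    genes <- gene_spans
    mcols(genes)$name <- sprintf("gene_%03d", seq_len(config$n_genes))
    transcripts <- gene_spans
    mcols(transcripts)$name <- sprintf("tx_%03d", seq_len(config$n_genes))
    mcols(transcripts)$gene <- mcols(genes)$name
    ex_l <- cds_l <- u5_l <- u3_l <- list()
    row <- function(ch, s, e, tx) data.frame(chrom = ch, start = s, end = e,
                                             tx = tx, stringsAsFactors = FALSE)
    for (i in seq_len(config$n_genes)) {
      gs <- gene_structures[[i]]
      g0 <- start(gene_spans)[i]
      ch <- as.character(seqnames(gene_spans))[i]
      minus <- as.character(strand(gene_spans))[i] == "-"
      es <- g0 + cumsum(c(0L, head(gs$ex_len, -1L) + gs$in_len))
      ee <- es + gs$ex_len - 1L
      n <- gs$n_ex
      tx <- mcols(transcripts)$name[i]
      # UTRs live at the transcription-direction ends of the terminal exons;
      # the CDS is everything exonic between them
      cs <- es; ce <- ee
      cds_keep <- rep(TRUE, n)
      if (minus) {
        if (gs$u5_full) {
          u5_l[[i]] <- row(ch, es[n], ee[n], tx)
          cds_keep[n] <- FALSE
        } else {
          u5_l[[i]] <- row(ch, ee[n] - gs$utr5 + 1L, ee[n], tx)
          ce[n] <- ee[n] - gs$utr5
        }
        u3_l[[i]] <- row(ch, es[1L], es[1L] + gs$utr3 - 1L, tx)
        cs[1L] <- es[1L] + gs$utr3
      } else {
        if (gs$u5_full) {
          u5_l[[i]] <- row(ch, es[1L], ee[1L], tx)
          cds_keep[1L] <- FALSE
        } else {
          u5_l[[i]] <- row(ch, es[1L], es[1L] + gs$utr5 - 1L, tx)
          cs[1L] <- es[1L] + gs$utr5
        }
        u3_l[[i]] <- row(ch, ee[n] - gs$utr3 + 1L, ee[n], tx)
        ce[n] <- ee[n] - gs$utr3
      }
      ex_l[[i]] <- row(ch, es, ee, tx)
      cds_l[[i]] <- row(ch, cs[cds_keep], ce[cds_keep], tx)
    }
    df2gr <- function(l) {
      d <- do.call(rbind, l)
      gr <- GRanges(d$chrom, IRanges(d$start, d$end))
      mcols(gr)$tx <- d$tx
      gr
    }
    ann <- GeneAnnotation(genes, transcripts, exons = df2gr(ex_l),
                          cds = df2gr(cds_l), utr5 = df2gr(u5_l),
                          utr3 = df2gr(u3_l))
    ann <- derive_introns(ann)

    # --- planted enhancers ---------------------------------------------
    e_len <- sample(config$enhancer_length_range[1]:
                      config$enhancer_length_range[2],
                    config$n_enhancers, replace = TRUE)
    e_class <- sample(names(config$class_mix), config$n_enhancers,
                      replace = TRUE, prob = config$class_mix)
    wide_introns <- ann$introns[width(ann$introns) >= max(e_len) + 60L]
    if (length(wide_introns) == 0L && any(e_class == "intronic"))
      stop("sizing error: no intron is wide enough for intronic enhancers")
    enh_df <- empty_df()
    for (i in seq_len(config$n_enhancers)) {
      placed <- FALSE
      for (att in seq_len(500L)) {
        if (e_class[i] == "intronic") {
          intr <- wide_introns[sample.int(length(wide_introns), 1L)]
          slack <- width(intr) - e_len[i] - 40L
          st <- start(intr) + 20L + sample.int(slack + 1L, 1L) - 1L
          ch <- as.character(seqnames(intr))
        } else {
          ch <- sample(names(cl), 1L, prob = as.numeric(cl))
          hi <- cl[[ch]] - e_len[i] - buf + 1L
          st <- sample.int(hi - buf, 1L) + buf
          if (df_overlaps(ch, st, st + e_len[i] - 1L, gene_df, 100L)) next
        }
        if (!df_overlaps(ch, st, st + e_len[i] - 1L, enh_df, 200L)) {
          enh_df <- rbind(enh_df,
                          data.frame(chrom = ch, start = st,
                                     end = st + e_len[i] - 1L,
                                     stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("sizing error: could not place enhancer ", i,
             " (reduce n_enhancers or enhancer length)")
    }
    enh <- GRanges(enh_df$chrom, IRanges(enh_df$start, enh_df$end))
    mcols(enh)$name <- sprintf("planted_%03d", seq_len(config$n_enhancers))
    mcols(enh)$fold <- config$enhancer_fold
    mcols(enh)$class <- e_class

    # rewrite enhancer sequence: shifted GC, planted repeat run and motifs
    rep_units <- sample(config$planted_repeat_units, config$n_enhancers,
                        replace = TRUE)
    mcols(enh)$repeat_unit <- rep_units
    rep_l <- motif_l <- list()
    for (i in seq_len(config$n_enhancers)) {
      len <- e_len[i]
      s <- rand_dna(len, config$background_gc + config$gc_shift)
      inserts <- c(strrep(rep_units[i], sample(7:10, 1L)),
                   vapply(config$planted_motifs, pwm_consensus, ""))
      n_ins <- length(inserts)
      seg <- floor(len / n_ins)
      offs <- integer(n_ins)
      for (j in seq_len(n_ins)) {
        w <- nchar(inserts[j])
        offs[j] <- (j - 1L) * seg + sample.int(seg - w, 1L)
        substr(s, offs[j] + 1L, offs[j] + w) <- inserts[j]
      }
      ch <- as.character(seqnames(enh))[i]
      st <- start(enh)[i]
      substr(seqs[[ch]], st, st + len - 1L) <- s
      rep_l[[i]] <- GRanges(ch, IRanges(st + offs[1L],
                                        width = nchar(inserts[1L])),
                            unit = rep_units[i])
      motif_l[[i]] <- GRanges(
        ch, IRanges(st + offs[-1L], width = nchar(inserts[-1L])),
        motif = vapply(config$planted_motifs, `[[`, "", "id"))
    }

    # --- N-gaps outside genes and enhancers ----------------------------
    avoid <- rbind(gene_df, enh_df)
    gaps_df <- empty_df()
    if (config$n_fraction > 0) {
      per_chrom_gap <- round(config$n_fraction * as.numeric(cl))
      for (ci in seq_along(cl)) {
        remaining <- per_chrom_gap[ci]
        while (remaining >= 500L) {
          glen <- min(remaining, sample(2000:6000, 1L))
          got <- tryCatch(place_intervals(
            1L, function(i) glen, cl[ci], rbind(avoid, gaps_df),
            margin = 50L, end_buffer = 0L),
            error = function(e) NULL)
          if (is.null(got)) break
          gaps_df <- rbind(gaps_df, got)
          remaining <- remaining - glen
        }
      }
      for (i in seq_len(nrow(gaps_df)))
        substr(seqs[[gaps_df$chrom[i]]], gaps_df$start[i], gaps_df$end[i]) <-
          strrep("N", gaps_df$end[i] - gaps_df$start[i] + 1L)
    }
    gaps <- GRanges(gaps_df$chrom, IRanges(gaps_df$start, gaps_df$end))

    if (config$mt_length > 0)
      seqs <- c(seqs, Mt = rand_dna(config$mt_length, config$background_gc))
    genome <- Genome(DNAStringSet(seqs),
                     excluded = if (config$mt_length > 0) "Mt"
                                else character())
    truth <- list(enhancers = enh,
                  repeats = suppressWarnings(do.call(c, rep_l)),
                  motifs = suppressWarnings(do.call(c, motif_l)),
                  n_gaps = gaps, config = config)
    list(genome = genome, annotation = ann, truth = truth)
  })
}

# membership of positions in a set of sorted, disjoint intervals, by
# chromosome-wise findInterval -- cheap enough to call on millions of points
points_in_ranges <- function(chr, pos, range_df) {
  hit <- logical(length(pos))
  if (is.null(range_df) || nrow(range_df) == 0L) return(hit)
  for (ch in unique(range_df$chrom)) {
    r <- range_df[range_df$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    sel <- which(chr == ch)
    if (length(sel) == 0L) next
    idx <- findInterval(pos[sel], r$start)
    hit[sel] <- idx > 0L & pos[sel] <= r$end[pmax(idx, 1L)]
  }
  hit
}

sample_fragments <- function(n, genome_lengths, len_range, accept_fun,
                             batch_factor = 1.3) {
  chs <- character(0); sts <- integer(0); lens <- integer(0)
  while (length(chs) < n) {
    m <- ceiling((n - length(chs)) * batch_factor) + 100L
    ch <- sample(names(genome_lengths), m, replace = TRUE,
                 prob = as.numeric(genome_lengths))
    len <- sample(len_range[1]:len_range[2], m, replace = TRUE)
    st <- as.integer(floor(runif(m, min = 1,
                                 max = genome_lengths[ch] - len + 1)))
    keep <- accept_fun(ch, st, len)
    chs <- c(chs, ch[keep]); sts <- c(sts, st[keep])
    lens <- c(lens, len[keep])
  }
  GRanges(chs[seq_len(n)], IRanges(sts[seq_len(n)],
                                   width = lens[seq_len(n)]))
}

#' Simulate per-replicate STARR-seq fragment libraries
#'
#' Input (plasmid) fragments are uniform over the non-N genome; cDNA
#' fragments have their start rate multiplied by `enhancer_fold` wherever
#' the fragment midpoint falls inside a planted enhancer (implemented by
#' thinning a uniform proposal). Fragment lengths are uniform on
#' `fragment_length_range`. Per-replicate RNG streams are derived as
#' `seed + replicate`.
#'
#' @param genome A [Genome] from [simulate_genome()].
#' @param truth The matching truth table.
#' @param config The [simulation_config()] used for the genome.
#' @return List of length `n_replicates`; each element is a list with
#'   `cdna` and `input` [FragmentLibrary] objects.
#' @export
simulate_fragments <- function(genome, truth, config) {
  ngaps <- n_gap_ranges(genome)
  gap_df <- do.call(rbind, c(list(empty_df()),
    lapply(names(ngaps), function(ch) {
      if (length(ngaps[[ch]]) == 0L) return(NULL)
      data.frame(chrom = ch, start = start(ngaps[[ch]]),
                 end = end(ngaps[[ch]]), stringsAsFactors = FALSE)
    })))
  enh_df <- data.frame(chrom = as.character(seqnames(truth$enhancers)),
                       start = start(truth$enhancers),
                       end = end(truth$enhancers), stringsAsFactors = FALSE)
  not_in_gap <- function(ch, st, len)
    !points_in_ranges(ch, st + len %/% 2L, gap_df)
  fold <- config$enhancer_fold
  lapply(seq_len(config$n_replicates), function(r) {
    with_seed(config$seed + r, {
      input <- sample_fragments(
        config$n_fragments_input, genome$lengths,
        config$fragment_length_range, not_in_gap)
      cdna <- sample_fragments(
        config$n_fragments_cdna, genome$lengths,
        config$fragment_length_range,
        function(ch, st, len) {
          ok <- not_in_gap(ch, st, len)
          if (fold > 1) {
            w <- ifelse(points_in_ranges(ch, st + len %/% 2L, enh_df),
                        fold, 1)
            ok & runif(length(ch)) < w / fold
          } else ok
        },
        batch_factor = if (fold > 1) 1.1 * fold else 1.3)
      list(cdna = FragmentLibrary(cdna, r, "cdna"),
           input = FragmentLibrary(input, r, "input"))
    })
  })
}

#' Write a simulated study to disk
#'
#' Writes the genome FASTA, annotation GFF3, truth-enhancer BED, one
#' fragment BED per replicate and channel, the planted motifs in JASPAR
#' format, and a YAML echo of the configuration.
#'
#' @param sim Result of [simulate_genome()].
#' @param libraries Result of [simulate_fragments()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, libraries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  write_bed(sim$truth$enhancers, file.path(dir, "truth_enhancers.bed"))
  for (r in seq_along(libraries)) for (chan in c("cdna", "input"))
    write_bed(libraries[[r]][[chan]]$fragments,
              file.path(dir, sprintf("fragments_rep%d_%s.bed", r, chan)))
  write_jaspar(sim$truth$config$planted_motifs,
               file.path(dir, "planted_motifs.jaspar"))
  cfg <- sim$truth$config
  cfg$planted_motifs <- vapply(cfg$planted_motifs, `[[`, "", "id")
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$class_mix <- as.list(cfg$class_mix)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
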