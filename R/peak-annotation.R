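# Classification of consensus enhancers against the gene annotation, and the
# genome-distribution statistics reported for an enhancer catalog.

max_overlap_score <- function(query, features) {
  score <- numeric(length(query))
  if (length(features) == 0L || length(query) == 0L) return(score)
  hits <- findOverlaps(query, features, ignore.strand = TRUE)
  if (length(hits) == 0L) return(score)
  ov <- width(pintersect(granges(query)[queryHits(hits)],
                         granges(features)[subjectHits(hits)],
                         ignore.strand = TRUE))
  frac <- ov / width(query)[queryHits(hits)]
  agg <- tapply(frac, queryHits(hits), max)
  score[as.integer(names(agg))] <- as.numeric(agg)
  score
}

#' Feature-overlap scores for enhancers
#'
#' For each enhancer, the UTR, exon (CDS) and mRNA scores are the fraction of
#' the enhancer covered by the best single feature of that type; when several
#' features of one type overlap the enhancer, only the larger score is
#' retained (max rule, not a sum).
#'
#' @param enhancers A `GRanges`.
#' @param ann A [GeneAnnotation].
#' @return A `data.frame` with columns `utr_score`, `exon_score`,
#'   `mrna_score`, one row per enhancer, each in \[0, 1\].
#' @export
score_features <- function(enhancers, ann) {
  utr <- suppressWarnings(c(granges(ann$utr5), granges(ann$utr3)))
  data.frame(
    utr_score = max_overlap_score(enhancers, utr),
    exon_score = max_overlap_score(enhancers, ann$cds),
    mrna_score = max_overlap_score(enhancers, ann$transcripts))
}

#' Classify enhancers by genomic context
#'
#' Each enhancer gets exactly one class: `intergenic` (no overlap with any
#' annotated gene), `UTR` or `exon` (overlap with UTR and/or CDS features,
#' the class with the higher score winning; ties go to UTR and are flagged),
#' or `intron` (gene overlap but neither UTR nor CDS). Intronic enhancers
#' get the ordinal label of the intron with which they overlap most (nearest
#' intron if none overlaps), computed on the longest transcript per gene.
#' Closest genes to the left and right are reported with gap distances
#' (0 = overlap).
#'
#' @param enhancers A `GRanges`.
#' @param ann A [GeneAnnotation] (introns derived; all isoforms allowed --
#'   the function collapses to the longest transcript per gene internally).
#' @return A `data.frame`: `class`, `utr_score`, `exon_score`, `mrna_score`,
#'   `intron_label`, `tie_flag`, `left_gene`, `left_distance`, `right_gene`,
#'   `right_distance`.
#' @export
classify_peaks <- function(enhancers, ann) {
  if (is.null(ann$introns)) ann <- derive_introns(ann)
  ann1 <- collapse_to_longest_transcript(ann)
  sc <- score_features(enhancers, ann1)
  gene_overlap <- countOverlaps(enhancers, ann1$genes,
                                ignore.strand = TRUE) > 0
  cls <- rep("intergenic", length(enhancers))
  tie <- rep(FALSE, length(enhancers))
  has_feat <- sc$utr_score > 0 | sc$exon_score > 0
  cls[gene_overlap & !has_feat] <- "intron"
  cls[has_feat & sc$utr_score >= sc$exon_score] <- "UTR"
  cls[has_feat & sc$exon_score > sc$utr_score] <- "exon"
  tie[has_feat & sc$utr_score == sc$exon_score] <- TRUE
  intron_label <- rep(NA_character_, length(enhancers))
  which_intron <- which(cls == "intron")
  if (length(which_intron) && length(ann1$introns)) {
    hits <- findOverlaps(enhancers[which_intron], ann1$introns,
                         ignore.strand = TRUE)
    if (length(hits)) {
      ov <- width(pintersect(
        granges(enhancers)[which_intron][queryHits(hits)],
        granges(ann1$introns)[subjectHits(hits)], ignore.strand = TRUE))
      d <- data.frame(q = queryHits(hits), s = subjectHits(hits), ov = ov)
      d <- d[order(d$q, -d$ov, start(ann1$introns)[d$s]), ]
      d <- d[!duplicated(d$q), ]
      intron_label[which_intron[d$q]] <- mcols(ann1$introns)$label[d$s]
    }
    # gene overlap but not inside any intron of the longest transcript
    # (e.g. enhancer over a gene end): use the nearest intron
    missing <- which_intron[is.na(intron_label[which_intron])]
    if (length(missing)) {
      nr <- GenomicRanges::nearest(enhancers[missing], ann1$introns,
                                   ignore.strand = TRUE)
      ok <- !is.na(nr)
      intron_label[missing[ok]] <- mcols(ann1$introns)$label[nr[ok]]
    }
  }
  genes <- ann1$genes
  cf <- closest_feature(enhancers, genes)
  data.frame(class = cls, sc, intron_label = intron_label, tie_flag = tie,
             left_gene = cf$left_name, left_distance = cf$left_distance,
             right_gene = cf$right_name, right_distance = cf$right_distance,
             stringsAsFactors = FALSE)
}

#' Chi-square test of enhancer counts across chromosomes
#'
#' Observed counts per (non-excluded) chromosome are compared with counts
#' expected in proportion to non-N chromosome lengths.
#'
#' @param enhancers A `GRanges`.
#' @param genome A [Genome].
#' @return List with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
chromosome_distribution_test <- function(enhancers, genome) {
  len <- effective_lengths(genome, analysed = TRUE)
  if (length(len) < 2L) stop("need at least 2 analysed chromosomes")
  obs <- table(factor(as.character(seqnames(enhancers)), levels = names(len)))
  expected <- sum(obs) * len / sum(len)
  if (any(expected == 0)) stop("zero expected count on some chromosome")
  ht <- suppressWarnings(chisq.test(as.vector(obs), p = len / sum(len)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       observed = as.vector(obs), expected = as.vector(expected))
}

#' One-way ANOVA of enhancer activity across chromosomes
#'
#' Tests whether mean log2 enrichment differs by chromosome arm.
#'
#' @param enhancers A `GRanges` with an `activity` metadata column
#'   (mean log2 enrichment).
#' @return List with `F`, `df`, `p_value`, `group_means`; `F` is `NA` with a
#'   `degenerate` flag when there is no within-group variance.
#' @export
activity_by_chromosome <- function(enhancers) {
  chrom <- factor(as.character(seqnames(enhancers)))
  act <- mcols(enhancers)$activity
  if (is.null(act)) stop("enhancers need an 'activity' metadata column")
  counts <- table(chrom)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 chromosomes with >= 2 enhancers each")
  gm <- tapply(act, chrom, mean)
  if (all(tapply(act, chrom, function(v) var(v) == 0)))
    return(list(F = NA_real_, df = c(length(counts) - 1L,
                                     length(act) - length(counts)),
                p_value = NA_real_, group_means = gm, degenerate = TRUE))
  fit <- anova(aov(act ~ chrom))
  list(F = fit$`F value`[1L], df = fit$Df, p_value = fit$`Pr(>F)`[1L],
       group_means = gm, degenerate = FALSE)
}
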