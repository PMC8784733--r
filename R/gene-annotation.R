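#' Gene annotation object
#'
#' Container for a gene annotation: gene and transcript spans plus exon, CDS
#' and UTR parts, all as `GRanges`. Introns are derived (see
#' [derive_introns()]) as the gaps between consecutive exons of a transcript,
#' with strand-aware ordinal labels.
#'
#' @param genes `GRanges` with a `name` column (gene ids).
#' @param transcripts `GRanges` with `name` (transcript id) and `gene`
#'   (parent gene id) columns.
#' @param exons,cds,utr5,utr3 `GRanges` with a `tx` column naming the owner
#'   transcript.
#' @param introns Optional derived `GRanges` with `tx` and `label` columns.
#' @return An object of class `GeneAnnotation`.
#' @export
GeneAnnotation <- function(genes, transcripts, exons, cds,
                           utr5 = GRanges(), utr3 = GRanges(),
                           introns = NULL) {
  ann <- structure(list(genes = genes, transcripts = transcripts,
                        exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                        introns = introns),
                   class = "GeneAnnotation")
  tx_span <- setNames(transcripts, mcols(transcripts)$name)
  for (part in c("exons", "cds", "utr5", "utr3")) {
    gr <- ann[[part]]
    if (length(gr) == 0L) next
    own <- tx_span[mcols(gr)$tx]
    bad <- as.character(seqnames(gr)) != as.character(seqnames(own)) |
      start(gr) < start(own) | end(gr) > end(own)
    if (any(bad))
      stop("annotation error: ", sum(bad), " ", part,
           " interval(s) not contained in their transcript")
  }
  ann
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat("GeneAnnotation:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts,", length(x$exons), "exons",
      if (!is.null(x$introns)) paste0(", ", length(x$introns), " introns"),
      "\n")
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Uses the feature types `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR`; all other types are ignored. GFF3 1-based closed
#' coordinates are kept as-is (the package's internal convention).
#'
#' @param path GFF3 file.
#' @param derive If `TRUE` (default), derive introns immediately.
#' @return A [GeneAnnotation].
#' @export
read_gff_annotation <- function(path, derive = TRUE) {
  gff <- rtracklayer::import(path, format = "gff3")
  first_parent <- function(gr) {
    p <- mcols(gr)$Parent
    vapply(p, function(v) if (length(v)) v[[1L]] else NA_character_, "")
  }
  pick <- function(type) gff[mcols(gff)$type == type]
  g <- pick("gene")
  genes <- granges(g)
  mcols(genes)$name <- mcols(g)$ID
  tx <- pick("mRNA")
  transcripts <- granges(tx)
  mcols(transcripts)$name <- mcols(tx)$ID
  mcols(transcripts)$gene <- first_parent(tx)
  part <- function(type) {
    p <- pick(type)
    out <- granges(p)
    mcols(out)$tx <- first_parent(p)
    out
  }
  ann <- GeneAnnotation(genes, transcripts, exons = part("exon"),
                        cds = part("CDS"), utr5 = part("five_prime_UTR"),
                        utr3 = part("three_prime_UTR"))
  if (derive) ann <- derive_introns(ann)
  ann
}

#' Write a gene annotation as GFF3
#' @param ann A [GeneAnnotation].
#' @param path Output file.
#' @export
write_gff_annotation <- function(ann, path) {
  rows <- list()
  add <- function(gr, type, id = NULL, parent = NULL) {
    if (length(gr) == 0L) return()
    out <- granges(gr)
    mcols(out)$source <- "starrscout"
    mcols(out)$type <- type
    if (!is.null(id)) mcols(out)$ID <- id
    if (!is.null(parent)) mcols(out)$Parent <- parent
    rows[[length(rows) + 1L]] <<- out
  }
  add(ann$genes, "gene", id = mcols(ann$genes)$name)
  add(ann$transcripts, "mRNA", id = mcols(ann$transcripts)$name,
      parent = mcols(ann$transcripts)$gene)
  for (spec in list(c("exons", "exon"), c("cds", "CDS"),
                    c("utr5", "five_prime_UTR"),
                    c("utr3", "three_prime_UTR"))) {
    gr <- ann[[spec[1L]]]
    add(gr, spec[2L], parent = mcols(gr)$tx)
  }
  all <- suppressWarnings(do.call(c, rows))
  all <- all[order(as.character(seqnames(all)), start(all),
                   match(mcols(all)$type,
                         c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
                           "three_prime_UTR")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Derive introns with strand-aware ordinal labels
#'
#' Introns are the gaps between consecutive exons of a transcript, walked in
#' transcription order. A gap upstream of the first coding (CDS-bearing) exon
#' is labelled `"5utr_intron"`; the gap after the k-th coding exon is
#' labelled `"intron_k"`. Single-exon transcripts yield no introns.
#' Transcripts without any CDS get plain ordinals `intron_1`, `intron_2`, ...
#'
#' @param ann A [GeneAnnotation].
#' @return The annotation with its `introns` slot populated (`GRanges` with
#'   `tx` and `label` columns).
#' @export
derive_introns <- function(ann) {
  # plain-vector bookkeeping: the per-transcript work is tiny, so a single
  # GRanges construction at the end keeps this fast on many transcripts
  ex <- data.frame(chrom = as.character(seqnames(ann$exons)),
                   start = start(ann$exons), end = end(ann$exons),
                   tx = mcols(ann$exons)$tx, stringsAsFactors = FALSE)
  cds <- data.frame(start = start(ann$cds), end = end(ann$cds),
                    tx = mcols(ann$cds)$tx, stringsAsFactors = FALSE)
  tx_strand <- setNames(as.character(strand(ann$transcripts)),
                        mcols(ann$transcripts)$name)
  rows <- vector("list", length(unique(ex$tx)))
  names(rows) <- unique(ex$tx)
  for (t in unique(ex$tx)) {
    e <- ex[ex$tx == t, , drop = FALSE]
    if (nrow(e) < 2L) next
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (any(e$start[-1L] <= e$end[-n]))
      stop("annotation error: overlapping exons in transcript ", t)
    minus <- identical(tx_strand[[t]], "-")
    cd <- cds[cds$tx == t, , drop = FALSE]
    # coding[i]: is the i-th exon (genomic order) CDS-bearing?
    coding <- vapply(seq_len(n), function(i)
      any(cd$start <= e$end[i] & cd$end >= e$start[i]), logical(1))
    ord <- if (minus) rev(seq_len(n)) else seq_len(n)
    gap_ord <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
    n_coding_before <- cumsum(coding[ord])[-n]  # after upstream exon i
    label <- if (any(coding))
      ifelse(n_coding_before == 0L, "5utr_intron",
             paste0("intron_", pmax(n_coding_before, 1L)))
    else paste0("intron_", seq_len(n - 1L))
    rows[[t]] <- data.frame(
      chrom = e$chrom[1L],
      start = e$end[-n][gap_ord] + 1L, end = e$start[-1L][gap_ord] - 1L,
      strand = if (minus) "-" else "+", tx = t, label = label,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  ann$introns <- if (length(rows)) {
    d <- do.call(rbind, rows)
    g <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand)
    mcols(g) <- DataFrame(tx = d$tx, label = d$label)
    unname(g)
  } else {
    g <- GRanges(); mcols(g)$tx <- character(); mcols(g)$label <- character(); g
  }
  ann
}

#' Collapse an annotation to one transcript per gene
#'
#' Keeps the longest transcript of each gene (ties to the lowest start, then
#' lexicographic id), the convention used before computing intron ordinals
#' for peak classification.
#'
#' @param ann A [GeneAnnotation].
#' @return A [GeneAnnotation] restricted to the kept transcripts.
#' @export
collapse_to_longest_transcript <- function(ann) {
  tx <- ann$transcripts
  d <- data.frame(name = mcols(tx)$name, gene = mcols(tx)$gene,
                  w = width(tx), s = start(tx), stringsAsFactors = FALSE)
  d <- d[order(d$gene, -d$w, d$s, d$name), ]
  keep <- d$name[!duplicated(d$gene)]
  sel <- function(gr) gr[mcols(gr)$tx %in% keep]
  GeneAnnotation(ann$genes, tx[mcols(tx)$name %in% keep],
                 exons = sel(ann$exons), cds = sel(ann$cds),
                 utr5 = sel(ann$utr5), utr3 = sel(ann$utr3),
                 introns = if (is.null(ann$introns)) NULL else sel(ann$introns))
}
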