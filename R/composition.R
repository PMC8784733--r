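# Sequence-composition analytics: GC content, perfect microsatellite repeats
# with hierarchical exclusion, the ten-control consensus statistical
# procedure, and dinucleotide repeat-class enrichment.

#' GC content of sequences
#'
#' (G + C) / (A + C + G + T); N bases are excluded from both numerator and
#' denominator. All-N sequences give `NA`.
#'
#' @param sequences Character vector (or `DNAStringSet`).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(sequences) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(toupper(sequences))
  f <- letterFrequency(sequences, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- (f[, "G"] + f[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

#' Find maximal perfect repeat runs
#'
#' Finds maximal uninterrupted runs of a 1-, 2- or 3-base unit. Runs are
#' read at their leftmost phase and counted in full units only; a trailing
#' partial unit is not part of the run. Runs must be at least 6 bases long
#' (equivalently >= 6 / >= 3 / >= 2 full units for mono-/di-/trinucleotide
#' repeats). Units that are themselves repetitions of a shorter unit (e.g.
#' AA, GGG) are never reported, and positions already inside a run found at
#' a smaller unit length can be masked out via `mask` so that mononucleotide
#' runs are excluded from the dinucleotide scan and so on (see
#' [repeat_profile()]).
#'
#' @param sequence A character string (A/C/G/T/N; N breaks runs).
#' @param unit_length 1, 2 or 3.
#' @param mask Optional logical vector (same length as the sequence);
#'   positions marked `TRUE` cannot participate in a run.
#' @return `data.frame` with `start`, `end` (1-based, inclusive), `unit`,
#'   `n_units`, `run_length`.
#' @export
find_perfect_repeats <- function(sequence, unit_length, mask = NULL) {
  stopifnot(unit_length %in% 1:3)
  k <- as.integer(unit_length)
  v <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(v)
  empty <- data.frame(start = integer(), end = integer(), unit = character(),
                      n_units = integer(), run_length = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L * k) return(empty)
  valid <- v %in% c("A", "C", "G", "T")
  if (!is.null(mask)) valid <- valid & !mask
  # chain[j]: position j starts a same-phase continuation (v[j] == v[j+k])
  chain <- v[seq_len(n - k)] == v[(k + 1L):n] &
    valid[seq_len(n - k)] & valid[(k + 1L):n]
  r <- rle(chain)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(empty)
  a <- starts[runs]                    # run region is [a, ends[run] + k]
  n_units <- (r$lengths[runs] + k) %/% k
  run_length <- n_units * k
  min_units <- c(6L, 3L, 2L)[k]
  keep <- run_length >= 6L & n_units >= min_units
  a <- a[keep]; n_units <- n_units[keep]; run_length <- run_length[keep]
  if (length(a) == 0L) return(empty)
  s_up <- paste(v, collapse = "")
  unit <- substring(s_up, a, a + k - 1L)
  periodic <- if (k == 1L) rep(FALSE, length(unit))
              else if (k == 2L) substr(unit, 1, 1) == substr(unit, 2, 2)
              else substr(unit, 1, 1) == substr(unit, 2, 2) &
                   substr(unit, 2, 2) == substr(unit, 3, 3)
  out <- data.frame(start = a, end = a + run_length - 1L, unit = unit,
                    n_units = n_units, run_length = run_length,
                    stringsAsFactors = FALSE)[!periodic, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical repeat scan of one sequence
#'
#' Runs [find_perfect_repeats()] at unit lengths 1, 2, 3 with hierarchical
#' exclusion: bases inside reported mononucleotide runs are masked before the
#' dinucleotide scan, and bases inside mono- or dinucleotide runs are masked
#' before the trinucleotide scan.
#'
#' @param sequence Character string.
#' @return Named list of `data.frame`s (`mono`, `di`, `tri`).
#' @export
scan_repeats <- function(sequence) {
  n <- nchar(sequence)
  mask <- rep(FALSE, n)
  res <- list()
  for (k in 1:3) {
    runs <- find_perfect_repeats(sequence, k, mask = mask)
    res[[c("mono", "di", "tri")[k]]] <- runs
    if (nrow(runs))
      for (i in seq_len(nrow(runs)))
        mask[runs$start[i]:runs$end[i]] <- TRUE
  }
  res
}

#' Per-sequence repeat profile
#'
#' For each sequence: presence per specific unit, run count, total run bases
#' and the fraction of the sequence inside runs, at one unit length (with
#' hierarchical exclusion of smaller-unit runs).
#'
#' @param sequences Character vector.
#' @param unit_length 1, 2 or 3.
#' @return List with `table` (`data.frame`: `n_runs`, `repeat_bases`,
#'   `fraction`, `any_repeat`), `presence` (logical matrix sequence x unit)
#'   and `runs` (per-sequence list of run tables).
#' @export
repeat_profile <- function(sequences, unit_length) {
  lvl <- c("mono", "di", "tri")[unit_length]
  runs <- lapply(sequences, function(s) scan_repeats(s)[[lvl]])
  units <- sort(unique(unlist(lapply(runs, `[[`, "unit"))))
  presence <- matrix(FALSE, nrow = length(sequences), ncol = length(units),
                     dimnames = list(NULL, units))
  for (i in seq_along(runs))
    if (nrow(runs[[i]]))
      presence[i, unique(runs[[i]]$unit)] <- TRUE
  tab <- data.frame(
    n_runs = vapply(runs, nrow, integer(1)),
    repeat_bases = vapply(runs, function(r) sum(r$run_length), numeric(1)),
    fraction = vapply(runs, function(r) sum(r$run_length), numeric(1)) /
      nchar(sequences),
    any_repeat = vapply(runs, nrow, integer(1)) > 0L)
  list(table = tab, presence = presence, runs = runs)
}

#' Ten-control consensus comparison
#'
#' The two-stage gatekeeping procedure used for every composition metric:
#' (1) a Kruskal-Wallis test across the 10 control sets alone -- if they
#' differ at `p < alpha` the controls are heterogeneous and no verdict is
#' made; (2) a Kruskal-Wallis test across all 11 groups -- if not
#' significant, the metric is `not_significant`; (3) ten two-sided
#' Mann-Whitney U tests of the enhancer set against each control set. The
#' metric is `enriched_in_enhancers` (or `depleted_in_enhancers`) only when
#' all ten post-hoc tests are significant at `alpha` *and* all ten control
#' means shift in the same direction relative to the enhancer mean.
#'
#' @param enhancer_values Numeric vector.
#' @param control_value_sets List of numeric vectors, one per control set,
#'   each the same length as `enhancer_values`.
#' @param alpha Significance level for every stage (default 0.001).
#' @param metric Optional metric name carried into the result.
#' @return List of class `ConsensusTestResult`: `metric`, `gate_kw_p`,
#'   `omnibus_kw_p`, `mwu_p` (10 values), `directions` (sign of enhancer
#'   mean minus control mean), `median_directions`, `verdict`.
#' @export
consensus_compare <- function(enhancer_values, control_value_sets,
                              alpha = 0.001, metric = "metric") {
  n_sets <- length(control_value_sets)
  if (any(lengths(control_value_sets) != length(enhancer_values)))
    stop("every control set must match the enhancer set size")
  res <- list(metric = metric, gate_kw_p = NA_real_, omnibus_kw_p = NA_real_,
              mwu_p = rep(NA_real_, n_sets),
              directions = rep(NA_real_, n_sets),
              median_directions = rep(NA_real_, n_sets),
              verdict = "not_significant")
  class(res) <- "ConsensusTestResult"
  kw <- function(groups) {
    vals <- unlist(groups, use.names = FALSE)
    if (length(unique(vals)) == 1L) return(1)  # no variation anywhere
    kruskal.test(groups)$p.value
  }
  res$gate_kw_p <- kw(control_value_sets)
  if (res$gate_kw_p < alpha) {
    res$verdict <- "controls_heterogeneous"
    return(res)
  }
  res$omnibus_kw_p <- kw(c(list(enhancer_values), control_value_sets))
  if (res$omnibus_kw_p >= alpha) return(res)
  for (i in seq_len(n_sets)) {
    ctrl <- control_value_sets[[i]]
    res$mwu_p[i] <- if (length(unique(c(enhancer_values, ctrl))) == 1L) 1 else
      wilcox.test(enhancer_values, ctrl, exact = FALSE,
                  correct = TRUE)$p.value
    res$directions[i] <- sign(mean(enhancer_values) - mean(ctrl))
    res$median_directions[i] <-
      sign(median(enhancer_values) - median(ctrl))
  }
  res$verdict <- posthoc_verdict(res$mwu_p, res$directions, alpha)
  res
}

# the all-10 + same-direction decision rule, separated out so its boundary
# (e.g. 9 of 10 significant post-hoc tests) can be exercised directly
posthoc_verdict <- function(mwu_p, directions, alpha = 0.001) {
  if (all(mwu_p < alpha) && length(unique(directions)) == 1L &&
      directions[1L] != 0) {
    if (directions[1L] > 0) "enriched_in_enhancers"
    else "depleted_in_enhancers"
  } else "not_significant"
}

#' @export
print.ConsensusTestResult <- function(x, ...) {
  cat(sprintf("consensus test [%s]: %s (gate KW p = %.3g, omnibus KW p = %s)\n",
              x$metric, x$verdict, x$gate_kw_p,
              format(x$omnibus_kw_p, digits = 3)))
  invisible(x)
}

dinuc_classes <- list(CA = c("CA", "AC", "TG", "GT"),
                      GA = c("GA", "AG", "TC", "CT"),
                      GC = c("GC", "CG"), TA = c("TA", "AT"))

#' Dinucleotide repeat-class enrichment
#'
#' For the four reverse-complement dinucleotide classes (CA, GA, GC, TA), a
#' sequence "contains" a class when it carries a perfect dinucleotide run
#' (>= 6 bp, mononucleotide runs excluded) whose unit belongs to the class.
#' Per control set, the log2 fold enrichment is
#' `log2(enhancer fraction / control fraction)`; the mean and standard
#' deviation over the control sets are reported.
#'
#' @param enhancer_seqs Character vector.
#' @param control_seq_sets List of character vectors (one per control set).
#' @return `data.frame` per class: `class`, `enhancer_fraction`,
#'   `mean_control_fraction`, `log2_fe_mean`, `log2_fe_sd`, `n_sets_used`
#'   (control sets with zero class fraction are excluded with a warning).
#' @export
dinucleotide_enrichment <- function(enhancer_seqs, control_seq_sets) {
  class_presence <- function(seqs) {
    pres <- repeat_profile(seqs, 2L)$presence
    vapply(dinuc_classes, function(units) {
      u <- intersect(units, colnames(pres))
      if (length(u) == 0L) rep(FALSE, length(seqs))
      else rowSums(pres[, u, drop = FALSE]) > 0
    }, logical(length(seqs)))
  }
  enh <- class_presence(enhancer_seqs)
  ctrl <- lapply(control_seq_sets, class_presence)
  out <- lapply(names(dinuc_classes), function(cl) {
    ef <- mean(enh[, cl])
    cf <- vapply(ctrl, function(m) mean(m[, cl]), numeric(1))
    usable <- cf > 0 & ef > 0
    if (any(!usable))
      warning("class ", cl, ": ", sum(!usable),
              " control set(s) with zero fraction excluded from log2 FE")
    l2 <- log2(ef / cf[usable])
    data.frame(class = cl, enhancer_fraction = ef,
               mean_control_fraction = mean(cf),
               log2_fe_mean = if (any(usable)) mean(l2) else NA_real_,
               log2_fe_sd = if (sum(usable) > 1L) sd(l2) else 0,
               n_sets_used = sum(usable), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
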