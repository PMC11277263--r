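# Sequence features of pause sites: positional nucleotide logos, GC
# metaplots (absolute +/- flank and length-scaled start->site->stop bins),
# nascent-peptide composition and net charge, and motif-pausing association.
# Anchors are data.frames with columns `transcript_id` and `position`
# (0-based transcript coordinate of the pause site).

BASES <- c("A", "C", "G", "T")

anchor_frame <- function(anchors) {
  stopifnot(all(c("transcript_id", "position") %in% names(anchors)))
  anchors
}

#' Positional nucleotide probability matrix around anchor sites
#'
#' Extracts the `window` around each anchor, drops anchors whose window runs
#' off the transcript (tallied in attribute `dropped`), and returns
#' per-position base probabilities.
#'
#' @param transcripts named list of transcript models.
#' @param anchors `data.frame` with `transcript_id`, `position` (0-based).
#' @param window relative window, default `c(-30, 30)`.
#' @param pseudocount added to each base count per column (default 0).
#' @return 4 x positions probability matrix (rows A,C,G,T; each column sums
#'   to 1), class `"ppm"`, attributes `n_sequences`, `dropped`,
#'   `pseudocount`.
#' @export
context_logo <- function(transcripts, anchors, window = c(-30L, 30L),
                         pseudocount = 0) {
  anchors <- anchor_frame(anchors)
  width <- window[2] - window[1] + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(BASES, window[1]:window[2]))
  n_used <- 0L; dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    tx <- transcripts[[anchors$transcript_id[i]]]
    lo <- anchors$position[i] + window[1]
    hi <- anchors$position[i] + window[2]
    if (is.null(tx) || lo < 0L || hi >= tx_length(tx)) {
      dropped <- dropped + 1L
      next
    }
    chars <- strsplit(substr(tx$sequence, lo + 1L, hi + 1L), "")[[1]]
    idx <- match(chars, BASES)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <- counts[cbind(idx[ok], which(ok))] + 1
    n_used <- n_used + 1L
  }
  probs <- sweep(counts + pseudocount, 2L,
                 colSums(counts + pseudocount), `/`)
  structure(probs, n_sequences = n_used, dropped = dropped,
            pseudocount = pseudocount, class = c("ppm", "matrix"))
}

#' GC metaplot on absolute coordinates around anchors
#'
#' Mean GC (indicator of G/C) per position relative to the anchors, up to
#' `flank` nt on either side; each position averages over the anchors whose
#' transcript extends that far.
#'
#' @param transcripts named list of transcript models.
#' @param anchors anchor `data.frame`.
#' @param flank flank size in nt (default 500).
#' @return `data.frame` with `rel_pos`, `gc`, `n` (contributing anchors),
#'   attribute `mode = "absolute"`.
#' @export
gc_absolute <- function(transcripts, anchors, flank = 500L) {
  anchors <- anchor_frame(anchors)
  rel <- (-flank):flank
  gc_sum <- numeric(length(rel))
  n <- integer(length(rel))
  for (i in seq_len(nrow(anchors))) {
    tx <- transcripts[[anchors$transcript_id[i]]]
    if (is.null(tx)) next
    pos <- anchors$position[i] + rel
    ok <- pos >= 0L & pos < tx_length(tx)
    chars <- strsplit(substr(tx$sequence, min(pos[ok]) + 1L, max(pos[ok]) + 1L), "")[[1]]
    gc_sum[ok] <- gc_sum[ok] + as.numeric(chars %in% c("G", "C"))
    n[ok] <- n[ok] + 1L
  }
  structure(data.frame(rel_pos = rel, gc = ifelse(n > 0, gc_sum / n, NA),
                       n = n),
            mode = "absolute", class = c("gc_metaplot", "data.frame"))
}

gc_of_bins <- function(chars, n_bins) {
  len <- length(chars)
  out <- rep(NA_real_, n_bins)
  if (len == 0L) return(out)
  bounds <- (0:n_bins) * len %/% n_bins
  for (b in seq_len(n_bins)) {
    if (bounds[b + 1L] > bounds[b]) {
      seg <- chars[(bounds[b] + 1L):bounds[b + 1L]]
      out[b] <- mean(seg %in% c("G", "C"))
    }
  }
  out
}

#' GC metaplot on length-scaled coordinates
#'
#' Splits each transcript's CDS into `n_bins` equal-width bins from the
#' start codon to the anchor and `n_bins` bins from the anchor to the stop
#' codon (the last bin absorbs the remainder; bins beyond a short segment
#' are `NA`), and averages bin GC across transcripts. The anchor must lie
#' strictly inside the CDS.
#'
#' @param transcripts named list of transcript models.
#' @param anchors anchor `data.frame`.
#' @param n_bins bins per segment (default 50, i.e. 100 bins total).
#' @return `data.frame` with `bin` (1..2*n_bins), `segment`
#'   (upstream/downstream), `gc`, `n`; attribute `mode = "scaled"`.
#' @export
gc_scaled <- function(transcripts, anchors, n_bins = 50L) {
  anchors <- anchor_frame(anchors)
  up <- matrix(NA_real_, nrow = nrow(anchors), ncol = n_bins)
  dn <- matrix(NA_real_, nrow = nrow(anchors), ncol = n_bins)
  for (i in seq_len(nrow(anchors))) {
    tx <- transcripts[[anchors$transcript_id[i]]]
    pos <- anchors$position[i]
    if (is.null(tx)) next
    if (pos <= tx$cds_start) stop("empty upstream segment: anchor at or before the CDS start")
    if (pos >= tx$cds_end) stop("anchor beyond the CDS end")
    chars <- strsplit(tx$sequence, "")[[1]]
    up[i, ] <- gc_of_bins(chars[(tx$cds_start + 1L):pos], n_bins)
    dn[i, ] <- gc_of_bins(chars[(pos + 1L):tx$cds_end], n_bins)
  }
  gc <- c(colMeans(up, na.rm = TRUE), colMeans(dn, na.rm = TRUE))
  n <- c(colSums(!is.na(up)), colSums(!is.na(dn)))
  structure(data.frame(bin = seq_len(2L * n_bins),
                       segment = rep(c("upstream", "downstream"), each = n_bins),
                       gc = gc, n = n),
            mode = "scaled", class = c("gc_metaplot", "data.frame"))
}

#' Nascent-peptide context around pause sites
#'
#' Maps each anchor to its codon (any of the three nucleotide positions of a
#' codon marks that codon), translates the CDS, and summarizes amino-acid
#' frequencies per codon position in `+/- aa_window` codons around the pause
#' codon together with the nascent-peptide net charge over that window
#' (K, R = +1; D, E = -1; H = 0 by default).
#'
#' @param transcripts named list of transcript models.
#' @param anchors anchor `data.frame` (positions inside the CDS).
#' @param aa_window codons on either side of the pause codon (default 10).
#' @param charge_map named charge per amino acid; unlisted residues are 0.
#' @return list with `freq` (amino acids x relative codon positions),
#'   `charge_profile` (mean positional charge), `net_charge` (per-anchor sum
#'   over the window), `n_anchors`, `dropped`.
#' @export
peptide_context <- function(transcripts, anchors, aa_window = 10L,
                            charge_map = c(K = 1, R = 1, D = -1, E = -1)) {
  anchors <- anchor_frame(anchors)
  rel <- (-aa_window):aa_window
  aa_levels <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  counts <- matrix(0, nrow = length(aa_levels), ncol = length(rel),
                   dimnames = list(aa_levels, rel))
  charge_sum <- numeric(length(rel))
  net <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    tx <- transcripts[[anchors$transcript_id[i]]]
    pos <- anchors$position[i]
    if (is.null(tx) || pos < tx$cds_start || pos >= tx$cds_end) {
      dropped <- dropped + 1L
      next
    }
    codon_idx <- (pos - tx$cds_start) %/% 3L
    ncod <- cds_length(tx) %/% 3L
    if (codon_idx + rel[1] < 0L || codon_idx + rel[length(rel)] >= ncod) {
      dropped <- dropped + 1L
      next
    }
    cds_seq <- substr(tx$sequence, tx$cds_start + 1L, tx$cds_end)
    pep <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(cds_seq))), "")[[1]]
    win_aa <- pep[codon_idx + rel + 1L]
    idx <- match(win_aa, aa_levels)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <- counts[cbind(idx[ok], which(ok))] + 1
    ch <- charge_map[win_aa]
    ch[is.na(ch)] <- 0
    charge_sum <- charge_sum + ch
    net <- c(net, sum(ch))
  }
  n_used <- nrow(anchors) - dropped
  freq <- if (n_used > 0) counts / n_used else counts
  list(freq = freq,
       charge_profile = if (n_used > 0) charge_sum / n_used else charge_sum,
       net_charge = net, n_anchors = n_used, dropped = dropped)
}

#' Motif-pausing association
#'
#' Compares the per-transcript maximum pause scores of transcripts carrying
#' a motif hit against those without, with a two-sided rank-sum test.
#'
#' @param max_scores named numeric vector of per-transcript maximum pause
#'   scores (typically one column of [pause_matrix()], restricted to paused
#'   transcripts).
#' @param motif_transcripts transcript ids carrying the motif (e.g. from
#'   [pwm_scan()] hits).
#' @return [compare_groups()] result plus `n_with`, `n_without`.
#' @export
motif_pause_association <- function(max_scores, motif_transcripts) {
  with_ids <- intersect(names(max_scores), motif_transcripts)
  without_ids <- setdiff(names(max_scores), motif_transcripts)
  if (!length(with_ids) || !length(without_ids))
    stop("both motif and non-motif groups must be non-empty")
  res <- compare_groups(max_scores, with_ids, without_ids)
  res$n_with <- length(with_ids)
  res$n_without <- length(without_ids)
  res
}
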