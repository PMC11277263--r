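# Footprint diagnostics: length histogram, P-site offset estimation,
# 3-nt periodicity, and metagene profiles anchored at start/stop codons.

#' Footprint length histogram
#'
#' @param alignments alignment `data.frame`.
#' @return named integer vector length -> total count (empty input gives an
#'   empty vector); counts sum to the total alignment mass.
#' @export
length_histogram <- function(alignments) {
  if (!nrow(alignments)) return(setNames(integer(0), character(0)))
  tab <- rowsum(alignments$count, alignments$length)
  setNames(as.integer(tab), rownames(tab))
}

end5_profile <- function(alignments, transcripts, rel_range) {
  # 5'-end counts relative to the start codon, pooled over transcripts
  cds_start <- vapply(transcripts, `[[`, 0L, "cds_start")[alignments$transcript_id]
  rel <- alignments$start5 - cds_start
  keep <- rel >= rel_range[1] & rel <= rel_range[2]
  prof <- setNames(numeric(rel_range[2] - rel_range[1] + 1L),
                   rel_range[1]:rel_range[2])
  if (any(keep)) {
    tab <- rowsum(alignments$count[keep], rel[keep])
    prof[as.character(rownames(tab))] <- as.numeric(tab)
  }
  prof
}

#' Estimate P-site offsets from the start-codon 5'-end peak
#'
#' For each footprint length, the 5'-end metagene around annotated start
#' codons is scanned in the window `search_window` (relative to the start
#' codon first base); the offset is the negated peak position. A length is
#' flagged unreliable -- and falls back to `default_offset` -- when it has
#' fewer than `min_reads` alignments or when the peak does not exceed
#' `bg_ratio` times the mean signal of the remaining window positions. Ties
#' are broken toward the smaller offset.
#'
#' @param alignments alignment `data.frame`.
#' @param transcripts named list of transcript models.
#' @param lengths footprint lengths to estimate (default: all observed).
#' @param search_window 5'-end peak search window relative to the start
#'   codon (default `c(-18, -6)`, bracketing the ~13 nt upstream
#'   accumulation).
#' @param min_reads minimum alignments per length (default 200).
#' @param bg_ratio required peak-to-background ratio (default 2).
#' @param default_offset fallback offset for unreliable lengths (default 12).
#' @return named integer vector length -> offset with a logical attribute
#'   `reliable` (same names).
#' @export
estimate_psite_offsets <- function(alignments, transcripts, lengths = NULL,
                                   search_window = c(-18L, -6L),
                                   min_reads = 200L, bg_ratio = 2,
                                   default_offset = 12L) {
  if (is.null(lengths)) lengths <- sort(unique(alignments$length))
  offs <- setNames(integer(length(lengths)), lengths)
  reliable <- setNames(logical(length(lengths)), lengths)
  for (L in lengths) {
    al <- alignments[alignments$length == L, , drop = FALSE]
    key <- as.character(L)
    if (sum(al$count) < min_reads) {
      offs[key] <- default_offset
      next
    }
    prof <- end5_profile(al, transcripts, search_window)
    pk <- max(prof)
    # ties toward the smaller offset = the position closest to the start codon
    peak_rel <- max(as.integer(names(prof)[prof == pk]))
    bg <- mean(prof[names(prof) != as.character(peak_rel)])
    if (pk == 0 || (bg > 0 && pk < bg_ratio * bg)) {
      offs[key] <- default_offset
    } else {
      offs[key] <- -peak_rel
      reliable[key] <- TRUE
    }
  }
  attr(offs, "reliable") <- reliable
  offs
}

#' 3-nt periodicity of P-sites over the CDS
#'
#' Fractions of offset-corrected P-sites falling in each codon frame,
#' restricted to P-sites inside annotated CDS regions.
#'
#' @param alignments alignment `data.frame`.
#' @param transcripts named list of transcript models.
#' @param offsets named integer vector length -> P-site offset.
#' @return numeric vector `c(f0, f1, f2)` summing to 1.
#' @export
frame_periodicity <- function(alignments, transcripts, offsets) {
  cds_start <- vapply(transcripts, `[[`, 0L, "cds_start")[alignments$transcript_id]
  cds_end <- vapply(transcripts, `[[`, 0L, "cds_end")[alignments$transcript_id]
  psite <- alignments$start5 + offsets[as.character(alignments$length)]
  in_cds <- psite >= cds_start & psite < cds_end
  if (!any(in_cds)) stop("no CDS P-sites")
  fr <- (psite[in_cds] - cds_start[in_cds]) %% 3L
  tot <- sum(alignments$count[in_cds])
  f <- vapply(0:2, function(k) sum(alignments$count[in_cds][fr == k]), 0) / tot
  setNames(f, c("f0", "f1", "f2"))
}

#' Metagene profile around the start or stop codon
#'
#' Sums footprint signal (P-sites or raw 5' ends) per position relative to
#' the first base of the start codon or of the stop codon, across all
#' transcripts long enough to contain the full window.
#'
#' @param alignments alignment `data.frame`.
#' @param transcripts named list of transcript models.
#' @param anchor `"start"` or `"stop"` (anchor position 0 = first base of
#'   the start/stop codon).
#' @param window integer `c(min, max)` of relative positions (default
#'   `c(-30, 60)`).
#' @param offsets named offsets (required for `site = "psite"`).
#' @param site `"psite"` (offset-corrected, default) or `"end5"`.
#' @param normalization `"raw"` (summed counts) or `"per_transcript_mean"`
#'   (each transcript's window scaled to mean 1 before summing).
#' @return `data.frame` with `rel_pos` and `value`; attributes `anchor`,
#'   `site` and `n_transcripts` (number of transcripts with a full window).
#' @export
metagene_profile <- function(alignments, transcripts,
                             anchor = c("start", "stop"),
                             window = c(-30L, 60L), offsets = NULL,
                             site = c("psite", "end5"),
                             normalization = c("raw", "per_transcript_mean")) {
  anchor <- match.arg(anchor)
  site <- match.arg(site)
  normalization <- match.arg(normalization)
  if (site == "psite" && is.null(offsets))
    stop("offsets are required for site = 'psite'")
  if (window[1] >= window[2]) stop("window bounds must be ordered")
  anchor_pos <- vapply(transcripts, function(tx)
    if (anchor == "start") tx$cds_start else tx$cds_end - 3L, 0L)
  lens <- vapply(transcripts, tx_length, 0L)
  eligible <- names(transcripts)[anchor_pos + window[1] >= 0L &
                                 anchor_pos + window[2] <= lens - 1L]
  rel_positions <- window[1]:window[2]
  total <- setNames(numeric(length(rel_positions)), rel_positions)
  al <- alignments[alignments$transcript_id %in% eligible, , drop = FALSE]
  if (nrow(al)) {
    pos <- if (site == "psite") al$start5 + offsets[as.character(al$length)] else al$start5
    rel <- pos - anchor_pos[al$transcript_id]
    keep <- rel >= window[1] & rel <= window[2]
    if (any(keep)) {
      if (normalization == "raw") {
        tab <- rowsum(al$count[keep], rel[keep])
        total[rownames(tab)] <- total[rownames(tab)] + as.numeric(tab)
      } else {
        for (id in unique(al$transcript_id[keep])) {
          sel <- keep & al$transcript_id == id
          tab <- rowsum(al$count[sel], rel[sel])
          contrib <- setNames(numeric(length(rel_positions)), rel_positions)
          contrib[rownames(tab)] <- as.numeric(tab)
          total <- total + contrib / mean(contrib)
        }
      }
    }
  }
  structure(data.frame(rel_pos = rel_positions, value = as.numeric(total)),
            anchor = anchor, site = site, n_transcripts = length(eligible),
            class = c("metagene_profile", "data.frame"))
}
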