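#' Construct a transcript model
#'
#' A transcript model is the package's basic annotation unit: the spliced
#' transcript sequence plus the CDS interval in transcript coordinates
#' (0-based, half-open; `cds_end` is the position after the stop codon).
#'
#' @param transcript_id transcript identifier.
#' @param sequence nucleotide string over A,C,G,T (U is mapped to T).
#' @param cds_start 0-based offset of the first CDS base.
#' @param cds_end 0-based exclusive end of the CDS (after the stop codon).
#' @param gene_id gene identifier (defaults to `transcript_id`).
#' @return an object of class `"transcript_model"`.
#' @export
transcript_model <- function(transcript_id, sequence, cds_start, cds_end,
                             gene_id = transcript_id) {
  sequence <- toupper(gsub("U", "T", as.character(sequence)))
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  tx <- structure(list(transcript_id = as.character(transcript_id),
                       sequence = sequence,
                       cds_start = cds_start, cds_end = cds_end,
                       gene_id = as.character(gene_id)),
                  class = "transcript_model")
  validate_transcript_model(tx)
  tx
}

validate_transcript_model <- function(tx) {
  L <- nchar(tx$sequence)
  if (!(tx$cds_start >= 0L && tx$cds_start < tx$cds_end && tx$cds_end <= L))
    stop(sprintf("transcript '%s': invalid CDS bounds [%d, %d) on length %d",
                 tx$transcript_id, tx$cds_start, tx$cds_end, L))
  if ((tx$cds_end - tx$cds_start) %% 3L != 0L)
    stop(sprintf("transcript '%s': CDS length %d is not a multiple of 3",
                 tx$transcript_id, tx$cds_end - tx$cds_start))
  invisible(tx)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s): %d nt, CDS [%d, %d) = %d nt\n",
              x$transcript_id, x$gene_id, nchar(x$sequence),
              x$cds_start, x$cds_end, x$cds_end - x$cds_start))
  invisible(x)
}

tx_length <- function(tx) nchar(tx$sequence)
cds_length <- function(tx) tx$cds_end - tx$cds_start

#' Read a transcriptome from FASTA + GFF3
#'
#' Reads transcript sequences from a FASTA file and CDS annotation from a
#' GFF3 file whose `seqid` column is the transcript id and whose CDS features
#' are given in transcript coordinates (1-based inclusive, the native GFF3
#' dialect). Transcripts without a CDS feature are skipped with a warning;
#' transcripts whose CDS length is not a multiple of 3 raise an error naming
#' the offending ids.
#'
#' @param fasta_path path to a transcript FASTA file.
#' @param gff3_path path to a GFF3 file with `CDS` features per transcript.
#' @return a named list of [transcript_model()] objects.
#' @export
read_transcriptome <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  gene_of <- character(0)
  mrna <- gff[gff$type == "mRNA"]
  if (length(mrna)) {
    gid <- as.character(mrna$Parent)
    gid[!nzchar(gid) | is.na(gid)] <- as.character(GenomicRanges::seqnames(mrna))[!nzchar(gid) | is.na(gid)]
    gene_of <- setNames(gid, as.character(GenomicRanges::seqnames(mrna)))
  }
  cds_by_tx <- split(cds, as.character(GenomicRanges::seqnames(cds)))
  models <- list()
  skipped <- character(0)
  bad_frame <- character(0)
  for (id in names(seqs)) {
    if (!id %in% names(cds_by_tx)) {
      skipped <- c(skipped, id)
      next
    }
    iv <- range(cds_by_tx[[id]])
    cds_start <- GenomicRanges::start(iv)[1] - 1L  # 1-based inclusive -> 0-based
    cds_end <- GenomicRanges::end(iv)[1]           # inclusive end -> exclusive
    if ((cds_end - cds_start) %% 3L != 0L) {
      bad_frame <- c(bad_frame, id)
      next
    }
    gid <- if (id %in% names(gene_of)) gene_of[[id]] else id
    models[[id]] <- transcript_model(id, as.character(seqs[[id]]),
                                     cds_start, cds_end, gene_id = gid)
  }
  if (length(bad_frame))
    stop("CDS length not divisible by 3 for: ", paste(bad_frame, collapse = ", "))
  if (length(skipped))
    warning(length(skipped), " transcript(s) without CDS annotation skipped: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  models[order(names(models))]
}

#' Write a transcriptome to FASTA + GFF3
#'
#' Inverse of [read_transcriptome()]: writes sequences as FASTA and mRNA/CDS
#' features (transcript coordinates, 1-based inclusive) as GFF3, in
#' lexicographic transcript order.
#'
#' @param transcripts named list of [transcript_model()] objects.
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the input list.
#' @export
write_transcriptome <- function(transcripts, fasta_path, gff3_path) {
  transcripts <- transcripts[order(names(transcripts))]
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- names(transcripts)
  Biostrings::writeXStringSet(seqs, fasta_path)
  lines <- c("##gff-version 3")
  for (tx in transcripts) {
    L <- tx_length(tx)
    lines <- c(lines,
      sprintf("%s\tribopause\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s",
              tx$transcript_id, L, tx$transcript_id, tx$gene_id),
      sprintf("%s\tribopause\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s",
              tx$transcript_id, tx$cds_start + 1L, tx$cds_end,
              tx$transcript_id, tx$transcript_id))
  }
  writeLines(lines, gff3_path)
  invisible(transcripts)
}

#' Read footprint alignments from TSV
#'
#' Reads a tab-separated alignment table with header columns
#' `transcript_id`, `start5` (0-based 5' end), `length`, `count`. Records on
#' unknown transcripts or out of transcript bounds are dropped and tallied;
#' lengths outside `length_range` are likewise dropped. Negative counts are a
#' hard error.
#'
#' @param tsv_path path to the alignments TSV.
#' @param transcripts optional named list of transcript models used for
#'   bounds validation; if `NULL`, no bounds check is performed.
#' @param length_range inclusive allowed footprint length range.
#' @return a `data.frame` (class `"rpf_alignments"`) with the four columns;
#'   attribute `dropped` holds the tally of removed records.
#' @export
read_alignments <- function(tsv_path, transcripts = NULL,
                            length_range = c(23L, 36L)) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "start5", "length", "count")
  if (!all(req %in% names(df)))
    stop("alignments TSV must have header columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  if (any(df$count < 0)) stop("negative count in alignments TSV")
  validate_alignments(df, transcripts, length_range)
}

validate_alignments <- function(df, transcripts = NULL,
                                length_range = c(23L, 36L)) {
  dropped <- c(unknown = 0L, bounds = 0L, length = 0L)
  keep_len <- df$length >= length_range[1] & df$length <= length_range[2]
  dropped[["length"]] <- sum(!keep_len)
  df <- df[keep_len, , drop = FALSE]
  if (!is.null(transcripts)) {
    known <- df$transcript_id %in% names(transcripts)
    dropped[["unknown"]] <- sum(!known)
    df <- df[known, , drop = FALSE]
    lens <- vapply(transcripts, tx_length, 0L)[df$transcript_id]
    ok <- df$start5 >= 0L & (df$start5 + df$length) <= lens
    dropped[["bounds"]] <- sum(!ok)
    df <- df[ok, , drop = FALSE]
  }
  if (sum(dropped) > 0)
    warning(sprintf("dropped alignments: %d unknown transcript, %d out of bounds, %d bad length",
                    dropped[["unknown"]], dropped[["bounds"]], dropped[["length"]]))
  rownames(df) <- NULL
  structure(df, dropped = dropped, class = c("rpf_alignments", "data.frame"))
}

#' Write footprint alignments to TSV
#'
#' @param alignments alignment `data.frame` with columns `transcript_id`,
#'   `start5`, `length`, `count`.
#' @param tsv_path output path.
#' @return invisibly, the alignments.
#' @export
write_alignments <- function(alignments, tsv_path) {
  df <- as.data.frame(alignments)
  df <- df[order(df$transcript_id, df$start5, df$length), ]
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(alignments)
}

#' Read / write a gene count table
#'
#' Count tables are genes x samples integer matrices written as TSV with a
#' `gene_id` first column; rows are ordered lexicographically by gene id.
#'
#' @param path TSV path.
#' @return `read_counts`: an integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative entries in count table")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in count table")
  m
}

#' @rdname read_counts
#' @param counts integer matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}
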