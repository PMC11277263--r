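#' Build per-base coverage from footprint alignments
#'
#' Converts footprint alignments into per-transcript depth vectors. In
#' `psite` mode each alignment adds its `count` at the single P-site position
#' `start5 + offset(length)`; in `body` mode it adds `count` at every base
#' the footprint covers. P-site mode conserves mass: the depth vector sums to
#' the total footprint count on the transcript.
#'
#' @param alignments alignment `data.frame` (see [read_alignments()]).
#' @param transcripts a single [transcript_model()] or a named list of them.
#' @param mode `"psite"` (default) or `"body"`.
#' @param offsets named integer vector length -> P-site offset (required in
#'   psite mode; an observed length with no offset is an error).
#' @return a named list of `"coverage_profile"` objects, each an integer
#'   depth vector with attributes `transcript_id` and `mode` (a single
#'   transcript model returns the one profile directly).
#' @export
build_coverage <- function(alignments, transcripts, mode = c("psite", "body"),
                           offsets = NULL) {
  mode <- match.arg(mode)
  single <- inherits(transcripts, "transcript_model")
  if (single) transcripts <- setNames(list(transcripts), transcripts$transcript_id)
  if (mode == "psite") {
    lens <- unique(alignments$length)
    missing_len <- setdiff(as.character(lens), names(offsets))
    if (is.null(offsets) || length(missing_len))
      stop("no P-site offset for footprint length(s): ",
           paste(if (is.null(offsets)) lens else missing_len, collapse = ", "))
  }
  al_by_tx <- split(alignments, factor(alignments$transcript_id, levels = names(transcripts)))
  out <- lapply(names(transcripts), function(id) {
    tx <- transcripts[[id]]
    L <- tx_length(tx)
    depth <- integer(L)
    al <- al_by_tx[[id]]
    if (!is.null(al) && nrow(al)) {
      if (mode == "psite") {
        pos <- al$start5 + offsets[as.character(al$length)]
        ok <- pos >= 0L & pos < L
        tab <- rowsum(al$count[ok], pos[ok])
        depth[as.integer(rownames(tab)) + 1L] <- depth[as.integer(rownames(tab)) + 1L] + as.integer(tab)
      } else {
        for (i in seq_len(nrow(al))) {
          span <- (al$start5[i] + 1L):(al$start5[i] + al$length[i])
          depth[span] <- depth[span] + al$count[i]
        }
      }
    }
    structure(depth, transcript_id = id, mode = mode, class = "coverage_profile")
  })
  names(out) <- names(transcripts)
  if (single) out[[1]] else out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s (%s mode): %d nt, total depth %d, %d covered bases\n",
              attr(x, "transcript_id"), attr(x, "mode"), length(x),
              sum(x), sum(x > 0)))
  invisible(x)
}
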