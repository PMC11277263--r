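# Position weight matrix construction, scanning, and exact tail p-values.
# Scores are log2((p + eps) / q) against a 0-order background; the score
# distribution under the background is computed by dynamic programming over
# columns, exactly (hash over partial sums) for narrow motifs and on a fine
# discretized grid for wide ones.

#' Build a position probability matrix from aligned segments
#'
#' @param segments character vector of equal-length nucleotide strings.
#' @param pseudocount added per base and column (default 0).
#' @return a `"ppm"` matrix (rows A,C,G,T; columns sum to 1) with attribute
#'   `n_sequences`.
#' @export
pwm_from_sequences <- function(segments, pseudocount = 0) {
  segments <- toupper(gsub("U", "T", segments))
  w <- unique(nchar(segments))
  if (length(w) != 1L) stop("segments must have equal length")
  counts <- matrix(0, nrow = 4L, ncol = w, dimnames = list(BASES, seq_len(w)))
  for (s in segments) {
    idx <- match(strsplit(s, "")[[1]], BASES)
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <- counts[cbind(idx[ok], which(ok))] + 1
  }
  probs <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), `/`)
  structure(probs, n_sequences = length(segments), pseudocount = pseudocount,
            class = c("ppm", "matrix"))
}

#' Write / read a position probability matrix
#'
#' Tab-separated text format: a `#PPM n=<count>` header line followed by
#' four rows labelled A, C, G, T.
#'
#' @param ppm a `"ppm"` matrix.
#' @param path file path.
#' @return `read_pwm`: the `"ppm"` matrix.
#' @export
write_pwm <- function(ppm, path) {
  n <- attr(ppm, "n_sequences")
  lines <- c(sprintf("#PPM n=%d", if (is.null(n)) 0L else n),
             vapply(BASES, function(b)
               paste(c(b, format(ppm[b, ], digits = 10)), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(ppm)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  n <- as.integer(sub("^#PPM n=", "", header))
  rows <- strsplit(lines[2:5], "\t")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(rows[[1]]) - 1L)))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  m <- m[BASES, , drop = FALSE]
  colnames(m) <- seq_len(ncol(m))
  structure(m, n_sequences = n, class = c("ppm", "matrix"))
}

pwm_score_matrix <- function(ppm, background, eps = 1e-3) {
  log2(sweep(unclass(ppm) + eps, 1L, background, `/`))
}

#' Exact tail distribution of PWM scores under a 0-order background
#'
#' Dynamic programming over motif columns. For motifs of up to `exact_width`
#' columns the partial score sums are kept exactly (accumulated
#' left-to-right, so they are bitwise identical to a brute-force enumeration
#' in the same order); wider motifs use a discretized grid with step
#' `grid_step`.
#'
#' @param score_mat 4 x w score matrix (rows A,C,G,T).
#' @param background named base probabilities.
#' @param exact_width widest motif handled exactly (default 12).
#' @param grid_step grid resolution for wide motifs (default 1e-4).
#' @return `data.frame` with `score` and `prob`, sorted by score.
#' @keywords internal
pwm_score_distribution <- function(score_mat, background, exact_width = 12L,
                                   grid_step = 1e-4) {
  w <- ncol(score_mat)
  exact <- w <= exact_width
  if (exact) {
    # partial sums kept as exact doubles; states merged by identity
    st_vals <- score_mat[, 1L]
    st_probs <- unname(background[BASES])
    grp <- match(st_vals, unique(st_vals))
    vals <- unique(st_vals)
    probs <- as.numeric(rowsum(st_probs, grp))
    if (w > 1L) for (j in 2:w) {
      nv <- as.numeric(outer(vals, score_mat[, j], `+`))
      np <- as.numeric(outer(probs, unname(background[BASES]), `*`))
      grp <- match(nv, unique(nv))
      vals <- unique(nv)
      probs <- as.numeric(rowsum(np, grp))
    }
  } else {
    keys <- round(score_mat[, 1L] / grid_step)
    probs <- unname(background[BASES])
    tab <- rowsum(probs, keys)
    keys <- as.numeric(rownames(tab)); probs <- as.numeric(tab)
    for (j in 2:w) {
      colk <- round(score_mat[, j] / grid_step)
      nk <- as.numeric(outer(keys, colk, `+`))
      np <- as.numeric(outer(probs, unname(background[BASES]), `*`))
      tab <- rowsum(np, nk)
      keys <- as.numeric(rownames(tab)); probs <- as.numeric(tab)
    }
    vals <- keys * grid_step
  }
  ord <- order(vals)
  data.frame(score = vals[ord], prob = probs[ord])
}

#' Scan a sequence with a position probability matrix
#'
#' Scores every window with `sum(log2((p + eps) / q))` against a 0-order
#' background and reports windows whose exact tail p-value
#' `P(score >= observed)` under the background is at most `p_threshold`.
#'
#' @param ppm a `"ppm"` probability matrix.
#' @param sequence nucleotide string, or a [transcript_model()].
#' @param background named base probabilities A,C,G,T (default: base
#'   composition of the scanned sequence).
#' @param p_threshold hit p-value threshold (default 1e-4).
#' @param eps pseudo-probability inside the log-odds (default 1e-3).
#' @return `data.frame` (class `"motif_hits"`) with `transcript_id`, `start`
#'   (0-based), `score`, `p_value`, sorted by position.
#' @export
pwm_scan <- function(ppm, sequence, background = NULL, p_threshold = 1e-4,
                     eps = 1e-3) {
  id <- NA_character_
  if (inherits(sequence, "transcript_model")) {
    id <- sequence$transcript_id
    sequence <- sequence$sequence
  }
  sequence <- toupper(gsub("U", "T", sequence))
  chars <- strsplit(sequence, "")[[1]]
  w <- ncol(ppm)
  if (is.null(background)) {
    tab <- table(factor(chars, levels = BASES))
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
    names(background) <- BASES
  }
  background <- background[BASES] / sum(background[BASES])
  sm <- pwm_score_matrix(ppm, background, eps)
  dist <- pwm_score_distribution(sm, background)
  tail_p <- rev(cumsum(rev(dist$prob)))
  n_win <- length(chars) - w + 1L
  if (n_win < 1L) return(empty_hits(id))
  base_idx <- match(chars, BASES)
  scores <- vapply(seq_len(n_win), function(s) {
    idx <- base_idx[s:(s + w - 1L)]
    if (anyNA(idx)) return(-Inf)
    sum(sm[cbind(idx, seq_len(w))])
  }, 0)
  pv <- vapply(scores, function(t) {
    if (!is.finite(t)) return(1)
    k <- which(dist$score >= t - 1e-9)
    if (length(k)) tail_p[k[1]] else 0
  }, 0)
  keep <- pv <= p_threshold
  out <- data.frame(transcript_id = rep(id, sum(keep)), start = which(keep) - 1L,
                    score = scores[keep], p_value = pv[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  structure(out, class = c("motif_hits", "data.frame"))
}

empty_hits <- function(id) {
  structure(data.frame(transcript_id = character(0), start = integer(0),
                       score = numeric(0), p_value = numeric(0)),
            class = c("motif_hits", "data.frame"))
}

#' Scan many transcripts with a PWM
#'
#' @param ppm a `"ppm"` matrix.
#' @param transcripts named list of transcript models.
#' @param background shared background (default: pooled base composition of
#'   all transcripts, the 0-order background of the scanned set).
#' @param ... passed to [pwm_scan()].
#' @return row-bound hit `data.frame`.
#' @export
pwm_scan_all <- function(ppm, transcripts, background = NULL, ...) {
  if (is.null(background)) {
    pooled <- table(factor(unlist(strsplit(vapply(transcripts, `[[`, "", "sequence"), "")),
                           levels = BASES))
    background <- setNames((as.numeric(pooled) + 1) / (sum(pooled) + 4), BASES)
  }
  out <- do.call(rbind, lapply(transcripts, function(tx)
    pwm_scan(ppm, tx, background = background, ...)))
  rownames(out) <- NULL
  structure(out, class = c("motif_hits", "data.frame"))
}
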