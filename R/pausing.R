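# Pause scoring and calling. The pause score of a position is its P-site
# depth divided by the mean depth of a W-nt window centered on it (window
# clipped at transcript ends, site included), so uniform coverage scores ~1.
# Scores are z-standardized within coverage bins (deciles of the window read
# total) and called at strict score/z/depth cutoffs.

#' Sliding-window pause scores for one coverage profile
#'
#' For every position with nonzero depth, computes
#' `score = depth / window_mean` where the window is the up-to-`W`-nt
#' stretch centered on the position (clipped at the transcript ends and
#' including the position itself).
#'
#' @param coverage a `"coverage_profile"` (P-site mode) or plain numeric
#'   depth vector.
#' @param W window width in nt; odd, >= 3 (even values are incremented).
#' @return `data.frame` with `transcript_id`, `position` (0-based), `depth`,
#'   `window_mean`, `window_total`, `score`.
#' @export
pause_scores <- function(coverage, W = 1001L) {
  W <- as.integer(W)
  if (W < 3L) stop("W must be >= 3")
  if (W %% 2L == 0L) W <- W + 1L
  depth <- as.numeric(coverage)
  L <- length(depth)
  id <- attr(coverage, "transcript_id")
  if (is.null(id)) id <- NA_character_
  half <- (W - 1L) %/% 2L
  cs <- c(0, cumsum(depth))
  idx <- which(depth > 0)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, L)
  wtot <- cs[hi + 1L] - cs[lo]
  wlen <- hi - lo + 1L
  wmean <- wtot / wlen
  data.frame(transcript_id = id, position = idx - 1L, depth = depth[idx],
             window_mean = wmean, window_total = wtot,
             score = depth[idx] / wmean, stringsAsFactors = FALSE)
}

#' Pause scores for a list of coverage profiles
#'
#' @param coverages named list of coverage profiles (P-site mode).
#' @param W window width, as in [pause_scores()].
#' @return row-bound `data.frame` of per-position scores.
#' @export
pause_score_table <- function(coverages, W = 1001L) {
  out <- do.call(rbind, lapply(coverages, pause_scores, W = W))
  rownames(out) <- NULL
  out
}

#' Z-score pause scores within coverage bins
#'
#' Bins scored positions into `n_bins` quantile bins (deciles by default) of
#' their window read total and standardizes scores within each bin:
#' `z = (score - bin mean) / bin sd`. Bins with fewer than two sites or zero
#' variance get `z = 0` with a warning.
#'
#' @param sites scored sites from [pause_scores()]/[pause_score_table()].
#' @param n_bins number of coverage bins (default 10).
#' @return `sites` with added columns `coverage_bin` and `z`.
#' @export
zscore_by_coverage_bin <- function(sites, n_bins = 10L) {
  if (!nrow(sites)) {
    sites$coverage_bin <- integer(0); sites$z <- numeric(0)
    return(sites)
  }
  qs <- unique(quantile(sites$window_total, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(qs) > 1L)
    cut(sites$window_total, breaks = qs, include.lowest = TRUE, labels = FALSE)
  else rep(1L, nrow(sites))
  z <- numeric(nrow(sites))
  degenerate <- FALSE
  for (b in unique(bin)) {
    sel <- bin == b
    s <- sites$score[sel]
    if (length(s) < 2L || sd(s) == 0) {
      z[sel] <- 0
      degenerate <- TRUE
    } else {
      z[sel] <- (s - mean(s)) / sd(s)
    }
  }
  if (degenerate)
    warning("one or more coverage bins had < 2 sites or zero score variance; z set to 0 there")
  sites$coverage_bin <- bin
  sites$z <- z
  sites
}

#' Call pause sites at strict cutoffs
#'
#' A position is called when `score > score_min`, `z > z_min` and
#' `depth > depth_min`, all strict inequalities.
#'
#' @param sites z-scored sites from [zscore_by_coverage_bin()].
#' @param score_min,z_min,depth_min calling cutoffs (defaults 50, 1.65, 20).
#' @return the called subset of `sites`, with a `called` column (all `TRUE`).
#' @export
call_pauses <- function(sites, score_min = 50, z_min = 1.65, depth_min = 20) {
  called <- sites$score > score_min & sites$z > z_min & sites$depth > depth_min
  out <- sites[called, , drop = FALSE]
  out$called <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Maximum pause score per transcript
#'
#' @param sites scored sites (one time point).
#' @param transcript_ids transcripts to report (default: those present in
#'   `sites`); transcripts with no scored position get 0.
#' @return named numeric vector of per-transcript maxima.
#' @export
max_pause_per_transcript <- function(sites, transcript_ids = NULL) {
  if (is.null(transcript_ids)) transcript_ids <- sort(unique(sites$transcript_id))
  out <- setNames(numeric(length(transcript_ids)), transcript_ids)
  if (nrow(sites)) {
    mx <- tapply(sites$score, sites$transcript_id, max)
    hit <- intersect(names(mx), transcript_ids)
    out[hit] <- mx[hit]
  }
  out
}

#' Per-transcript maximum pause scores across time points
#'
#' Builds the transcripts x time points matrix of maximum pause scores,
#' restricted to transcripts with at least one called pause in at least one
#' time point.
#'
#' @param sites_by_timepoint named list (one z-scored site table per time
#'   point).
#' @param score_min,z_min,depth_min calling cutoffs used for the row
#'   restriction.
#' @return numeric matrix (rows: paused transcripts; columns: time points).
#' @export
pause_matrix <- function(sites_by_timepoint, score_min = 50, z_min = 1.65,
                         depth_min = 20) {
  called_tx <- sort(unique(unlist(lapply(sites_by_timepoint, function(s)
    call_pauses(s, score_min, z_min, depth_min)$transcript_id))))
  m <- vapply(sites_by_timepoint, max_pause_per_transcript,
              numeric(length(called_tx)), transcript_ids = called_tx)
  if (length(called_tx) == 1L) m <- matrix(m, nrow = 1L,
                                           dimnames = list(called_tx, names(sites_by_timepoint)))
  m
}

#' Cluster pausing dynamics across time points
#'
#' Rows of the pause matrix are z-scored across time points (constant rows
#' become zeros) and clustered with k-means (default) or Ward hierarchical
#' clustering. Labels are renumbered by descending cluster size so that a
#' fixed seed yields stable, comparable labels.
#'
#' @param mat pause matrix from [pause_matrix()].
#' @param k number of clusters (default 5, the usual dynamics-class count).
#' @param seed random seed for k-means initialization.
#' @param method `"kmeans"` (default) or `"hward"` (Ward.D2 on Euclidean
#'   distance).
#' @return integer cluster labels named by transcript, with attribute
#'   `method`.
#' @export
cluster_pause_dynamics <- function(mat, k = 5L, seed = 1L,
                                   method = c("kmeans", "hward")) {
  method <- match.arg(method)
  if (k < 2L) stop("k must be >= 2")
  z <- t(apply(mat, 1L, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  n_distinct <- nrow(unique(z))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct profiles; reducing k from %d", n_distinct, k))
    k <- max(1L, n_distinct)
  }
  if (k == 1L) {
    labels <- setNames(rep(1L, nrow(mat)), rownames(mat))
    return(structure(labels, method = method))
  }
  raw <- if (method == "kmeans") {
    with_seed(seed, kmeans(z, centers = k, nstart = 10L)$cluster)
  } else {
    cutree(hclust(dist(z), method = "ward.D2"), k = k)
  }
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  labels <- setNames(as.integer(relabel[as.character(raw)]), rownames(mat))
  structure(labels, method = method)
}
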