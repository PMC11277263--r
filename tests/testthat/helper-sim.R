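# Shared fixtures, built in code.

# a tiny deterministic transcript: 20 nt UTR5, 30-codon CDS, 20 nt UTR3
toy_transcript <- function(id = "tx1", seed = 1) {
  set.seed(seed)
  utr5 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  body <- paste(sample(c("A", "C", "G", "T"), 84, replace = TRUE), collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  transcript_model(id, paste0(utr5, "ATG", body, "TAA", utr3), 20L, 110L)
}

small_world <- function(n = 40, seed = 1, ...) {
  simulate_transcriptome(sim_config(n_transcripts = n, seed = seed, ...))
}

default_offsets <- setNames(rep(12L, 5), 27:31)

# independent brute-force pause-score oracle: explicit loops, no windows tricks
pause_scores_bruteforce <- function(depth, W) {
  if (W %% 2 == 0) W <- W + 1
  half <- (W - 1) / 2
  L <- length(depth)
  rows <- list()
  for (i in seq_len(L)) {
    if (depth[i] <= 0) next
    lo <- max(1, i - half); hi <- min(L, i + half)
    s <- 0
    for (j in lo:hi) s <- s + depth[j]
    m <- s / (hi - lo + 1)
    rows[[length(rows) + 1]] <- c(i - 1, depth[i], m, s, depth[i] / m)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("position", "depth", "window_mean", "window_total", "score")
  as.data.frame(out)
}

# independent sort-based TI oracle
ti_bruteforce <- function(depth) {
  covered <- sort(depth[depth > 0])
  n <- length(covered)
  if (n == 0) return(list(median = NA_real_, coverage = 0, ti = 0))
  med <- if (n %% 2 == 1) covered[(n + 1) / 2]
         else (covered[n / 2] + covered[n / 2 + 1]) / 2
  list(median = med, coverage = n / length(depth), ti = med * n / length(depth))
}
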