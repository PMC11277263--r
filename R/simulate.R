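# Synthetic Ribo-seq generator: transcript models with controllable GC
# structure, footprint libraries with planted codon-level pauses, matched
# RNA-seq / RPF count tables, and a protein table coupled to pausing.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic Ribo-seq study: transcript architecture and GC
#' structure, footprint length/offset/frame behavior, planted pauses with
#' dwell factor and downstream depletion, motif and upstream-C planting,
#' expression structure, and count/protein noise models.
#'
#' @param n_transcripts number of transcripts (one gene each).
#' @param utr5_range,utr3_range inclusive length ranges (nt) of the UTRs.
#' @param cds_codons_range inclusive range of CDS length in codons
#'   (including start and stop codons).
#' @param base_gc baseline transcript GC fraction.
#' @param gc_offset extra GC added to paused transcripts (the paused-group
#'   GC elevation).
#' @param gc_slope linear 5'->3' GC gradient across the transcript
#'   (negative = GC decreases toward the 3' end).
#' @param gc_sd per-transcript GC jitter (s.d.).
#' @param length_probs named probability vector over footprint lengths.
#' @param frame_fidelity probability that a footprint's P-site falls exactly
#'   in frame 0 of its codon; off-frame footprints shift by +/-1 nt.
#' @param psite_offsets named integer vector: true P-site offset per length.
#' @param start_codon_weight sampling weight multiplier of the initiation
#'   codon (emulates start-codon footprint accumulation).
#' @param expression_meanlog,expression_sdlog lognormal transcript
#'   expression rates.
#' @param paused_fraction fraction of transcripts given a planted pause
#'   (exact count `round(fraction * n)`).
#' @param pause_codon_margin codons excluded at the CDS start/end when
#'   drawing the pause codon.
#' @param dwell dwell factor lambda >= 1: multiplier on the pause codon's
#'   footprint sampling weight.
#' @param depletion downstream depletion d in (0, 1]: weight multiplier for
#'   codons downstream of the pause (run-off scarcity).
#' @param motif motif sequence planted in-frame downstream of pauses.
#' @param motif_prob probability a paused transcript receives the motif.
#' @param motif_offset nt from the pause P-site base to the motif start
#'   (multiple of 3).
#' @param c13_prob marginal probability of a C exactly 13 nt upstream of the
#'   pause site (planted as C with this probability, otherwise a non-C base,
#'   so the realized frequency equals the probability).
#' @param de_fraction,de_fc fraction of genes with a planted RNA fold change
#'   and its value (applied in condition B).
#' @param te_fraction,te_fc fraction of genes with a planted translation
#'   efficiency multiplier (applied to RPF counts) and its value.
#' @param rna_mean mean RNA-seq count scale per gene.
#' @param rna_dispersion negative-binomial dispersion (> 0).
#' @param protein_base,protein_gamma,protein_sdlog protein table model:
#'   abundance = base * (1/dwell)^gamma * lognormal(sdlog).
#' @param seed base seed; all generators are pure functions of
#'   (config, seed).
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_transcripts = 200L,
                       utr5_range = c(30L, 80L),
                       cds_codons_range = c(150L, 400L),
                       utr3_range = c(40L, 120L),
                       base_gc = 0.45, gc_offset = 0.08,
                       gc_slope = -0.10, gc_sd = 0.02,
                       length_probs = c(`27` = 0.15, `28` = 0.20, `29` = 0.30,
                                        `30` = 0.20, `31` = 0.15),
                       frame_fidelity = 0.95,
                       psite_offsets = setNames(rep(12L, 5L), 27:31),
                       start_codon_weight = 5,
                       expression_meanlog = 0, expression_sdlog = 1,
                       paused_fraction = 0.5,
                       pause_codon_margin = c(5L, 12L),
                       dwell = 200, depletion = 1,
                       motif = "CGCCGCCGCCGCCGCC", motif_prob = 0.5,
                       motif_offset = 9L,
                       c13_prob = 0.6,
                       de_fraction = 0, de_fc = 4,
                       te_fraction = 0, te_fc = 2,
                       rna_mean = 200, rna_dispersion = 0.05,
                       protein_base = 100, protein_gamma = 1,
                       protein_sdlog = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_transcripts <- as.integer(n_transcripts)
  cfg$seed <- as.integer(seed)
  cfg$motif_offset <- as.integer(motif_offset)
  if (abs(sum(length_probs) - 1) > 1e-9) stop("length_probs must sum to 1")
  if (dwell < 1) stop("dwell factor must be >= 1")
  if (depletion <= 0 || depletion > 1) stop("depletion must be in (0, 1]")
  if (frame_fidelity < 0 || frame_fidelity > 1) stop("frame_fidelity in [0,1]")
  if (!all(names(length_probs) %in% names(psite_offsets)))
    stop("psite_offsets must cover every length in length_probs")
  max_off <- max(psite_offsets); max_len <- max(as.integer(names(length_probs)))
  if (utr5_range[1] < max_off + 2L)
    stop("5'UTR too short for footprint geometry (need >= offset + 2)")
  if (utr3_range[1] < max_len - min(psite_offsets) - 1L)
    stop("3'UTR too short for footprint geometry")
  if (cds_codons_range[1] <= sum(pause_codon_margin) + 2L)
    stop("CDS too short for the pause-codon margins")
  if (motif_offset %% 3L != 0L) stop("motif_offset must be a multiple of 3")
  if (3L * pause_codon_margin[2] < motif_offset + nchar(motif) + 3L)
    stop("pause_codon_margin[2] too small to fit the planted motif before the stop codon")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d transcripts, %.0f%% paused (lambda=%g, d=%g), seed %d\n",
              x$n_transcripts, 100 * x$paused_fraction, x$dwell, x$depletion, x$seed))
  invisible(x)
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

# position-specific GC probabilities for one transcript
gc_profile_of <- function(gc_tx, slope, L) {
  rel <- if (L > 1) (seq_len(L) - 1) / (L - 1) else 0.5
  pmin(pmax(gc_tx + slope * (rel - 0.5), 0.05), 0.95)
}

sample_sequence <- function(gc_pos) {
  L <- length(gc_pos)
  strong <- runif(L) < gc_pos           # G or C
  second <- runif(L) < 0.5
  ifelse(strong, ifelse(second, "G", "C"), ifelse(second, "A", "T"))
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Draws transcript models (5'UTR + CDS + 3'UTR, ATG/TAA bounded) with a
#' controllable GC profile, marks an exact fraction of transcripts as paused,
#' plants the pause codon, the downstream motif and the upstream C signal,
#' and records everything in a truth table. Deterministic under the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return a list with elements `transcripts` (named list of
#'   [transcript_model()]) and `truth` (one `data.frame` row per transcript:
#'   paused flag, 0-based pause position and codon, dwell, depletion, motif
#'   flag, expression rate, planted RNA/TE fold changes, target GC).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_transcripts
    ids <- sprintf("tx%04d", seq_len(n))
    utr5 <- sample_range(n, config$utr5_range)
    ncod <- sample_range(n, config$cds_codons_range)
    utr3 <- sample_range(n, config$utr3_range)
    n_paused <- round(config$paused_fraction * n)
    paused <- logical(n)
    paused[sample.int(n, n_paused)] <- TRUE
    gc_tx <- pmin(pmax(config$base_gc + config$gc_offset * paused +
                         rnorm(n, 0, config$gc_sd), 0.10), 0.90)
    expr <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)
    rna_fc <- rep(1, n)
    if (config$de_fraction > 0)
      rna_fc[sample.int(n, round(config$de_fraction * n))] <- config$de_fc
    te_mult <- rep(1, n)
    if (config$te_fraction > 0)
      te_mult[sample.int(n, round(config$te_fraction * n))] <- config$te_fc
    m <- config$pause_codon_margin
    motif <- config$motif
    transcripts <- vector("list", n)
    pause_codon <- rep(NA_integer_, n)
    pause_pos <- rep(NA_integer_, n)
    has_motif <- logical(n)
    for (i in seq_len(n)) {
      L <- utr5[i] + 3L * ncod[i] + utr3[i]
      cds_start <- utr5[i]
      cds_end <- cds_start + 3L * ncod[i]
      seq_chr <- sample_sequence(gc_profile_of(gc_tx[i], config$gc_slope, L))
      seq_chr[cds_start + 1:3] <- c("A", "T", "G")
      seq_chr[(cds_end - 2):cds_end] <- c("T", "A", "A")
      if (paused[i]) {
        pc <- if (m[1] >= ncod[i] - 1L - m[2]) m[1]
              else sample(m[1]:(ncod[i] - 1L - m[2]), 1L)
        pause_codon[i] <- pc
        pp <- cds_start + 3L * pc
        pause_pos[i] <- pp
        if (config$motif_prob > 0 && runif(1) < config$motif_prob) {
          has_motif[i] <- TRUE
          mstart <- pp + config$motif_offset
          seq_chr[(mstart + 1):(mstart + nchar(motif))] <-
            strsplit(motif, "")[[1]]
        }
        if (config$c13_prob > 0) {
          cpos <- pp - 13L
          if (cpos >= 0L) {
            gc_here <- gc_profile_of(gc_tx[i], config$gc_slope, L)[cpos + 1L]
            seq_chr[cpos + 1L] <- if (runif(1) < config$c13_prob) "C"
              else sample(c("A", "G", "T"), 1L,
                          prob = c((1 - gc_here) / 2, gc_here / 2, (1 - gc_here) / 2))
          }
        }
      }
      transcripts[[i]] <- transcript_model(ids[i], paste(seq_chr, collapse = ""),
                                           cds_start, cds_end)
    }
    names(transcripts) <- ids
    truth <- data.frame(
      transcript_id = ids, gene_id = ids,
      paused = paused, pause_pos = pause_pos, pause_codon = pause_codon,
      dwell = ifelse(paused, config$dwell, 1),
      depletion = ifelse(paused, config$depletion, 1),
      motif = has_motif,
      expression = expr, rna_fc = rna_fc, te_mult = te_mult,
      gc_target = gc_tx,
      stringsAsFactors = FALSE
    )
    list(transcripts = transcripts, truth = truth)
  })
}

#' Simulate a footprint (RPF) library with planted pauses
#'
#' Draws exactly `n_reads` footprints. Transcripts are sampled proportionally
#' to their expression rate; within a transcript, P-site codons are sampled
#' with unit weight, with the initiation codon up-weighted, the pause codon
#' weighted by the dwell factor and downstream codons down-weighted by the
#' depletion factor. With probability `frame_fidelity` the P-site lands in
#' frame 0; otherwise it shifts by one nt. Footprint 5' ends are the P-site
#' minus the true length-specific offset.
#'
#' @param transcripts,truth output of [simulate_transcriptome()].
#' @param config the [sim_config()].
#' @param n_reads total footprint count to emit (> 0).
#' @param dwell_scale optional per-transcript multiplier in `[0, 1]` on the
#'   excess dwell (`lambda_t = 1 + (lambda - 1) * scale`); scalar or vector
#'   over transcripts. Used to modulate pausing across time points.
#' @param seed random seed (default derived from the config seed).
#' @return an alignment `data.frame` (`transcript_id`, `start5`, `length`,
#'   `count`) whose counts sum to `n_reads`.
#' @export
simulate_rpf_library <- function(transcripts, truth, config, n_reads,
                                 dwell_scale = 1, seed = config$seed + 1L) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  n <- length(transcripts)
  dwell_scale <- rep_len(dwell_scale, n)
  with_seed(seed, {
    lens <- as.integer(names(config$length_probs))
    tx_draw <- sample.int(n, n_reads, replace = TRUE,
                          prob = truth$expression)
    reads <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sum(tx_draw == i)
      if (k == 0L) next
      tx <- transcripts[[i]]
      ncod <- cds_length(tx) %/% 3L
      w <- rep(1, ncod)
      w[1L] <- w[1L] * config$start_codon_weight
      if (isTRUE(truth$paused[i])) {
        pc <- truth$pause_codon[i]
        lam <- 1 + (truth$dwell[i] - 1) * dwell_scale[i]
        w[pc + 1L] <- w[pc + 1L] * lam
        if (pc + 2L <= ncod)
          w[(pc + 2L):ncod] <- w[(pc + 2L):ncod] * truth$depletion[i]
      }
      codon <- sample.int(ncod, k, replace = TRUE, prob = w) - 1L
      shift <- integer(k)
      off_frame <- runif(k) >= config$frame_fidelity
      shift[off_frame] <- sample(c(-1L, 1L), sum(off_frame), replace = TRUE)
      psite <- tx$cds_start + 3L * codon + shift
      rl <- lens[sample.int(length(lens), k, replace = TRUE,
                            prob = config$length_probs)]
      start5 <- psite - config$psite_offsets[as.character(rl)]
      ok <- start5 >= 0L & (start5 + rl) <= tx_length(tx)
      if (!all(ok)) {  # clamp the rare boundary read back in range
        start5[!ok] <- pmin(pmax(start5[!ok], 0L), tx_length(tx) - rl[!ok])
      }
      reads[[i]] <- data.frame(transcript_id = tx$transcript_id,
                               start5 = start5, length = rl,
                               stringsAsFactors = FALSE)
    }
    all_reads <- do.call(rbind, reads)
    agg <- aggregate(list(count = rep(1L, nrow(all_reads))),
                     all_reads[c("transcript_id", "start5", "length")], sum)
    agg <- agg[order(agg$transcript_id, agg$start5, agg$length), ]
    rownames(agg) <- NULL
    structure(agg, class = c("rpf_alignments", "data.frame"))
  })
}

#' Simulate matched count tables (RNA-seq or RPF)
#'
#' Negative-binomial counts for two conditions (A, B) with `n_samples`
#' replicates each. Gene means follow the transcriptome's expression rates
#' scaled to `rna_mean`; condition B applies the planted RNA fold change,
#' and the RPF assay additionally applies the planted TE multiplier.
#'
#' @param transcripts,truth output of [simulate_transcriptome()].
#' @param config the [sim_config()] (`rna_dispersion` must be > 0).
#' @param n_samples replicates per condition.
#' @param assay `"rna"` or `"rpf"`.
#' @param seed random seed.
#' @return integer matrix genes x samples with columns `A1..An, B1..Bn`.
#' @export
simulate_rna_counts <- function(transcripts, truth, config, n_samples = 3L,
                                assay = c("rna", "rpf"),
                                seed = config$seed + 2L) {
  assay <- match.arg(assay)
  if (config$rna_dispersion <= 0) stop("rna_dispersion must be > 0")
  with_seed(seed + (assay == "rpf"), {
    base <- config$rna_mean * truth$expression / mean(truth$expression)
    if (assay == "rpf") base <- base * truth$te_mult
    mu_a <- base
    mu_b <- base * truth$rna_fc
    n <- length(base)
    size <- 1 / config$rna_dispersion
    m <- matrix(0L, nrow = n, ncol = 2L * n_samples,
                dimnames = list(truth$gene_id,
                                c(paste0("A", seq_len(n_samples)),
                                  paste0("B", seq_len(n_samples)))))
    for (j in seq_len(n_samples)) m[, j] <- rnbinom(n, mu = mu_a, size = size)
    for (j in seq_len(n_samples)) m[, n_samples + j] <- rnbinom(n, mu = mu_b, size = size)
    m
  })
}

#' Simulate a protein abundance table coupled to pausing
#'
#' Protein abundance = `protein_base * (1 / dwell)^protein_gamma *`
#' lognormal noise, so paused (high-dwell) transcripts produce
#' stochastically less protein when `protein_gamma > 0` and the groups are
#' exchangeable when `protein_gamma = 0`.
#'
#' @param truth truth table from [simulate_transcriptome()].
#' @param config the [sim_config()].
#' @param seed random seed.
#' @return `data.frame` with `gene_id` and `abundance`.
#' @export
simulate_protein_table <- function(truth, config, seed = config$seed + 3L) {
  with_seed(seed, {
    ab <- config$protein_base * (1 / truth$dwell)^config$protein_gamma *
      rlnorm(nrow(truth), 0, config$protein_sdlog)
    data.frame(gene_id = truth$gene_id, abundance = ab,
               stringsAsFactors = FALSE)
  })
}

#' Write / read the planted-truth table
#'
#' @param truth truth `data.frame` from [simulate_transcriptome()].
#' @param path TSV path.
#' @return `read_truth`: the truth `data.frame`.
#' @export
write_truth <- function(truth, path) {
  write.table(truth[order(truth$transcript_id), ], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
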