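#' Analysis configuration
#'
#' Bundles the tunable parameters shared by the analysis stages: P-site
#' offsets per read length, the pause-scoring window, the pause-calling
#' cutoffs, the translation-efficiency z threshold, and the differential
#' expression filter.
#'
#' @param psite_offsets named integer vector mapping read length to P-site
#'   offset (nt from the footprint 5' end to the P-site codon first base).
#'   Default: offset 12 for lengths 23--36.
#' @param pause_window sliding-window width W (nt) used for pause scoring;
#'   clipped at transcript ends. Must be odd and >= 3.
#' @param score_min,z_min,depth_min pause-calling cutoffs; a site is called
#'   when score > score_min, z > z_min and depth > depth_min (all strict).
#'   Defaults 50, 1.65, 20.
#' @param te_z_threshold |z| threshold on standardized log2 delta-TE
#'   (default 1.5, strict).
#' @param de_lfc_min,de_p_max differential expression filter: |log2 fold
#'   change| > de_lfc_min and p < de_p_max (defaults 1 and 0.05).
#' @param rpf_count_floor minimum mean raw RPF count per gene for the RPF
#'   differential test (default 5).
#' @param length_range allowed footprint lengths, inclusive (default 23--36).
#' @param coverage_region denominator region for translation intensity:
#'   `"cds"` (default) or `"transcript"`.
#' @param n_bins number of coverage bins for pause z-scoring (default 10).
#' @param seed base random seed used by seeded stages.
#' @return an object of class `"analysis_config"` (a validated list).
#' @export
analysis_config <- function(psite_offsets = setNames(rep(12L, 14L), 23:36),
                            pause_window = 1001L,
                            score_min = 50,
                            z_min = 1.65,
                            depth_min = 20,
                            te_z_threshold = 1.5,
                            de_lfc_min = 1,
                            de_p_max = 0.05,
                            rpf_count_floor = 5,
                            length_range = c(23L, 36L),
                            coverage_region = c("cds", "transcript"),
                            n_bins = 10L,
                            seed = 1L) {
  coverage_region <- match.arg(coverage_region)
  stopifnot(is.numeric(psite_offsets), !is.null(names(psite_offsets)))
  pause_window <- as.integer(pause_window)
  if (pause_window < 3L) stop("pause_window must be >= 3")
  if (pause_window %% 2L == 0L) pause_window <- pause_window + 1L
  vals <- c(score_min, z_min, depth_min, te_z_threshold, de_lfc_min, de_p_max)
  if (any(!is.finite(vals))) stop("all thresholds must be finite")
  structure(list(
    psite_offsets = setNames(as.integer(psite_offsets), names(psite_offsets)),
    pause_window = pause_window,
    score_min = score_min, z_min = z_min, depth_min = depth_min,
    te_z_threshold = te_z_threshold,
    de_lfc_min = de_lfc_min, de_p_max = de_p_max,
    rpf_count_floor = rpf_count_floor,
    length_range = as.integer(length_range),
    coverage_region = coverage_region,
    n_bins = as.integer(n_bins),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Ribo-seq analysis configuration\n")
  cat(sprintf("  pause window W = %d nt; call cutoffs: score > %g, z > %g, depth > %g\n",
              x$pause_window, x$score_min, x$z_min, x$depth_min))
  cat(sprintf("  TE |z| > %g; DE |log2FC| > %g & p < %g (RPF floor %g)\n",
              x$te_z_threshold, x$de_lfc_min, x$de_p_max, x$rpf_count_floor))
  offs <- unique(x$psite_offsets)
  cat(sprintf("  P-site offsets: %s for lengths %s-%s; TI region: %s\n",
              paste(offs, collapse = ","), min(as.integer(names(x$psite_offsets))),
              max(as.integer(names(x$psite_offsets))), x$coverage_region))
  invisible(x)
}
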