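# Translation-level metrics: median-of-ratios normalization, a transparent
# differential expression filter (|log2FC| > 1 & p < 0.05), translation
# efficiency with robust delta-TE z-scoring (|z| > 1.5), the coverage-aware
# translation intensity TI = median covered depth x fraction of region
# covered, and rank-sum group comparisons.

#' Median-of-ratios count normalization
#'
#' Size factors are medians of per-sample count ratios to the per-gene
#' geometric mean, computed over genes positive in every sample.
#'
#' @param counts integer matrix genes x samples.
#' @return list with `size_factors` (named numeric) and `normalized`
#'   (matrix of count / size factor).
#' @export
normalize_counts <- function(counts) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has positive counts in all samples; consider adding a pseudocount")
  loggeo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2L,
              function(col) exp(median(log(col) - loggeo)))
  list(size_factors = sf,
       normalized = sweep(counts, 2L, sf, `/`))
}

#' Differential expression / translation filter
#'
#' Computes log2 fold changes from group means of normalized counts
#' (pseudocount 0.5) and p-values from a negative-binomial Wald test with
#' method-of-moments dispersion (default) or an exact Poisson test on the
#' group sums. A gene is significant when `|log2FC| > lfc_min` and
#' `p < p_max`; for the RPF assay, genes whose mean raw count is below
#' `count_floor` are never significant.
#'
#' @param counts raw integer matrix genes x samples.
#' @param groupA,groupB column names (or indices) of the two groups.
#' @param test `"nb_wald"` or `"exact_poisson"`.
#' @param assay `"rna"` or `"rpf"` (`"rpf"` applies the mean-count floor).
#' @param lfc_min,p_max,count_floor filter parameters (defaults 1, 0.05, 5).
#' @return `data.frame` with `gene_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `p_value`, `significant`.
#' @export
differential_expression <- function(counts, groupA, groupB,
                                    test = c("nb_wald", "exact_poisson"),
                                    assay = c("rna", "rpf"),
                                    lfc_min = 1, p_max = 0.05,
                                    count_floor = 5) {
  test <- match.arg(test)
  assay <- match.arg(assay)
  a <- counts[, groupA, drop = FALSE]
  b <- counts[, groupB, drop = FALSE]
  if (!ncol(a) || !ncol(b)) stop("each group needs at least one column")
  norm <- normalize_counts(counts[, c(colnames(a), colnames(b)), drop = FALSE])
  na_ <- norm$normalized[, colnames(a), drop = FALSE]
  nb_ <- norm$normalized[, colnames(b), drop = FALSE]
  mu_a <- rowMeans(na_); mu_b <- rowMeans(nb_)
  log2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  if (test == "nb_wald") {
    # pooled within-group variance, moment dispersion with a small floor
    va <- if (ncol(na_) > 1) apply(na_, 1L, var) else rep(0, nrow(na_))
    vb <- if (ncol(nb_) > 1) apply(nb_, 1L, var) else rep(0, nrow(nb_))
    mu <- (mu_a + mu_b) / 2
    disp <- pmax(((va + vb) / 2 - mu) / pmax(mu, 1e-8)^2, 1e-4)
    se2 <- (1 / pmax(mu_a, 0.5) + disp) / ncol(na_) +
           (1 / pmax(mu_b, 0.5) + disp) / ncol(nb_)
    wald <- (log2fc * log(2)) / sqrt(se2)
    p <- 2 * pnorm(-abs(wald))
  } else {
    sa <- rowSums(na_); sb <- rowSums(nb_)
    frac <- ncol(nb_) / (ncol(na_) + ncol(nb_))
    p <- vapply(seq_len(nrow(counts)), function(i) {
      tot <- round(sa[i] + sb[i])
      if (tot == 0) return(1)
      stats::binom.test(round(sb[i]), tot, p = frac)$p.value
    }, 0)
  }
  significant <- abs(log2fc) > lfc_min & p < p_max
  if (assay == "rpf") {
    raw_mean <- rowMeans(counts[, c(colnames(a), colnames(b)), drop = FALSE])
    significant <- significant & raw_mean >= count_floor
  }
  data.frame(gene_id = rownames(counts), base_mean_a = mu_a,
             base_mean_b = mu_b, log2fc = log2fc, p_value = p,
             significant = significant, row.names = NULL,
             stringsAsFactors = FALSE)
}

tpm_like <- function(counts, lengths) {
  rate <- counts / lengths
  sweep(rate, 2L, colSums(rate), `/`) * 1e6
}

#' Translation efficiency per sample
#'
#' TE = length-normalized, library-scaled RPF abundance over the matching
#' RNA abundance (TPM-like units on both sides). Genes whose RNA abundance
#' is zero or whose mean raw count falls below `floor` in either assay are
#' masked (`NA`).
#'
#' @param rpf_counts,rna_counts integer matrices with shared gene rownames
#'   and shared sample columns.
#' @param lengths named vector of per-gene region lengths (CDS lengths) used
#'   for the density normalization.
#' @param floor minimum mean raw count per assay (default 10).
#' @return numeric matrix of TE values, genes x samples.
#' @export
translation_efficiency <- function(rpf_counts, rna_counts, lengths,
                                   floor = 10) {
  genes <- intersect(rownames(rpf_counts), rownames(rna_counts))
  samples <- intersect(colnames(rpf_counts), colnames(rna_counts))
  rpf <- rpf_counts[genes, samples, drop = FALSE]
  rna <- rna_counts[genes, samples, drop = FALSE]
  len <- lengths[genes]
  te <- tpm_like(rpf, len) / tpm_like(rna, len)
  te[tpm_like(rna, len) == 0] <- NA
  low <- rowMeans(rpf) < floor | rowMeans(rna) < floor
  te[low, ] <- NA
  te
}

#' Delta-TE with robust z-scoring
#'
#' `log2_dte = log2(teB / teA)` per gene, standardized across genes with the
#' median and the MAD (scaled by 1.4826): `z = (log2_dte - median) / MAD`.
#' A gene is significant when `|z| > z_threshold` (strict).
#'
#' @param teA,teB named TE vectors (or single-column matrices) for the two
#'   conditions.
#' @param z_threshold significance threshold on |z| (default 1.5).
#' @return `data.frame` with `gene_id`, `te_a`, `te_b`, `log2_dte`, `z`,
#'   `significant` (genes with missing or nonpositive TE are dropped).
#' @export
delta_te <- function(teA, teB, z_threshold = 1.5) {
  teA <- if (is.matrix(teA)) rowMeans(teA) else teA
  teB <- if (is.matrix(teB)) rowMeans(teB) else teB
  genes <- intersect(names(teA), names(teB))
  a <- teA[genes]; b <- teB[genes]
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  ld <- log2(b[ok] / a[ok])
  md <- median(ld)
  s <- mad(ld)   # 1.4826 * MAD by default
  z <- if (s > 0) (ld - md) / s else rep(0, length(ld))
  data.frame(gene_id = genes[ok], te_a = a[ok], te_b = b[ok],
             log2_dte = ld, z = z,
             significant = abs(z) > z_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Translation intensity (TI)
#'
#' `TI = median depth over covered bases x coverage`, where coverage is the
#' fraction of region bases with nonzero footprint depth. The median is the
#' standard median (the two central values are averaged for an even number
#' of covered bases). The region defaults to the CDS; the whole transcript
#' is available as an alternative denominator. Intended for body-mode
#' coverage profiles ("nucleotides in RPFs over nucleotides in the region").
#'
#' @param coverage a coverage profile or numeric depth vector.
#' @param transcript transcript model supplying the CDS bounds (not needed
#'   for `region = "transcript"` on a plain vector).
#' @param region `"cds"` (default) or `"transcript"`.
#' @return list with `median_depth`, `coverage`, `n_covered`,
#'   `region_length` and `ti` (`ti = 0` and `median_depth = NA` when nothing
#'   is covered).
#' @export
translation_intensity <- function(coverage, transcript = NULL,
                                  region = c("cds", "transcript")) {
  region <- match.arg(region)
  depth <- as.numeric(coverage)
  if (region == "cds") {
    if (is.null(transcript)) stop("region = 'cds' requires the transcript model")
    if (cds_length(transcript) <= 0) stop("empty region")
    depth <- depth[(transcript$cds_start + 1L):transcript$cds_end]
  }
  L <- length(depth)
  if (L == 0L) stop("empty region")
  covered <- depth[depth > 0]
  n <- length(covered)
  cov_frac <- n / L
  med <- if (n) median(covered) else NA_real_
  list(median_depth = med, coverage = cov_frac, n_covered = n,
       region_length = L, ti = if (n) med * cov_frac else 0)
}

#' Translation intensity for a list of coverage profiles
#'
#' @param coverages named list of coverage profiles (body mode).
#' @param transcripts named list of transcript models.
#' @param region as in [translation_intensity()].
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `median_depth`, `coverage`, `ti`.
#' @export
translation_intensity_table <- function(coverages, transcripts,
                                        region = c("cds", "transcript")) {
  region <- match.arg(region)
  rows <- lapply(names(coverages), function(id) {
    ti <- translation_intensity(coverages[[id]], transcripts[[id]], region)
    data.frame(transcript_id = id, median_depth = ti$median_depth,
               coverage = ti$coverage, ti = ti$ti,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact when both groups have at most 20
#' observations and no ties, normal approximation with tie correction
#' otherwise.
#'
#' @param values named numeric vector.
#' @param groupA,groupB names (ids) of the two groups.
#' @return list with `statistic`, `p_value`, `median_a`, `median_b`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(values, groupA, groupB) {
  a <- values[intersect(groupA, names(values))]
  b <- values[intersect(groupB, names(values))]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b))
}
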