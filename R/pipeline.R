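# End-to-end synthetic run: generate data, run every analysis stage in
# dependency order, write deterministic TSV outputs and a JSON manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a seeded synthetic study (transcriptome with planted pauses, a
#' footprint library per time point with a pause-release schedule, matched
#' RNA/RPF count tables, a protein table), then runs every analysis stage:
#' footprint diagnostics, pause scoring/calling per time point, pause-matrix
#' clustering, differential expression, TE/delta-TE, TI and the
#' pausing-vs-TI and pausing-vs-protein comparisons, pause-site sequence
#' features, motif scanning and association, and the motif ensemble free
#' energy. All outputs are tab-separated files under `outdir` plus a
#' `manifest.json` written last. Reruns with the same configuration are
#' byte-identical.
#'
#' @param outdir output directory (created if missing).
#' @param sim a [sim_config()].
#' @param analysis an [analysis_config()].
#' @param n_reads footprints per time-point library.
#' @param time_points time point labels.
#' @param pause_release per-time-point multiplier on the planted excess
#'   dwell (1 = full pausing, 0 = fully released); emulates dark-to-light
#'   release.
#' @param k_clusters clusters for the pause-dynamics clustering.
#' @return the manifest (invisibly): config hash, seed, package version,
#'   per-stage outputs, wall time.
#' @export
run_all <- function(outdir,
                    sim = sim_config(),
                    analysis = analysis_config(),
                    n_reads = 50000L,
                    time_points = c("0h", "0.5h", "1h", "2h", "4h"),
                    pause_release = c(1, 0.10, 0.05, 0.02, 0.02),
                    k_clusters = 5L) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  outputs <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  cfg_json <- p("config.json")
  jsonlite::write_json(list(sim = unclass(sim), analysis = unclass(analysis),
                            n_reads = n_reads, time_points = time_points,
                            pause_release = pause_release,
                            k_clusters = k_clusters),
                       cfg_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, cfg_json)

  # --- simulate ---
  world <- stage("simulate", simulate_transcriptome(sim))
  transcripts <- world$transcripts
  truth <- world$truth
  write_transcriptome(transcripts, p("transcripts.fa"), p("transcripts.gff3"))
  write_truth(truth, p("truth.tsv"))
  libs <- lapply(seq_along(time_points), function(t)
    simulate_rpf_library(transcripts, truth, sim, n_reads,
                         dwell_scale = pause_release[t],
                         seed = sim$seed + 10L + t))
  names(libs) <- time_points
  for (t in time_points)
    write_alignments(libs[[t]], p(sprintf("alignments_%s.tsv", t)))
  outputs <- c(outputs, p("transcripts.fa"), p("transcripts.gff3"), p("truth.tsv"),
               p(sprintf("alignments_%s.tsv", time_points)))

  # --- metagene diagnostics (first time point) ---
  al1 <- libs[[1]]
  offsets_est <- stage("metagene", {
    lh <- length_histogram(al1)
    write_tsv(data.frame(length = names(lh), count = lh), p("length_hist.tsv"))
    offs <- estimate_psite_offsets(al1, transcripts)
    write_tsv(data.frame(length = names(offs), offset = as.integer(offs),
                         reliable = attr(offs, "reliable")), p("offsets.tsv"))
    fr <- frame_periodicity(al1, transcripts, offs)
    write_tsv(data.frame(frame = 0:2, fraction = as.numeric(fr)), p("frames.tsv"))
    for (anch in c("start", "stop")) {
      mp <- metagene_profile(al1, transcripts, anchor = anch,
                             offsets = offs, site = "end5")
      write_tsv(as.data.frame(mp), p(sprintf("metagene_%s.tsv", anch)))
    }
    offs
  })
  outputs <- c(outputs, p(c("length_hist.tsv", "offsets.tsv", "frames.tsv",
                            "metagene_start.tsv", "metagene_stop.tsv")))

  # --- pausing per time point ---
  sites_by_tp <- stage("pauses", lapply(libs, function(al) {
    cov <- build_coverage(al, transcripts, mode = "psite", offsets = offsets_est)
    sites <- pause_score_table(cov, W = analysis$pause_window)
    suppressWarnings(zscore_by_coverage_bin(sites, n_bins = analysis$n_bins))
  }))
  for (t in time_points) {
    s <- sites_by_tp[[t]]
    called <- call_pauses(s, analysis$score_min, analysis$z_min, analysis$depth_min)
    s$called <- paste(s$transcript_id, s$position) %in%
      paste(called$transcript_id, called$position)
    s$position <- s$position + 1L  # 1-based in reports
    write_tsv(s, p(sprintf("pauses_%s.tsv", t)))
  }
  outputs <- c(outputs, p(sprintf("pauses_%s.tsv", time_points)))

  pm <- stage("pause_matrix",
              pause_matrix(sites_by_tp, analysis$score_min, analysis$z_min,
                           analysis$depth_min))
  write_tsv(data.frame(transcript_id = rownames(pm), pm, check.names = FALSE),
            p("pause_matrix.tsv"))
  cl <- stage("cluster", {
    k <- min(k_clusters, nrow(pm))
    if (nrow(pm) >= 2 && k >= 2)
      suppressWarnings(cluster_pause_dynamics(pm, k = k, seed = analysis$seed))
    else setNames(rep(1L, nrow(pm)), rownames(pm))
  })
  write_tsv(data.frame(transcript_id = names(cl), cluster = as.integer(cl)),
            p("clusters.tsv"))
  outputs <- c(outputs, p(c("pause_matrix.tsv", "clusters.tsv")))

  # --- counts, DE, TE, TI, protein ---
  stage("metrics", {
    rna <- simulate_rna_counts(transcripts, truth, sim, assay = "rna")
    rpf <- simulate_rna_counts(transcripts, truth, sim, assay = "rpf")
    write_counts(rna, p("counts_rna.tsv"))
    write_counts(rpf, p("counts_rpf.tsv"))
    ga <- grep("^A", colnames(rna), value = TRUE)
    gb <- grep("^B", colnames(rna), value = TRUE)
    write_tsv(differential_expression(rna, ga, gb, assay = "rna",
                                      lfc_min = analysis$de_lfc_min,
                                      p_max = analysis$de_p_max),
              p("de_rna.tsv"))
    write_tsv(differential_expression(rpf, ga, gb, assay = "rpf",
                                      lfc_min = analysis$de_lfc_min,
                                      p_max = analysis$de_p_max,
                                      count_floor = analysis$rpf_count_floor),
              p("de_rpf.tsv"))
    cds_len <- vapply(transcripts, cds_length, 0L)
    te <- translation_efficiency(rpf, rna, cds_len)
    dte <- delta_te(rowMeans(te[, ga, drop = FALSE]),
                    rowMeans(te[, gb, drop = FALSE]),
                    z_threshold = analysis$te_z_threshold)
    write_tsv(dte, p("te.tsv"))
    body_cov <- build_coverage(libs[[1]], transcripts, mode = "body")
    ti <- translation_intensity_table(body_cov, transcripts,
                                      region = analysis$coverage_region)
    write_tsv(ti, p("ti.tsv"))
    ti_v <- setNames(ti$ti, ti$transcript_id)
    cmp_ti <- compare_groups(ti_v, truth$transcript_id[truth$paused],
                             truth$transcript_id[!truth$paused])
    prot <- simulate_protein_table(truth, sim)
    write_tsv(prot, p("protein.tsv"))
    prot_v <- setNames(prot$abundance, prot$gene_id)
    cmp_prot <- compare_groups(prot_v, truth$gene_id[truth$paused],
                               truth$gene_id[!truth$paused])
    write_tsv(data.frame(
      comparison = c("ti_paused_vs_nonpaused", "protein_paused_vs_nonpaused"),
      median_paused = c(cmp_ti$median_a, cmp_prot$median_a),
      median_nonpaused = c(cmp_ti$median_b, cmp_prot$median_b),
      p_value = c(cmp_ti$p_value, cmp_prot$p_value)),
      p("group_comparisons.tsv"))
  })
  outputs <- c(outputs, p(c("counts_rna.tsv", "counts_rpf.tsv", "de_rna.tsv",
                            "de_rpf.tsv", "te.tsv", "ti.tsv", "protein.tsv",
                            "group_comparisons.tsv")))

  # --- sequence features around called pauses (first time point) ---
  stage("features", {
    called1 <- call_pauses(sites_by_tp[[1]], analysis$score_min,
                           analysis$z_min, analysis$depth_min)
    anchors <- do.call(rbind, lapply(split(called1, called1$transcript_id),
                                     function(d) d[which.max(d$score),
                                                   c("transcript_id", "position")]))
    if (is.null(anchors) || !nrow(anchors)) {
      anchors <- truth[truth$paused, c("transcript_id", "pause_pos")]
      names(anchors)[2] <- "position"
    }
    logo <- context_logo(transcripts, anchors)
    write_tsv(data.frame(base = rownames(logo), unclass(logo),
                         check.names = FALSE), p("logo.tsv"))
    write_tsv(as.data.frame(gc_absolute(transcripts, anchors, flank = 300L)),
              p("gc_absolute.tsv"))
    in_cds <- vapply(seq_len(nrow(anchors)), function(i) {
      tx <- transcripts[[anchors$transcript_id[i]]]
      anchors$position[i] > tx$cds_start && anchors$position[i] < tx$cds_end
    }, TRUE)
    write_tsv(as.data.frame(gc_scaled(transcripts, anchors[in_cds, ])),
              p("gc_scaled.tsv"))
    ppm <- read_pwm(system.file("extdata", "cgc_motif.ppm",
                                package = "ribopause"))
    hits <- pwm_scan_all(ppm, transcripts)
    write_tsv(data.frame(hits), p("motif_hits.tsv"))
    dg <- tryCatch(ensemble_free_energy(sim$motif), error = function(e) NA_real_)
    write_tsv(data.frame(sequence = sim$motif, ensemble_dG_kcal_mol = dg),
              p("energy.tsv"))
  })
  outputs <- c(outputs, p(c("logo.tsv", "gc_absolute.tsv", "gc_scaled.tsv",
                            "motif_hits.tsv", "energy.tsv")))

  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = sim$seed,
    package_version = as.character(utils::packageVersion("ribopause")),
    outputs = basename(outputs),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
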