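test_that("context logo columns are probabilities with correct planted signals", {
  # all sequences C at -13 -> that column is (0,1,0,0)
  txs <- lapply(1:5, function(i) {
    set.seed(i)
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    substr(s, 61 - 13, 61 - 13) <- "C"   # anchor at 0-based 60
    transcript_model(paste0("t", i), s, 30L, 90L)
  })
  names(txs) <- paste0("t", 1:5)
  anchors <- data.frame(transcript_id = names(txs), position = 60L)
  logo <- context_logo(txs, anchors, window = c(-20L, 5L))
  expect_equal(colSums(logo), setNames(rep(1, 26), -20:5))
  expect_equal(unname(logo[, "-13"]), c(0, 1, 0, 0))
  # incomplete windows are dropped and tallied
  a2 <- rbind(anchors, data.frame(transcript_id = "t1", position = 2L))
  logo2 <- context_logo(txs, a2, window = c(-20L, 5L))
  expect_identical(attr(logo2, "dropped"), 1L)
  expect_identical(attr(logo2, "n_sequences"), 5L)
})

test_that("uniform sequences give flat logos within multinomial error", {
  set.seed(8)
  txs <- lapply(1:40, function(i)
    transcript_model(paste0("u", i),
                     paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
                     30L, 120L))
  names(txs) <- paste0("u", 1:40)
  anchors <- do.call(rbind, lapply(names(txs), function(id)
    data.frame(transcript_id = id, position = 40L + 3L * (0:12))))
  logo <- context_logo(txs, anchors, window = c(-5L, 5L))  # 520 anchors
  expect_true(all(abs(logo - 0.25) < 0.08))
})

test_that("the planted C-at--13 frequency is recovered from simulated pause sites", {
  w <- small_world(n = 300, seed = 23, c13_prob = 0.6)
  anch <- w$truth[w$truth$paused, c("transcript_id", "pause_pos")]
  names(anch)[2] <- "position"
  logo <- context_logo(w$transcripts, anch, window = c(-20L, 5L))
  expect_lt(abs(logo["C", "-13"] - 0.60), 0.05)
  # unplanted neighboring positions stay near background C (~gc/2 + planted-group offset)
  bgC <- mean(logo["C", c("-20", "-19", "-18", "-5", "-4")])
  expect_lt(bgC, 0.40)
})

test_that("GC metaplots handle pure-composition and planted-offset cases", {
  gc_tx <- transcript_model("gc", paste0("ATG", strrep("GC", 60), "TAA"), 0L, 126L)
  at_tx <- transcript_model("at", paste0("ATG", strrep(c("ATATAT"), 20), "TAA"), 0L, 126L)
  a1 <- data.frame(transcript_id = "gc", position = 60L)
  g1 <- gc_absolute(list(gc = gc_tx), a1, flank = 30L)
  expect_true(all(g1$gc[g1$rel_pos > 3 & g1$rel_pos < 50] == 1))
  a2 <- data.frame(transcript_id = "at", position = 60L)
  g2 <- gc_absolute(list(at = at_tx), a2, flank = 30L)
  expect_true(all(g2$gc[abs(g2$rel_pos) <= 20] == 0))
})

test_that("paused-vs-random GC offset is recovered within sampling error", {
  # motif planting off: the inserted GC-rich motif would otherwise add its
  # own GC on top of the group offset being measured
  w <- small_world(n = 600, seed = 29, gc_offset = 0.08, motif_prob = 0)
  paused <- w$truth[w$truth$paused, ]
  nonpaused <- w$truth[!w$truth$paused, ]
  anch_p <- data.frame(transcript_id = paused$transcript_id,
                       position = paused$pause_pos)
  # comparison anchors: random CDS sites on non-paused transcripts drawn by
  # the same positional rule as planted pauses
  set.seed(1)
  anch_r <- data.frame(
    transcript_id = nonpaused$transcript_id,
    position = vapply(nonpaused$transcript_id, function(id) {
      tx <- w$transcripts[[id]]
      ncod <- (tx$cds_end - tx$cds_start) %/% 3
      tx$cds_start + 3L * sample(5:(ncod - 13), 1)
    }, 0L))
  gp <- gc_absolute(w$transcripts, anch_p, flank = 100L)
  gr <- gc_absolute(w$transcripts, anch_r, flank = 100L)
  offset <- mean(gp$gc) - mean(gr$gc)
  expect_lt(abs(offset - 0.08), 0.02)
})

test_that("scaled GC bins follow a planted gradient and reject edge anchors", {
  ramp <- paste(c("ATG",
                  vapply(0:59, function(i) {
                    gc <- 0.3 + 0.4 * i / 59
                    if ((i * 7) %% 10 / 10 < gc) "GCG" else "ATA"
                  }, ""), "TAA"), collapse = "")
  tx <- transcript_model("ramp", ramp, 0L, nchar(ramp))
  # flat transcript -> flat profile
  flat <- transcript_model("flat", paste0("ATG", strrep("GCAT", 45), "TAA"), 0L, 186L)
  af <- data.frame(transcript_id = "flat", position = 90L)
  gf <- gc_scaled(list(flat = flat), af)
  expect_identical(nrow(gf), 100L)
  # bins narrower than the GCAT period are 0/1; their means stay at 0.5
  expect_equal(mean(gf$gc[gf$segment == "upstream"], na.rm = TRUE), 0.5,
               tolerance = 0.1)
  expect_equal(mean(gf$gc[gf$segment == "downstream"], na.rm = TRUE), 0.5,
               tolerance = 0.1)
  # monotone GC ramp -> upstream bins below downstream bins on average
  ar <- data.frame(transcript_id = "ramp", position = 3L * 30L)
  gr <- gc_scaled(list(ramp = tx), ar)
  expect_lt(mean(gr$gc[gr$segment == "upstream"], na.rm = TRUE),
            mean(gr$gc[gr$segment == "downstream"], na.rm = TRUE))
  expect_error(gc_scaled(list(ramp = tx), data.frame(transcript_id = "ramp", position = 0L)),
               "empty upstream segment")
})

test_that("peptide context maps any codon nucleotide to its codon and sums charges", {
  # CDS: ATG AAA AAA GAT GAA TAA -> M K K D E *
  tx <- transcript_model("p", paste0(strrep("C", 6), "ATGAAAAAAGATGAATAA", strrep("C", 6)),
                         6L, 24L)
  # anchor on the 2nd nt of the first K codon: codon index 1
  a_k <- data.frame(transcript_id = "p", position = 6L + 3L + 1L)
  pc_k <- peptide_context(list(p = tx), a_k, aa_window = 1L)
  expect_equal(pc_k$net_charge, 2)           # M K K window: K+K = +2
  expect_equal(unname(pc_k$freq["K", "0"]), 1)
  a_d <- data.frame(transcript_id = "p", position = 6L + 9L + 2L)  # D codon
  pc_d <- peptide_context(list(p = tx), a_d, aa_window = 1L)
  expect_equal(pc_d$net_charge, -2 + 1)      # K D E window: +1 -1 -1
  pc_d2 <- peptide_context(list(p = tx), a_d, aa_window = 0L)
  expect_equal(pc_d2$net_charge, -1)
})

test_that("PWM scanning scores the consensus maximally and finds planted motifs", {
  ppm <- read_pwm(system.file("extdata", "cgc_motif.ppm", package = "ribopause"))
  expect_equal(colSums(unclass(ppm)), setNames(rep(1, 16), 1:16))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  hits_cons <- pwm_scan(ppm, "CGCCGCCGCCGCCGCC", background = bg, p_threshold = 1)
  max_score <- sum(apply(log2((unclass(ppm) + 1e-3) / 0.25), 2, max))
  expect_equal(max(hits_cons$score), max_score)
  set.seed(4)
  rand <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  planted <- paste0(substr(rand, 1, 200), "CGCCGCCGCCGCCGCC", substr(rand, 201, 400))
  hits <- pwm_scan(ppm, planted, background = bg)
  expect_true(200 %in% hits$start)   # 0-based planted offset
  expect_identical(hits$start[which.max(hits$score)], 200L)
})

test_that("PWM tail p-values match exhaustive enumeration for a 6-column motif", {
  set.seed(12)
  p6 <- matrix(runif(24, 0.05, 1), 4, 6, dimnames = list(c("A", "C", "G", "T"), 1:6))
  p6 <- sweep(p6, 2, colSums(p6), "/")
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  sm <- log2(sweep(p6 + 1e-3, 1, bg, "/"))
  dist <- ribopause:::pwm_score_distribution(sm, bg)
  tail_dp <- function(t) sum(dist$prob[dist$score >= t - 1e-9])
  grid <- as.matrix(expand.grid(rep(list(1:4), 6)))
  scores <- apply(grid, 1, function(r) sum(sm[cbind(r, 1:6)]))
  probs <- apply(grid, 1, function(r) prod(bg[r]))
  for (t in unname(quantile(scores, c(0.25, 0.5, 0.9, 0.99, 0.999)))) {
    expect_equal(tail_dp(t), sum(probs[scores >= t - 1e-9]), tolerance = 1e-12)
  }
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
})

test_that("motif-pausing association couples motif presence to dwell", {
  # planted: motif transcripts get high max scores, others low
  set.seed(6)
  scores <- setNames(c(rlnorm(50, log(200), 0.4), rlnorm(50, log(20), 0.4)),
                     sprintf("t%03d", 1:100))
  res <- motif_pause_association(scores, sprintf("t%03d", 1:50))
  expect_lt(res$p_value, 0.001)
  expect_gt(res$median_a, res$median_b)
  expect_error(motif_pause_association(scores, character(0)), "non-empty")
  # null: label permutation gives non-extreme p most of the time
  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    motif_pause_association(setNames(rlnorm(60, 3, 0.5), paste0("x", 1:60)),
                            paste0("x", sample(60, 30)))$p_value
  }, 0)
  expect_gt(mean(ps), 0.2)
})

test_that("ensemble free energy is deterministic and strand-asymmetric", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  dg <- ensemble_free_energy("CGCCGCCGCCGCCGCC")
  expect_equal(dg, ensemble_free_energy("cgccgccgccgccgcc"))
  expect_equal(ensemble_free_energy("AAAAAAAAAA"), 0)
  # reverse complement gives its own value; both are finite and recorded
  rc <- ensemble_free_energy("GGCGGCGGCGGCGGCG")
  expect_true(is.finite(rc))
})

test_that("written PWM files round-trip", {
  set.seed(9)
  segs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""), "")
  ppm <- pwm_from_sequences(segs, pseudocount = 0.5)
  path <- tempfile(fileext = ".ppm")
  write_pwm(ppm, path)
  back <- read_pwm(path)
  expect_equal(unclass(back), unclass(ppm), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(attr(back, "n_sequences"), 20L)
})
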