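test_that("median-of-ratios size factors match closed forms and DESeq2", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- normalize_counts(m)$size_factors
  expect_equal(unname(sf), c(1, 1))
  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  rownames(m2) <- paste0("g", 1:3)
  sf2 <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  one <- matrix(c(8L, 2L), 1, 2, dimnames = list("g1", c("a", "b")))
  sf3 <- normalize_counts(one)$size_factors
  expect_equal(unname(sf3[1] / sf3[2]), 4)
  expect_error(normalize_counts(matrix(c(0L, 1L, 1L, 0L), 2, 2,
                                       dimnames = list(c("g1", "g2"), c("a", "b")))),
               "pseudocount")
  skip_if_not_installed("DESeq2")
  set.seed(1)
  big <- matrix(rnbinom(600, mu = 100, size = 10), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  expect_equal(unname(normalize_counts(big)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(big)), tolerance = 1e-8)
})

test_that("differential expression applies the dual filter and the RPF floor", {
  set.seed(3)
  m <- matrix(rnbinom(100 * 6, mu = 300, size = 20), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), c(paste0("A", 1:3), paste0("B", 1:3))))
  de <- differential_expression(m, paste0("A", 1:3), paste0("B", 1:3))
  same <- differential_expression(cbind(m[, 1:3], setNames(as.data.frame(m[, 1:3]),
                                                           paste0("B", 1:3)) |> as.matrix()),
                                  paste0("A", 1:3), paste0("B", 1:3))
  expect_true(all(same$log2fc == 0))
  expect_false(any(same$significant))
  # a strong fold change on a gene below the RPF floor is never significant
  low <- m
  low["g001", ] <- c(0L, 1L, 0L, 8L, 6L, 9L)   # mean 4 < 5
  de_rpf <- differential_expression(low, paste0("A", 1:3), paste0("B", 1:3),
                                    assay = "rpf")
  expect_false(de_rpf$significant[de_rpf$gene_id == "g001"])
  expect_error(differential_expression(m, character(0), paste0("B", 1:3)),
               "at least one column")
})

test_that("planted fold changes are detected with high power", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 200
    mu <- rep(500, n)
    fc_genes <- 1:20
    muB <- mu; muB[fc_genes] <- muB[fc_genes] * 4
    m <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3),
               matrix(rnbinom(n * 3, mu = muB, size = 20), n, 3))
    dimnames(m) <- list(sprintf("g%03d", 1:n), c(paste0("A", 1:3), paste0("B", 1:3)))
    de <- differential_expression(m, paste0("A", 1:3), paste0("B", 1:3))
    mean(de$significant[fc_genes])
  }, 0)
  expect_gte(mean(hits), 0.90)
})

test_that("differential expression is null-calibrated", {
  set.seed(77)
  fracs <- vapply(1:10, function(s) {
    m <- matrix(rnbinom(300 * 6, mu = 200, size = 10), 300, 6,
                dimnames = list(sprintf("g%03d", 1:300), c(paste0("A", 1:3), paste0("B", 1:3))))
    de <- differential_expression(m, paste0("A", 1:3), paste0("B", 1:3))
    mean(de$significant)
  }, 0)
  mc_se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 2 * mc_se + 1e-12)
})

test_that("translation efficiency behaves as a density ratio", {
  n <- 1000
  len <- setNames(rep(300L, n), sprintf("g%04d", 1:n))
  set.seed(5)
  rna <- matrix(rpois(n, 200), n, 1, dimnames = list(names(len), "s1"))
  rpf <- rna  # equal shares -> TE exactly 1
  te <- translation_efficiency(rpf, rna, len, floor = 0)
  expect_equal(unname(te[, 1]), rep(1, n))
  # doubling one gene's RPF count doubles its TE up to the library-size effect
  rpf2 <- rpf; rpf2[1, 1] <- rpf2[1, 1] * 2L
  te2 <- translation_efficiency(rpf2, rna, len, floor = 0)
  expect_lt(abs(te2[1, 1] / (2 * te[1, 1]) - 1), 0.01)
  # zero RNA -> masked
  rna3 <- rna; rna3[2, 1] <- 0L
  te3 <- translation_efficiency(rpf, rna3, len, floor = 0)
  expect_true(is.na(te3[2, 1]))
})

test_that("delta-TE z-scoring is robust, strict at the boundary, and has normal tails", {
  te_a <- setNames(rep(1, 5), paste0("g", 1:5))
  te_b <- setNames(c(1, 2, 4, 0.5, 0.25), paste0("g", 1:5))
  d <- delta_te(te_a, te_b)
  expect_equal(d$z[d$gene_id == "g1"], 0)  # at the cohort median
  # exact threshold is not significant (strict >)
  ld <- c(rnorm(100), 1.5)
  z_ref <- (ld - median(ld)) / mad(ld)
  fake_a <- setNames(rep(1, 101), paste0("g", 1:101))
  fake_b <- setNames(2^ld, paste0("g", 1:101))
  d2 <- delta_te(fake_a, fake_b)
  expect_equal(d2$z, unname(z_ref))
  expect_false(any(d2$significant[abs(d2$z) <= 1.5]))
  # symmetric normal null: ~13.4% of genes beyond |z| > 1.5
  set.seed(11)
  ld3 <- rnorm(2000)
  d3 <- delta_te(setNames(rep(1, 2000), paste0("g", 1:2000)),
                 setNames(2^ld3, paste0("g", 1:2000)))
  expect_lt(abs(mean(d3$significant) - 2 * pnorm(-1.5)), 0.03)
})

test_that("translation intensity matches hand computations and its invariants", {
  tx <- toy_transcript()  # CDS [20, 110), 90 nt
  depth <- numeric(130)
  depth[21:110] <- 10
  ti <- translation_intensity(depth, tx)
  expect_equal(ti$median_depth, 10)
  expect_equal(ti$coverage, 1)
  expect_equal(ti$ti, 10)
  # region of length 8, 4 covered bases of depth 5 -> median 5, coverage 0.5, ti 2.5
  d8 <- c(5, 5, 5, 5, 0, 0, 0, 0)
  ti8 <- translation_intensity(d8, region = "transcript")
  expect_equal(c(ti8$median_depth, ti8$coverage, ti8$ti), c(5, 0.5, 2.5))
  d8b <- c(2, 4, 6, 8, 0, 0, 0, 0)
  ti8b <- translation_intensity(d8b, region = "transcript")
  expect_equal(c(ti8b$median_depth, ti8b$ti), c(5, 2.5))
  # no coverage -> ti 0
  ti0 <- translation_intensity(numeric(8), region = "transcript")
  expect_identical(ti0$ti, 0)
  expect_true(is.na(ti0$median_depth))
  expect_error(translation_intensity(numeric(0), region = "transcript"), "empty region")
})

test_that("TI matches the sort-based oracle on random profiles of both parities", {
  set.seed(21)
  for (i in 1:300) {
    L <- sample(5:60, 1)
    depth <- rpois(L, sample(c(0.5, 2, 8), 1))
    got <- translation_intensity(depth, region = "transcript")
    want <- ti_bruteforce(depth)
    expect_equal(got$ti, want$ti)
    expect_equal(got$coverage, want$coverage)
    expect_true(got$coverage >= 0 && got$coverage <= 1)
    if (got$n_covered > 0) {
      expect_lte(got$ti, got$median_depth)
      expect_lte(got$ti, max(depth))
      # permutation invariance of the covered multiset
      got_p <- translation_intensity(sample(depth), region = "transcript")
      expect_equal(got_p$ti, got$ti)
    }
  }
})

test_that("rank-sum comparison matches exact enumeration and rejects empty groups", {
  v <- setNames(c(1, 2, 3, 4, 5, 6), paste0("g", 1:6))
  r <- compare_groups(v, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(r$p_value, 0.1)   # 2/20 arrangements as extreme, two-sided
  same <- setNames(c(1, 2, 3, 1, 2, 3), paste0("g", 1:6))
  r2 <- compare_groups(same, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(r2$p_value, 1)
  expect_error(compare_groups(v, character(0), paste0("g", 4:6)), "non-empty")
})
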