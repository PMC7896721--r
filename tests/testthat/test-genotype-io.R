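test_that("bed round trip is lossless, including missing calls and 1x1", {
  set.seed(1)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  dos[1, ] <- 1L  # keep every SNP informative for later reuse
  gm <- genotypes(dos, toy_snps(12), toy_inds(5, sex = "male"))
  pre <- file.path(withr::local_tempdir(), "p")
  write_plink(gm, pre)
  back <- read_plink(pre)
  expect_identical(back$dosage, gm$dosage)
  expect_equal(back$snps$bp, gm$snps$bp)
  expect_equal(back$individuals$population, gm$individuals$population)
  expect_equal(back$individuals$sex, gm$individuals$sex)

  g1 <- genotypes(matrix(2L, 1, 1), toy_snps(1), toy_inds(1))
  pre1 <- file.path(withr::local_tempdir(), "one")
  write_plink(g1, pre1)
  expect_identical(read_plink(pre1)$dosage, g1$dosage)
})

test_that("bed decoder matches hand-computed 2-bit codes", {
  # 3 individuals x 2 SNPs. Pairs are packed LSB-first:
  # SNP1: ind1=00 (hom A1, dosage 2), ind2=10 (het, 1), ind3=11 (hom A2, 0)
  #   -> byte 00 11 10 00 (MSB..LSB) = 0x38
  # SNP2: ind1=01 (missing), ind2=00 (2), ind3=10 (1)
  #   -> byte 00 10 00 01 = 0x21
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x21)),
           file.path(dir, "hand.bed"))
  writeLines(c("1\tsA\t0\t100\tA\tB", "1\tsB\t0\t200\tA\tB"),
             file.path(dir, "hand.bim"))
  writeLines(c("F1 i1 0 0 1 -9", "F1 i2 0 0 2 -9", "F1 i3 0 0 0 -9"),
             file.path(dir, "hand.fam"))
  gm <- read_plink(file.path(dir, "hand"))
  expect_identical(gm$dosage[, 1], c(i1 = 2L, i2 = 1L, i3 = 0L))
  expect_identical(gm$dosage[, 2], c(i1 = NA_integer_, i2 = 2L, i3 = 1L))
  expect_equal(gm$individuals$sex, c("male", "female", "unknown"))
})

test_that("bed reader rejects corrupt input", {
  dir <- withr::local_tempdir()
  expect_error(read_plink(file.path(dir, "nope")), class = "introsel_error")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x38)), file.path(dir, "bad.bed"))
  writeLines("1\ts\t0\t100\tA\tB", file.path(dir, "bad.bim"))
  writeLines("F i1 0 0 1 -9", file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad")), "magic",
               class = "introsel_error")
  # size inconsistent with bim/fam
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x38)),
           file.path(dir, "bad2.bed"))
  writeLines("1\ts\t0\t100\tA\tB", file.path(dir, "bad2.bim"))
  writeLines("F i1 0 0 1 -9", file.path(dir, "bad2.fam"))
  expect_error(read_plink(file.path(dir, "bad2")), "inconsistent",
               class = "introsel_error")
})

test_that("ped/map round trip preserves dosages up to allele relabeling", {
  set.seed(2)
  dos <- matrix(sample(c(0:2, NA), 80, replace = TRUE,
                       prob = c(.5, .3, .15, .05)), 8, 10)
  gm <- genotypes(dos, toy_snps(10), toy_inds(8))
  pre <- file.path(withr::local_tempdir(), "t")
  write_plink(gm, pre, format = "ped")
  back <- read_plink(pre)
  # the text reader re-derives A1 as the minor allele, so dosages agree
  # up to a 2 - x flip at SNPs where the written A1 was the major allele
  for (k in seq_len(10)) {
    same <- identical(back$dosage[, k], gm$dosage[, k])
    flip <- identical(back$dosage[, k], 2L - gm$dosage[, k])
    expect_true(same || flip)
  }
})

test_that("QC applies the documented filter sequence", {
  set.seed(3)
  # 12 clean individuals over enough SNPs that no second pair is IBS-close
  n <- 12
  m <- 24
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  dos[, 3] <- c(rep(0L, n - 1), 1L)         # MAF 1/24: above the 0.01 cut
  dos[, 4] <- 0L                            # monomorphic -> MAF 0
  dos[, 5] <- c(rep(NA_integer_, 3), dos[4:n, 5])  # call rate 9/12 = 0.75
  dos <- rbind(dos, dos[1, ])               # duplicate of i001
  snps <- toy_snps(m)
  snps$chrom[m] <- "X"                      # sex chromosome
  inds <- toy_inds(n + 1)
  gm <- genotypes(dos, snps, inds)
  out <- apply_qc(gm, qc_params())
  rep_ <- out$report
  expect_equal(rep_$removed_individuals[rep_$step == "ibs_duplicates"], 1L)
  # lexicographically smallest id of the duplicate pair kept
  expect_true("i001" %in% out$genotypes$individuals$id)
  expect_false("i013" %in% out$genotypes$individuals$id)
  expect_equal(rep_$removed_snps[rep_$step == "maf"], 1L)        # column 4
  expect_equal(rep_$removed_snps[rep_$step == "call_rate"], 1L)  # column 5
  expect_equal(rep_$removed_snps[rep_$step == "autosomes"], 1L)  # column m
  expect_false("s0004" %in% out$genotypes$snps$id)
  expect_false("s0005" %in% out$genotypes$snps$id)
  expect_false(sprintf("s%04d", m) %in% out$genotypes$snps$id)

  # idempotence: a second pass removes nothing
  out2 <- apply_qc(out$genotypes, qc_params())
  expect_identical(out2$genotypes$dosage, out$genotypes$dosage)
  expect_true(all(out2$report$removed_snps == 0))
  expect_true(all(out2$report$removed_individuals == 0))
})

test_that("all-clean input passes QC unchanged with zero counts", {
  set.seed(4)
  dos <- matrix(rbinom(200, 2, 0.5), 20, 10)
  gm <- toy_gm(dos)
  out <- apply_qc(gm, qc_params())
  expect_identical(out$genotypes$dosage, gm$dosage)
  expect_true(all(out$report$removed_snps == 0))
  expect_true(all(out$report$removed_individuals == 0))
})

test_that("LD pruning drops duplicated SNPs and keeps independent ones", {
  set.seed(5)
  base <- rbinom(60, 2, 0.5)
  dos <- cbind(base, base, matrix(rbinom(60 * 4, 2, 0.5), 60, 4))
  gm <- toy_gm(dos)
  kept <- ld_prune(gm)
  expect_true(1 %in% kept)     # earlier duplicate kept
  expect_false(2 %in% kept)    # later duplicate removed
  set.seed(6)
  indep <- toy_gm(matrix(rbinom(100 * 6, 2, 0.5), 100, 6))
  expect_identical(ld_prune(indep), 1:6)
  expect_error(ld_prune(gm, window_snps = 5, step = 10),
               class = "introsel_error")
})

test_that("pruned set matches a brute-force greedy pass and its invariant", {
  set.seed(7)
  n <- 80
  z <- rbinom(n, 2, 0.5)
  dos <- cbind(z,
               ifelse(runif(n) < 0.9, z, rbinom(n, 2, 0.5)),
               rbinom(n, 2, 0.5),
               ifelse(runif(n) < 0.95, z, rbinom(n, 2, 0.5)),
               rbinom(n, 2, 0.5))
  gm <- toy_gm(dos)
  kept <- ld_prune(gm, window_snps = 5, step = 2, r2_max = 0.5)
  # brute force: walk windows, remove the later member of any offending pair
  keep <- rep(TRUE, 5)
  for (s in seq(1, 4, by = 2)) {
    win <- s:min(s + 4, 5)
    for (a in win) for (b in win) {
      if (a < b && keep[a] && keep[b]) {
        r2 <- cor(dos[, a], dos[, b])^2
        if (!is.na(r2) && r2 > 0.5) keep[b] <- FALSE
      }
    }
  }
  expect_identical(kept, which(keep))
  # invariant: no surviving within-window pair exceeds the cutoff
  for (a in kept) for (b in kept) {
    if (a < b && b - a < 5) {
      expect_lte(cor(dos[, a], dos[, b])^2, 0.5 + 1e-12)
    }
  }
})
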