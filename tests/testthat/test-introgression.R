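quartet_gm <- function(freqs, n_per_pop = 30, seed = 81) {
  # freqs: list with p1, p2, p3, po vectors of allele1 frequencies
  set.seed(seed)
  m <- length(freqs$p1)
  dos <- do.call(rbind, lapply(freqs[c("p1", "p2", "p3", "po")],
                               function(p) {
    matrix(rbinom(n_per_pop * m, 2, rep(p, each = n_per_pop)), n_per_pop,
           m)
  }))
  genotypes(dos, toy_snps(m, spacing = 5e4),
            toy_inds(4 * n_per_pop,
                     population = rep(c("P1", "P2", "P3", "O"),
                                      each = n_per_pop)))
}

pop_map <- c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O")

test_that("site patterns are outgroup-polarized sample frequencies", {
  dos <- rbind(c(0L, 2L), c(0L, 2L),   # P1
               c(2L, 2L), c(2L, 2L),   # P2
               c(2L, 0L), c(2L, 2L),   # P3
               c(0L, 2L), c(0L, 2L))   # O
  gm <- genotypes(dos, toy_snps(2),
                  toy_inds(8, population = rep(c("P1", "P2", "P3", "O"),
                                               each = 2)))
  sp <- site_patterns(gm, pop_map)
  # SNP1: outgroup fixed for allele2 -> derived = allele1:
  # p1 = 0, p2 = 1, p3 = 1, po = 0 -> ABBA = 1, BABA = 0
  expect_equal(sp$p1[1], 0)
  expect_equal(sp$p2[1], 1)
  expect_equal(sp$p3[1], 1)
  expect_equal(sp$po[1], 0)
  # SNP2: outgroup major allele is allele1 -> polarization flips, so the
  # derived frequency is 1 - allele1 frequency
  expect_equal(sp$p3[2], 0.5)
  expect_equal(sp$p2[2], 0)
  expect_equal(sp$po[2], 0)
  # pattern arithmetic at the classic ABBA site
  expect_equal((1 - sp$p1[1]) * sp$p2[1] * sp$p3[1] * (1 - sp$po[1]), 1)
  expect_equal(sp$p1[1] * (1 - sp$p2[1]) * sp$p3[1] * (1 - sp$po[1]), 0)
})

test_that("D equals its ratio-of-sums and flips sign when P1/P2 swap", {
  set.seed(82)
  m <- 400
  freqs <- list(p1 = runif(m, .1, .9), p2 = runif(m, .1, .9),
                p3 = runif(m, .1, .9), po = runif(m, 0, .3))
  gm <- quartet_gm(freqs)
  sp <- site_patterns(gm, pop_map)
  d <- d_statistic(sp, block_size_bp = 1e6)
  num <- (1 - sp$p1) * sp$p2 * sp$p3 * (1 - sp$po) -
    sp$p1 * (1 - sp$p2) * sp$p3 * (1 - sp$po)
  den <- (1 - sp$p1) * sp$p2 * sp$p3 * (1 - sp$po) +
    sp$p1 * (1 - sp$p2) * sp$p3 * (1 - sp$po)
  expect_equal(d$d, sum(num) / sum(den), tolerance = 1e-12)
  swapped <- pop_map[c(P1 = "P2", P2 = "P1", P3 = "P3", O = "O")]
  names(swapped) <- c("P1", "P2", "P3", "O")
  d2 <- d_statistic(site_patterns(gm, swapped), block_size_bp = 1e6)
  expect_equal(d2$d, -d$d, tolerance = 1e-12)
})

test_that("f3 reproduces exact arithmetic with the finite-sample term", {
  # every SNP: pA = 0.5 (all 60 alleles het), pB = 0, pC = 1
  m <- 50
  dos <- rbind(matrix(1L, 30, m),    # A
               matrix(0L, 5, m),     # B
               matrix(2L, 5, m))     # C
  gm <- genotypes(dos, toy_snps(m),
                  toy_inds(40, population = rep(c("A", "B", "C"),
                                                c(30, 5, 5))))
  f3 <- f3_test(gm, "A", "B", "C", block_size_bp = 1e6)
  # (0.5 - 0)(0.5 - 1) - 0.25/(60 - 1); the correction vanishes as n grows
  expect_equal(f3$f3, -0.25 - 0.25 / 59, tolerance = 1e-12)
  expect_error(f3_test(subset_genotypes(gm, individuals = c(1, 31:40)),
                       "A", "B", "C"),
               class = "introsel_error")
})

test_that("f3 is unbiased for an unadmixed target and negative for a mix", {
  m <- 800
  n <- 40
  # unbiasedness gate: when A is another sample of B's source population,
  # the finite-sample correction centres f3 on zero (|z| ~ N(0,1); the
  # mean over seeds must sit well inside two standard errors)
  zs <- vapply(1:3, function(s) {
    set.seed(820 + s)
    pS <- runif(m, 0.1, 0.9)
    pC <- runif(m, 0.1, 0.9)
    dos <- rbind(matrix(rbinom(n * m, 2, rep(pS, each = n)), n, m),
                 matrix(rbinom(n * m, 2, rep(pS, each = n)), n, m),
                 matrix(rbinom(n * m, 2, rep(pC, each = n)), n, m))
    gm <- genotypes(dos, toy_snps(m, spacing = 5e4),
                    toy_inds(3 * n, population = rep(c("A", "B", "C"),
                                                     each = n)))
    f3_test(gm, "A", "B", "C", block_size_bp = 2e6)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2 / sqrt(3))
  # fresh 50/50 mix: one allele from each source population
  set.seed(83)
  pS <- runif(m, 0.1, 0.9)
  pC <- runif(m, 0.1, 0.9)
  dos <- rbind(matrix(rbinom(n * m, 1, rep(pS, each = n)) +
                        rbinom(n * m, 1, rep(pC, each = n)), n, m),
               matrix(rbinom(n * m, 2, rep(pS, each = n)), n, m),
               matrix(rbinom(n * m, 2, rep(pC, each = n)), n, m))
  gm2 <- genotypes(dos, toy_snps(m, spacing = 5e4),
                   toy_inds(3 * n, population = rep(c("A", "B", "C"),
                                                    each = n)))
  f32 <- f3_test(gm2, "A", "B", "C", block_size_bp = 2e6)
  expect_lt(f32$z, -2)
  expect_true(f32$significant)
})

test_that("window statistics match a hand-rolled 20-SNP computation", {
  set.seed(84)
  m <- 20
  freqs <- list(p1 = runif(m, .1, .9), p2 = runif(m, .1, .9),
                p3 = runif(m, .1, .9), po = runif(m, 0, .2))
  gm <- quartet_gm(freqs, n_per_pop = 25)
  sp <- site_patterns(gm, pop_map)
  ws <- window_scan(sp, window_snps = 10, step_snps = 2,
                    dxy_pairs = list(c("P2", "P3")),
                    pi_pops = c("P1", "P2"))
  starts <- seq(1, 11, by = 2)
  expect_equal(nrow(ws), length(starts))
  abba_f <- function(a, b, c, d) (1 - a) * b * c * (1 - d)
  baba_f <- function(a, b, c, d) a * (1 - b) * c * (1 - d)
  for (i in seq_along(starts)) {
    w <- starts[i]:(starts[i] + 9)
    num <- den <- numeric(10)
    for (j in seq_along(w)) {
      k <- w[j]
      p1 <- sp$p1[k]; p2 <- sp$p2[k]; p3 <- sp$p3[k]; po <- sp$po[k]
      num[j] <- abba_f(p1, p2, p3, po) - baba_f(p1, p2, p3, po)
      if (p2 >= p1) {
        pd <- max(p2, p3)
        den[j] <- abba_f(p1, pd, pd, po) - baba_f(p1, pd, pd, po)
      } else {
        pd <- max(p1, p3)
        den[j] <- -(abba_f(pd, p2, pd, po) - baba_f(pd, p2, pd, po))
      }
    }
    expect_equal(ws$f_dm[i], sum(num) / sum(den), tolerance = 1e-12)
    expect_equal(ws$start_bp[i], sp$bp[w[1]])
    expect_equal(ws$end_bp[i], sp$bp[w[10]])
    expect_equal(ws$dxy_P2_P3[i],
                 mean(sp$p2[w] * (1 - sp$p3[w]) +
                        sp$p3[w] * (1 - sp$p2[w])),
                 tolerance = 1e-12)
    n2 <- 2 * sp$n2[w]
    expect_equal(ws$pi_P2[i],
                 mean(2 * sp$p2[w] * (1 - sp$p2[w]) * n2 / (n2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("f_dM hits 1 at a pure ABBA window and stays within [-1, 1]", {
  sp <- tibble::tibble(id = sprintf("s%d", 1:10), chrom = "1",
                       bp = seq(1e5, 1e6, length.out = 10),
                       p1 = 0, p2 = 1, p3 = 1, po = 0,
                       n1 = 20, n2 = 20, n3 = 20, no = 20)
  ws <- window_scan(sp, 10, 2, dxy_pairs = list(c("P2", "P3")),
                    pi_pops = "P2")
  expect_equal(ws$f_dm, 1)
  expect_equal(ws$dxy_P2_P3, 0)
  # fixed-different pair has dxy = 1
  sp2 <- dplyr::mutate(sp, p3 = 0)
  ws2 <- window_scan(sp2, 10, 2, dxy_pairs = list(c("P2", "P3")),
                     pi_pops = "P2")
  expect_equal(ws2$dxy_P2_P3, 1)
  set.seed(85)
  m <- 300
  freqs <- list(p1 = runif(m), p2 = runif(m), p3 = runif(m),
                po = runif(m, 0, .4))
  ws3 <- window_scan(site_patterns(quartet_gm(freqs), pop_map))
  ok <- !is.na(ws3$f_dm)
  expect_true(all(ws3$f_dm[ok] >= -1 - 1e-9 & ws3$f_dm[ok] <= 1 + 1e-9))
})

test_that("pi and dxy are invariant to allele relabeling", {
  set.seed(86)
  m <- 60
  freqs <- list(p1 = runif(m, .2, .8), p2 = runif(m, .2, .8),
                p3 = runif(m, .2, .8), po = runif(m, .2, .8))
  gm <- quartet_gm(freqs)
  gmf <- genotypes(2L - gm$dosage, gm$snps, gm$individuals)
  w1 <- window_scan(site_patterns(gm, pop_map), pi_pops = c("P1", "P2"),
                    dxy_pairs = list(c("P1", "P2")))
  w2 <- window_scan(site_patterns(gmf, pop_map), pi_pops = c("P1", "P2"),
                    dxy_pairs = list(c("P1", "P2")))
  expect_equal(w1$pi_P1, w2$pi_P1, tolerance = 1e-12)
  expect_equal(w1$dxy_P1_P2, w2$dxy_P1_P2, tolerance = 1e-12)
})

test_that("window significance uses the normal-quantile threshold", {
  set.seed(87)
  n <- 300
  f <- rnorm(n, 0.1, 0.05)
  f[150] <- 0.1 + 5 * 0.05
  ws <- tibble::tibble(chrom = "1",
                       start_snp = seq_len(n), end_snp = seq_len(n) + 9,
                       start_bp = seq(1e5, by = 2e4, length.out = n),
                       end_bp = seq(1e5, by = 2e4, length.out = n) + 1.8e5,
                       f_dm = f)
  out <- significant_windows(ws, p_cut = 0.01)
  expect_true(out$windows$significant[150])
  expect_equal(out$threshold,
               mean(f) + qnorm(0.99) * sd(f), tolerance = 1e-12)
  expect_equal(round(qnorm(0.99), 4), 2.3263)
  expect_gte(nrow(out$regions), 1)
  # constant scans have no empirical tail
  flat <- dplyr::mutate(ws, f_dm = 0.2)
  expect_warning(out2 <- significant_windows(flat), "variance")
  expect_equal(sum(out2$windows$significant), 0)
})

test_that("haplotype tables tally distinct strings per population", {
  al <- rbind(c(1, 1, 0), c(1, 1, 0),      # ind1: two identical haps
              c(1, 1, 0), c(1, 1, 0))      # ind2: same
  snps <- toy_snps(3)
  inds <- toy_inds(2)
  pan <- haplotypes(al, snps, inds)
  hf <- haplotype_freqs(pan, 1:3)
  expect_equal(nrow(hf), 1)
  expect_equal(hf$total, 4)
  expect_true(hf$most_frequent)
  # 3 distinct haplotypes across two populations, counts conserved
  al2 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(0, 1, 0), c(0, 1, 0))
  inds2 <- toy_inds(3)
  inds2$population <- c("X", "X", "Y")
  pan2 <- haplotypes(al2, snps, inds2)
  hf2 <- haplotype_freqs(pan2, 1:3)
  expect_equal(nrow(hf2), 3)
  expect_equal(sum(hf2$X), 4)
  expect_equal(sum(hf2$Y), 2)
  expect_equal(hf2$total[hf2$haplotype == "010"], 3)
})
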