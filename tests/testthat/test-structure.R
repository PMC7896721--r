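test_that("IBS distances match hand arithmetic and bounds", {
  dos <- rbind(c(0L, 1L, 2L, 2L),
               c(0L, 1L, 2L, 2L),
               c(2L, 1L, 0L, 0L))
  gm <- toy_gm(dos)
  d <- ibs_matrix(gm)
  expect_equal(d["i001", "i002"], 0)           # identical individuals
  # i1 vs i3: diffs |0-2|,|1-1|,|2-0|,|2-0| -> IBS = mean(0,1,0,0) = 0.25
  expect_equal(d["i001", "i003"], 0.75)
  opp <- toy_gm(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L)))
  expect_equal(ibs_matrix(opp)[1, 2], 1)       # opposite homozygotes
  expect_equal(diag(d), c(i001 = 0, i002 = 0, i003 = 0))
})

test_that("Weir-Cockerham FST equals a brute-force variance-component oracle", {
  set.seed(61)
  n1 <- 15
  n2 <- 22
  m <- 100
  dos <- rbind(matrix(rbinom(n1 * m, 2, rep(runif(m, .1, .9), each = n1)),
                      n1, m),
               matrix(rbinom(n2 * m, 2, rep(runif(m, .1, .9), each = n2)),
                      n2, m))
  gm <- genotypes(dos, toy_snps(m),
                  toy_inds(n1 + n2,
                           population = rep(c("A", "B"), c(n1, n2))))
  got <- wc_fst(gm, "A", "B")
  # independent textbook computation, SNP by SNP with explicit sums
  num <- den <- numeric(m)
  for (k in seq_len(m)) {
    xa <- dos[1:n1, k]
    xb <- dos[(n1 + 1):(n1 + n2), k]
    nv <- c(length(xa), length(xb))
    pv <- c(sum(xa) / (2 * nv[1]), sum(xb) / (2 * nv[2]))
    hv <- c(mean(xa == 1), mean(xb == 1))
    r <- 2
    nbar <- mean(nv)
    nc <- (sum(nv) - sum(nv^2) / sum(nv)) / (r - 1)
    pbar <- sum(nv * pv) / sum(nv)
    s2 <- sum(nv * (pv - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nv * hv) / sum(nv)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num[k] <- a
    den[k] <- a + b + cc
  }
  ok <- abs(den) > 1e-300
  expect_equal(got$fst, sum(num[ok]) / sum(den[ok]), tolerance = 1e-12)
  expect_equal(got$per_snp$fst[ok], (num / den)[ok], tolerance = 1e-12)
})

test_that("FST edge cases: fixed difference and shared frequencies", {
  gm <- genotypes(rbind(matrix(0L, 5, 3), matrix(2L, 5, 3)),
                  toy_snps(3),
                  toy_inds(10, population = rep(c("A", "B"), each = 5)))
  f <- wc_fst(gm, "A", "B")
  expect_equal(f$per_snp$fst, rep(1, 3))
  set.seed(62)
  p <- runif(400, 0.2, 0.8)
  big <- genotypes(matrix(rbinom(200 * 400, 2, rep(p, each = 200)),
                          200, 400),
                   toy_snps(400),
                   toy_inds(200, population = rep(c("A", "B"),
                                                  each = 100)))
  expect_lt(abs(wc_fst(big, "A", "B")$fst), 0.01)
  mono <- genotypes(matrix(0L, 4, 2) + diag(0L, 4, 2) * 0,
                    toy_snps(2),
                    toy_inds(4, population = rep(c("A", "B"), each = 2)))
  expect_error(wc_fst(mono, "A", "B"), class = "introsel_range_error")
})

test_that("neighbor joining recovers additive trees", {
  # 3 taxa: unique unrooted tree with closed-form branch lengths
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
  # additive 4-taxon distances reproduce topology and path lengths
  true <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  dm4 <- cophenetic(true)
  rec <- nj_tree(dm4)
  expect_equal(ape::dist.topo(ape::unroot(true), rec), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_equal(cophenetic(rec)[rownames(dm4), colnames(dm4)], dm4,
               tolerance = 1e-10)
  # permuting the label order yields an isomorphic tree
  perm <- sample(4)
  rec2 <- nj_tree(dm4[perm, perm])
  expect_equal(ape::dist.topo(rec, rec2), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "introsel_error")
})

test_that("GRM PCA separates deep splits and is PSD", {
  set.seed(63)
  m <- 400
  pa <- runif(m, 0.1, 0.9)
  shift <- pmin(pmax(pa + runif(m, -0.4, 0.4), 0.02), 0.98)
  dos <- rbind(matrix(rbinom(40 * m, 2, rep(pa, each = 40)), 40, m),
               matrix(rbinom(40 * m, 2, rep(shift, each = 40)), 40, m))
  gm <- genotypes(dos, toy_snps(m),
                  toy_inds(80, population = rep(c("A", "B"), each = 40)))
  pc <- pca_grm(gm, k = 4)
  lab <- gm$individuals$population == "A"
  # PC1 partitions the populations perfectly up to sign
  side <- pc$vectors[, 1] > median(pc$vectors[, 1])
  expect_true(all(side == lab) || all(side == !lab))
  expect_true(all(pc$values > -1e-8))
  # GRM diagonal ~ 1 on HWE data
  hwe <- simulate_hwe_panel(100, 800, seed = 64)
  expect_lt(abs(mean(diag(grm(hwe))) - 1), 0.05)
})

test_that("supervised ancestry recovers pure and mosaic individuals", {
  set.seed(65)
  m <- 600
  pA <- runif(m, 0.05, 0.95)
  pB <- runif(m, 0.05, 0.95)
  ref <- cbind(A = pA, B = pB)
  pure <- rbinom(m, 2, pA)
  blocks <- rep(c(TRUE, FALSE), length.out = m)
  mosaic <- ifelse(blocks, rbinom(m, 2, pA), rbinom(m, 2, pB))
  gm <- genotypes(rbind(pure, mosaic), toy_snps(m), toy_inds(2))
  q <- suppressWarnings(supervised_ancestry(gm, ref))
  expect_gte(q$A[1], 0.95)
  expect_lt(abs(q$A[2] - 0.5), 0.05)
  expect_equal(q$A + q$B, c(1, 1), tolerance = 1e-9)
  expect_true(all(q$A >= 0 & q$A <= 1))
})

test_that("conservation tiers use mean/SD cutpoints as printed", {
  props <- tibble::tibble(id = c("a", "b", "c", "d"),
                          population = "P",
                          CN = c(0.90, 0.80, 0.62, 0.40))
  # externally supplied scale (a published cohort): cutpoints drop out
  # at mean - 1 SD and mean - 2 SD
  cg <- classify_conservation(props, "CN", center = 0.7325,
                              scale = 0.1222)
  expect_equal(unname(cg$cutpoints["minus1sd"]), 0.6103)
  expect_equal(unname(cg$cutpoints["minus2sd"]), 0.4881)
  cg2 <- classify_conservation(props, "CN", center = 0.7, scale = 0.1)
  expect_equal(cg2$assignments$group,
               c("nucleus", "nucleus", "candidate1", "discard"))
  # with variance present, someone is always below the mean
  cg3 <- classify_conservation(props, "CN")
  expect_gt(sum(cg3$assignments$group != "nucleus"), 0)
  flat <- dplyr::mutate(props, CN = 0.5)
  expect_error(classify_conservation(flat, "CN"),
               class = "introsel_range_error")
})

test_that("inbreeding outliers are flagged above mean + 2 SD", {
  set.seed(66)
  props <- tibble::tibble(id = sprintf("i%02d", 1:40), population = "P",
                          CN = runif(40, 0.5, 0.9))
  f <- tibble::tibble(id = props$id, f = c(rep(0.05, 39), 0.9))
  cg <- classify_conservation(props, "CN", f = f)
  expect_true(cg$assignments$f_outlier[40])
  expect_false(any(cg$assignments$f_outlier[1:39]))
})

test_that("family assignment cuts clades containing at least one boar", {
  txt <- "((m1:0.1,f1:0.1,f2:0.1):1,(m2:0.1,f3:0.1,f4:0.1):1);"
  tree <- ape::read.tree(text = txt)
  sex <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female",
           f3 = "female", f4 = "female")
  fam <- assign_families(tree, sex)
  expect_equal(attr(fam, "n_families"), 2)
  expect_equal(fam$family[fam$id == "m1"], fam$family[fam$id == "f1"])
  expect_false(fam$family[fam$id == "m1"] == fam$family[fam$id == "m2"])
  # three clades, three males -> three one-boar families
  txt3 <- "(((m1:.1,f1:.1):1,(m2:.1,f2:.1):1):0.5,(m3:.1,f3:.1):1);"
  tree3 <- ape::read.tree(text = txt3)
  sex3 <- c(m1 = "male", m2 = "male", m3 = "male",
            f1 = "female", f2 = "female", f3 = "female")
  fam3 <- assign_families(tree3, sex3)
  expect_equal(attr(fam3, "n_families"), 3)
  per <- table(fam3$family[fam3$sex == "male"])
  expect_true(all(per == 1))
  # all-female input cannot satisfy the constraint
  sexf <- setNames(rep("female", 6), names(sex3))
  expect_error(assign_families(tree3, sexf),
               class = "introsel_range_error")
})
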