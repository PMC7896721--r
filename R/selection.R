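#' Extended haplotype homozygosity from a core SNP
#'
#' `EHH(x)` is the probability that two random carriers of the core allele
#' are identical over every SNP from the core out to `x`:
#' `sum_h C(n_h, 2) / C(n, 2)` over distinct extended haplotypes. Computed
#' outward SNP by SNP until EHH drops below `min_ehh` or the chromosome
#' ends.
#'
#' @param panel a phased [haplotypes] object
#' @param core_snp SNP id or index
#' @param core_allele 0 or 1 (value in the haplotype matrix)
#' @param direction `"both"`, `"left"` or `"right"`
#' @param min_ehh truncation level
#' @return tibble: snp (index), bp, cm, side, ehh; includes the core
#'   itself (ehh = 1) on each requested side
#' @export
ehh <- function(panel, core_snp, core_allele, direction = "both",
                min_ehh = 0.05) {
  assert_that(panel$phased, "EHH needs a phased panel",
              "introsel_phase_error")
  core <- if (is.character(core_snp)) match(core_snp, panel$snps$id) else
    core_snp
  assert_that(!is.na(core) && core >= 1 && core <= ncol(panel$alleles),
              "core SNP not found")
  carriers <- which(panel$alleles[, core] == core_allele)
  assert_that(length(carriers) >= 2,
              "core allele carried by fewer than two haplotypes",
              "introsel_range_error")
  H <- panel$alleles[carriers, , drop = FALSE]
  n <- nrow(H)
  denom <- choose(n, 2)
  chr <- panel$snps$chrom[core]
  on_chr <- which(panel$snps$chrom == chr)
  one_side <- function(idx_seq, side) {
    grp <- rep(1L, n)
    snp_v <- core
    ehh_v <- 1
    for (j in idx_seq) {
      key <- grp * 2L + H[, j]
      grp <- match(key, unique(key))
      e <- sum(choose(tabulate(grp), 2)) / denom
      snp_v <- c(snp_v, j)
      ehh_v <- c(ehh_v, e)
      if (e < min_ehh) break
    }
    tibble::tibble(snp = snp_v, bp = panel$snps$bp[snp_v],
                   cm = panel$snps$cm[snp_v], side = side, ehh = ehh_v)
  }
  out <- list()
  if (direction %in% c("both", "left")) {
    left <- rev(on_chr[on_chr < core])
    out$left <- one_side(left, "left")
  }
  if (direction %in% c("both", "right")) {
    right <- on_chr[on_chr > core]
    out$right <- one_side(right, "right")
  }
  dplyr::bind_rows(out)
}

# integrated EHH on one side: trapezoid over genetic distance (Morgans),
# truncated at the first point below min_ehh
ihh_side <- function(curve) {
  if (nrow(curve) < 2) return(0)
  x <- abs(curve$cm - curve$cm[1]) / 100
  y <- curve$ehh
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# fast iHH for one core allele: both sides summed, trapezoid over Morgans,
# stopping at the first EHH point below min_ehh (that boundary segment is
# included) or after max_extend SNPs
ihh_core <- function(H, cm, core, allele, min_ehh = 0.05,
                     max_extend = 400L) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  denom <- n * (n - 1) / 2
  m <- length(cm)
  total <- 0
  for (dir in c(-1L, 1L)) {
    grp <- rep(1L, n)
    prev_e <- 1
    prev_cm <- cm[core]
    j <- core
    steps <- 0L
    repeat {
      j <- j + dir
      if (j < 1L || j > m) break
      key <- grp * 2L + H[carriers, j]
      grp <- match(key, unique(key))
      e <- sum(choose(tabulate(grp), 2)) / denom
      total <- total + abs(cm[j] - prev_cm) / 100 * (prev_e + e) / 2
      prev_e <- e
      prev_cm <- cm[j]
      steps <- steps + 1L
      if (e < min_ehh || steps >= max_extend) break
    }
  }
  total
}

#' Integrated haplotype score scan
#'
#' For each SNP with minor allele frequency at least `maf_min`, the
#' unstandardized score is `ln(iHH_ancestral / iHH_derived)`, where iHH is
#' the trapezoid integral of the allele's EHH curve against genetic
#' distance on both sides of the core. Scores are standardized to mean 0,
#' SD 1 within derived-allele-frequency bins (bins with fewer than 20
#' SNPs merged with their neighbor). Unpolarized SNPs (no ancestral-allele
#' annotation) use allele2 as the reference orientation and are flagged;
#' their sign is untrusted and they enter the candidate ranking through
#' |iHS| only, like every other SNP.
#'
#' @param panel a phased [haplotypes] object with `ancestral` annotation
#'   in its SNP table (1/2/NA)
#' @param maf_min minimum minor allele frequency for a core SNP
#' @param bins number of derived-allele-frequency bins for standardization
#' @param min_ehh EHH truncation level
#' @param top_q tail mass of |iHS| declared significant
#' @param flank_bp half-width of the reported candidate region around each
#'   significant SNP
#' @return tibble of class `scan_result`: id, chrom, bp, daf, statistic
#'   (raw), std (standardized iHS), polarized, significant; attributes
#'   `method = "iHS"` and `regions` (merged +/- flank windows)
#' @export
ihs_scan <- function(panel, maf_min = 0.05, bins = 50, min_ehh = 0.05,
                     top_q = 0.01, flank_bp = 50000) {
  assert_that(panel$phased, "iHS needs a phased panel",
              "introsel_phase_error")
  m <- ncol(panel$alleles)
  freq1 <- colMeans(panel$alleles)
  anc <- panel$snps$ancestral
  anc_eff <- ifelse(is.na(anc), 2L, anc)   # reference orientation fallback
  # derived allele in matrix coding: allele1 is coded 1, allele2 coded 0
  derived_code <- ifelse(anc_eff == 1L, 0L, 1L)
  daf <- ifelse(derived_code == 1L, freq1, 1 - freq1)
  raw <- rep(NA_real_, m)
  for (chr in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chr)
    Hc <- panel$alleles[, idx, drop = FALSE]
    cmc <- panel$snps$cm[idx]
    for (kk in seq_along(idx)) {
      k <- idx[kk]
      maf <- min(freq1[k], 1 - freq1[k])
      if (is.na(maf) || maf < maf_min) next
      ihh_d <- ihh_core(Hc, cmc, kk, derived_code[k], min_ehh)
      ihh_a <- ihh_core(Hc, cmc, kk, 1L - derived_code[k], min_ehh)
      if (is.na(ihh_d) || is.na(ihh_a) || ihh_d <= 0 || ihh_a <= 0) next
      raw[k] <- log(ihh_a / ihh_d)
    }
  }
  std <- standardize_by_bin(raw, daf, bins = bins, min_bin = 20)
  score <- abs(std)
  have <- which(!is.na(score))
  sig <- rep(FALSE, m)
  if (length(have) > 0) {
    sig[have[empirical_top(score[have], q = top_q)]] <- TRUE
  }
  out <- tibble::tibble(id = panel$snps$id, chrom = panel$snps$chrom,
                        bp = panel$snps$bp, daf = daf, statistic = raw,
                        std = std, polarized = !is.na(anc),
                        significant = sig)
  attr(out, "method") <- "iHS"
  attr(out, "regions") <- merge_intervals(data.frame(
    chrom = out$chrom[sig], start = pmax(out$bp[sig] - flank_bp, 1),
    end = out$bp[sig] + flank_bp))
  class(out) <- c("scan_result", class(out))
  out
}

# standardize x within frequency bins; small bins merged rightward
standardize_by_bin <- function(x, freq, bins = 50, min_bin = 20) {
  out <- rep(NA_real_, length(x))
  have <- which(!is.na(x))
  if (length(have) == 0) return(out)
  br <- seq(0, 1, length.out = bins + 1)
  b <- cut(freq[have], br, include.lowest = TRUE, labels = FALSE)
  # merge sparse bins with their nearest populated neighbor
  tab <- table(factor(b, levels = seq_len(bins)))
  merged <- as.integer(names(tab))
  sizes <- as.integer(tab)
  lab <- seq_len(bins)
  repeat {
    small <- which(sizes > 0 & sizes < min_bin)
    if (length(small) == 0 || sum(sizes > 0) <= 1) break
    s <- small[1]
    others <- which(sizes > 0)
    others <- others[others != s]
    nb <- others[which.min(abs(others - s))]
    sizes[nb] <- sizes[nb] + sizes[s]
    sizes[s] <- 0
    lab[lab == merged[s]] <- merged[nb]
  }
  b2 <- lab[b]
  for (g in unique(b2)) {
    sel <- have[b2 == g]
    mu <- mean(x[sel])
    sdv <- sd(x[sel])
    out[sel] <- if (length(sel) >= 2 && sdv > 0) (x[sel] - mu) / sdv else 0
  }
  out
}

#' EigenGWAS: regression of a principal component on each SNP
#'
#' Single-SNP linear regression of the PC1 score on dosage; the Wald
#' chi-square is genomic-control corrected (`lambda` = median chi-square /
#' 0.4549) before p-values, and significance is Bonferroni (`0.05 / m`).
#'
#' @param gm a [genotypes] object
#' @param pc numeric vector of per-individual PC scores (e.g.
#'   `pca_grm(gm)$vectors[, 1]`), or `NULL` to compute PC1 internally
#' @param gc apply genomic control (part of the method; switchable off)
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @return tibble of class `scan_result`: id, chrom, bp, beta, se,
#'   chisq, p, significant; attributes `method = "EigenGWAS"`, `lambda`
#' @export
eigengwas <- function(gm, pc = NULL, gc = TRUE, alpha = 0.05) {
  y <- pc %||% pca_grm(gm, k = 1)$vectors[, 1]
  assert_that(length(y) == n_ind(gm),
              "PC vector length must match individuals")
  X <- gm$dosage
  obs <- !is.na(X)
  nk <- colSums(obs)
  Y <- matrix(y, n_ind(gm), n_snp(gm))
  Y[!obs] <- NA
  sx <- colSums(X, na.rm = TRUE)
  sy <- colSums(Y, na.rm = TRUE)
  sxx <- colSums(X * X, na.rm = TRUE)
  sxy <- colSums(X * Y, na.rm = TRUE)
  syy <- colSums(Y * Y, na.rm = TRUE)
  vx <- sxx - sx^2 / nk
  vy <- syy - sy^2 / nk
  cxy <- sxy - sx * sy / nk
  ok <- nk >= 3 & vx > 1e-12
  beta <- unname(ifelse(ok, cxy / vx, NA_real_))
  rss <- unname(pmax(vy - beta^2 * vx, 0))
  se <- unname(ifelse(ok, sqrt(rss / (nk - 2) / vx), NA_real_))
  nk <- unname(nk)
  chisq <- (beta / se)^2
  lambda <- 1
  if (gc) {
    lambda <- median(chisq[ok], na.rm = TRUE) / qchisq(0.5, df = 1)
    chisq <- chisq / lambda
  }
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  mtest <- sum(ok)
  out <- tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom,
                        bp = gm$snps$bp, beta = beta, se = se,
                        chisq = chisq, p = p,
                        significant = !is.na(p) & p < alpha / mtest)
  attr(out, "method") <- "EigenGWAS"
  attr(out, "lambda") <- lambda
  class(out) <- c("scan_result", class(out))
  out
}

#' Empirical top-tail selection
#'
#' Indices whose score reaches the `ceiling(q * n)`-th largest value (an
#' order statistic from the top); ties at the threshold are all included.
#'
#' @param scores numeric vector
#' @param q upper tail mass
#' @return integer indices
#' @export
empirical_top <- function(scores, q = 0.01) {
  assert_that(length(scores) > 0, "no scores", "introsel_empty_error")
  if (length(scores) < 100) {
    warn("fewer than 100 scores; the top tail is poorly defined")
  }
  k <- ceiling(q * length(scores))
  thr <- sort(scores, decreasing = TRUE)[k]
  which(scores >= thr)
}

#' Multi-method candidate overlap
#'
#' SNPs flagged by at least `min_methods` scans, reported with merged
#' flanking windows.
#'
#' @param sets named list: method -> vector of significant SNP ids
#' @param snps SNP map tibble (id, chrom, bp), e.g. `gm$snps`
#' @param min_methods minimum number of supporting methods
#' @param flank_bp half-width of the reported window around each SNP
#' @return a list: `snps` (tibble id, chrom, bp, n_methods, methods),
#'   `regions` (tibble chrom, start, end merged over overlapping windows)
#' @export
overlap_candidates <- function(sets, snps, min_methods = 2,
                               flank_bp = 50000) {
  assert_that(length(sets) >= 2, "need at least two method sets")
  all_ids <- unique(unlist(sets))
  hits <- vapply(all_ids, function(id)
    sum(vapply(sets, function(s) id %in% s, logical(1))), integer(1))
  keep <- all_ids[hits >= min_methods]
  idx <- match(keep, snps$id)
  cand <- tibble::tibble(
    id = keep, chrom = snps$chrom[idx], bp = snps$bp[idx],
    n_methods = hits[match(keep, all_ids)],
    methods = vapply(keep, function(id) paste(names(sets)[vapply(
      sets, function(s) id %in% s, logical(1))], collapse = ","),
      character(1)))
  cand <- cand[order(cand$chrom, cand$bp), ]
  regions <- merge_intervals(data.frame(
    chrom = cand$chrom, start = pmax(cand$bp - flank_bp, 1),
    end = cand$bp + flank_bp))
  list(snps = cand, regions = regions)
}
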