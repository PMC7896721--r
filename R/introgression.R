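#' Four-population site patterns
#'
#' Per-SNP derived-allele sample frequencies for the quartet (((P1, P2),
#' P3), O). SNPs are polarized so that the outgroup-major allele is the
#' ancestral ("A") state when the outgroup is informative; SNPs with a
#' population entirely missing at that site are dropped.
#'
#' @param gm a [genotypes] object
#' @param pops named character vector mapping `P1`, `P2`, `P3`, `O` to
#'   population labels in the panel
#' @return tibble of class `site_patterns`: id, chrom, bp, p1, p2, p3, po
#'   (derived-allele frequencies) and n1, n2, n3, no (non-missing diploid
#'   counts)
#' @export
site_patterns <- function(gm, pops) {
  assert_that(all(c("P1", "P2", "P3", "O") %in% names(pops)),
              "pops must name P1, P2, P3 and O")
  rows <- lapply(pops[c("P1", "P2", "P3", "O")], function(p)
    pop_rows(gm, p))
  fr <- lapply(rows, function(r) col_freq(gm$dosage[r, , drop = FALSE]))
  ns <- lapply(rows, function(r)
    colSums(!is.na(gm$dosage[r, , drop = FALSE])))
  keep <- Reduce(`&`, lapply(ns, function(n) n > 0))
  assert_that(any(keep), "no SNP has data in all four populations",
              "introsel_empty_error")
  # polarize: derived = allele that is minor in the outgroup
  flip <- fr[["O"]] > 0.5
  fr <- lapply(fr, function(p) ifelse(flip, 1 - p, p))
  out <- tibble::tibble(
    id = gm$snps$id[keep], chrom = gm$snps$chrom[keep],
    bp = gm$snps$bp[keep],
    p1 = fr[["P1"]][keep], p2 = fr[["P2"]][keep], p3 = fr[["P3"]][keep],
    po = fr[["O"]][keep],
    n1 = ns[["P1"]][keep], n2 = ns[["P2"]][keep], n3 = ns[["P3"]][keep],
    no = ns[["O"]][keep])
  class(out) <- c("site_patterns", class(out))
  out
}

abba <- function(p1, p2, p3, po) (1 - p1) * p2 * p3 * (1 - po)
baba <- function(p1, p2, p3, po) p1 * (1 - p2) * p3 * (1 - po)

# contiguous genomic block labels for the jackknife
jackknife_blocks <- function(chrom, bp, block_size_bp) {
  paste(chrom, floor(bp / block_size_bp), sep = ":")
}

# delete-one-block jackknife for a ratio statistic sum(num)/sum(den)
block_jackknife <- function(num, den, blocks) {
  tot_n <- sum(num)
  tot_d <- sum(den)
  assert_that(abs(tot_d) > 1e-300, "zero denominator",
              "introsel_range_error")
  est <- tot_n / tot_d
  ub <- unique(blocks)
  B <- length(ub)
  if (B < 2) {
    return(list(est = est, se = NA_real_, z = NA_real_, n_blocks = B))
  }
  loo <- vapply(ub, function(b) {
    sel <- blocks == b
    (tot_n - sum(num[sel])) / (tot_d - sum(den[sel]))
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(est = est, se = se, z = est / se, n_blocks = B)
}

#' Patterson's D (ABBA-BABA) statistic
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` over SNPs, with
#' `ABBA = (1 - p1) p2 p3 (1 - pO)` and `BABA = p1 (1 - p2) p3 (1 - pO)`.
#' Positive D indicates excess allele sharing between P2 and P3 (gene flow
#' into the recipient). The standard error comes from a delete-one
#' jackknife over contiguous genomic blocks; `Z = D / SE`.
#'
#' @param sp a `site_patterns` tibble
#' @param block_size_bp jackknife block size
#' @return a list of class `dstat_result`: d, se, z, p (two-sided normal),
#'   n_blocks, n_snps, abba, baba
#' @export
d_statistic <- function(sp, block_size_bp = 5e6) {
  num <- abba(sp$p1, sp$p2, sp$p3, sp$po) -
    baba(sp$p1, sp$p2, sp$p3, sp$po)
  den <- abba(sp$p1, sp$p2, sp$p3, sp$po) +
    baba(sp$p1, sp$p2, sp$p3, sp$po)
  blocks <- jackknife_blocks(sp$chrom, sp$bp, block_size_bp)
  if (length(unique(blocks)) < 20) {
    warn("fewer than 20 jackknife blocks; the SE is unstable")
  }
  jk <- block_jackknife(num, den, blocks)
  structure(list(d = jk$est, se = jk$se, z = jk$z,
                 p = 2 * pnorm(-abs(jk$z)), n_blocks = jk$n_blocks,
                 n_snps = nrow(sp), abba = sum(abba(sp$p1, sp$p2, sp$p3,
                                                    sp$po)),
                 baba = sum(baba(sp$p1, sp$p2, sp$p3, sp$po))),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (SE %.4f, Z = %.2f, %d blocks, %d SNPs)\n",
              x$d, x$se, x$z, x$n_blocks, x$n_snps))
  invisible(x)
}

#' Three-population admixture test f3(A; B, C)
#'
#' `f3 = mean[(pA - pB)(pA - pC) - pA(1 - pA)/(nA - 1)]` over SNPs, with
#' `nA` the non-missing allele count in the target A (the subtraction is
#' the finite-sample bias correction for the variance of the estimated
#' target frequency). A significantly negative value (jackknife Z < -2)
#' indicates that A is admixed between sources related to B and C.
#'
#' @param gm a [genotypes] object
#' @param target,ref1,ref2 population labels for A, B, C
#' @param block_size_bp jackknife block size
#' @return a list of class `f3_result`: f3, se, z, significant,
#'   n_blocks, n_snps
#' @export
f3_test <- function(gm, target, ref1, ref2, block_size_bp = 5e6) {
  ra <- pop_rows(gm, target)
  assert_that(length(ra) >= 2,
              "target population needs >= 2 individuals for the correction")
  dosA <- gm$dosage[ra, , drop = FALSE]
  pa <- col_freq(dosA)
  na <- 2 * colSums(!is.na(dosA))
  pb <- allele_freqs(gm, ref1)
  pc_ <- allele_freqs(gm, ref2)
  keep <- !is.na(pa) & !is.na(pb) & !is.na(pc_) & na >= 2
  assert_that(any(keep), "no usable SNPs", "introsel_empty_error")
  val <- (pa - pb) * (pa - pc_) - pa * (1 - pa) / (na - 1)
  val <- val[keep]
  blocks <- jackknife_blocks(gm$snps$chrom[keep], gm$snps$bp[keep],
                             block_size_bp)
  jk <- block_jackknife(val, rep(1, length(val)), blocks)
  structure(list(f3 = jk$est, se = jk$se, z = jk$z,
                 significant = !is.na(jk$z) && jk$z < -2,
                 n_blocks = jk$n_blocks, n_snps = sum(keep),
                 pops = c(A = target, B = ref1, C = ref2)),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.5f (Z = %.2f%s)\n",
              x$pops[1], x$pops[2], x$pops[3], x$f3, x$z,
              if (x$significant) ", significant admixture" else ""))
  invisible(x)
}

# f_dM site terms: numerator ABBA - BABA; denominator per Malinsky's
# dynamic donor choice
fdm_site_terms <- function(p1, p2, p3, po) {
  num <- abba(p1, p2, p3, po) - baba(p1, p2, p3, po)
  den <- numeric(length(p1))
  up <- p2 >= p1
  pd <- pmax(p2, p3)
  den[up] <- (abba(p1, pd, pd, po) - baba(p1, pd, pd, po))[up]
  pd2 <- pmax(p1, p3)
  den[!up] <- -(abba(pd2, p2, pd2, po) - baba(pd2, p2, pd2, po))[!up]
  list(num = num, den = den)
}

#' Sliding-window f_dM, dxy and pi
#'
#' Windows of `window_snps` SNPs advancing by `step_snps`, never spanning
#' chromosomes. Per window: Malinsky's `f_dM` (positive for P3-P2
#' sharing, negative for P3-P1); absolute divergence `dxy(X, Y) =
#' mean[pX (1 - pY) + pY (1 - pX)]` for each requested population pair;
#' and nucleotide diversity `pi_X = mean[2 pX (1 - pX) * 2nX/(2nX - 1)]`
#' for each requested population. On array data all three are
#' per-variant (not per-bp) averages, so their absolute values are not
#' comparable to sequence-based estimates.
#'
#' @param sp a `site_patterns` tibble
#' @param window_snps,step_snps window geometry
#' @param dxy_pairs list of 2-vectors over `c("P1","P2","P3","O")`
#' @param pi_pops character vector over the same labels
#' @return tibble of class `window_stats`: chrom, start_snp, end_snp,
#'   start_bp, end_bp, f_dm (NA when the window denominator is 0), plus
#'   `dxy_X_Y` and `pi_X` columns
#' @export
window_scan <- function(sp, window_snps = 10, step_snps = 2,
                        dxy_pairs = list(c("P2", "P3")),
                        pi_pops = c("P1", "P2")) {
  freq_col <- c(P1 = "p1", P2 = "p2", P3 = "p3", O = "po")
  n_col <- c(P1 = "n1", P2 = "n2", P3 = "n3", O = "no")
  terms <- fdm_site_terms(sp$p1, sp$p2, sp$p3, sp$po)
  out <- list()
  for (chr in unique(sp$chrom)) {
    idx <- which(sp$chrom == chr)
    m <- length(idx)
    if (m < window_snps) next
    starts <- seq(1, m - window_snps + 1, by = step_snps)
    for (s in starts) {
      w <- idx[s:(s + window_snps - 1)]
      den <- sum(terms$den[w])
      fdm <- if (abs(den) < 1e-300) NA_real_ else sum(terms$num[w]) / den
      row <- tibble::tibble(
        chrom = chr, start_snp = w[1], end_snp = w[window_snps],
        start_bp = sp$bp[w[1]], end_bp = sp$bp[w[window_snps]],
        f_dm = fdm)
      for (pr in dxy_pairs) {
        px <- sp[[freq_col[pr[1]]]][w]
        py <- sp[[freq_col[pr[2]]]][w]
        row[[paste0("dxy_", pr[1], "_", pr[2])]] <-
          mean(px * (1 - py) + py * (1 - px))
      }
      for (pp in pi_pops) {
        p <- sp[[freq_col[pp]]][w]
        n2x <- 2 * sp[[n_col[pp]]][w]
        row[[paste0("pi_", pp)]] <-
          mean(2 * p * (1 - p) * n2x / (n2x - 1))
      }
      out[[length(out) + 1]] <- row
    }
  }
  assert_that(length(out) > 0, "no window fits on any chromosome",
              "introsel_empty_error")
  res <- dplyr::bind_rows(out)
  class(res) <- c("window_stats", class(res))
  res
}

#' Significant introgression windows and genome-level summaries
#'
#' Z-transforms the defined `f_dM` values; one-sided upper-tail normal
#' p-values flag significantly introgressed windows (the alternative of
#' interest is sharing between P3 and P2), which are merged into regions.
#' Also reports the fraction of the windowed genome with positive `f_dM`
#' and, when pi columns are named, the relative diversity boost
#' `(pi_target - pi_ref) / pi_ref` averaged over positive-`f_dM` windows
#' and over significant windows.
#'
#' @param ws a `window_stats` tibble from [window_scan]
#' @param p_cut significance level on the one-sided p
#' @param pi_target,pi_ref column names in `ws` (e.g. `"pi_P2"`,
#'   `"pi_P1"`), or `NULL` to skip the boost summary
#' @return a list of class `fdm_summary`: `windows` (input plus z, p,
#'   significant), `regions` (merged significant windows), `threshold`
#'   (f_dM value at the significance cut), `genome_fraction_positive`,
#'   `pi_boost_positive`, `pi_boost_significant`
#' @export
significant_windows <- function(ws, p_cut = 0.01, pi_target = NULL,
                                pi_ref = NULL) {
  if (nrow(ws) < 100) {
    warn("fewer than 100 windows; the empirical Z-transform is unstable")
  }
  ok <- !is.na(ws$f_dm)
  mu <- mean(ws$f_dm[ok])
  sdv <- sd(ws$f_dm[ok])
  if (!is.finite(sdv) || sdv == 0) {
    # a constant scan carries no empirical tail: nothing is significant
    warn("zero variance in f_dM; no window can be significant")
    ws$z <- NA_real_
    ws$p <- NA_real_
    ws$significant <- FALSE
    sdv <- NA_real_
  } else {
    ws$z <- (ws$f_dm - mu) / sdv
    ws$p <- 1 - pnorm(ws$z)
    ws$significant <- !is.na(ws$p) & ws$p < p_cut
  }
  regions <- merge_intervals(data.frame(
    chrom = ws$chrom[ws$significant], start = ws$start_bp[ws$significant],
    end = ws$end_bp[ws$significant]))
  pos <- ok & ws$f_dm > 0
  pos_bp <- merge_intervals(data.frame(chrom = ws$chrom[pos],
                                       start = ws$start_bp[pos],
                                       end = ws$end_bp[pos]))
  all_bp <- merge_intervals(data.frame(chrom = ws$chrom,
                                       start = ws$start_bp,
                                       end = ws$end_bp))
  span <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start + 1)
  boost <- function(sel) {
    if (is.null(pi_target) || is.null(pi_ref) || !any(sel)) return(NA_real_)
    mt <- mean(ws[[pi_target]][sel])
    mr <- mean(ws[[pi_ref]][sel])
    (mt - mr) / mr
  }
  structure(list(
    windows = ws, regions = regions,
    threshold = mu + qnorm(1 - p_cut) * sdv,
    genome_fraction_positive = span(pos_bp) / span(all_bp),
    pi_boost_positive = boost(pos),
    pi_boost_significant = boost(ws$significant)),
    class = "fdm_summary")
}

#' Haplotype frequency table over a SNP range
#'
#' Distinct haplotype strings with per-population counts; per-population
#' counts sum to twice the population's individual count.
#'
#' @param panel a phased [haplotypes] object
#' @param snp_range integer vector of SNP indices (or SNP ids)
#' @return tibble: haplotype (character of 0/1 alleles), total, one count
#'   column per population, most_frequent flag
#' @export
haplotype_freqs <- function(panel, snp_range) {
  assert_that(panel$phased, "haplotype counting needs a phased panel",
              "introsel_phase_error")
  idx <- if (is.character(snp_range)) match(snp_range, panel$snps$id) else
    snp_range
  assert_that(!anyNA(idx) && all(idx >= 1 & idx <= ncol(panel$alleles)),
              "snp_range out of bounds")
  H <- panel$alleles[, idx, drop = FALSE]
  str <- apply(H, 1, paste0, collapse = "")
  pop <- rep(panel$individuals$population, each = 2)
  tab <- table(str, pop)
  out <- tibble::tibble(haplotype = rownames(tab),
                        total = as.integer(rowSums(tab)))
  for (p in colnames(tab)) out[[p]] <- as.integer(tab[, p])
  out <- out[order(-out$total), ]
  out$most_frequent <- seq_len(nrow(out)) == 1
  out
}
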