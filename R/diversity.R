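#' Observed and expected heterozygosity
#'
#' Per population: Ho is the mean over SNPs of the observed heterozygote
#' fraction; He is the mean over SNPs of `2p(1-p) * 2n/(2n-1)` (the
#' small-sample unbiased estimator, with `n` the non-missing diploid count
#' at the SNP). Missing calls are skipped per SNP; monomorphic SNPs
#' contribute zero to both.
#'
#' @param gm a [genotypes] object
#' @param population a single population label, or `NULL` for every
#'   population in the panel
#' @return tibble: population, n_ind, n_snps, ho, he
#' @export
het_stats <- function(gm, population = NULL) {
  pops <- population %||% unique(gm$individuals$population)
  purrr::map_dfr(pops, function(pop) {
    rows <- pop_rows(gm, pop)
    assert_that(length(rows) >= 2,
                sprintf("population '%s' needs >= 2 individuals", pop))
    dos <- gm$dosage[rows, , drop = FALSE]
    n <- colSums(!is.na(dos))
    use <- n > 0
    ho_k <- colMeans(dos == 1, na.rm = TRUE)[use]
    p <- col_freq(dos)[use]
    nn <- n[use]
    he_k <- 2 * p * (1 - p) * (2 * nn / (2 * nn - 1))
    tibble::tibble(population = pop, n_ind = length(rows),
                   n_snps = sum(use), ho = mean(ho_k), he = mean(he_k))
  })
}

#' Pairwise LD against physical and genetic distance
#'
#' Composite genotypic r-squared (squared Pearson correlation of dosages,
#' no phasing) for all intra-chromosome SNP pairs up to `max_dist_bp`.
#' Genetic distance comes from the cM map when present, otherwise from a
#' 1 cM/Mb fallback (flagged via the `map_source` attribute).
#'
#' @param gm a [genotypes] object
#' @param population population label (`NULL` = all individuals)
#' @param max_dist_bp maximum pair separation in bp
#' @return tibble of class `ld_pairs`: chrom, snp_a, snp_b, dist_bp,
#'   dist_m (Morgans), r2
#' @export
ld_decay <- function(gm, population = NULL, max_dist_bp = 10e6) {
  rows <- if (is.null(population)) seq_len(n_ind(gm)) else
    pop_rows(gm, population)
  if (length(rows) < 10) {
    warn(sprintf("only %d individuals; r2 estimates will be noisy",
                 length(rows)))
  }
  have_cm <- !anyNA(gm$snps$cm) && any(gm$snps$cm != 0)
  out <- list()
  for (chr in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == chr)
    if (length(idx) < 2) next
    r2 <- r2_matrix(gm$dosage[rows, idx, drop = FALSE])
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    a <- idx[pr[, 1]]
    b <- idx[pr[, 2]]
    dist_bp <- abs(gm$snps$bp[b] - gm$snps$bp[a])
    okd <- dist_bp > 0 & dist_bp <= max_dist_bp
    dist_m <- if (have_cm) {
      abs(gm$snps$cm[b] - gm$snps$cm[a]) / 100
    } else {
      dist_bp * 1e-8  # 1 cM/Mb fallback
    }
    out[[chr]] <- tibble::tibble(
      chrom = chr, snp_a = gm$snps$id[a][okd], snp_b = gm$snps$id[b][okd],
      dist_bp = dist_bp[okd], dist_m = dist_m[okd],
      r2 = r2[upper.tri(r2)][okd])
  }
  res <- dplyr::bind_rows(out)
  res <- res[!is.na(res$r2), , drop = FALSE]
  assert_that(nrow(res) > 0, "no SNP pairs within max_dist_bp",
              "introsel_empty_error")
  attr(res, "map_source") <- if (have_cm) "cm_map" else "1cM_per_Mb"
  class(res) <- c("ld_pairs", class(res))
  res
}

#' LD extent: distance at which mean r-squared decays to a target
#'
#' Bins pairs by physical distance, averages r-squared per bin, and
#' linearly interpolates the first downward crossing of `r2_target`.
#'
#' @param pairs an `ld_pairs` tibble from [ld_decay]
#' @param r2_target the r-squared level defining the extent
#' @param bin_width_bp distance bin width
#' @return the extent in bp (a single number)
#' @export
ld_extent <- function(pairs, r2_target = 0.3, bin_width_bp = 10000) {
  bin <- floor(pairs$dist_bp / bin_width_bp)
  agg <- dplyr::summarise(dplyr::group_by(tibble::tibble(bin = bin,
                                                         r2 = pairs$r2),
                                          bin),
                          r2 = mean(r2), .groups = "drop")
  agg <- agg[order(agg$bin), ]
  mid <- (agg$bin + 0.5) * bin_width_bp
  r2 <- agg$r2
  assert_that(r2[1] >= r2_target,
              "LD curve is below the target already in the first bin",
              "introsel_range_error")
  cross <- which(r2[-length(r2)] >= r2_target & r2[-1] < r2_target)
  assert_that(length(cross) > 0, "LD curve never crosses the target",
              "introsel_range_error")
  i <- cross[1]
  mid[i] + (r2[i] - r2_target) / (r2[i] - r2[i + 1]) * (mid[i + 1] - mid[i])
}

#' Sved's equation
#'
#' `Ne_t = (1/(4c)) (1/r2 - 1)` at `t = 1/(2c)` generations: the
#' equilibrium relation between LD at genetic distance `c` (Morgans) and
#' effective population size `t` generations ago.
#'
#' @param r2 mean r-squared
#' @param c genetic distance in Morgans
#' @return tibble: c, t, ne
#' @export
sved_ne <- function(r2, c) {
  assert_that(all(r2 > 0), "r2 must be positive", "introsel_range_error")
  tibble::tibble(c = c, t = 1 / (2 * c), ne = (1 / (4 * c)) * (1 / r2 - 1))
}

#' LD-based effective population size trajectory
#'
#' Pairs are binned by genetic distance `c`; each bin contributes
#' `Ne = (1/(4c)) (1/mean(r2) - 1)` at `t = 1/(2c)` generations before
#' present. An optional `1/n` sampling correction on r-squared (off by
#' default) can be enabled via `n_sample`.
#'
#' @param pairs an `ld_pairs` tibble from [ld_decay]
#' @param c_range range of genetic distance (Morgans) to use
#' @param n_bins number of equal-width c bins
#' @param n_sample if non-NULL, subtract `1/n_sample` from mean r-squared
#'   per bin before applying the equation
#' @return tibble of class `ne_estimate`: t, c, r2, ne, n_pairs
#' @export
estimate_ne <- function(pairs, c_range = c(0.005, 0.25), n_bins = 20,
                        n_sample = NULL) {
  keep <- pairs$dist_m >= c_range[1] & pairs$dist_m <= c_range[2]
  assert_that(any(keep), "no pairs in the requested c range",
              "introsel_empty_error")
  br <- seq(c_range[1], c_range[2], length.out = n_bins + 1)
  bin <- cut(pairs$dist_m[keep], br, include.lowest = TRUE, labels = FALSE)
  d <- tibble::tibble(bin = bin, c = pairs$dist_m[keep], r2 = pairs$r2[keep])
  agg <- dplyr::summarise(dplyr::group_by(d, bin),
                          c = mean(c), r2 = mean(r2),
                          n_pairs = dplyr::n(), .groups = "drop")
  if (!is.null(n_sample)) agg$r2 <- pmax(agg$r2 - 1 / n_sample, 1e-12)
  assert_that(all(agg$r2 > 0), "mean r2 of zero in a bin",
              "introsel_range_error")
  out <- tibble::tibble(t = 1 / (2 * agg$c), c = agg$c, r2 = agg$r2,
                        ne = (1 / (4 * agg$c)) * (1 / agg$r2 - 1),
                        n_pairs = agg$n_pairs)
  out <- out[order(out$t), ]
  class(out) <- c("ne_estimate", class(out))
  out
}

#' Recent-Ne summary
#'
#' Mean Ne over trajectory bins with `t <= t_max` ("the past t_max
#' generations").
#'
#' @param ne a `ne_estimate` tibble from [estimate_ne]
#' @param t_max horizon in generations
#' @return a single number
#' @export
ne_recent <- function(ne, t_max = 5) {
  keep <- ne$t <= t_max
  assert_that(any(keep), "no bins within the requested horizon",
              "introsel_empty_error")
  mean(ne$ne[keep])
}

#' SNP-based method-of-moments inbreeding coefficient
#'
#' Per individual, `F = (O_hom - E_hom) / (L - E_hom)` over the supplied
#' (typically LD-pruned) SNP set, with `E_hom = sum(1 - 2p(1-p) *
#' 2n/(2n-1))` over the individual's non-missing SNPs and allele
#' frequencies taken within the individual's own population.
#'
#' @param gm a [genotypes] object
#' @param pruned SNP indices to use (e.g. from [ld_prune]); default all
#' @return tibble: id, population, f
#' @export
snp_inbreeding <- function(gm, pruned = NULL) {
  idx <- pruned %||% seq_len(n_snp(gm))
  assert_that(length(idx) > 0, "pruned SNP set is empty",
              "introsel_empty_error")
  sub <- gm$dosage[, idx, drop = FALSE]
  pops <- unique(gm$individuals$population)
  pfreq <- matrix(NA_real_, length(pops), length(idx),
                  dimnames = list(pops, NULL))
  nobs <- pfreq
  for (pop in pops) {
    d <- sub[gm$individuals$population == pop, , drop = FALSE]
    pfreq[pop, ] <- col_freq(d)
    nobs[pop, ] <- colSums(!is.na(d))
  }
  f <- vapply(seq_len(n_ind(gm)), function(i) {
    pop <- gm$individuals$population[i]
    x <- sub[i, ]
    ok <- !is.na(x) & !is.na(pfreq[pop, ]) & nobs[pop, ] >= 1
    p <- pfreq[pop, ok]
    n <- nobs[pop, ok]
    ehet <- 2 * p * (1 - p) * (2 * n / (2 * n - 1))
    e_hom <- sum(1 - ehet)
    l <- sum(ok)
    o_hom <- sum(x[ok] != 1)
    denom <- l - e_hom
    if (abs(denom) < 1e-12) {
      stop_introsel("degenerate inbreeding denominator (L == E_hom)")
    }
    (o_hom - e_hom) / denom
  }, numeric(1))
  tibble::tibble(id = gm$individuals$id,
                 population = gm$individuals$population, f = f)
}
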