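#' ROH caller parameters
#'
#' PLINK `--homozyg`-style settings. `min_snps = NULL` computes the
#' Lencz false-positive bound via [min_roh_snps] from the panel's own SNP
#' count, individual count and mean observed heterozygosity at call time.
#'
#' @param window_snps sliding-window width in SNPs
#' @param max_het_per_window heterozygous calls tolerated per window
#' @param max_missing_per_window missing calls tolerated per window
#' @param min_snps minimum SNPs per accepted segment, or `NULL` to compute
#' @param min_length_bp minimum segment length
#' @param density_bp_per_snp maximum bp per SNP inside a segment
#'   (1 SNP / 100 kb)
#' @param max_gap_bp maximum gap between consecutive segment SNPs
#' @param hit_fraction_threshold fraction of passing windows covering a SNP
#'   required for it to enter a candidate run (PLINK default 0.05)
#' @param alpha false-positive rate fed to the Lencz formula
#' @param genome_length_bp autosomal genome length used for F_ROH
#' @return a list of class `roh_params`
#' @export
roh_params <- function(window_snps = 50, max_het_per_window = 1,
                       max_missing_per_window = 5, min_snps = NULL,
                       min_length_bp = 1e6, density_bp_per_snp = 1e5,
                       max_gap_bp = 1e6, hit_fraction_threshold = 0.05,
                       alpha = 0.05, genome_length_bp = 2.45e9) {
  assert_that(hit_fraction_threshold > 0 && hit_fraction_threshold <= 1,
              "hit_fraction_threshold must lie in (0, 1]")
  assert_that(all(c(window_snps, min_length_bp, density_bp_per_snp,
                    max_gap_bp, genome_length_bp) > 0),
              "ROH parameters must be positive")
  structure(list(window_snps = window_snps,
                 max_het_per_window = max_het_per_window,
                 max_missing_per_window = max_missing_per_window,
                 min_snps = min_snps, min_length_bp = min_length_bp,
                 density_bp_per_snp = density_bp_per_snp,
                 max_gap_bp = max_gap_bp,
                 hit_fraction_threshold = hit_fraction_threshold,
                 alpha = alpha, genome_length_bp = genome_length_bp),
            class = "roh_params")
}

#' Minimum SNP count for a non-spurious ROH (Lencz bound)
#'
#' `l = ceil( ln(alpha / (n_snps * n_ind)) / ln(1 - het) )`: the run length
#' below which a fully homozygous stretch is expected by chance at family
#' rate `alpha` across the whole scan.
#'
#' @param alpha tolerated genome-and-cohort-wide false-positive rate
#' @param n_snps SNPs per individual in the scan
#' @param n_ind individuals in the scan
#' @param het mean per-SNP heterozygosity of the panel
#' @return integer minimum SNP count
#' @export
min_roh_snps <- function(alpha, n_snps, n_ind, het) {
  assert_that(het > 0 && het < 1, "het must lie strictly in (0, 1)")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie strictly in (0, 1)")
  assert_that(n_snps >= 1 && n_ind >= 1, "counts must be >= 1")
  ceil_safe(log(alpha / (n_snps * n_ind)) / log(1 - het))
}

roh_class <- function(length_bp) {
  ifelse(length_bp > 10e6, ">10Mb", ifelse(length_bp >= 5e6, "5-10Mb",
                                           "<5Mb"))
}

#' Call runs of homozygosity
#'
#' PLINK `--homozyg` emulation: a `window_snps`-wide window slides one SNP
#' at a time along each chromosome; a window passes when it contains at
#' most `max_het_per_window` heterozygous and `max_missing_per_window`
#' missing calls. Each SNP's hit fraction is the share of passing windows
#' among windows covering it; SNPs at or above `hit_fraction_threshold`
#' form candidate runs, which are split at inter-SNP gaps above
#' `max_gap_bp`, trimmed at both ends to the outermost homozygous
#' non-missing SNP, and accepted when they satisfy the minimum SNP count,
#' length and density thresholds. Lengths in bp are `end - start + 1`
#' (1-based inclusive positions).
#'
#' @param gm a [genotypes] object
#' @param params a [roh_params] list
#' @return tibble of class `roh_set`: id, population, chrom, start_bp,
#'   end_bp, n_snps, length_bp, class (`<5Mb` / `5-10Mb` / `>10Mb`)
#' @export
call_roh <- function(gm, params = roh_params()) {
  w <- params$window_snps
  l_min <- params$min_snps
  if (is.null(l_min)) {
    het <- mean(gm$dosage == 1, na.rm = TRUE)
    l_min <- min_roh_snps(params$alpha, n_snp(gm), n_ind(gm), het)
  }
  segs <- list()
  chrom_list <- unique(gm$snps$chrom)
  for (chr in chrom_list) {
    idx <- which(gm$snps$chrom == chr)
    m <- length(idx)
    if (m < w) {
      warn(sprintf("chromosome %s has %d SNPs < window %d; skipped",
                   chr, m, w))
      next
    }
    bp <- gm$snps$bp[idx]
    gap_after <- c(diff(bp), Inf)
    n_win <- m - w + 1
    for (i in seq_len(n_ind(gm))) {
      x <- gm$dosage[i, idx]
      het <- as.integer(!is.na(x) & x == 1)
      mis <- as.integer(is.na(x))
      ch <- cumsum(het)
      cm_ <- cumsum(mis)
      nh <- ch[w:m] - c(0, ch)[1:n_win]
      nm <- cm_[w:m] - c(0, cm_)[1:n_win]
      pass <- as.integer(nh <= params$max_het_per_window &
                           nm <= params$max_missing_per_window)
      cp <- c(0, cumsum(pass))
      k <- seq_len(m)
      lo <- pmax(k - w + 1, 1)
      hi <- pmin(k, n_win)
      covered <- hi - lo + 1
      npass <- cp[pmax(hi, lo - 1) + 1] - cp[lo]
      ok_cov <- covered > 0
      hit <- ifelse(ok_cov, npass / pmax(covered, 1), 0)
      cand <- hit >= params$hit_fraction_threshold & ok_cov
      if (!any(cand)) next
      r <- rle(cand)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (run in which(r$values)) {
        a <- starts[run]
        b <- ends[run]
        # split at large gaps
        cut_after <- which(gap_after[a:(b - 1)] > params$max_gap_bp)
        bounds <- cbind(c(a, a + cut_after),
                        c(a + cut_after - 1, b))
        if (b == a) bounds <- cbind(a, b)
        for (s in seq_len(nrow(bounds))) {
          aa <- bounds[s, 1]
          bb <- bounds[s, 2]
          # trim to outermost homozygous non-missing SNP
          seg <- aa:bb
          hom <- !is.na(x[seg]) & x[seg] != 1
          if (!any(hom)) next
          aa <- seg[which(hom)[1]]
          bb <- seg[which(hom)[length(which(hom))]]
          ns <- bb - aa + 1
          len <- bp[bb] - bp[aa] + 1
          if (ns >= l_min && len >= params$min_length_bp &&
              len / ns <= params$density_bp_per_snp) {
            segs[[length(segs) + 1]] <- tibble::tibble(
              id = gm$individuals$id[i],
              population = gm$individuals$population[i],
              chrom = chr, start_bp = bp[aa], end_bp = bp[bb],
              n_snps = ns, length_bp = len)
          }
        }
      }
    }
  }
  out <- if (length(segs) == 0) {
    tibble::tibble(id = character(), population = character(),
                   chrom = character(), start_bp = numeric(),
                   end_bp = numeric(), n_snps = integer(),
                   length_bp = numeric())
  } else dplyr::bind_rows(segs)
  out$class <- roh_class(out$length_bp)
  attr(out, "min_snps") <- l_min
  class(out) <- c("roh_set", class(out))
  out
}

#' ROH-based inbreeding coefficients
#'
#' `F_ROH` = total ROH length / autosomal genome length, decomposed by
#' segment length class (`<5Mb` ~ ancestral, `5-10Mb` ~ intermediate,
#' `>10Mb` ~ recent inbreeding). Individuals with no called segment get 0.
#'
#' @param roh a `roh_set` tibble from [call_roh]
#' @param gm the source [genotypes] object (supplies the full individual
#'   roster), or `NULL` to report only individuals present in `roh`
#' @param genome_length_bp autosomal genome length
#' @return tibble: id, froh, froh_lt5, froh_5_10, froh_gt10
#' @export
roh_inbreeding <- function(roh, gm = NULL, genome_length_bp = 2.45e9) {
  assert_that(genome_length_bp > 0, "genome length must be positive")
  ids <- if (!is.null(gm)) gm$individuals$id else unique(roh$id)
  base <- tibble::tibble(id = ids)
  cls <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(roh), .data$id, .data$class),
    len = sum(.data$length_bp), .groups = "drop")
  wide <- tidyr::pivot_wider(cls, names_from = "class", values_from = "len",
                             values_fill = 0)
  for (col in c("<5Mb", "5-10Mb", ">10Mb")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  out <- dplyr::left_join(base, wide, by = "id")
  out[is.na(out)] <- 0
  tibble::tibble(id = out$id,
                 froh = (out$`<5Mb` + out$`5-10Mb` + out$`>10Mb`) /
                   genome_length_bp,
                 froh_lt5 = out$`<5Mb` / genome_length_bp,
                 froh_5_10 = out$`5-10Mb` / genome_length_bp,
                 froh_gt10 = out$`>10Mb` / genome_length_bp)
}

#' ROH incidence scan
#'
#' Counts, per SNP, the individuals whose called ROH covers its position,
#' and flags SNPs in the top `top_q` tail of the empirical count
#' distribution (ties at the threshold included) as putatively selected.
#'
#' @param roh a `roh_set` tibble from [call_roh]
#' @param gm the source [genotypes] object
#' @param top_q upper tail mass declared significant
#' @return tibble of class `scan_result`: id, chrom, bp, statistic (count),
#'   significant; attribute `method` = "ROH"
#' @export
roh_incidence_scan <- function(roh, gm, top_q = 0.01) {
  counts <- integer(n_snp(gm))
  for (chr in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == chr)
    bp <- gm$snps$bp[idx]
    seg <- roh[roh$chrom == chr, , drop = FALSE]
    if (nrow(seg) == 0) next
    delta <- integer(length(idx) + 1)
    for (r in seq_len(nrow(seg))) {
      a <- findInterval(seg$start_bp[r] - 1, bp) + 1   # first bp >= start
      b <- findInterval(seg$end_bp[r], bp)             # last bp <= end
      if (a > b) next
      delta[a] <- delta[a] + 1L
      delta[b + 1] <- delta[b + 1] - 1L
    }
    counts[idx] <- cumsum(delta[seq_along(idx)])
  }
  sig <- empirical_top(counts, q = top_q)
  out <- tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom,
                        bp = gm$snps$bp, statistic = counts,
                        significant = seq_along(counts) %in% sig)
  attr(out, "method") <- "ROH"
  class(out) <- c("scan_result", class(out))
  out
}
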