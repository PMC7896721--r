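#' Quality-control parameters
#'
#' Defaults follow common SNP-array practice for livestock panels: MAF >=
#' 0.01, call rate >= 90% for both SNPs and individuals, removal of one
#' member of any pair with identity-by-state above 0.99, and restriction to
#' mapped autosomal SNPs.
#'
#' @param maf_min minimum minor allele frequency (SNPs below are dropped)
#' @param call_rate_min minimum call rate, applied to SNPs first, then
#'   individuals
#' @param ibs_dup_threshold IBS similarity above which a pair is treated as
#'   duplicates; the lexicographically smallest id of each duplicate cluster
#'   is kept (deterministic stand-in for random choice)
#' @param autosomes_only drop unmapped SNPs and sex chromosomes/MT
#' @return a list of class `qc_params`
#' @export
qc_params <- function(maf_min = 0.01, call_rate_min = 0.90,
                      ibs_dup_threshold = 0.99, autosomes_only = TRUE) {
  for (v in c(maf_min, call_rate_min, ibs_dup_threshold)) {
    assert_that(is.numeric(v) && v >= 0 && v <= 1,
                "QC thresholds must lie in [0, 1]")
  }
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 ibs_dup_threshold = ibs_dup_threshold,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "qc_params")
}

non_autosome_labels <- c("X", "Y", "XY", "MT", "M", "0", "23", "24", "25",
                         "26")

#' Apply panel quality control
#'
#' Filters are applied sequentially: (1) duplicate individuals by IBS, (2)
#' SNPs by minor allele frequency, (3) call rate - SNPs first, then
#' individuals, (4) non-autosomal and unmapped SNPs. Each step's removals
#' are tallied in the report.
#'
#' @param gm a [genotypes] object
#' @param qc a [qc_params] list
#' @return a list with elements `genotypes` (filtered panel) and `report`
#'   (tibble: step, removed_snps, removed_individuals)
#' @export
apply_qc <- function(gm, qc = qc_params()) {
  report <- tibble::tibble(step = character(), removed_snps = integer(),
                           removed_individuals = integer())
  note <- function(step, snps = 0L, inds = 0L) {
    report <<- dplyr::bind_rows(report, tibble::tibble(
      step = step, removed_snps = as.integer(snps),
      removed_individuals = as.integer(inds)))
  }

  # (1) duplicate individuals by IBS
  drop_ids <- character()
  if (n_ind(gm) >= 2) {
    ibs <- pairwise_ibs(gm$dosage)
    dup <- which(ibs > qc$ibs_dup_threshold & upper.tri(ibs), arr.ind = TRUE)
    if (nrow(dup) > 0) {
      g <- igraph::graph_from_edgelist(
        cbind(rownames(ibs)[dup[, 1]], colnames(ibs)[dup[, 2]]),
        directed = FALSE)
      comps <- igraph::components(g)
      for (k in seq_len(comps$no)) {
        ids <- names(comps$membership)[comps$membership == k]
        drop_ids <- c(drop_ids, setdiff(ids, min(ids)))
      }
    }
  }
  note("ibs_duplicates", inds = length(drop_ids))
  if (length(drop_ids) > 0) {
    keep <- !(gm$individuals$id %in% drop_ids)
    assert_that(any(keep), "all individuals removed as duplicates",
                "introsel_empty_error")
    gm <- subset_genotypes(gm, individuals = keep)
  }

  # (2) MAF
  maf <- col_maf(gm$dosage)
  keep_snp <- !is.na(maf) & maf >= qc$maf_min
  note("maf", snps = sum(!keep_snp))
  assert_that(any(keep_snp), "all SNPs removed by MAF filter",
              "introsel_empty_error")
  gm <- subset_genotypes(gm, snps = keep_snp)

  # (3) call rate: SNPs first, then individuals
  snp_cr <- colMeans(!is.na(gm$dosage))
  keep_snp <- snp_cr >= qc$call_rate_min
  n_removed_snps <- sum(!keep_snp)
  assert_that(any(keep_snp), "all SNPs removed by call-rate filter",
              "introsel_empty_error")
  gm <- subset_genotypes(gm, snps = keep_snp)
  ind_cr <- rowMeans(!is.na(gm$dosage))
  keep_ind <- ind_cr >= qc$call_rate_min
  note("call_rate", snps = n_removed_snps, inds = sum(!keep_ind))
  assert_that(any(keep_ind), "all individuals removed by call-rate filter",
              "introsel_empty_error")
  gm <- subset_genotypes(gm, individuals = keep_ind)

  # (4) autosomes only
  if (qc$autosomes_only) {
    keep_snp <- !(toupper(gm$snps$chrom) %in% non_autosome_labels) &
      gm$snps$bp > 0
    note("autosomes", snps = sum(!keep_snp))
    assert_that(any(keep_snp), "all SNPs removed as non-autosomal",
                "introsel_empty_error")
    gm <- subset_genotypes(gm, snps = keep_snp)
  } else {
    note("autosomes", snps = 0L)
  }

  list(genotypes = gm, report = report)
}

#' Greedy windowed LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: within each window of
#' `window_snps` consecutive SNPs (advancing by `step`), the later SNP of
#' any pair with genotypic r-squared above `r2_max` is removed. r-squared is
#' the squared Pearson correlation of dosages (composite genotypic LD, no
#' phasing), computed pairwise-complete over missing calls.
#'
#' @param gm a [genotypes] object
#' @param window_snps window width in SNPs
#' @param step SNPs to advance between windows
#' @param r2_max maximum tolerated pairwise r-squared
#' @return integer vector of retained SNP indices (into `gm$snps`)
#' @export
ld_prune <- function(gm, window_snps = 50, step = 10, r2_max = 0.5) {
  assert_that(step <= window_snps, "step must not exceed window size")
  keep <- rep(TRUE, n_snp(gm))
  for (chr in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == chr)
    m <- length(idx)
    starts <- seq(1, max(1, m - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, m)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- r2_matrix(gm$dosage[, win, drop = FALSE])
      for (a in seq_len(length(win) - 1)) {
        if (!keep[win[a]]) next
        for (b in (a + 1):length(win)) {
          if (!keep[win[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[win[b]] <- FALSE
        }
      }
    }
  }
  which(keep)
}
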