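#' Identity-by-state distance matrix
#'
#' `IBS(i,j)` is the mean over shared non-missing SNPs of
#' `1 - |x_i - x_j| / 2`; the returned matrix holds distances `1 - IBS`
#' (zero diagonal, symmetric).
#'
#' @param gm a [genotypes] object
#' @return symmetric distance matrix with individual ids as dimnames and
#'   attribute `kind = "ibs"`
#' @export
ibs_matrix <- function(gm) {
  assert_that(n_ind(gm) >= 2, "need at least two individuals")
  d <- 1 - pairwise_ibs(gm$dosage)
  diag(d) <- 0
  attr(d, "kind") <- "ibs"
  d
}

# Weir-Cockerham variance components for two populations at each SNP.
# Returns per-SNP a (among-population), and d = a + b + c.
wc_components <- function(dosA, dosB) {
  nA <- colSums(!is.na(dosA))
  nB <- colSums(!is.na(dosB))
  pA <- col_freq(dosA)
  pB <- col_freq(dosB)
  hA <- colMeans(dosA == 1, na.rm = TRUE)
  hB <- colMeans(dosB == 1, na.rm = TRUE)
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = unname(a), d = unname(a + b + cc))
}

#' Weir-Cockerham FST between two populations
#'
#' Variance-components estimator theta: per SNP `a / (a + b + c)`;
#' genome-wide as the ratio of sums. Negative per-SNP values are retained
#' (not truncated). SNPs monomorphic in both populations have an undefined
#' ratio and are excluded from the sums.
#'
#' @param gm a [genotypes] object
#' @param pop_a,pop_b population labels
#' @return a list of class `fst_result`: `fst` (genome-wide), `per_snp`
#'   (tibble id, chrom, bp, a, d, fst), `n_snps_used`
#' @export
wc_fst <- function(gm, pop_a, pop_b) {
  ra <- pop_rows(gm, pop_a)
  rb <- pop_rows(gm, pop_b)
  assert_that(length(ra) >= 2 && length(rb) >= 2,
              "both populations need >= 2 individuals")
  comp <- wc_components(gm$dosage[ra, , drop = FALSE],
                        gm$dosage[rb, , drop = FALSE])
  ok <- is.finite(comp$d) & abs(comp$d) > 1e-300
  assert_that(any(ok),
              "all SNPs monomorphic across both populations (0/0)",
              "introsel_range_error")
  per <- tibble::tibble(id = gm$snps$id, chrom = gm$snps$chrom,
                        bp = gm$snps$bp, a = comp$a, d = comp$d,
                        fst = ifelse(ok, comp$a / comp$d, NA_real_))
  structure(list(fst = sum(comp$a[ok]) / sum(comp$d[ok]), per_snp = per,
                 n_snps_used = sum(ok), pops = c(pop_a, pop_b)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST(%s, %s) = %.4f (%d SNPs)\n",
              x$pops[1], x$pops[2], x$fst, x$n_snps_used))
  invisible(x)
}

#' Pairwise population FST matrix
#'
#' @param gm a [genotypes] object
#' @param pops populations to include (default all with >= 2 individuals)
#' @return symmetric matrix of genome-wide FST values, attribute
#'   `kind = "fst"`
#' @export
fst_matrix <- function(gm, pops = NULL) {
  if (is.null(pops)) {
    tab <- table(gm$individuals$population)
    pops <- names(tab)[tab >= 2]
  }
  k <- length(pops)
  assert_that(k >= 2, "need at least two populations")
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      f <- wc_fst(gm, pops[i], pops[j])$fst
      M[i, j] <- f
      M[j, i] <- f
    }
  }
  attr(M, "kind") <- "fst"
  M
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on any symmetric distance matrix (1-IBS
#' between individuals or FST between populations).
#'
#' @param dm symmetric distance matrix with dimnames
#' @return an [ape::phylo] tree
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  assert_that(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8,
                               check.attributes = FALSE)),
              "distance matrix must be symmetric")
  assert_that(nrow(dm) >= 3, "need at least three taxa")
  ape::nj(stats::as.dist(dm))
}

#' Genomic relationship matrix
#'
#' VanRaden/GCTA-style GRM: `G_ij = (1/m) sum_k (x_ik - 2 p_k)(x_jk - 2
#' p_k) / (2 p_k (1 - p_k))` over polymorphic SNPs; missing dosages are
#' replaced by the SNP mean (zero contribution). Tiny negative eigenvalues
#' from finite sampling are tolerated down to -1e-8 by construction checks
#' downstream.
#'
#' @param gm a [genotypes] object
#' @param snps optional SNP index set (e.g. an LD-pruned set)
#' @return n x n symmetric matrix with individual ids as dimnames
#' @export
grm <- function(gm, snps = NULL) {
  idx <- snps %||% seq_len(n_snp(gm))
  assert_that(length(idx) > 0, "SNP set is empty", "introsel_empty_error")
  X <- gm$dosage[, idx, drop = FALSE]
  p <- col_freq(X)
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  assert_that(ncol(X) > 0, "no polymorphic SNPs for the GRM",
              "introsel_empty_error")
  Z <- sweep(X, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  dimnames(G) <- list(gm$individuals$id, gm$individuals$id)
  G
}

#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of [grm]; monomorphic SNPs are excluded inside the
#' GRM kernel.
#'
#' @param gm a [genotypes] object
#' @param k number of components to return
#' @param snps optional SNP index set
#' @return a list of class `pca_grm`: `vectors` (n x k, ids as rownames),
#'   `values` (all n eigenvalues, descending), `var_explained` (length k)
#' @export
pca_grm <- function(gm, k = 10, snps = NULL) {
  assert_that(n_ind(gm) >= 2, "need at least two individuals")
  G <- grm(gm, snps)
  e <- eigen(G, symmetric = TRUE)
  k <- min(k, n_ind(gm))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(vec) <- gm$individuals$id
  colnames(vec) <- paste0("PC", seq_len(k))
  pos <- sum(pmax(e$values, 0))
  structure(list(vectors = vec, values = e$values,
                 var_explained = pmax(e$values[seq_len(k)], 0) /
                   max(pos, .Machine$double.eps)),
            class = "pca_grm")
}

#' @export
print.pca_grm <- function(x, ...) {
  cat(sprintf("<pca_grm> %d individuals, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$vectors), ncol(x$vectors),
              100 * x$var_explained[1],
              100 * (x$var_explained[2] %||% NA)))
  invisible(x)
}
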