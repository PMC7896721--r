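#' Phased haplotype panels
#'
#' A `haplotypes` object stores phased binary haplotypes: a `2 * n_ind x
#' n_snp` matrix of 0/1 alleles (1 = carries `allele1`), two consecutive
#' rows per individual, with the same SNP map and individual metadata as
#' [genotypes]. Used by the EHH/iHS machinery and haplotype-frequency
#' tables; the Wright-Fisher simulator emits phase directly.
#'
#' @param alleles binary matrix, two rows per individual
#' @param snps,individuals as in [genotypes]
#' @param phased logical flag; EHH-based statistics require `TRUE`
#' @return an object of class `haplotypes`
#' @export
haplotypes <- function(alleles, snps, individuals, phased = TRUE) {
  snps <- tibble::as_tibble(snps)
  individuals <- tibble::as_tibble(individuals)
  if (!"ancestral" %in% names(snps)) snps$ancestral <- NA_integer_
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  assert_that(nrow(alleles) == 2 * nrow(individuals),
              "haplotype matrix must have two rows per individual")
  assert_that(ncol(alleles) == nrow(snps),
              "haplotype columns must match SNP map")
  assert_that(all(alleles %in% 0:1), "haplotype alleles must be 0/1")
  rownames(alleles) <- paste0(rep(individuals$id, each = 2), "_",
                              rep(1:2, nrow(individuals)))
  colnames(alleles) <- snps$id
  structure(list(alleles = alleles, snps = snps, individuals = individuals,
                 phased = isTRUE(phased)),
            class = "haplotypes")
}

#' @export
print.haplotypes <- function(x, ...) {
  cat(sprintf("<haplotypes> %d haplotypes (%d individuals) x %d SNPs%s\n",
              nrow(x$alleles), nrow(x$individuals), ncol(x$alleles),
              if (x$phased) ", phased" else ", UNPHASED"))
  invisible(x)
}

#' Collapse a haplotype panel to genotype dosages
#'
#' @param panel a [haplotypes] object
#' @return a [genotypes] object (dosage = copies of `allele1`)
#' @export
as_genotypes <- function(panel) {
  odd <- seq(1, nrow(panel$alleles), by = 2)
  dos <- panel$alleles[odd, , drop = FALSE] +
    panel$alleles[odd + 1, , drop = FALSE]
  genotypes(dos, panel$snps, panel$individuals)
}
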