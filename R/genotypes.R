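#' Genotype panel objects
#'
#' A `genotypes` object is the substrate of every statistic in the package:
#' a diploid dosage matrix (individuals x SNPs, values 0/1/2 counting copies
#' of `allele1`, `NA` for missing) together with a SNP map and per-individual
#' metadata.
#'
#' @param dosage integer/numeric matrix, individuals in rows, SNPs in
#'   columns; entries in `{0, 1, 2, NA}`. Row and column names are taken
#'   from `individuals$id` and `snps$id` if absent.
#' @param snps a data frame with columns `id`, `chrom` (character), `bp`
#'   (1-based physical position, strictly increasing within chromosome) and
#'   optionally `cm` (genetic position, centimorgans), `allele1`, `allele2`
#'   (base labels) and `ancestral` (1 or 2: which allele is ancestral, `NA`
#'   if unpolarized).
#' @param individuals a data frame with columns `id`, `population` and
#'   optionally `sex` (`"male"`, `"female"` or `"unknown"`).
#'
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, snps, individuals) {
  snps <- tibble::as_tibble(snps)
  individuals <- tibble::as_tibble(individuals)
  if (!"cm" %in% names(snps)) snps$cm <- NA_real_
  if (!"allele1" %in% names(snps)) snps$allele1 <- "A"
  if (!"allele2" %in% names(snps)) snps$allele2 <- "B"
  if (!"ancestral" %in% names(snps)) snps$ancestral <- NA_integer_
  if (!"sex" %in% names(individuals)) individuals$sex <- "unknown"
  snps$chrom <- as.character(snps$chrom)
  snps$id <- as.character(snps$id)
  individuals$id <- as.character(individuals$id)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- individuals$id
  colnames(dosage) <- snps$id
  x <- structure(list(dosage = dosage, snps = snps,
                      individuals = individuals),
                 class = "genotypes")
  validate_genotypes(x)
}

validate_genotypes <- function(x) {
  assert_that(nrow(x$dosage) == nrow(x$individuals),
              "dosage rows must match individuals")
  assert_that(ncol(x$dosage) == nrow(x$snps),
              "dosage columns must match SNP table")
  assert_that(nrow(x$dosage) >= 1 && ncol(x$dosage) >= 1,
              "need at least one individual and one SNP")
  vals <- x$dosage[!is.na(x$dosage)]
  assert_that(all(vals %in% 0:2), "dosages must be 0, 1, 2 or NA")
  assert_that(!anyNA(x$individuals$population) &&
                all(nzchar(x$individuals$population)),
              "every individual needs a population label")
  assert_that(!anyDuplicated(x$individuals$id),
              "individual ids must be unique")
  by_chrom <- split(x$snps$bp, x$snps$chrom)
  ok <- all(vapply(by_chrom, function(bp) all(diff(bp) > 0), logical(1)))
  assert_that(ok, "bp must be strictly increasing within chromosome")
  x
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d individuals x %d SNPs, %d chromosome(s)\n",
              n_ind(x), n_snp(x), length(unique(x$snps$chrom))))
  pops <- table(x$individuals$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Panel dimensions
#' @param gm a `genotypes` object
#' @return integer count
#' @export
n_ind <- function(gm) nrow(gm$dosage)

#' @rdname n_ind
#' @export
n_snp <- function(gm) ncol(gm$dosage)

#' Subset a genotype panel
#'
#' @param gm a `genotypes` object
#' @param snps,individuals integer or logical index vectors (or ids)
#' @return a `genotypes` object
#' @export
subset_genotypes <- function(gm, snps = NULL, individuals = NULL) {
  si <- seq_len(n_snp(gm))
  ii <- seq_len(n_ind(gm))
  if (!is.null(snps)) {
    si <- if (is.character(snps)) match(snps, gm$snps$id) else si[snps]
  }
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) {
      match(individuals, gm$individuals$id)
    } else ii[individuals]
  }
  assert_that(!anyNA(si) && !anyNA(ii), "subset index out of range")
  genotypes(gm$dosage[ii, si, drop = FALSE], gm$snps[si, ], gm$individuals[ii, ])
}

# row indices of a population's individuals
pop_rows <- function(gm, population) {
  idx <- which(gm$individuals$population == population)
  assert_that(length(idx) > 0,
              sprintf("population '%s' not present", population))
  idx
}

#' Per-SNP allele1 frequencies
#'
#' @param gm a `genotypes` object
#' @param population optional population label; default uses all individuals
#' @return numeric vector, one frequency per SNP (`NA` where all calls missing)
#' @export
allele_freqs <- function(gm, population = NULL) {
  dos <- gm$dosage
  if (!is.null(population)) dos <- dos[pop_rows(gm, population), , drop = FALSE]
  col_freq(dos)
}

# pairwise IBS similarity matrix: mean over shared non-missing SNPs of
# 1 - |x_i - x_j| / 2
pairwise_ibs <- function(dos) {
  n <- nrow(dos)
  M <- matrix(1, n, n, dimnames = list(rownames(dos), rownames(dos)))
  if (n < 2) return(M)
  obs <- !is.na(dos)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    di <- abs(sweep(dos[rest, , drop = FALSE], 2, dos[i, ], "-"))
    sim <- rowMeans(1 - di / 2, na.rm = TRUE)
    shared <- obs[rest, , drop = FALSE] & rep(obs[i, ], each = length(rest))
    none <- rowSums(shared) == 0
    if (any(none)) {
      stop_introsel(sprintf(
        "no shared non-missing SNPs between individuals %s and %s",
        rownames(dos)[i], rownames(dos)[rest[which(none)[1]]]))
    }
    M[i, rest] <- sim
    M[rest, i] <- sim
  }
  M
}
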