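#' Read a PLINK fileset
#'
#' Reads binary `bed`/`bim`/`fam` (SNP-major, magic bytes `6c 1b 01`) or text
#' `ped`/`map` filesets into a [genotypes] object. Dosages count copies of
#' the bim A1 allele (`allele1`); the heterozygous-missing code `01` becomes
#' `NA`. The fam family id is used as the population label and fam sex codes
#' 1/2/0 map to male/female/unknown.
#'
#' @param prefix path prefix (without extension)
#' @return a [genotypes] object
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop_introsel(sprintf("no %s.bed or %s.ped found", prefix, prefix),
                  "introsel_io_error")
  }
}

read_bim <- function(path) {
  bim <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "bp", "allele1",
                                  "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "character", "character"))
  tibble::as_tibble(bim)
}

read_fam <- function(path) {
  fam <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "id", "pat", "mat", "sexcode",
                                  "pheno"))
  tibble::tibble(id = as.character(fam$id),
                 population = as.character(fam$fid),
                 sex = c("unknown", "male", "female")[
                   match(fam$sexcode, c(0, 1, 2), nomatch = 1)])
}

# 2-bit genotype codes, pairs packed LSB-first within each byte:
# 00 -> hom A1 (dosage 2), 01 -> missing, 10 -> het, 11 -> hom A2 (dosage 0)
plink_code_to_dosage <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

byte_decode_table <- function() {
  codes <- t(vapply(0:255, function(b) {
    bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
  }, integer(4)))
  matrix(plink_code_to_dosage[codes + 1L], nrow = 256)
}

read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- read_bim(paste0(prefix, ".bim"))
  fam <- read_fam(paste0(prefix, ".fam"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  assert_that(length(raw) >= 3 &&
                identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)),
              "bad bed magic bytes (expected 6c 1b 01, SNP-major)",
              "introsel_io_error")
  bps <- ceiling(n / 4)
  assert_that(length(raw) == 3 + bps * m,
              "bed size inconsistent with bim/fam row counts",
              "introsel_io_error")
  tab <- byte_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = m)
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    g <- tab[body[, j] + 1L, , drop = FALSE]
    dos[, j] <- as.vector(t(g))[seq_len(n)]
  }
  genotypes(dos, bim[, c("id", "chrom", "bp", "cm", "allele1", "allele2")],
            fam)
}

read_plink_ped <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "bp"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  assert_that(ncol(ped) == 6 + 2 * m,
              "ped column count inconsistent with map", "introsel_io_error")
  fam <- tibble::tibble(id = as.character(ped[[2]]),
                        population = as.character(ped[[1]]),
                        sex = c("unknown", "male", "female")[
                          match(ped[[5]], c(0, 1, 2), nomatch = 1)])
  n <- nrow(ped)
  dos <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (k in seq_len(m)) {
    x <- as.character(ped[[6 + 2 * k - 1]])
    y <- as.character(ped[[6 + 2 * k]])
    ok <- x != "0" & y != "0"
    alleles <- sort(unique(c(x[ok], y[ok])))
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    # A1 = minor allele (PLINK convention)
    cnt1 <- sum(x[ok] == alleles[1]) + sum(y[ok] == alleles[1])
    cnt2 <- sum(x[ok] == alleles[2]) + sum(y[ok] == alleles[2])
    if (cnt1 > cnt2) alleles <- alleles[c(2, 1)]
    a1[k] <- alleles[1]
    a2[k] <- alleles[2]
    dos[ok, k] <- (x[ok] == alleles[1]) + (y[ok] == alleles[1])
  }
  snps <- tibble::tibble(id = map$id, chrom = map$chrom, bp = map$bp,
                         cm = map$cm, allele1 = a1, allele2 = a2)
  genotypes(dos, snps, fam)
}

#' Write a PLINK fileset
#'
#' Lossless inverse of [read_plink]: emits `bed`/`bim`/`fam` (default) or
#' `ped`/`map`.
#'
#' @param gm a [genotypes] object
#' @param prefix output path prefix
#' @param format `"bed"` or `"ped"`
#' @return `prefix`, invisibly
#' @export
write_plink <- function(gm, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  dir <- dirname(prefix)
  assert_that(dir.exists(dir), sprintf("directory '%s' does not exist", dir),
              "introsel_io_error")
  sexcode <- c(male = 1L, female = 2L, unknown = 0L)[gm$individuals$sex]
  fam <- data.frame(gm$individuals$population, gm$individuals$id, 0L, 0L,
                    unname(sexcode), -9L)
  bim <- data.frame(gm$snps$chrom, gm$snps$id,
                    ifelse(is.na(gm$snps$cm), 0, gm$snps$cm),
                    gm$snps$bp, gm$snps$allele1, gm$snps$allele2)
  if (format == "bed") {
    write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    n <- n_ind(gm)
    m <- n_snp(gm)
    # dosage -> 2-bit code
    codemap <- c(`0` = 3L, `1` = 2L, `2` = 0L)
    pad <- ceiling(n / 4) * 4
    out <- raw(3 + ceiling(n / 4) * m)
    out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
    pos <- 4L
    shift <- c(1L, 4L, 16L, 64L)
    for (j in seq_len(m)) {
      g <- gm$dosage[, j]
      code <- ifelse(is.na(g), 1L, codemap[as.character(g)])
      code <- c(code, rep(0L, pad - n))
      bytes <- colSums(matrix(code * shift, nrow = 4))
      out[pos:(pos + length(bytes) - 1L)] <- as.raw(bytes)
      pos <- pos + length(bytes)
    }
    writeBin(out, paste0(prefix, ".bed"))
  } else {
    write.table(data.frame(bim[[1]], bim[[2]], bim[[3]], bim[[4]]),
                paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    al <- matrix("0", n_ind(gm), 2 * n_snp(gm))
    for (k in seq_len(n_snp(gm))) {
      g <- gm$dosage[, k]
      a1 <- gm$snps$allele1[k]
      a2 <- gm$snps$allele2[k]
      first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
      second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
      al[, 2 * k - 1] <- first
      al[, 2 * k] <- second
    }
    write.table(cbind(fam[1:5], -9, al), paste0(prefix, ".ped"),
                quote = FALSE, sep = " ", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(prefix)
}
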