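# small builders used across the suite

toy_snps <- function(m, chrom = "1", spacing = 1e5, start = 1e5) {
  tibble::tibble(id = sprintf("s%04d", seq_len(m)),
                 chrom = chrom,
                 bp = seq(start, by = spacing, length.out = m),
                 cm = seq(start, by = spacing, length.out = m) / 1e6)
}

toy_inds <- function(n, population = "POP", sex = "unknown") {
  tibble::tibble(id = sprintf("i%03d", seq_len(n)),
                 population = population, sex = sex)
}

toy_gm <- function(dos, chrom = "1", population = "POP") {
  dos <- as.matrix(dos)
  genotypes(dos, toy_snps(ncol(dos), chrom = chrom),
            toy_inds(nrow(dos), population = population))
}

# evenly spaced multi-chromosome map (for ROH fixtures)
grid_gm <- function(n_ind, n_snp_per_chrom, n_chrom = 2, spacing = 25000,
                    population = "POP") {
  snps <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    tibble::tibble(id = sprintf("c%d_s%05d", c, seq_len(n_snp_per_chrom)),
                   chrom = as.character(c),
                   bp = seq(spacing, by = spacing,
                            length.out = n_snp_per_chrom),
                   cm = seq(spacing, by = spacing,
                            length.out = n_snp_per_chrom) / 1e6)
  }))
  m <- nrow(snps)
  genotypes(matrix(1L, n_ind, m), snps, toy_inds(n_ind, population))
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
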