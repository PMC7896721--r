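#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Weir-Cockerham FST result
#'
#' @param x a `fst_result` object
#' @param ... unused
#' @return per-SNP tibble (id, chrom, bp, a, d, fst)
#' @export
tidy.fst_result <- function(x, ...) x$per_snp

#' @rdname tidy.fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(fst = x$fst, n_snps_used = x$n_snps_used,
                 pop_a = x$pops[1], pop_b = x$pops[2])
}

#' Tidy a Patterson's D result
#'
#' @param x a `dstat_result` object
#' @param ... unused
#' @return one-row tibble (d, se, z, p, n_blocks, n_snps)
#' @export
glance.dstat_result <- function(x, ...) {
  tibble::tibble(d = x$d, se = x$se, z = x$z, p = x$p,
                 n_blocks = x$n_blocks, n_snps = x$n_snps)
}

#' Tidy an f3 test result
#'
#' @param x an `f3_result` object
#' @param ... unused
#' @return one-row tibble (f3, se, z, significant, n_blocks, n_snps)
#' @export
glance.f3_result <- function(x, ...) {
  tibble::tibble(f3 = x$f3, se = x$se, z = x$z,
                 significant = x$significant, n_blocks = x$n_blocks,
                 n_snps = x$n_snps)
}

#' Tidy GRM principal components
#'
#' @param x a `pca_grm` object
#' @param ... unused
#' @return tibble: id plus one column per component
#' @export
tidy.pca_grm <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = rownames(x$vectors)),
                   tibble::as_tibble(x$vectors))
}

#' @rdname tidy.pca_grm
#' @export
glance.pca_grm <- function(x, ...) {
  tibble::tibble(component = seq_len(ncol(x$vectors)),
                 eigenvalue = x$values[seq_len(ncol(x$vectors))],
                 var_explained = x$var_explained)
}

#' Tidy a conservation grouping
#'
#' @param x a `conservation_grouping` object
#' @param ... unused
#' @return the per-individual assignment tibble
#' @export
tidy.conservation_grouping <- function(x, ...) x$assignments

#' @rdname tidy.conservation_grouping
#' @export
glance.conservation_grouping <- function(x, ...) {
  tibble::tibble(mean = x$center, sd = x$scale,
                 cut_mean = x$cutpoints["mean"],
                 cut_minus1sd = x$cutpoints["minus1sd"],
                 cut_minus2sd = x$cutpoints["minus2sd"])
}

#' Tidy an introgression window summary
#'
#' @param x a `fdm_summary` object
#' @param ... unused
#' @return the per-window tibble with z, p and significance flags
#' @export
tidy.fdm_summary <- function(x, ...) x$windows

#' @rdname tidy.fdm_summary
#' @export
glance.fdm_summary <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$windows),
                 n_significant = sum(x$windows$significant),
                 threshold = x$threshold,
                 genome_fraction_positive = x$genome_fraction_positive,
                 pi_boost_positive = x$pi_boost_positive,
                 pi_boost_significant = x$pi_boost_significant)
}
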