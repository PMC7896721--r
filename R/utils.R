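#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor median pchisq pnorm qchisq qnorm quantile rbinom
#'   rnorm rpois runif sd var setNames optimize
#' @importFrom utils head tail read.table write.table
NULL

# integer-safe ceiling guard against representation error (e.g. 18.000000001)
ceil_safe <- function(x) as.integer(ceiling(x - 1e-9))

stop_introsel <- function(msg, class = "introsel_error") {
  abort(msg, class = c(class, "introsel_error"))
}

assert_that <- function(ok, msg, class = "introsel_error") {
  if (!isTRUE(ok)) stop_introsel(msg, class)
  invisible(TRUE)
}

# allele frequency (allele coded by dosage counts) per SNP, missing skipped
col_freq <- function(dos) {
  n <- colSums(!is.na(dos))
  s <- colSums(dos, na.rm = TRUE)
  unname(ifelse(n > 0, s / (2 * n), NA_real_))
}

# minor allele frequency per SNP
col_maf <- function(dos) {
  p <- col_freq(dos)
  pmin(p, 1 - p)
}

# squared Pearson correlation between dosage columns, pairwise complete
r2_matrix <- function(dos) {
  suppressWarnings(cor(dos, use = "pairwise.complete.obs"))^2
}

# merge overlapping/adjacent [start, end] intervals (1-based inclusive)
merge_intervals <- function(df, gap = 0L) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      j <- nrow(out)
      if (df$chrom[i] == out$chrom[j] && df$start[i] <= out$end[j] + gap + 1) {
        out$end[j] <- max(out$end[j], df$end[i])
      } else {
        out <- rbind(out, df[i, , drop = FALSE])
      }
    }
  }
  tibble::as_tibble(out)
}
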