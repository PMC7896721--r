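# REML profile log-likelihood pieces for y = X b + g + e with
# Var(y) = Vg (K + delta I), evaluated in the eigenbasis of K.
reml_fit <- function(yt, Xt, d, delta) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- d + delta
  Xw <- Xt / v
  XtWX <- crossprod(Xt, Xw)
  XtWy <- crossprod(Xw, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / v)
  vg <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * vg) + (n - p) + sum(log(v)) +
                  2 * sum(log(diag(ch))))
  list(ll = ll, beta = as.vector(beta), vg = vg,
       cov_unscaled = chol2inv(ch))
}

profile_delta <- function(yt, Xt, d, grid = 10^seq(-4, 4, length.out = 41)) {
  lls <- vapply(grid, function(del) {
    f <- reml_fit(yt, Xt, d, del)
    if (is.null(f)) -Inf else f$ll
  }, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(function(ld) {
    f <- reml_fit(yt, Xt, d, exp(ld))
    if (is.null(f)) -Inf else f$ll
  }, interval = log(c(lo, hi)), maximum = TRUE)
  exp(opt$maximum)
}

#' Single-SNP linear mixed-model association
#'
#' Fits `y = W a + x b + u + e` with `u ~ N(0, Vg K)` per SNP: the kinship
#' matrix is eigendecomposed once, the variance ratio `delta = Ve / Vg` is
#' profiled by restricted maximum likelihood on a log grid with local
#' refinement, and each SNP's effect is tested with a Wald chi-square
#' `(b / se)^2` on 1 df. Missing dosages at the tested SNP are mean-imputed
#' for the association stage only.
#'
#' @param gm a [genotypes] object
#' @param pheno tibble with columns `id` and `trait` (see
#'   [simulate_phenotype]); rows are matched to the panel by id
#' @param covariates optional data frame of fixed-effect columns (plus the
#'   intercept, always included); factors are expanded via
#'   [stats::model.matrix]
#' @param kinship n x n GRM (default: [grm] on all SNPs); must be
#'   symmetric positive semi-definite up to -1e-8
#' @param snps SNP ids or indices to test (default all)
#' @return tibble of class `lmm_result`: id, chrom, bp, beta, se, chisq,
#'   p, vg, ve, delta
#' @export
lmm_assoc <- function(gm, pheno, covariates = NULL, kinship = NULL,
                      snps = NULL) {
  ids <- gm$individuals$id
  ord <- match(ids, pheno$id)
  assert_that(!anyNA(ord), "every genotyped individual needs a phenotype")
  y <- pheno$trait[ord]
  n <- length(y)
  W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cdf <- as.data.frame(covariates)[ord, , drop = FALSE]
    Wc <- stats::model.matrix(~ ., data = cdf)
    W <- cbind(1, Wc[, -1, drop = FALSE])
    colnames(W)[1] <- "intercept"
  }
  assert_that(qr(W)$rank == ncol(W), "singular covariate matrix")
  K <- kinship %||% grm(gm)
  assert_that(isTRUE(all.equal(K, t(K), tolerance = 1e-8,
                               check.attributes = FALSE)),
              "kinship must be symmetric")
  ek <- eigen(K, symmetric = TRUE)
  assert_that(min(ek$values) > -1e-6 * max(abs(ek$values), 1),
              "kinship is not positive semi-definite")
  d <- pmax(ek$values, 0)
  U <- ek$vectors
  yt <- as.vector(crossprod(U, y))
  Wt <- crossprod(U, W)
  idx <- if (is.null(snps)) seq_len(n_snp(gm)) else if (is.character(snps))
    match(snps, gm$snps$id) else snps
  assert_that(!anyNA(idx), "unknown SNP in test set")
  assert_that(n > ncol(W) + 1, "more fixed effects than samples")
  res <- purrr::map_dfr(idx, function(k) {
    x <- gm$dosage[, k]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (var(x) < 1e-12) {
      return(tibble::tibble(id = gm$snps$id[k], chrom = gm$snps$chrom[k],
                            bp = gm$snps$bp[k], beta = NA_real_,
                            se = NA_real_, chisq = NA_real_, p = NA_real_,
                            vg = NA_real_, ve = NA_real_,
                            delta = NA_real_))
    }
    Xt <- cbind(Wt, crossprod(U, x))
    delta <- profile_delta(yt, Xt, d)
    f <- reml_fit(yt, Xt, d, delta)
    j <- ncol(Xt)
    se <- sqrt(f$vg * f$cov_unscaled[j, j])
    chisq <- (f$beta[j] / se)^2
    tibble::tibble(id = gm$snps$id[k], chrom = gm$snps$chrom[k],
                   bp = gm$snps$bp[k], beta = f$beta[j], se = se,
                   chisq = chisq,
                   p = pchisq(chisq, df = 1, lower.tail = FALSE),
                   vg = f$vg, ve = f$vg * delta, delta = delta)
  })
  class(res) <- c("lmm_result", class(res))
  attr(res, "n") <- n
  res
}

# REML log-likelihood at a given delta for one SNP model (exposed for
# optimizer sanity checks in the test-suite)
reml_loglik <- function(gm, pheno, kinship, snp, delta,
                        covariates = NULL) {
  ids <- gm$individuals$id
  y <- pheno$trait[match(ids, pheno$id)]
  W <- matrix(1, length(y), 1)
  if (!is.null(covariates)) {
    cdf <- as.data.frame(covariates)[match(ids, pheno$id), , drop = FALSE]
    W <- stats::model.matrix(~ ., data = cdf)
  }
  ek <- eigen(kinship, symmetric = TRUE)
  U <- ek$vectors
  x <- gm$dosage[, snp]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  f <- reml_fit(as.vector(crossprod(U, y)),
                cbind(crossprod(U, W), crossprod(U, x)),
                pmax(ek$values, 0), delta)
  f$ll
}
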