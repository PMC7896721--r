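#' Demographic scenario for the admixture simulator
#'
#' Describes a four-population history on the topology (((P1, P2), P3), O):
#' an outgroup O splits first, then a donor lineage P3 (e.g. European
#' commercial breeds), and finally the native pair P1 and P2, with a
#' single admixture pulse from P3 into the recipient P2. Defaults emulate
#' a conserved indigenous herd (P2) of ~200 breeding animals that received
#' a recent European pulse of about one quarter of its ancestry; P1 is a
#' large, closely related native reference panel (recent breed-level
#' divergence), so that supervised ancestry against P1/P3 reference
#' frequencies is close to unbiased, while the donor split is deep.
#'
#' @param n_snps total SNP count across chromosomes
#' @param n_chrom number of chromosomes (equal SNP share per chromosome)
#' @param chrom_length_bp physical length of each chromosome
#' @param recomb_rate recombination rate, cM/Mb (uniform map)
#' @param pop_sizes named diploid census sizes for O, P1, P2, P3;
#'   ancestral lineages may be sized explicitly via entries `P12`, `P123`
#'   and `ROOT`, otherwise a merged lineage uses the largest size among
#'   its descendants
#' @param split_gens named generations before present of the O split, the
#'   P3 split and the P1/P2 split; must satisfy O > P3 > P12 > admix_gen
#' @param admix_gen generation (before present) at which the admixed P2
#'   cohort is born
#' @param admix_frac pulse fraction: probability that each parent of a P2
#'   individual born at `admix_gen` is drawn from P3
#' @param sample_sizes named number of diploids sampled per population at
#'   present
#' @param seed optional integer seed
#' @return a list of class `demography`
#' @export
demography <- function(n_snps = 2000, n_chrom = 2, chrom_length_bp = 1e8,
                       recomb_rate = 1.0,
                       pop_sizes = c(O = 80, P1 = 400, P2 = 200,
                                     P3 = 150, P12 = 200, P123 = 200,
                                     ROOT = 150),
                       split_gens = c(O = 100, P3 = 60, P12 = 6),
                       admix_gen = 4, admix_frac = 0.25,
                       sample_sizes = c(O = 30, P1 = 150, P2 = 60,
                                        P3 = 60),
                       seed = NULL) {
  assert_that(all(c("O", "P1", "P2", "P3") %in% names(pop_sizes)),
              "pop_sizes needs O, P1, P2, P3")
  assert_that(all(c("O", "P3", "P12") %in% names(split_gens)),
              "split_gens needs O, P3, P12")
  assert_that(split_gens["O"] > split_gens["P3"] &&
                split_gens["P3"] > split_gens["P12"] &&
                split_gens["P12"] > admix_gen && admix_gen >= 0,
              "split order must satisfy O > P3 > P12 > admix_gen >= 0")
  assert_that(admix_frac >= 0 && admix_frac <= 1,
              "admix_frac must lie in [0, 1]")
  assert_that(all(sample_sizes <= pop_sizes[names(sample_sizes)]),
              "cannot sample more diploids than the census size")
  structure(list(n_snps = n_snps, n_chrom = n_chrom,
                 chrom_length_bp = chrom_length_bp,
                 recomb_rate = recomb_rate, pop_sizes = pop_sizes,
                 split_gens = split_gens, admix_gen = admix_gen,
                 admix_frac = admix_frac, sample_sizes = sample_sizes,
                 seed = seed),
            class = "demography")
}

# random SNP map: positions uniform per chromosome, cM from the uniform rate
make_snp_map <- function(n_snps, n_chrom, chrom_length_bp, recomb_rate) {
  per <- rep(n_snps %/% n_chrom, n_chrom)
  per[seq_len(n_snps %% n_chrom)] <- per[seq_len(n_snps %% n_chrom)] + 1
  maps <- lapply(seq_len(n_chrom), function(c) {
    bp <- sort(sample.int(chrom_length_bp, per[c]))
    tibble::tibble(chrom = as.character(c), bp = bp,
                   cm = bp * recomb_rate / 1e6)
  })
  map <- dplyr::bind_rows(maps)
  map$id <- sprintf("snp%05d", seq_len(nrow(map)))
  map[, c("id", "chrom", "bp", "cm")]
}

# Recombination masks for one cohort of gametes, SNP-major (m x n_gam).
# Per chromosome each gamete gets an independent start phase (independent
# assortment) and Poisson-distributed crossovers on the centimorgan map;
# the mask value (0/1) selects the first or second parental haplotype.
# All gametes of a generation are built in one vectorized pass: crossover
# break points are pooled, ordered by (gamete, position), and expanded
# into alternating-phase segments with a single rep(); two crossovers in
# the same inter-SNP interval yield zero-length segments and so cancel.
step_masks <- function(mapinfo, n_gam) {
  M <- matrix(0L, mapinfo$m, n_gam)
  for (c in seq_along(mapinfo$chrom_idx)) {
    idx <- mapinfo$chrom_idx[[c]]
    m_c <- length(idx)
    phase0 <- rbinom(n_gam, 1L, 0.5)
    ncx <- rpois(n_gam, mapinfo$chrom_morgans[c])
    tot <- sum(ncx)
    if (tot == 0L) {
      M[idx, ] <- rep(phase0, each = m_c)
      next
    }
    gam <- rep.int(seq_len(n_gam), ncx)
    pos <- runif(tot, mapinfo$cm_lo[c], mapinfo$cm_hi[c])
    cut <- findInterval(pos, mapinfo$cm[idx])
    keep <- cut > 0L & cut < m_c
    gam <- gam[keep]
    cut <- cut[keep]
    o <- order(gam, cut)
    gam <- gam[o]
    cut <- cut[o]
    k_g <- tabulate(gam, n_gam)
    off <- c(0L, cumsum(k_g))[seq_len(n_gam)]
    rank <- seq_along(gam) - off[gam]
    prev <- ifelse(rank > 1L, c(0L, cut)[seq_along(cut)], 0L)
    pos_last <- cumsum(k_g)
    lastcut <- integer(n_gam)
    has <- k_g > 0L
    lastcut[has] <- cut[pos_last[has]]
    seg_gam <- c(gam, seq_len(n_gam))
    seg_idx <- c(rank, k_g + 1L)
    seg_len <- c(cut - prev, m_c - lastcut)
    seg_phase <- (phase0[seg_gam] + seg_idx - 1L) %% 2L
    o3 <- order(seg_gam, seg_idx)
    M[idx, ] <- rep.int(seg_phase[o3], seg_len[o3])
  }
  M
}

# Produce all offspring gametes of one pool in a vectorized pass. Pools
# are SNP-major: H and A are m x (2 * N) with two haplotype columns per
# diploid. pulse_pool: optional donor pool from which each parent is
# drawn with probability pulse_p. Ancestry matrices are only propagated
# once they exist (post-pulse), keeping the long pre-pulse epochs cheap.
make_offspring <- function(par_pool, n_off, mapinfo, pulse_pool = NULL,
                           pulse_p = 0) {
  m <- mapinfo$m
  n_gam <- 2L * n_off
  M <- step_masks(mapinfo, n_gam)
  src_pulse <- if (!is.null(pulse_pool) && pulse_p > 0) {
    runif(n_gam) < pulse_p
  } else rep(FALSE, n_gam)
  track <- !is.null(par_pool$A) ||
    (!is.null(pulse_pool) && !is.null(pulse_pool$A))
  H <- matrix(0L, m, n_gam)
  A <- if (track) matrix(0L, m, n_gam) else NULL
  snp_off <- seq_len(m)
  for (use_pulse in unique(src_pulse)) {
    cols <- which(src_pulse == use_pulse)
    pool <- if (use_pulse) pulse_pool else par_pool
    par <- sample.int(ncol(pool$H) / 2, length(cols), replace = TRUE)
    # element (k, g) reads haplotype column 2*par[g]-1 + mask, row k
    lin <- rep((2L * par - 2L) * m, each = m) +
      as.vector(M[, cols, drop = FALSE]) * m + snp_off
    H[, cols] <- pool$H[lin]
    if (track) A[, cols] <- pool$A[lin]
  }
  list(H = H, A = A)
}

build_mapinfo <- function(map) {
  chroms <- unique(map$chrom)
  cm_lo <- vapply(chroms, function(c) min(map$cm[map$chrom == c]),
                  numeric(1))
  cm_hi <- vapply(chroms, function(c) max(map$cm[map$chrom == c]),
                  numeric(1))
  list(m = nrow(map), cm = map$cm,
       chrom_idx = lapply(chroms, function(c) which(map$chrom == c)),
       cm_lo = cm_lo, cm_hi = cm_hi,
       chrom_morgans = (cm_hi - cm_lo) / 100)
}

pool_lineage <- c(O = "ROOT", P123 = "ROOT", P3 = "P123", P12 = "P123",
                  P1 = "P12", P2 = "P12")

pools_at_gen <- function(t, sg) {
  if (t >= sg["O"]) "ROOT"
  else if (t >= sg["P3"]) c("O", "P123")
  else if (t >= sg["P12"]) c("O", "P3", "P12")
  else c("O", "P1", "P2", "P3")
}

merged_size <- function(name, pop_sizes) {
  if (name %in% names(pop_sizes)) return(unname(pop_sizes[[name]]))
  members <- switch(name,
                    ROOT = c("O", "P1", "P2", "P3"),
                    P123 = c("P1", "P2", "P3"),
                    P12 = c("P1", "P2"),
                    name)
  max(pop_sizes[members])
}

#' Forward Wright-Fisher simulation with an admixture pulse
#'
#' Simulates diploid populations forward in time on the (((P1, P2), P3), O)
#' topology with recombination (Poisson crossovers on the cM map,
#' independent assortment between chromosomes). All polymorphism is
#' standing ancestral variation: founder haplotypes draw each allele
#' independently with frequencies Uniform(0.05, 0.95), and no new mutations
#' arise. At the pulse generation each parent of a P2 newborn is drawn from
#' P3 with probability `admix_frac`; local donor ancestry is tracked
#' exactly through every meiosis and reported as truth tracts.
#'
#' @param dp a [demography] object
#' @return a list with `panel` (phased [haplotypes]), `genotypes`
#'   ([genotypes]; `ancestral` column set to the outgroup major allele),
#'   and `tracts` (tibble: id, hap, chrom, start_bp, end_bp, donor, one row
#'   per maximal donor-ancestry run over the sampled SNPs)
#' @export
simulate_panel <- function(dp) {
  if (!is.null(dp$seed)) set.seed(dp$seed)
  map <- make_snp_map(dp$n_snps, dp$n_chrom, dp$chrom_length_bp,
                      dp$recomb_rate)
  mapinfo <- build_mapinfo(map)
  m <- nrow(map)

  sg <- dp$split_gens
  p_founder <- runif(m, 0.05, 0.95)
  n_root <- merged_size("ROOT", dp$pop_sizes)
  pools <- list(ROOT = list(
    H = matrix(rbinom(2 * n_root * m, 1L, p_founder), m, 2 * n_root),
    A = NULL))

  for (t_child in seq(sg["O"] - 1, 0)) {
    child_names <- pools_at_gen(t_child, sg)
    parent_names <- pools_at_gen(t_child + 1, sg)
    if (t_child == dp$admix_gen && dp$admix_frac > 0) {
      # mark donor material in the parental generation; ancestry matrices
      # come into existence here and propagate through every later meiosis
      for (nm in parent_names) {
        pools[[nm]]$A <- matrix(if (nm == "P3") 1L else 0L,
                                m, ncol(pools[[nm]]$H))
      }
    }
    nxt <- list()
    for (nm in child_names) {
      par_nm <- if (nm %in% parent_names) nm else pool_lineage[[nm]]
      n_off <- merged_size(nm, dp$pop_sizes)
      if (nm == "P2" && t_child == dp$admix_gen && dp$admix_frac > 0) {
        nxt[[nm]] <- make_offspring(pools[[par_nm]], n_off, mapinfo,
                                    pulse_pool = pools[["P3"]],
                                    pulse_p = dp$admix_frac)
      } else {
        nxt[[nm]] <- make_offspring(pools[[par_nm]], n_off, mapinfo)
      }
    }
    pools <- nxt
  }

  # sample diploids at present; haplotypes become row-major (2n x m)
  samp <- lapply(c("O", "P1", "P2", "P3"), function(nm) {
    k <- dp$sample_sizes[[nm]]
    pick <- sort(sample.int(ncol(pools[[nm]]$H) / 2, k))
    hap_cols <- as.vector(rbind(2 * pick - 1, 2 * pick))
    A <- pools[[nm]]$A %||% matrix(0L, m, ncol(pools[[nm]]$H))
    list(pop = nm, H = t(pools[[nm]]$H[, hap_cols, drop = FALSE]),
         A = t(A[, hap_cols, drop = FALSE]))
  })
  H <- do.call(rbind, lapply(samp, `[[`, "H"))
  A <- do.call(rbind, lapply(samp, `[[`, "A"))
  pops <- unlist(lapply(samp, function(s) rep(s$pop, nrow(s$H) / 2)))
  ids <- sprintf("%s_%03d", pops, unlist(lapply(samp, function(s)
    seq_len(nrow(s$H) / 2))))
  individuals <- tibble::tibble(
    id = ids, population = pops,
    sex = ifelse(rbinom(length(ids), 1, 0.5) == 1, "male", "female"))

  # ancestral allele = outgroup-sample major allele
  o_rows <- which(rep(pops, each = 2) == "O")
  fO <- colMeans(H[o_rows, , drop = FALSE])
  snps <- tibble::tibble(id = map$id, chrom = map$chrom, bp = map$bp,
                         cm = map$cm, allele1 = "A", allele2 = "B",
                         ancestral = ifelse(fO >= 0.5, 1L, 2L))
  panel <- haplotypes(H, snps, individuals, phased = TRUE)
  gm <- as_genotypes(panel)

  # donor tracts are reported for the recipient's samples; the donor
  # population itself trivially carries its own label everywhere
  p2 <- which(individuals$population == "P2")
  tracts <- extract_tracts(
    A[as.vector(rbind(2 * p2 - 1, 2 * p2)), , drop = FALSE],
    individuals[p2, ], snps)
  list(panel = panel, genotypes = gm, tracts = tracts)
}

# maximal runs of donor ancestry per sampled haplotype
extract_tracts <- function(A, individuals, snps) {
  out <- list()
  for (i in seq_len(nrow(individuals))) {
    for (h in 1:2) {
      a <- A[2 * i - 2 + h, ]
      if (!any(a == 1L)) next
      for (chr in unique(snps$chrom)) {
        idx <- which(snps$chrom == chr)
        r <- rle(a[idx] == 1L)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        w <- which(r$values)
        if (length(w) == 0) next
        out[[length(out) + 1]] <- tibble::tibble(
          id = individuals$id[i], hap = h, chrom = chr,
          start_bp = snps$bp[idx[starts[w]]],
          end_bp = snps$bp[idx[ends[w]]], donor = "P3")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(id = character(), hap = integer(),
                          chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), donor = character()))
  }
  dplyr::bind_rows(out)
}

#' Truth donor-ancestry fraction per individual
#'
#' Fraction of sampled SNP positions carrying donor ancestry, computed from
#' simulator truth tracts (bp-weighted by SNP spans would differ only by
#' map irregularity; SNP-count weighting matches how the frequency-based
#' statistics see the data).
#'
#' @param tracts tibble from [simulate_panel]
#' @param gm the matching [genotypes] object
#' @param population population to summarize (default `"P2"`)
#' @return tibble: id, donor_fraction
#' @export
donor_fraction <- function(tracts, gm, population = "P2") {
  ids <- gm$individuals$id[gm$individuals$population == population]
  m <- n_snp(gm)
  frac <- vapply(ids, function(i) {
    tr <- tracts[tracts$id == i, , drop = FALSE]
    if (nrow(tr) == 0) return(0)
    cov <- 0L
    for (r in seq_len(nrow(tr))) {
      idx <- gm$snps$chrom == tr$chrom[r] & gm$snps$bp >= tr$start_bp[r] &
        gm$snps$bp <= tr$end_bp[r]
      cov <- cov + sum(idx)
    }
    cov / (2 * m)
  }, numeric(1))
  tibble::tibble(id = ids, donor_fraction = unname(frac))
}

#' Single-population Wright-Fisher panel
#'
#' Constant-size neutral control without splits or admixture, used for null
#' calibrations (LD-based Ne recovery, EigenGWAS inflation, association
#' type-I error).
#'
#' @param n_ind diploids sampled at present
#' @param pop_size constant diploid census size
#' @param generations generations simulated after the founder draw
#' @param n_snps,n_chrom,chrom_length_bp,recomb_rate map parameters as in
#'   [demography]
#' @param seed optional integer seed
#' @return a list with `panel` and `genotypes`
#' @export
simulate_population <- function(n_ind, pop_size = 100, generations = 60,
                                n_snps = 1000, n_chrom = 2,
                                chrom_length_bp = 1e8, recomb_rate = 1.0,
                                seed = NULL) {
  assert_that(n_ind <= pop_size, "cannot sample more than the census size")
  if (!is.null(seed)) set.seed(seed)
  map <- make_snp_map(n_snps, n_chrom, chrom_length_bp, recomb_rate)
  mapinfo <- build_mapinfo(map)
  m <- nrow(map)
  p <- runif(m, 0.05, 0.95)
  pool <- list(H = matrix(rbinom(2 * pop_size * m, 1L, p), m,
                          2 * pop_size),
               A = NULL)
  for (g in seq_len(generations)) {
    pool <- make_offspring(pool, pop_size, mapinfo)
  }
  pick <- sort(sample.int(pop_size, n_ind))
  hap_cols <- as.vector(rbind(2 * pick - 1, 2 * pick))
  H <- t(pool$H[, hap_cols, drop = FALSE])
  individuals <- tibble::tibble(
    id = sprintf("IND_%03d", seq_len(n_ind)), population = "POP",
    sex = ifelse(rbinom(n_ind, 1, 0.5) == 1, "male", "female"))
  snps <- tibble::tibble(id = map$id, chrom = map$chrom, bp = map$bp,
                         cm = map$cm, allele1 = "A", allele2 = "B",
                         ancestral = NA_integer_)
  panel <- haplotypes(H, snps, individuals)
  list(panel = panel, genotypes = as_genotypes(panel))
}

#' Unstructured Hardy-Weinberg panel
#'
#' Independent HWE draws at every SNP (no LD, no relatedness): the exact
#' "unrelated panmictic" null used for false-positive guards and
#' genomic-control calibration. Allele frequencies are Uniform over
#' `freq_range` (the default gives mean heterozygosity ~0.36).
#'
#' @param n_ind individuals
#' @param n_snps SNPs
#' @param freq_range allele1 frequency range
#' @param n_chrom chromosomes (equal SNP share)
#' @param chrom_length_bp chromosome length for the bp map
#' @param seed optional integer seed
#' @return a [genotypes] object (single population `"POP"`)
#' @export
simulate_hwe_panel <- function(n_ind, n_snps, freq_range = c(0.05, 0.95),
                               n_chrom = 1, chrom_length_bp = 1e8,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- make_snp_map(n_snps, n_chrom, chrom_length_bp, 1.0)
  p <- runif(n_snps, freq_range[1], freq_range[2])
  dos <- matrix(rbinom(n_ind * n_snps, 2L, rep(p, each = n_ind)), n_ind,
                n_snps)
  genotypes(dos,
            tibble::tibble(id = map$id, chrom = map$chrom, bp = map$bp,
                           cm = map$cm),
            tibble::tibble(id = sprintf("IND_%04d", seq_len(n_ind)),
                           population = "POP",
                           sex = ifelse(rbinom(n_ind, 1, 0.5) == 1,
                                        "male", "female")))
}

#' Simulate a quantitative phenotype on a genotype panel
#'
#' y = sum(x_k beta_k) + g + e with polygenic g drawn from N(0, GRM * s2g)
#' and the environmental variance set so that the realized broad genetic
#' share Var(Xb + g) / Var(y) equals `h2`.
#'
#' @param gm a [genotypes] object
#' @param causal named numeric vector: names are SNP ids (or coercible
#'   indices), values are allelic effects in trait units; `NULL` for a pure
#'   polygenic trait
#' @param h2 target heritability in [0, 1]
#' @param seed optional integer seed
#' @param covariates if `TRUE`, add a 2-level batch effect (0.5 units) and
#'   an age covariate (slope 0.01 units/day) to the table and the phenotype
#' @return tibble: id, trait (+ batch, age when requested)
#' @export
simulate_phenotype <- function(gm, causal = NULL, h2 = 0.3, seed = NULL,
                               covariates = FALSE) {
  assert_that(h2 >= 0 && h2 <= 1, "h2 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_ind(gm)
  xb <- rep(0, n)
  if (!is.null(causal) && length(causal) > 0) {
    assert_that(!is.null(names(causal)),
                "causal must be named by SNP id or index")
    idx <- if (all(names(causal) %in% gm$snps$id)) {
      match(names(causal), gm$snps$id)
    } else {
      suppressWarnings(as.integer(names(causal)))
    }
    assert_that(all(idx >= 1 & idx <= n_snp(gm)),
                "causal SNP index out of range")
    X <- gm$dosage[, idx, drop = FALSE]
    X[is.na(X)] <- 0L
    xb <- as.vector(X %*% unname(causal))
  }
  g <- rep(0, n)
  if (h2 > 0) {
    K <- grm(gm)
    ek <- eigen(K, symmetric = TRUE)
    g <- as.vector(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n)))
  }
  signal <- xb + g
  v_sig <- var(signal)
  if (h2 == 0 || v_sig < 1e-12) {
    y <- signal + rnorm(n)
  } else {
    y <- signal + rnorm(n, sd = sqrt(v_sig * (1 - h2) / h2))
  }
  out <- tibble::tibble(id = gm$individuals$id, trait = y)
  if (covariates) {
    batch <- sample(c("b1", "b2"), n, replace = TRUE)
    age <- round(runif(n, 180, 400))
    out$trait <- out$trait + 0.5 * (batch == "b2") + 0.01 * (age - 290)
    out$batch <- batch
    out$age <- age
  }
  out
}

#' Plant runs of homozygosity into a fixture panel
#'
#' Regenerates the panel's genotypes at Hardy-Weinberg equilibrium with
#' allele frequencies drawn Uniform(0.2, 0.8) (per-SNP heterozygosity at
#' least ~0.32, so spurious long homozygous runs are vanishingly rare),
#' then forces each planned interval's SNPs homozygous for the planned
#' individual. Two heterozygous sentinel SNPs are placed immediately
#' outside each planted interval so the recovered run boundaries are
#' identifiable rather than extending into chance homozygous flanks.
#'
#' @param gm a [genotypes] object supplying the map and individual roster
#' @param plan tibble with columns id, chrom, start_bp, end_bp; intervals
#'   for one individual must not overlap
#' @param seed optional integer seed
#' @return list with `genotypes` (new panel) and `truth` (the plan,
#'   augmented with the planted SNP count and realized SNP-span bounds)
#' @export
plant_roh <- function(gm, plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- tibble::as_tibble(plan)
  plan$chrom <- as.character(plan$chrom)
  for (i in unique(plan$id)) {
    iv <- plan[plan$id == i, ]
    for (chr in unique(iv$chrom)) {
      v <- iv[iv$chrom == chr, ]
      v <- v[order(v$start_bp), ]
      if (nrow(v) > 1 && any(v$start_bp[-1] <= v$end_bp[-nrow(v)])) {
        stop_introsel(sprintf("overlapping planted intervals for '%s'", i))
      }
    }
  }
  n <- n_ind(gm)
  m <- n_snp(gm)
  q <- runif(m, 0.2, 0.8)
  dos <- matrix(rbinom(n * m, 2L, rep(q, each = n)), n, m)
  truth <- plan
  truth$n_snps <- NA_integer_
  truth$span_start_bp <- NA_real_
  truth$span_end_bp <- NA_real_
  for (r in seq_len(nrow(plan))) {
    i <- match(plan$id[r], gm$individuals$id)
    assert_that(!is.na(i), sprintf("unknown individual '%s'", plan$id[r]))
    on_chr <- which(gm$snps$chrom == plan$chrom[r])
    assert_that(length(on_chr) > 0 &&
                  plan$start_bp[r] >= 1 &&
                  plan$end_bp[r] >= plan$start_bp[r],
                "planted interval outside chromosome bounds")
    inside <- on_chr[gm$snps$bp[on_chr] >= plan$start_bp[r] &
                       gm$snps$bp[on_chr] <= plan$end_bp[r]]
    dos[i, inside] <- 2L * rbinom(length(inside), 1L, q[inside])
    # heterozygous sentinels delimit the run
    before <- on_chr[gm$snps$bp[on_chr] < plan$start_bp[r]]
    after <- on_chr[gm$snps$bp[on_chr] > plan$end_bp[r]]
    dos[i, tail(before, 2)] <- 1L
    dos[i, head(after, 2)] <- 1L
    truth$n_snps[r] <- length(inside)
    truth$span_start_bp[r] <- if (length(inside)) min(gm$snps$bp[inside]) else NA
    truth$span_end_bp[r] <- if (length(inside)) max(gm$snps$bp[inside]) else NA
  }
  list(genotypes = genotypes(dos, gm$snps, gm$individuals), truth = truth)
}
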