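#' Assemble a pipeline configuration
#'
#' A run configuration bundles the input source (a PLINK prefix or a
#' [demography] to simulate from), the quartet population assignment for
#' the introgression stage, the ancestry lineages, and per-stage parameter
#' blocks. `yaml` files with the same field names are accepted via
#' [read_config].
#'
#' @param input either a list `list(plink = prefix)` or `list(demography =
#'   demography(...))`
#' @param pops named character vector assigning `P1`, `P2`, `P3`, `O` to
#'   population labels; `P2` is the recipient/target population
#' @param lineages named character vector: ancestry reference lineages
#'   (e.g. `c(CN = "P1", EU = "P3")`); the first is the "native" lineage
#'   used for conservation tiers
#' @param qc a [qc_params] block
#' @param roh a [roh_params] block
#' @param window_snps,step_snps f_dM window geometry
#' @param seed root seed; per-stage streams are derived from it
#' @param out_dir optional directory: stage tables are written as TSV and
#'   the summary as JSON
#' @return list of class `run_config`
#' @export
run_config <- function(input, pops = c(P1 = "P1", P2 = "P2", P3 = "P3",
                                       O = "O"),
                       lineages = c(CN = "P1", EU = "P3"),
                       qc = qc_params(), roh = roh_params(),
                       window_snps = 10, step_snps = 2, seed = 1,
                       out_dir = NULL) {
  assert_that(is.list(input) &&
                (!is.null(input$plink) || !is.null(input$demography)),
              "input must provide a plink prefix or a demography")
  assert_that(all(c("P1", "P2", "P3", "O") %in% names(pops)),
              "pops must assign P1, P2, P3 and O")
  assert_that(length(lineages) >= 2, "need at least two ancestry lineages")
  structure(list(input = input, pops = pops, lineages = lineages, qc = qc,
                 roh = roh, window_snps = window_snps,
                 step_snps = step_snps, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path a yaml file with fields mirroring [run_config]; demography
#'   parameters go under `input: demography:`
#' @return a `run_config` list
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(input$demography)) {
    dp <- input$demography
    for (nm in c("pop_sizes", "split_gens", "sample_sizes")) {
      if (!is.null(dp[[nm]])) dp[[nm]] <- unlist(dp[[nm]])
    }
    input$demography <- do.call(demography, dp)
  }
  run_config(input = input,
             pops = unlist(y$pops %||% c(P1 = "P1", P2 = "P2", P3 = "P3",
                                         O = "O")),
             lineages = unlist(y$lineages %||% c(CN = "P1", EU = "P3")),
             qc = do.call(qc_params, y$qc %||% list()),
             roh = do.call(roh_params, y$roh %||% list()),
             window_snps = y$window_snps %||% 10,
             step_snps = y$step_snps %||% 2,
             seed = y$seed %||% 1,
             out_dir = y$out_dir)
}

#' Run the full analysis workflow
#'
#' Executes every stage in dependency order on one panel: QC, diversity
#' (He/Ho, LD decay, Ne, SNP-based F), ROH and F_ROH, structure (PCA,
#' IBS/NJ, supervised ancestry, conservation tiers, families), selection
#' scans (ROH incidence, iHS when phase is available, EigenGWAS, >= 2
#' method overlap), introgression (f3, Patterson's D, f_dM/dxy/pi
#' windows), and - when a phenotype is simulated or supplied - LMM
#' association. Identical config + seed gives identical output.
#'
#' @param cfg a `run_config` list
#' @param pheno optional phenotype tibble for the association stage; when
#'   absent and the input is simulated, a phenotype with one causal SNP is
#'   generated
#' @return a list of stage results plus `summary` (a flat list of headline
#'   numbers); writes `summary.json` and stage TSVs under `out_dir` when
#'   configured
#' @export
run_all <- function(cfg, pheno = NULL) {
  assert_that(inherits(cfg, "run_config"), "cfg must come from run_config()")
  set.seed(cfg$seed)
  stage_seeds <- sample.int(2^31 - 2, 8)
  res <- list()

  # ---- input ----
  panel <- NULL
  tracts <- NULL
  if (!is.null(cfg$input$demography)) {
    dp <- cfg$input$demography
    dp$seed <- stage_seeds[1]
    sim <- simulate_panel(dp)
    gm <- sim$genotypes
    panel <- sim$panel
    tracts <- sim$tracts
  } else {
    gm <- read_plink(cfg$input$plink)
  }
  missing_pops <- setdiff(unname(cfg$pops), unique(gm$individuals$population))
  assert_that(length(missing_pops) == 0,
              paste("populations not present in the panel:",
                    paste(missing_pops, collapse = ", ")))

  # ---- qc ----
  qcres <- apply_qc(gm, cfg$qc)
  gm <- qcres$genotypes
  res$qc_report <- qcres$report
  if (!is.null(panel)) {
    keep_s <- match(gm$snps$id, panel$snps$id)
    keep_i <- match(gm$individuals$id, panel$individuals$id)
    hap_rows <- as.vector(rbind(2 * keep_i - 1, 2 * keep_i))
    panel <- haplotypes(panel$alleles[hap_rows, keep_s, drop = FALSE],
                        gm$snps, gm$individuals)
  }
  target <- cfg$pops[["P2"]]

  # ---- diversity ----
  res$het <- het_stats(gm)
  ld <- ld_decay(gm, population = target, max_dist_bp = 30e6)
  res$ld_extent_bp <- tryCatch(ld_extent(ld), error = function(e) NA_real_)
  res$ne <- estimate_ne(ld)
  pruned <- ld_prune(gm)
  res$f_snp <- snp_inbreeding(gm, pruned)

  # ---- roh ----
  res$roh <- call_roh(gm, cfg$roh)
  res$froh <- roh_inbreeding(res$roh, gm, cfg$roh$genome_length_bp)

  # ---- structure ----
  pca <- pca_grm(gm, k = 5, snps = pruned)
  res$pca <- pca
  ref <- lineage_freqs(gm, cfg$lineages)
  target_gm <- subset_genotypes(gm,
                                individuals = gm$individuals$population ==
                                  target)
  props <- supervised_ancestry(target_gm, ref[, , drop = FALSE])
  res$ancestry <- props
  native <- names(cfg$lineages)[1]
  res$conservation <- classify_conservation(
    props, native,
    f = res$f_snp[res$f_snp$id %in% props$id, ],
    froh = res$froh[res$froh$id %in% props$id, ])
  ibs <- ibs_matrix(target_gm)
  tree <- nj_tree(ibs)
  res$tree <- tree
  res$families <- assign_families(tree, target_gm$individuals,
                                  max_families = 10)

  # ---- selection ----
  roh_scan <- roh_incidence_scan(res$roh[res$roh$population == target, ],
                                 gm)
  res$roh_scan <- roh_scan
  # differentiation scan between the target and its native relatives,
  # using PC1 of that subset as the phenotype
  native_gm <- subset_genotypes(
    gm, individuals = gm$individuals$population %in%
      cfg$pops[c("P1", "P2")])
  eg <- eigengwas(native_gm, pca_grm(native_gm, k = 1)$vectors[, 1])
  res$eigengwas <- eg
  sets <- list(ROH = roh_scan$id[roh_scan$significant],
               EigenGWAS = eg$id[eg$significant])
  if (!is.null(panel)) {
    target_rows <- which(rep(gm$individuals$population, each = 2) == target)
    tp <- haplotypes(panel$alleles[target_rows, , drop = FALSE], gm$snps,
                     gm$individuals[gm$individuals$population == target, ])
    ihs <- ihs_scan(tp)
    res$ihs <- ihs
    sets$iHS <- ihs$id[ihs$significant]
  }
  res$candidates <- overlap_candidates(sets, gm$snps)

  # ---- introgression ----
  res$f3 <- f3_test(gm, target, cfg$pops[["P1"]], cfg$pops[["P3"]])
  sp <- site_patterns(gm, cfg$pops)
  res$d <- d_statistic(sp)
  ws <- window_scan(sp, cfg$window_snps, cfg$step_snps)
  res$fdm <- significant_windows(ws, pi_target = "pi_P2", pi_ref = "pi_P1")

  # ---- association ----
  if (is.null(pheno) && !is.null(panel)) {
    set.seed(stage_seeds[2])
    causal_idx <- sample.int(n_snp(gm), 1)
    causal <- setNames(0.5, gm$snps$id[causal_idx])
    pheno <- simulate_phenotype(gm, causal = causal, h2 = 0.3,
                                seed = stage_seeds[3])
    res$causal_snp <- names(causal)
  }
  if (!is.null(pheno)) {
    K <- grm(gm, pruned)
    test_set <- if (!is.null(res$causal_snp)) {
      ci <- match(res$causal_snp, gm$snps$id)
      sort(unique(c(ci, sample.int(n_snp(gm), 20))))
    } else seq_len(min(n_snp(gm), 50))
    res$assoc <- lmm_assoc(gm, pheno, kinship = K, snps = test_set)
  }
  if (!is.null(tracts)) res$tracts <- tracts

  # ---- summary ----
  het_t <- res$het[res$het$population == target, ]
  res$summary <- list(
    n_ind = n_ind(gm), n_snp = n_snp(gm),
    he_target = het_t$he, ho_target = het_t$ho,
    ld_extent_kb = res$ld_extent_bp / 1000,
    ne_recent = ne_recent(res$ne),
    f_mean_target = mean(res$f_snp$f[gm$individuals$population == target]),
    froh_mean_target = mean(
      res$froh$froh[gm$individuals$population == target]),
    nucleus_size = sum(res$conservation$assignments$group == "nucleus"),
    n_families = attr(res$families, "n_families"),
    ancestry_native_mean = mean(props[[native]]),
    f3 = res$f3$f3, f3_z = res$f3$z,
    d = res$d$d, d_z = res$d$z,
    n_significant_windows = sum(res$fdm$windows$significant),
    genome_fraction_positive = res$fdm$genome_fraction_positive,
    pi_boost_positive = res$fdm$pi_boost_positive,
    n_candidate_snps = nrow(res$candidates$snps),
    assoc_min_p = if (!is.null(res$assoc)) min(res$assoc$p, na.rm = TRUE)
    else NA_real_)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res$summary,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in c("het", "froh", "f_snp", "roh")) {
      write.table(res[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ape::write.tree(res$tree, file.path(cfg$out_dir, "nj_target.nwk"))
  }
  invisible(res)
}
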