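#' Reference lineage allele frequencies
#'
#' Convenience helper: per-SNP allele1 frequencies for each reference
#' population, as the matrix [supervised_ancestry] expects.
#'
#' @param gm a [genotypes] object
#' @param pops named character vector: lineage label -> population label
#' @return matrix `n_snp x n_lineage`
#' @export
lineage_freqs <- function(gm, pops) {
  out <- vapply(pops, function(p) allele_freqs(gm, p),
                numeric(n_snp(gm)))
  colnames(out) <- names(pops) %||% pops
  out
}

#' Supervised ancestry proportions
#'
#' Per individual, maximizes the binomial likelihood of the dosages under
#' the mixture frequency `sum_l q_l p_{l,k}` with the reference lineage
#' frequencies held fixed (an EM iteration on the ancestry simplex; the
#' supervised analogue of an ADMIXTURE run with frozen allele
#' frequencies). Reference frequencies are clamped to [0.001, 0.999].
#'
#' @param gm a [genotypes] object
#' @param ref_freqs matrix `n_snp x n_lineage` of reference allele1
#'   frequencies (see [lineage_freqs]); needs >= 2 lineages
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   proportion vector
#' @return tibble: id, population, one proportion column per lineage
#'   (rows sum to 1)
#' @export
supervised_ancestry <- function(gm, ref_freqs, max_iter = 2000,
                                tol = 1e-7) {
  P <- as.matrix(ref_freqs)
  assert_that(ncol(P) >= 2, "need at least two reference lineages")
  assert_that(nrow(P) == n_snp(gm),
              "ref_freqs rows must match the SNP count")
  P[is.na(P)] <- 0.5
  P <- pmin(pmax(P, 0.001), 0.999)
  L <- ncol(P)
  lin <- colnames(P) %||% paste0("L", seq_len(L))
  Q <- matrix(NA_real_, n_ind(gm), L, dimnames = list(gm$individuals$id,
                                                      lin))
  for (i in seq_len(n_ind(gm))) {
    x <- gm$dosage[i, ]
    ok <- !is.na(x)
    xi <- x[ok]
    Pi <- P[ok, , drop = FALSE]
    q <- rep(1 / L, L)
    for (it in seq_len(max_iter)) {
      pm <- as.vector(Pi %*% q)
      # expected lineage-of-origin counts for allele1 and allele2 copies
      w1 <- sweep(Pi, 1, pm, "/") * q[col(Pi)]
      w0 <- sweep(1 - Pi, 1, 1 - pm, "/") * q[col(Pi)]
      cnt <- colSums(w1 * xi) + colSums(w0 * (2 - xi))
      q_new <- cnt / sum(cnt)
      if (max(abs(q_new - q)) < tol) {
        q <- q_new
        break
      }
      q <- q_new
      if (it == max_iter) {
        warn(sprintf("ancestry EM did not converge for individual %s",
                     gm$individuals$id[i]))
      }
    }
    Q[i, ] <- q
  }
  out <- tibble::as_tibble(Q)
  dplyr::bind_cols(tibble::tibble(id = gm$individuals$id,
                                  population = gm$individuals$population),
                   out)
}

#' Conservation-tier classification from a lineage proportion
#'
#' Splits individuals into four tiers at the mean, mean - 1 SD and mean -
#' 2 SD of the chosen lineage proportion: `nucleus` (>= mean),
#' `candidate1` ([mean - 1 SD, mean)), `candidate2` ([mean - 2 SD,
#' mean - 1 SD)) and `discard` (< mean - 2 SD). Individuals whose SNP-based
#' F or F_ROH exceeds its own mean + 2 SD are flagged as inbreeding
#' outliers.
#'
#' @param props tibble from [supervised_ancestry]
#' @param lineage column of `props` holding the proportion to classify on
#' @param f optional tibble from [snp_inbreeding] (columns id, f)
#' @param froh optional tibble from [roh_inbreeding] (columns id, froh)
#' @param center,scale optional externally supplied mean and SD of the
#'   proportion (e.g. from a larger reference cohort); default: computed
#'   from `props`
#' @return a list of class `conservation_grouping`: `assignments` (tibble
#'   id, proportion, group, f_outlier, froh_outlier), `cutpoints` (named:
#'   mean, minus1sd, minus2sd), `center`, `scale`
#' @export
classify_conservation <- function(props, lineage, f = NULL, froh = NULL,
                                  center = NULL, scale = NULL) {
  assert_that(lineage %in% names(props),
              sprintf("no column '%s' in the proportions table", lineage))
  p <- props[[lineage]]
  assert_that(length(p) >= 2, "need proportions for >= 2 individuals")
  mu <- center %||% mean(p)
  sdv <- scale %||% sd(p)
  assert_that(is.finite(sdv) && sdv > 0,
              "zero variance in the lineage proportions",
              "introsel_range_error")
  cut1 <- mu - sdv
  cut2 <- mu - 2 * sdv
  group <- ifelse(p >= mu, "nucleus",
                  ifelse(p >= cut1, "candidate1",
                         ifelse(p >= cut2, "candidate2", "discard")))
  asg <- tibble::tibble(id = props$id, proportion = p, group = group)
  flag_outlier <- function(tbl, col) {
    if (is.null(tbl)) return(rep(NA, nrow(asg)))
    v <- tbl[[col]][match(asg$id, tbl$id)]
    thr <- mean(v, na.rm = TRUE) + 2 * sd(v, na.rm = TRUE)
    v > thr
  }
  asg$f_outlier <- flag_outlier(f, "f")
  asg$froh_outlier <- flag_outlier(froh, "froh")
  structure(list(assignments = asg,
                 cutpoints = c(mean = mu, minus1sd = cut1, minus2sd = cut2),
                 center = mu, scale = sdv),
            class = "conservation_grouping")
}

#' @export
print.conservation_grouping <- function(x, ...) {
  cat(sprintf(
    "conservation tiers (cutpoints %.4f / %.4f / %.4f):\n",
    x$cutpoints[1], x$cutpoints[2], x$cutpoints[3]))
  print(table(x$assignments$group))
  invisible(x)
}

#' Assign family groups by cutting a NJ tree
#'
#' Cuts internal edges of the individual tree, longest first, until no
#' further cut leaves every resulting leaf group with at least `min_boars`
#' males (or `max_families` is reached). Each surviving component is a
#' monophyletic family.
#'
#' @param tree an [ape::phylo] tree whose tips are individual ids
#' @param sex named character vector id -> sex (`"male"` / `"female"` /
#'   `"unknown"`), or a tibble with columns id, sex
#' @param min_boars minimum males per family
#' @param max_families optional cap on the number of families
#' @return tibble: id, sex, family (integer label); attribute `n_families`
#' @export
assign_families <- function(tree, sex, min_boars = 1, max_families = Inf) {
  if (is.data.frame(sex)) sex <- setNames(sex$sex, sex$id)
  tips <- tree$tip.label
  assert_that(all(tips %in% names(sex)), "every leaf needs a sex label")
  male <- sex[tips] == "male"
  assert_that(sum(male) >= min_boars,
              "fewer males than required for a single family",
              "introsel_range_error")
  n_tip <- length(tips)
  edges <- tree$edge
  elen <- tree$edge.length %||% rep(1, nrow(edges))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  igraph::E(g)$weight <- elen
  internal <- which(edges[, 1] > n_tip & edges[, 2] > n_tip)
  ord <- internal[order(elen[internal], decreasing = TRUE)]
  male_of <- function(membership) {
    comp_of_tip <- membership[as.character(seq_len(n_tip))]
    tapply(male, comp_of_tip, sum)
  }
  edge_ids <- function(sel) {
    if (length(sel) == 0) return(integer())
    vp <- as.vector(t(matrix(as.character(edges[sel, , drop = FALSE]),
                             ncol = 2)))
    igraph::get_edge_ids(g, vp)
  }
  cut_edges <- integer()
  for (e in ord) {
    if (length(cut_edges) + 1 >= max_families) break
    trial <- igraph::delete_edges(g, edge_ids(c(cut_edges, e)))
    memb <- igraph::components(trial)$membership
    if (all(male_of(memb) >= min_boars)) cut_edges <- c(cut_edges, e)
  }
  final <- igraph::delete_edges(g, edge_ids(cut_edges))
  memb <- igraph::components(final)$membership
  fam_raw <- memb[as.character(seq_len(n_tip))]
  fam <- as.integer(factor(fam_raw, levels = unique(fam_raw)))
  out <- tibble::tibble(id = tips, sex = unname(sex[tips]), family = fam)
  attr(out, "n_families") <- length(unique(fam))
  out
}
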