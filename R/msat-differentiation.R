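## Microsatellite differentiation: bias-corrected GST (Nei & Chesser 1983),
## Hedrick's standardized G'ST and Jost's D, per locus and multilocus.

## per-locus Hs/Ht/Ho components for one locus given a list of per-pop
## allele-count tables and per-pop (n_genotyped, Ho)
nei_chesser_components <- function(freqs, ns, hos) {
  keep <- ns > 0
  freqs <- freqs[keep]; ns <- ns[keep]; hos <- hos[keep]
  k <- length(ns)
  if (k < 2L) return(NULL)
  ntilde <- k / sum(1 / ns)                       # harmonic mean sample size
  alleles <- sort(unique(unlist(lapply(freqs, names))))
  P <- sapply(freqs, function(f) {
    v <- stats::setNames(numeric(length(alleles)), alleles)
    v[names(f)] <- f / sum(f)
    v
  })
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L, dimnames = list(alleles, NULL))
  x2bar <- mean(colSums(P^2))
  xbar2 <- sum(rowMeans(P)^2)
  Ho <- mean(hos)
  Hs <- ntilde / (ntilde - 1) * (1 - x2bar - Ho / (2 * ntilde))
  Ht <- 1 - xbar2 + Hs / (ntilde * k) - Ho / (2 * ntilde * k)
  list(Hs = Hs, Ht = Ht, Ho = Ho, k = k)
}

gst_family <- function(Hs, Ht, k) {
  gst <- if (Ht > 0) (Ht - Hs) / Ht else 0
  gprime <- if (Hs < 1 && k > 1) gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs)) else NA_real_
  d <- if (Hs < 1 && k > 1) (k / (k - 1)) * (Ht - Hs) / (1 - Hs) else NA_real_
  c(Fst = gst, Fst_prime = gprime, jost_d = d)
}

## per-pop allele count tables for one locus (list over pops)
locus_freqs <- function(gt, pm, j, pops) {
  lapply(pops, function(pop) {
    i <- match(intersect(pop_samples(pm, pop), gt$sample_ids), gt$sample_ids)
    a <- c(gt$a1[i, j], gt$a2[i, j])
    table(a[!is.na(a)])
  })
}

## multilocus + per-locus statistics for a set of pops; grp_override allows
## permuted population labels (named vector sample -> pop)
msat_gst_stats <- function(gt, pm, pops, assignments = NULL) {
  assignments <- assignments %||% pm$assignments
  nl <- length(gt$locus_ids)
  per_locus <- matrix(NA_real_, nl, 3,
                      dimnames = list(gt$locus_ids, c("Fst", "Fst_prime", "jost_d")))
  Hs_all <- Ht_all <- rep(NA_real_, nl)
  for (j in seq_len(nl)) {
    freqs <- list(); ns <- numeric(0); hos <- numeric(0)
    for (pop in pops) {
      ids <- intersect(names(assignments)[assignments == pop], gt$sample_ids)
      i <- match(ids, gt$sample_ids)
      a1 <- gt$a1[i, j]; a2 <- gt$a2[i, j]
      ok <- !is.na(a1)
      ns <- c(ns, sum(ok))
      hos <- c(hos, if (sum(ok)) mean(a1[ok] != a2[ok]) else NA_real_)
      a <- c(a1[ok], a2[ok])
      freqs[[length(freqs) + 1L]] <- table(a)
    }
    comp <- nei_chesser_components(freqs, ns, hos)
    if (is.null(comp)) next
    Hs_all[j] <- comp$Hs; Ht_all[j] <- comp$Ht
    per_locus[j, ] <- gst_family(comp$Hs, comp$Ht, comp$k)
  }
  ok <- !is.na(Hs_all)
  k <- length(pops)
  multi <- if (any(ok)) gst_family(mean(Hs_all[ok]), mean(Ht_all[ok]), k)
           else c(Fst = NA_real_, Fst_prime = NA_real_, jost_d = NA_real_)
  list(per_locus = per_locus, multilocus = multi,
       Hs = Hs_all, Ht = Ht_all)
}

#' Microsatellite differentiation: FST, Hedrick's F'ST and Jost's D
#'
#' Per-locus and multilocus differentiation from diploid genotypes:
#' bias-corrected GST computed from Nei & Chesser (1983) small-sample
#' estimators of within- (`Hs`) and total- (`Ht`) heterozygosity, Hedrick's
#' standardized `F'ST = GST (k-1+Hs) / ((k-1)(1-Hs))` and Jost's
#' `D = (k/(k-1)) (Ht-Hs)/(1-Hs)` (`k` = number of populations), the latter
#' two correcting the downward bias of GST at high within-population
#' heterozygosity. Multilocus values combine loci as ratios of
#' locus-averaged `Hs`/`Ht` (ratio of averages, not average of ratios).
#' P-values come from permuting individuals among populations; pairwise
#' matrices carry Benjamini-Yekutieli FDR flags.
#'
#' @param gt a [genotype_table()].
#' @param pm a [popmap()].
#' @param n_perm permutations for the p-values (0 skips testing).
#' @param seed optional integer seed.
#' @param alpha FDR level for pairwise flags.
#' @return Object of class `DifferentiationResult`: `per_locus` (data.frame
#'   locus x `(Fst, Fst_prime, jost_d)`), `multilocus`, `overall_p`,
#'   `pairwise` (list of three matrices), `pairwise_p`, `fdr_significant`,
#'   `fdr_critical`.
#' @export
differentiation <- function(gt, pm, n_perm = 10000L, seed = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(pm, "PopulationMap"))
  pops <- pm$populations
  if (length(pops) < 2L) stopf("need >= 2 populations")
  obs <- msat_gst_stats(gt, pm, pops)
  ids <- intersect(names(pm$assignments), gt$sample_ids)
  base_assign <- pm$assignments[ids]

  overall_p <- NA_real_
  if (n_perm > 0L) {
    overall_p <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 0L), {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- stats::setNames(sample(base_assign), ids)
        st <- msat_gst_stats(gt, pm, pops, assignments = perm)$multilocus["Fst"]
        if (!is.na(st) && st >= obs$multilocus["Fst"] - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }

  P <- length(pops)
  mk <- function() matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pw <- list(Fst = mk(), Fst_prime = mk(), jost_d = mk())
  for (nm in names(pw)) diag(pw[[nm]]) <- 0
  pwp <- mk()
  pair_id <- 0L
  for (i in seq_len(P - 1L)) for (j2 in (i + 1L):P) {
    pair_id <- pair_id + 1L
    pair <- pops[c(i, j2)]
    st <- msat_gst_stats(gt, pm, pair)$multilocus
    for (nm in names(pw)) pw[[nm]][i, j2] <- pw[[nm]][j2, i] <- st[[nm]]
    if (n_perm > 0L && !is.na(st[["Fst"]])) {
      sel <- ids[base_assign %in% pair]
      pa <- base_assign[sel]
      pwp[i, j2] <- pwp[j2, i] <- with_seed(
        if (is.null(seed)) NULL else derive_seed(seed, pair_id), {
          hits <- 0L
          for (b in seq_len(n_perm)) {
            perm <- stats::setNames(sample(pa), sel)
            sp <- msat_gst_stats(gt, pm, pair, assignments = perm)$multilocus["Fst"]
            if (!is.na(sp) && sp >= st[["Fst"]] - 1e-12) hits <- hits + 1L
          }
          (1 + hits) / (n_perm + 1)
        })
    }
  }
  pv <- pwp[upper.tri(pwp)]
  fdr <- if (any(!is.na(pv))) fdr_correct(pv[!is.na(pv)], alpha = alpha) else NULL
  flags <- matrix(NA, P, P, dimnames = list(pops, pops))
  if (!is.null(fdr)) {
    f <- rep(NA, length(pv)); f[!is.na(pv)] <- fdr$significant
    flags[upper.tri(flags)] <- f
    flags[lower.tri(flags)] <- t(flags)[lower.tri(flags)]
  }
  structure(list(per_locus = as.data.frame(obs$per_locus),
                 multilocus = obs$multilocus,
                 overall_p = overall_p,
                 pairwise = pw, pairwise_p = pwp,
                 fdr_significant = flags,
                 fdr_critical = if (is.null(fdr)) NA_real_ else fdr$critical,
                 n_perm = n_perm, seed = seed),
            class = "DifferentiationResult")
}

#' @export
print.DifferentiationResult <- function(x, ...) {
  cat(sprintf("Multilocus: FST = %.3f, F'ST = %.3f, Jost's D = %.3f (overall p = %.4g)\n",
              x$multilocus["Fst"], x$multilocus["Fst_prime"],
              x$multilocus["jost_d"], x$overall_p))
  invisible(x)
}

#' Goldstein's (delta-mu)^2 distance between populations
#'
#' For each population pair, the squared difference of mean allele sizes,
#' averaged over loci; under strict stepwise mutation its expectation is
#' `2 mu t` after `t` generations of divergence. Loci without data in
#' either population of a pair are skipped for that pair.
#'
#' @param gt a [genotype_table()].
#' @param pm a [popmap()].
#' @return Symmetric matrix of class `DeltaMuResult` (zero diagonal).
#' @export
delta_mu_squared <- function(gt, pm) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(pm, "PopulationMap"))
  pops <- pm$populations
  ## mean allele size per pop x locus
  M <- matrix(NA_real_, length(pops), length(gt$locus_ids),
              dimnames = list(pops, gt$locus_ids))
  for (pop in pops) {
    i <- match(intersect(pop_samples(pm, pop), gt$sample_ids), gt$sample_ids)
    for (j in seq_along(gt$locus_ids)) {
      a <- c(gt$a1[i, j], gt$a2[i, j])
      a <- a[!is.na(a)]
      if (length(a)) M[pop, j] <- mean(a)
    }
  }
  P <- length(pops)
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(max(P - 1L, 0L))) for (j in (i + 1L):P) {
    ok <- !is.na(M[i, ]) & !is.na(M[j, ])
    D[i, j] <- D[j, i] <- if (any(ok)) mean((M[i, ok] - M[j, ok])^2) else NA_real_
  }
  class(D) <- c("DeltaMuResult", class(D))
  D
}
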