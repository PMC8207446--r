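## One-level AMOVA (populations / individuals within populations) on a
## matrix of squared inter-individual distances, Excoffier et al. (1992).

## phi from squared-distance matrix D2 and an integer group vector
amova_phi_stat <- function(D2, grp) {
  N <- length(grp)
  pops <- unique(grp)
  P <- length(pops)
  ssd_w <- 0
  sizes <- numeric(P)
  for (pi in seq_len(P)) {
    idx <- which(grp == pops[pi])
    sizes[pi] <- length(idx)
    ssd_w <- ssd_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssd_t <- sum(D2) / (2 * N)
  ssd_a <- ssd_t - ssd_w
  df_w <- N - P
  df_a <- P - 1
  if (df_w <= 0 || df_a <= 0) return(NA_real_)
  s2w <- ssd_w / df_w
  nprime <- (N - sum(sizes^2) / N) / df_a
  s2a <- (ssd_a / df_a - s2w) / nprime
  tot <- s2a + s2w
  if (tot == 0) return(0)
  s2a / tot
}

## permutation p-value for phi by shuffling individuals among populations
amova_perm_p <- function(D2, grp, obs, n_perm) {
  if (is.na(obs)) return(NA_real_)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    ph <- amova_phi_stat(D2, sample(grp))
    if (!is.na(ph) && ph >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

## shared engine for amova_phist / haplotype_fst
amova_engine <- function(D2, grp, pops, n_perm, seed, alpha, statistic) {
  overall <- amova_phi_stat(D2, grp)
  overall_p <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 0L),
                         amova_perm_p(D2, grp, overall, n_perm))
  P <- length(pops)
  pw <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pwp <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(pw) <- 0
  pair_id <- 0L
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    pair_id <- pair_id + 1L
    idx <- which(grp == pops[i] | grp == pops[j])
    if (sum(grp[idx] == pops[i]) < 2L || sum(grp[idx] == pops[j]) < 2L) next
    sub <- D2[idx, idx]
    g <- grp[idx]
    st <- amova_phi_stat(sub, g)
    pp <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, pair_id),
                    amova_perm_p(sub, g, st, n_perm))
    pw[i, j] <- pw[j, i] <- st
    pwp[i, j] <- pwp[j, i] <- pp
  }
  pv <- pwp[upper.tri(pwp)]
  fdr <- if (any(!is.na(pv))) fdr_correct(pv[!is.na(pv)], alpha = alpha) else NULL
  flags <- matrix(NA, P, P, dimnames = list(pops, pops))
  if (!is.null(fdr)) {
    f <- rep(NA, length(pv)); f[!is.na(pv)] <- fdr$significant
    flags[upper.tri(flags)] <- f
    flags[lower.tri(flags)] <- t(flags)[lower.tri(flags)]
  }
  structure(list(statistic = statistic, overall = overall,
                 overall_p = overall_p, pairwise = pw, pairwise_p = pwp,
                 fdr_significant = flags,
                 fdr_critical = if (is.null(fdr)) NA_real_ else fdr$critical,
                 n_perm = n_perm, seed = seed),
            class = "DivergenceResult")
}

#' @export
print.DivergenceResult <- function(x, ...) {
  cat(sprintf("%s AMOVA: overall = %.4f (p = %.4g, %d permutations)\n",
              x$statistic, x$overall, x$overall_p, x$n_perm))
  cat("Pairwise:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' AMOVA Phi-ST from molecular distances
#'
#' One-level analysis of molecular variance: partitions squared
#' inter-individual molecular distances among and within populations and
#' returns overall and pairwise Phi-ST with permutation p-values
#' (individuals shuffled among populations) and Benjamini-Yekutieli FDR
#' flags on the pairwise tests. The entries of `dist` are used directly as
#' squared distances; the conventional input is the matrix of pairwise
#' difference counts ([pairwise_differences()], squared Euclidean in
#' haplotype space), which is the default when `dist` is `NULL`.
#'
#' @param aln an [alignment()] object.
#' @param pm a [popmap()].
#' @param dist optional `DistanceMatrixSeq` covering all samples.
#' @param n_perm number of permutations.
#' @param seed optional integer seed; overall and each pairwise test use
#'   independent derived streams.
#' @param alpha FDR level for the pairwise flags.
#' @return A `DivergenceResult`: list with `overall`, `overall_p`,
#'   `pairwise`, `pairwise_p`, `fdr_significant`, `fdr_critical`.
#' @export
amova_phist <- function(aln, pm, dist = NULL, n_perm = 10000L, seed = NULL,
                        alpha = 0.05) {
  stopifnot(inherits(aln, "Alignment"), inherits(pm, "PopulationMap"))
  ids <- intersect(aln$sample_ids, names(pm$assignments))
  if (length(unique(pm$assignments[ids])) < 2L)
    stopf("need >= 2 populations")
  if (is.null(dist)) dist <- pairwise_differences(subset_alignment(aln, ids))
  if (!all(ids %in% rownames(dist))) stopf("dist does not cover all samples")
  D2 <- unclass(dist)[ids, ids]
  if (anyNA(D2)) stopf("distance matrix contains NA for analyzed samples")
  amova_engine(D2, as.character(pm$assignments[ids]), pm$populations,
               n_perm, seed, alpha, "PhiST")
}

#' Haplotype-frequency FST (AMOVA on 0/1 distances)
#'
#' AMOVA in which the distance between distinct haplotypes is identically 1,
#' so only haplotype frequencies matter ("haplotype diversities only").
#'
#' @param ht a [collapse_haplotypes()] result.
#' @param n_perm,seed,alpha as in [amova_phist()].
#' @return A `DivergenceResult` (statistic `"FST"`).
#' @export
haplotype_fst <- function(ht, n_perm = 10000L, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(ht, "HaplotypeTable"))
  pops <- rownames(ht$counts)
  hap <- integer(0); grp <- character(0)
  for (p in pops) for (j in seq_len(ncol(ht$counts))) {
    cnt <- ht$counts[p, j]
    if (cnt > 0L) { hap <- c(hap, rep(j, cnt)); grp <- c(grp, rep(p, cnt)) }
  }
  if (length(unique(grp)) < 2L) stopf("need >= 2 populations")
  D2 <- 1 * outer(hap, hap, "!=")
  amova_engine(D2, grp, pops[pops %in% grp], n_perm, seed, alpha, "FST")
}
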