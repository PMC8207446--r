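## Tajima's D, Fu's Fs and their coalescent-simulation p-values.

## Tajima (1989) D from segregating sites S, mean pairwise differences k
## and sample size n
tajima_d_stat <- function(S, k, n) {
  if (n < 4L || S == 0L) return(0)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Ewens sampling distribution of the number of alleles K for sample size n
## and scaled mutation rate theta: P(K = k) proportional to |s(n,k)| theta^k,
## via the signless-Stirling recurrence (doubles suffice for n <= ~140).
ewens_k_dist <- function(n, theta) {
  if (theta <= 0) return(c(1, rep(0, n - 1L)))
  ls <- -Inf
  s <- rep(0, n); s[1L] <- 1          # |s(1,k)|
  if (n > 1L) for (m in 1:(n - 1L)) {
    s_new <- m * s
    s_new[2:n] <- s_new[2:n] + s[1:(n - 1L)]
    s <- s_new
  }
  logp <- log(s) + seq_len(n) * log(theta)
  logp <- logp - max(logp[is.finite(logp)])
  p <- exp(logp)
  p / sum(p)
}

## Fu (1997) Fs from observed allele (haplotype) count k0 and theta-hat
## (mean pairwise differences per locus)
fu_fs_stat <- function(n, theta, k0) {
  if (theta <= 0 || n < 2L) return(0)
  p <- ewens_k_dist(n, theta)
  sp <- sum(p[k0:n])
  sp <- min(max(sp, 1e-300), 1 - 1e-15)
  log(sp / (1 - sp))
}

## Simulate one neutral-coalescent sample (infinite-sites) and return the
## summaries needed for the tests: S, mean pairwise differences k and the
## number of distinct haplotypes. theta is per locus (= 2 N mu L, haploid).
sim_neutral_summaries <- function(n, theta) {
  ## coalescent intervals and branch descendant sets
  active <- as.list(seq_len(n))
  blen <- numeric(0)
  bdesc <- list()
  k <- n
  while (k > 1L) {
    t_int <- stats::rexp(1L, rate = k * (k - 1) / 2)
    ## every active lineage gains t_int of branch length
    for (lin in active) {
      blen[length(blen) + 1L] <- t_int
      bdesc[[length(bdesc) + 1L]] <- lin
    }
    pair <- sample.int(k, 2L)
    merged <- c(active[[pair[1L]]], active[[pair[2L]]])
    active[[pair[1L]]] <- merged
    active[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  ## consolidate: total length per distinct descendant set is what matters;
  ## place mutations Poisson(theta/2 * total length), each on a branch
  ## chosen proportionally to its length
  tot <- sum(blen)
  S <- stats::rpois(1L, theta / 2 * tot)
  if (S == 0L)
    return(list(S = 0L, k = 0, n_hap = 1L))
  br <- sample.int(length(blen), S, replace = TRUE, prob = blen)
  cnt <- vapply(bdesc[br], length, 1L)
  kbar <- sum(cnt * (n - cnt)) / (n * (n - 1) / 2)
  ## haplotype identity: incidence pattern of mutations across tips
  M <- matrix(FALSE, S, n)
  for (s in seq_len(S)) M[s, bdesc[[br[s]]]] <- TRUE
  n_hap <- length(unique(apply(M, 2L, paste, collapse = "")))
  list(S = S, k = kbar, n_hap = n_hap)
}

#' Tajima's D and Fu's Fs neutrality tests
#'
#' Computes per-population Tajima's D (from `S` and mean pairwise
#' differences) and Fu's Fs (from the Ewens sampling formula applied to the
#' observed number of haplotypes, with theta estimated by mean pairwise
#' differences). P-values come from neutral coalescent simulation
#' conditioned on the sample size and the observed theta-hat (`n_sim`
#' replicates); they are lower-tail probabilities, the convention under
#' which a significant deficit (negative D, negative Fs) indicates
#' expansion. Monomorphic populations are reported as `D = Fs = 0` with
#' `p = 1`.
#'
#' @inheritParams collapse_haplotypes
#' @param n_sim number of coalescent replicates per population.
#' @param seed optional integer seed (required for reproducible p-values).
#' @return The [diversity_summary()] data.frame with columns
#'   `tajima_d, tajima_p, fu_fs, fu_fs_p` appended.
#' @export
neutrality_tests <- function(aln, pm, n_sim = 1000L, seed = NULL,
                             max_missing = 0.1) {
  ds <- diversity_summary(aln, pm, max_missing = max_missing)
  ht <- collapse_haplotypes(aln, pm, max_missing = max_missing)
  popv <- pm$assignments[names(ht$assignments)]
  ds$tajima_d <- NA_real_; ds$tajima_p <- NA_real_
  ds$fu_fs <- NA_real_; ds$fu_fs_p <- NA_real_
  for (r in seq_len(nrow(ds))) {
    n <- ds$n[r]
    if (is.na(ds$S[r]) || n < 2L) next
    S <- ds$S[r]; k <- ds$k[r]
    if (S == 0L) {
      ds$tajima_d[r] <- 0; ds$tajima_p[r] <- 1
      ds$fu_fs[r] <- 0; ds$fu_fs_p[r] <- 1
      next
    }
    n_hap <- length(unique(ht$assignments[popv == ds$population[r]]))
    D <- tajima_d_stat(S, k, n)
    Fs <- fu_fs_stat(n, k, n_hap)
    sims <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, r), {
      replicate(n_sim, {
        s <- sim_neutral_summaries(n, k)
        c(D = tajima_d_stat(s$S, s$k, n),
          Fs = if (s$S == 0L) 0 else fu_fs_stat(n, s$k, s$n_hap))
      })
    })
    ds$tajima_d[r] <- D
    ds$tajima_p[r] <- (1 + sum(sims["D", ] <= D)) / (n_sim + 1)
    ds$fu_fs[r] <- Fs
    ds$fu_fs_p[r] <- (1 + sum(sims["Fs", ] <= Fs)) / (n_sim + 1)
  }
  ds
}
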