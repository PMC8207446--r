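## Per-population haplotype and nucleotide diversity (Nei 1987).

## mean pairwise difference count between rows of an encoded matrix,
## pairwise deletion; returns list(k = mean differences per pair,
## k_site = mean differences per site)
mean_pairwise_diff <- function(enc) {
  n <- nrow(enc)
  if (n < 2L) return(list(k = NA_real_, k_site = NA_real_))
  tot <- 0; tot_site <- 0; np <- 0L
  for (i in 1:(n - 1L)) {
    si <- enc[i, ]
    for (j in (i + 1L):n) {
      sj <- enc[j, ]
      ok <- !is.na(si) & !is.na(sj)
      m <- sum(ok)
      if (m == 0L) next
      d <- sum(si[ok] != sj[ok])
      tot <- tot + d
      tot_site <- tot_site + d / m
      np <- np + 1L
    }
  }
  if (np == 0L) return(list(k = NA_real_, k_site = NA_real_))
  list(k = tot / np, k_site = tot_site / np)
}

## number of segregating sites (>= 2 distinct non-missing bases)
n_segregating <- function(enc) {
  sum(apply(enc, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

## Nei (1987) haplotype diversity and its sampling variance
hap_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(c(h = NA_real_, sd = NA_real_))
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(v, 0)))
}

## Tajima (1983) variance of pi per site
pi_sd <- function(pi, n, L) {
  if (is.na(pi) || n < 2L) return(NA_real_)
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  sqrt(max(v, 0))
}

#' Per-population diversity summary
#'
#' Computes, for each population: sample size, number of segregating sites
#' `S`, haplotype diversity `h` with Nei's standard deviation, and
#' nucleotide diversity `pi` per site (mean pairwise differences with
#' pairwise deletion of missing sites) with Tajima's standard deviation.
#' Populations with fewer than 2 usable samples are reported with `NA`
#' statistics.
#'
#' @inheritParams collapse_haplotypes
#' @return A data.frame of class `DiversitySummary`, one row per population,
#'   columns `population, n, S, h, h_sd, pi, pi_sd, k` (`k` = mean pairwise
#'   differences per sequence pair, unscaled), plus attribute `locus`.
#' @export
diversity_summary <- function(aln, pm, max_missing = 0.1) {
  stopifnot(inherits(aln, "Alignment"), inherits(pm, "PopulationMap"))
  ht <- collapse_haplotypes(aln, pm, max_missing = max_missing)
  keep <- names(ht$assignments)
  enc <- encode_alignment(aln)[keep, , drop = FALSE]
  popv <- pm$assignments[keep]
  out <- lapply(pm$populations, function(pop) {
    idx <- which(popv == pop)
    n <- length(idx)
    if (n < 2L)
      return(data.frame(population = pop, n = n, S = NA_integer_,
                        h = NA_real_, h_sd = NA_real_,
                        pi = NA_real_, pi_sd = NA_real_, k = NA_real_))
    e <- enc[idx, , drop = FALSE]
    S <- n_segregating(e)
    hd <- hap_diversity(tabulate(ht$assignments[keep][idx],
                                 nbins = length(ht$haplotype_sequences)))
    mp <- mean_pairwise_diff(e)
    data.frame(population = pop, n = n, S = S,
               h = unname(hd["h"]), h_sd = unname(hd["sd"]),
               pi = mp$k_site, pi_sd = pi_sd(mp$k_site, n, aln$length),
               k = mp$k)
  })
  res <- do.call(rbind, out)
  attr(res, "locus") <- aln$locus_label
  class(res) <- c("DiversitySummary", "data.frame")
  res
}
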