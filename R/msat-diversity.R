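#' Per-locus, per-population microsatellite diversity
#'
#' Observed heterozygosity `Ho`, unbiased expected heterozygosity `He`
#' (Nei's estimator `2n/(2n-1) * (1 - sum p^2)` over `2n` gene copies) and
#' rarefied allelic richness `AR(g)` (expected allele count in a
#' hypergeometric subsample of `g` gene copies). The default `g = 2`
#' satisfies the identity `AR(2) = 1 + He`, the scale on which compact
#' richness tables are usually printed.
#'
#' @param gt a [genotype_table()].
#' @param pm a [popmap()].
#' @param g rarefaction size in gene copies (`>= 2`); cells with fewer than
#'   `g` gene copies are `NA`.
#' @return Object of class `LocusDiversity`: list with `per_locus` (long
#'   data.frame locus x population: `n, Ho, He, k, AR`) and `per_population`
#'   (across-locus means).
#' @export
locus_diversity <- function(gt, pm, g = 2L) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(pm, "PopulationMap"))
  if (!is_count(g) || g < 2L) stopf("g must be an integer >= 2")
  rows <- list()
  for (loc in gt$locus_ids) {
    j <- match(loc, gt$locus_ids)
    for (pop in pm$populations) {
      ids <- intersect(pop_samples(pm, pop), gt$sample_ids)
      i <- match(ids, gt$sample_ids)
      a1 <- gt$a1[i, j]; a2 <- gt$a2[i, j]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loc, population = pop, n = 0L, Ho = NA_real_,
          He = NA_real_, k = NA_integer_, AR = NA_real_)
        next
      }
      alle <- c(a1[ok], a2[ok])
      cnt <- table(alle)
      T2 <- 2L * n
      p <- as.numeric(cnt) / T2
      Ho <- mean(a1[ok] != a2[ok])
      He <- if (T2 > 1L) T2 / (T2 - 1) * (1 - sum(p^2)) else NA_real_
      AR <- if (T2 >= g)
        sum(1 - exp(lchoose(T2 - as.numeric(cnt), g) - lchoose(T2, g)))
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = pop, n = n, Ho = Ho, He = He,
        k = length(cnt), AR = AR)
    }
  }
  per_locus <- do.call(rbind, rows)
  per_population <- do.call(rbind, lapply(pm$populations, function(pop) {
    d <- per_locus[per_locus$population == pop, ]
    data.frame(population = pop,
               n = max(d$n),
               mean_Ho = mean(d$Ho, na.rm = TRUE),
               mean_He = mean(d$He, na.rm = TRUE),
               mean_AR = mean(d$AR, na.rm = TRUE))
  }))
  structure(list(per_locus = per_locus, per_population = per_population,
                 g = g),
            class = "LocusDiversity")
}

#' @export
print.LocusDiversity <- function(x, ...) {
  cat(sprintf("LocusDiversity (rarefaction g = %d gene copies):\n", x$g))
  print(x$per_population, row.names = FALSE)
  invisible(x)
}
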