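#' Benjamini-Yekutieli false discovery rate correction
#'
#' Step-up FDR procedure valid under arbitrary dependence (Benjamini &
#' Yekutieli 2001): with `m` p-values sorted ascending, the largest `i` with
#' `p_(i) <= i * alpha / (m * c(m))`, `c(m) = sum(1/1..1/m)`, determines the
#' realized critical value; all p-values at or below it are flagged.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha target FDR level.
#' @return List with `significant` (logical, parallel to `pvalues`),
#'   `critical` (the realized critical p-value; 0 if nothing is rejected),
#'   `alpha` and `m`.
#' @export
fdr_correct <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stopf("empty p-value list")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(pvalues)
  cm <- sum(1 / seq_len(m))
  o <- order(pvalues)
  ps <- pvalues[o]
  thresh <- seq_len(m) * alpha / (m * cm)
  pass <- which(ps <= thresh)
  if (length(pass) == 0L)
    return(list(significant = rep(FALSE, m), critical = 0,
                alpha = alpha, m = m))
  imax <- max(pass)
  crit <- thresh[imax]
  list(significant = pvalues <= ps[imax], critical = crit,
       alpha = alpha, m = m)
}
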