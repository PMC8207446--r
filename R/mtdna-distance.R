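#' Tamura (1992) pairwise distances with gamma rate correction
#'
#' Computes the Tamura 3-parameter distance, which corrects for
#' transition/transversion bias and GC-content bias, optionally with a
#' gamma-distributed rate-heterogeneity correction of shape `gamma_a`
#' (`gamma_a = Inf` gives the uncorrected Tamura distance). Missing sites
#' (gaps, `N`, ambiguity codes) are excluded pairwise. A saturated pair
#' (logarithm/power argument not positive) is reported as `NA` with a
#' warning.
#'
#' @param aln an [alignment()] object.
#' @param gamma_a gamma shape parameter `a > 0`, or `Inf` for no rate
#'   heterogeneity.
#' @return Object of class `DistanceMatrixSeq`: a symmetric numeric matrix
#'   with zero diagonal and attributes `method` and `gamma_a`.
#' @export
tamura_gamma_distance <- function(aln, gamma_a = Inf) {
  stopifnot(inherits(aln, "Alignment"))
  if (!(is.numeric(gamma_a) && length(gamma_a) == 1L && gamma_a > 0))
    stopf("gamma_a must be a positive number (or Inf)")
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  saturated <- 0L
  ## base codes: A=1, C=2, G=3, T=4; transitions A<->G (1,3), C<->T (2,4)
  for (i in seq_len(n - 1L)) {
    si <- enc[i, ]
    for (j in (i + 1L):n) {
      sj <- enc[j, ]
      ok <- !is.na(si) & !is.na(sj)
      m <- sum(ok)
      if (m == 0L) { D[i, j] <- D[j, i] <- NA_real_; next }
      a <- si[ok]; b <- sj[ok]
      diff <- a != b
      ts <- diff & ((a == 1L & b == 3L) | (a == 3L & b == 1L) |
                      (a == 2L & b == 4L) | (a == 4L & b == 2L))
      P <- sum(ts) / m
      Q <- sum(diff & !ts) / m
      gc <- (sum(a == 2L | a == 3L) + sum(b == 2L | b == 3L)) / (2 * m)
      h <- 2 * gc * (1 - gc)
      w1 <- if (h > 0) 1 - P / h - Q else NA_real_
      w2 <- 1 - 2 * Q
      d <- tamura_terms(P, Q, h, w1, w2, gamma_a)
      if (is.na(d)) saturated <- saturated + 1L
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated > 0L)
    warnf("%d saturated pair(s) reported as NA", saturated)
  attr(D, "method") <- if (is.finite(gamma_a)) "tamura+gamma" else "tamura"
  attr(D, "gamma_a") <- gamma_a
  class(D) <- c("DistanceMatrixSeq", class(D))
  D
}

tamura_terms <- function(P, Q, h, w1, w2, a) {
  if (w2 <= 0) return(NA_real_)
  if (h == 0) {
    if (P > 0) return(NA_real_)
    t1 <- 0
  } else {
    if (is.na(w1) || w1 <= 0) return(NA_real_)
    t1 <- if (is.finite(a)) h * a * (w1^(-1 / a) - 1) else -h * log(w1)
  }
  t2 <- if (is.finite(a)) 0.5 * (1 - h) * a * (w2^(-1 / a) - 1)
        else -0.5 * (1 - h) * log(w2)
  t1 + t2
}

#' Pairwise difference counts between sequences
#'
#' Number of differing sites per sequence pair with pairwise deletion of
#' missing data; the conventional (squared-Euclidean) molecular distance fed
#' to AMOVA.
#'
#' @param aln an [alignment()] object.
#' @return Symmetric integer-valued matrix of class `DistanceMatrixSeq`.
#' @export
pairwise_differences <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    si <- enc[i, ]
    for (j in (i + 1L):n) {
      sj <- enc[j, ]
      ok <- !is.na(si) & !is.na(sj)
      D[i, j] <- D[j, i] <- sum(si[ok] != sj[ok])
    }
  }
  attr(D, "method") <- "pairwise_differences"
  class(D) <- c("DistanceMatrixSeq", class(D))
  D
}
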