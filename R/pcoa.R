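#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it.
#' Coordinates are built from positive eigenvalues only; negative
#' eigenvalues (non-Euclidean input) are reported.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_axes maximum number of axes to return.
#' @return Object of class `Ordination`: `coordinates` (points x axes),
#'   `eigenvalues` (all, descending), `percent_variance` (per returned
#'   axis, relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(unclass(d))
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10 * max(abs(e$values), 1e-300))
  naxes <- min(n_axes, length(pos))
  coords <- if (naxes > 0L)
    e$vectors[, pos[seq_len(naxes)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(naxes)]]), naxes)
  else matrix(0, n, 0)
  rownames(coords) <- rownames(d)
  colnames(coords) <- if (naxes > 0L) paste0("Axis", seq_len(naxes)) else character(0)
  pv <- if (length(pos)) 100 * e$values[pos[seq_len(naxes)]] / sum(e$values[pos])
        else numeric(0)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 percent_variance = pv),
            class = "Ordination")
}

#' @export
print.Ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d axes (%s%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f", x$percent_variance), collapse = ", ")))
  invisible(x)
}
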