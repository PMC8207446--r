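## ABC scenario choice: summary statistics, reference table, direct
## (k-nearest-neighbour) posterior estimator, confidence evaluation.

## ---- fast summary-statistic engine ---------------------------------------

## unique-haplotype reduction of an alignment: counts per pop x haplotype
## and the haplotype pairwise-difference matrix (complete data assumed for
## simulated input; missing sites are tolerated and compared pairwise).
hap_reduce <- function(aln, pm) {
  ids <- intersect(aln$sample_ids, names(pm$assignments))
  enc <- encode_alignment(aln)[ids, , drop = FALSE]
  ## work on variable sites only: invariant sites never contribute
  ## differences under pairwise deletion
  pres <- 0L
  for (b in 1:4) pres <- pres + (colSums(enc == b, na.rm = TRUE) > 0L)
  enc <- enc[, pres >= 2L, drop = FALSE]
  n <- nrow(enc)
  key <- if (ncol(enc))
    do.call(paste, c(as.data.frame(enc), sep = ","))
  else rep("", n)
  uh <- unique(key)
  hidx <- match(key, uh)
  H <- length(uh)
  um <- enc[match(uh, key), , drop = FALSE]
  ## difference counts between unique haplotypes via indicator cross-products
  eq <- matrix(0, H, H)
  for (b in 1:4) {
    I <- (um == b); I[is.na(I)] <- FALSE
    eq <- eq + tcrossprod(I)
  }
  shared <- if (anyNA(um)) tcrossprod(!is.na(um)) else matrix(ncol(um), H, H)
  D <- shared - eq
  diag(D) <- 0
  pops <- pm$populations
  cnt <- matrix(0, length(pops), H, dimnames = list(pops, NULL))
  pv <- pm$assignments[ids]
  for (i in seq_along(ids)) cnt[pv[i], hidx[i]] <- cnt[pv[i], hidx[i]] + 1
  list(counts = cnt, D = D, enc_hap = um)
}

## exact two-population AMOVA phi from haplotype counts + distance matrix
phi_pair_from_counts <- function(cA, cB, D) {
  nA <- sum(cA); nB <- sum(cB); N <- nA + nB
  if (nA < 2 || nB < 2) return(NA_real_)
  qf <- function(x, y) as.numeric(x %*% D %*% y)
  ssd_w <- qf(cA, cA) / (2 * nA) + qf(cB, cB) / (2 * nB)
  cc <- cA + cB
  ssd_t <- qf(cc, cc) / (2 * N)
  ssd_a <- ssd_t - ssd_w
  s2w <- ssd_w / (N - 2)
  nprime <- (N - (nA^2 + nB^2) / N)
  s2a <- (ssd_a - s2w) / nprime
  tot <- s2a + s2w
  if (tot == 0) 0 else s2a / tot
}

## per-pop mean pairwise differences from haplotype counts
pi_from_counts <- function(cc, D) {
  n <- sum(cc)
  if (n < 2) return(NA_real_)
  as.numeric(cc %*% D %*% cc) / (n * (n - 1))
}

## per-pop segregating sites from the haplotypes present
S_from_counts <- function(cc, enc_hap) {
  sel <- which(cc > 0)
  if (length(sel) < 2L) return(0L)
  e <- enc_hap[sel, , drop = FALSE]
  pres <- 0L
  for (b in 1:4) pres <- pres + (colSums(e == b, na.rm = TRUE) > 0L)
  sum(pres >= 2L)
}

## microsatellite per-locus allele-count arrays: list over loci of
## (pop x allele-state counts), plus per-locus per-pop (n_genotyped, Ho)
msat_counts <- function(gt, pm) {
  ids <- intersect(gt$sample_ids, names(pm$assignments))
  i <- match(ids, gt$sample_ids)
  pops <- pm$populations
  pidx <- match(pm$assignments[ids], pops)
  np <- length(pops)
  lapply(seq_along(gt$locus_ids), function(j) {
    a1 <- gt$a1[i, j]; a2 <- gt$a2[i, j]
    ok <- !is.na(a1)
    vals <- c(a1[ok], a2[ok])
    pp <- c(pidx[ok], pidx[ok])
    states <- sort(unique(vals))
    cnt <- matrix(0, np, length(states),
                  dimnames = list(pops, states))
    idx <- (match(vals, states) - 1L) * np + pp
    tb <- tabulate(idx, np * length(states))
    cnt[] <- tb
    n_g <- tabulate(pidx[ok], np)
    ho <- vapply(seq_len(np), function(p) {
      sel <- ok & pidx == p
      if (!any(sel)) NA_real_ else mean(a1[sel] != a2[sel])
    }, 0)
    list(counts = cnt, n = n_g, Ho = ho, states = states)
  })
}

## Nei-Chesser corrected Hs/Ht for a subset of populations of one locus
nc_pair <- function(lc, sel) {
  cnt <- lc$counts[sel, , drop = FALSE]
  ns <- lc$n[sel]; hos <- lc$Ho[sel]
  keep <- ns > 0
  if (sum(keep) < 2L) return(NULL)
  cnt <- cnt[keep, , drop = FALSE]; ns <- ns[keep]; hos <- hos[keep]
  k <- nrow(cnt)
  P <- cnt / (2 * ns)
  ntilde <- k / sum(1 / ns)
  x2bar <- mean(rowSums(P^2))
  xbar2 <- sum(colMeans(P)^2)
  Ho <- mean(hos)
  Hs <- ntilde / (ntilde - 1) * (1 - x2bar - Ho / (2 * ntilde))
  Ht <- 1 - xbar2 + Hs / (ntilde * k) - Ho / (2 * ntilde * k)
  c(Hs = Hs, Ht = Ht)
}

#' Compute the fixed ABC summary-statistic vector
#'
#' The ordered statistic set used for ABC distances: per population, mtDNA
#' Tajima's D, mtDNA mean pairwise differences and microsatellite mean
#' genic diversity (unbiased expected heterozygosity averaged over loci);
#' per population pair, mtDNA pairwise Phi-ST (AMOVA on difference counts),
#' microsatellite pairwise FST (bias-corrected GST, multilocus
#' ratio-of-averages) and Goldstein's (delta-mu)^2. Undefined components
#' (e.g. monomorphic data) are imputed as 0, the value they take at zero
#' divergence/diversity.
#'
#' @param ds a [make_synthetic_study()] result, or any list with elements
#'   `mt_aln`, `mt_popmap`, `genotypes`, `msat_popmap`.
#' @return Named numeric vector of class `SummaryStatsVector`; the name
#'   layout is stable across datasets with the same populations.
#' @export
compute_summary_stats <- function(ds) {
  pm <- ds$mt_popmap
  pops <- pm$populations
  for (p in pops)
    if (!p %in% ds$msat_popmap$populations)
      stopf("population '%s' missing from microsatellite data", p)
  hr <- hap_reduce(ds$mt_aln, pm)
  np <- length(pops)
  mt_D <- mt_pi <- numeric(np)
  for (p in seq_len(np)) {
    cc <- hr$counts[p, ]
    n <- sum(cc)
    pi <- pi_from_counts(cc, hr$D)
    S <- S_from_counts(cc, hr$enc_hap)
    mt_pi[p] <- if (is.na(pi)) 0 else pi
    mt_D[p] <- if (n >= 4 && S > 0) tajima_d_stat(S, pi, n) else 0
  }
  mc <- msat_counts(ds$genotypes, ds$msat_popmap)
  ppos <- match(pops, ds$msat_popmap$populations)
  he <- vapply(seq_len(np), function(p) {
    hes <- vapply(mc, function(lc) {
      T2 <- 2 * lc$n[ppos[p]]
      if (T2 < 2) return(NA_real_)
      pr <- lc$counts[ppos[p], ] / T2
      T2 / (T2 - 1) * (1 - sum(pr^2))
    }, 0)
    mean(hes, na.rm = TRUE)
  }, 0)
  npair <- np * (np - 1) / 2
  phi <- fst <- dmu <- numeric(npair)
  nm_pair <- character(npair)
  pid <- 0L
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    pid <- pid + 1L
    nm_pair[pid] <- paste0(pops[i], ".", pops[j])
    ph <- phi_pair_from_counts(hr$counts[i, ], hr$counts[j, ], hr$D)
    phi[pid] <- if (is.na(ph)) 0 else ph
    hs <- ht <- numeric(0)
    d2 <- numeric(0)
    for (lc in mc) {
      comp <- nc_pair(lc, ppos[c(i, j)])
      if (!is.null(comp)) { hs <- c(hs, comp["Hs"]); ht <- c(ht, comp["Ht"]) }
      ni <- lc$n[ppos[i]]; nj <- lc$n[ppos[j]]
      if (ni > 0 && nj > 0) {
        mi <- sum(lc$counts[ppos[i], ] * lc$states) / (2 * ni)
        mj <- sum(lc$counts[ppos[j], ] * lc$states) / (2 * nj)
        d2 <- c(d2, (mi - mj)^2)
      }
    }
    fst[pid] <- if (length(hs) && mean(ht) > 0)
      (mean(ht) - mean(hs)) / mean(ht) else 0
    dmu[pid] <- if (length(d2)) mean(d2) else 0
  }
  out <- c(stats::setNames(mt_D, paste0("mtD.", pops)),
           stats::setNames(mt_pi, paste0("mtPi.", pops)),
           stats::setNames(he, paste0("He.", pops)),
           stats::setNames(phi, paste0("mtPhiST.", nm_pair)),
           stats::setNames(fst, paste0("msatFST.", nm_pair)),
           stats::setNames(dmu, paste0("dmu2.", nm_pair)))
  class(out) <- c("SummaryStatsVector", "numeric")
  out
}

## ---- reference table and model choice ------------------------------------

## robust per-statistic scale: MAD, falling back to SD, then 1
robust_scales <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    s <- stats::mad(X[, j])
    if (s > 0) return(s)
    s <- stats::sd(X[, j])
    if (!is.na(s) && s > 0) s else 1
  }, 0)
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter sets from the
#' priors, simulates a full synthetic dataset for each, and summarizes it
#' with [compute_summary_stats()]. Per-statistic robust scale factors
#' (median absolute deviation over the whole table, falling back to the
#' standard deviation and then to 1 for degenerate statistics) are stored
#' for distance normalization.
#'
#' @param scenarios character vector of scenario ids (names of
#'   `config$scenarios`).
#' @param n_per_scenario simulated datasets per scenario.
#' @param seed integer seed.
#' @param config a [synthetic_config()].
#' @param progress print a progress line per 500 simulations.
#' @return Object of class `ReferenceTable`: `stats` (matrix), `scenario`
#'   (character), `params` (list of drawn value vectors), `scales`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, seed,
                                  config = synthetic_config(),
                                  progress = FALSE) {
  if (!all(scenarios %in% names(config$scenarios)))
    stopf("unknown scenario id(s)")
  rows <- list(); labs <- character(0); pars <- list()
  r <- 0L
  for (sid in scenarios) {
    for (b in seq_len(n_per_scenario)) {
      r <- r + 1L
      ds <- make_synthetic_study(sid, derive_seed(seed, r), config = config)
      rows[[r]] <- compute_summary_stats(ds)
      labs[r] <- sid
      pars[[r]] <- ds$params$values
      if (progress && r %% 500L == 0L)
        message(sprintf("reference table: %d simulations", r))
    }
  }
  X <- do.call(rbind, rows)
  structure(list(stats = X, scenario = labs, params = pars,
                 scales = robust_scales(X), seed = seed),
            class = "ReferenceTable")
}

#' @export
print.ReferenceTable <- function(x, ...) {
  cat(sprintf("ReferenceTable: %d rows x %d statistics (%s)\n",
              nrow(x$stats), ncol(x$stats),
              paste(sprintf("%s: %d", names(table(x$scenario)),
                            table(x$scenario)), collapse = ", ")))
  invisible(x)
}

#' Direct-approach ABC posterior probabilities
#'
#' Estimates the posterior probability of each scenario as its frequency
#' among the `k` simulated datasets closest to the observed
#' summary-statistic vector in Euclidean distance after dividing every
#' statistic by its robust scale factor. Ties at the k-th distance are
#' broken by stable row order.
#'
#' @param observed a [compute_summary_stats()] vector.
#' @param table a [build_reference_table()] result.
#' @param k number of nearest neighbours (default 500).
#' @param exclude optional row indices to ignore (used for holdout
#'   confidence evaluation).
#' @return Object of class `ModelChoiceResult`: `posterior` (named, sums to
#'   1), `k`, `kth_distance`.
#' @export
direct_posterior <- function(observed, table, k = 500L, exclude = NULL) {
  stopifnot(inherits(table, "ReferenceTable"))
  if (!is_count(k)) stopf("k must be a positive integer")
  X <- table$stats; labs <- table$scenario
  if (!is.null(exclude)) { X <- X[-exclude, , drop = FALSE]; labs <- labs[-exclude] }
  if (k > nrow(X)) stopf("k (%d) exceeds table rows (%d)", k, nrow(X))
  obs <- as.numeric(observed)[match(colnames(X), names(observed))]
  if (anyNA(obs)) stopf("observed vector missing statistics present in the table")
  Z <- sweep(X, 2L, table$scales, "/")
  oz <- obs / table$scales
  d2 <- rowSums(sweep(Z, 2L, oz, "-")^2)
  nn <- order(d2)[seq_len(k)]          # order() is stable: ties by row order
  scen <- sort(unique(table$scenario))
  post <- vapply(scen, function(s) mean(labs[nn] == s), 0)
  structure(list(posterior = post, k = k,
                 kth_distance = sqrt(d2[nn[k]])),
            class = "ModelChoiceResult")
}

#' @export
print.ModelChoiceResult <- function(x, ...) {
  cat("ABC direct posterior probabilities (k =", x$k, "):\n")
  print(round(x$posterior, 4))
  invisible(x)
}

#' Confidence of ABC scenario choice
#'
#' Estimates per-scenario misclassification rates from pseudo-observed
#' datasets: either held-out reference-table rows (`method = "holdout"`,
#' leave-one-out) or fresh simulations from the priors
#' (`method = "fresh"`). A pseudo-observed dataset is classified by
#' [direct_posterior()]; the error is the rate at which the true scenario
#' does not obtain the highest posterior.
#'
#' @param table a [build_reference_table()] result.
#' @param k nearest neighbours for classification.
#' @param n_pods number of pseudo-observed datasets.
#' @param seed integer seed.
#' @param method `"holdout"` or `"fresh"`.
#' @param config needed for `method = "fresh"`.
#' @return List with `confusion` (true x chosen counts), `error_rates`
#'   (per true scenario), `overall_error`.
#' @export
scenario_confidence <- function(table, k = 500L, n_pods = 500L, seed = NULL,
                                method = c("holdout", "fresh"),
                                config = synthetic_config()) {
  stopifnot(inherits(table, "ReferenceTable"))
  method <- match.arg(method)
  if (!is_count(n_pods)) stopf("n_pods must be a positive integer")
  if (nrow(table$stats) <= k) stopf("reference table too small for k")
  scen <- sort(unique(table$scenario))
  conf <- matrix(0L, length(scen), length(scen),
                 dimnames = list(true = scen, chosen = scen))
  with_seed(seed, {
    if (method == "holdout") {
      idx <- sample.int(nrow(table$stats), n_pods,
                        replace = n_pods > nrow(table$stats))
      for (i in idx) {
        mc <- direct_posterior(table$stats[i, ], table, k = k, exclude = i)
        pick <- names(which.max(mc$posterior))
        conf[table$scenario[i], pick] <- conf[table$scenario[i], pick] + 1L
      }
    } else {
      per <- ceiling(n_pods / length(scen))
      done <- 0L
      for (s in scen) for (b in seq_len(per)) {
        if (done >= n_pods) break
        done <- done + 1L
        ds <- make_synthetic_study(s, derive_seed(seed %||% 0, 1e6 + done),
                                   config = config)
        mc <- direct_posterior(compute_summary_stats(ds), table, k = k)
        pick <- names(which.max(mc$posterior))
        conf[s, pick] <- conf[s, pick] + 1L
      }
    }
  })
  err <- 1 - diag(conf) / pmax(rowSums(conf), 1L)
  list(confusion = conf, error_rates = err,
       overall_error = 1 - sum(diag(conf)) / sum(conf))
}
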