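## Heterozygosity-excess bottleneck test (Cornuet & Luikart 1996 approach):
## for each polymorphic locus the expected equilibrium heterozygosity Heq is
## obtained by simulating coalescent samples conditioned on the observed
## allele count k under the chosen mutation model, and an across-locus
## Wilcoxon signed-rank test asks whether observed He systematically
## exceeds Heq (the bottleneck signature).

## coalescent branches for n genes: list(len =, desc = list of tip sets).
## Nodes are created in coalescence order so a parent's index always
## exceeds its children's, letting descendant sets accumulate in one pass.
coal_branches <- function(n) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  ntime <- numeric(nn)
  active <- seq_len(n)
  k <- n; t <- 0; nxt <- n + 1L
  while (k > 1L) {
    t <- t - log(stats::runif(1L)) / (k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    parent[active[pair]] <- nxt
    ntime[nxt] <- t
    active[pair[1L]] <- nxt
    active <- active[-pair[2L]]
    k <- k - 1L
    nxt <- nxt + 1L
  }
  desc <- vector("list", nn)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(nn - 1L))
    desc[[parent[v]]] <- c(desc[[parent[v]]], desc[[v]])
  list(len = ntime[parent[seq_len(nn - 1L)]] - ntime[seq_len(nn - 1L)],
       desc = desc[seq_len(nn - 1L)])
}

## single-population coalescent with a piecewise-constant size history:
## sizes[1] applies from the present back to change_time (generations),
## sizes[2] earlier. Pairwise rate 1/N; branch lengths in generations.
coal_branches_varN <- function(n, sizes, change_time) {
  nn <- 2L * n - 1L
  parent <- integer(nn)
  ntime <- numeric(nn)
  active <- seq_len(n)
  k <- n; t <- 0; nxt <- n + 1L
  while (k > 1L) {
    repeat {
      N <- if (t < change_time) sizes[1L] else sizes[2L]
      dt <- -log(stats::runif(1L)) * N / (k * (k - 1) / 2)
      if (t < change_time && t + dt >= change_time) { t <- change_time; next }
      t <- t + dt
      break
    }
    pair <- sample.int(k, 2L)
    parent[active[pair]] <- nxt
    ntime[nxt] <- t
    active[pair[1L]] <- nxt
    active <- active[-pair[2L]]
    k <- k - 1L
    nxt <- nxt + 1L
  }
  desc <- vector("list", nn)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(nn - 1L))
    desc[[parent[v]]] <- c(desc[[parent[v]]], desc[[v]])
  list(len = ntime[parent[seq_len(nn - 1L)]] - ntime[seq_len(nn - 1L)],
       desc = desc[seq_len(nn - 1L)],
       child_time = ntime[seq_len(nn - 1L)])
}

## sample n gene copies under the infinite-alleles model from a piecewise
## size history: each mutation creates a fresh allele; the mutation nearest
## each tip wins (branches processed oldest child first)
sim_iam_sample_varN <- function(n, mu, sizes, change_time) {
  br <- coal_branches_varN(n, sizes, change_time)
  S <- stats::rpois(1L, mu * sum(br$len))
  val <- integer(n)              # 0 = ancestral allele
  if (S > 0L) {
    hit <- unique(sample.int(length(br$len), S, replace = TRUE, prob = br$len))
    for (b in hit[order(br$child_time[hit], decreasing = TRUE)])
      val[br$desc[[b]]] <- b     # branch id as fresh allele label
  }
  val
}

## sample n gene copies under SMM/TPM from a piecewise-size history;
## mutation rate mu per generation
sim_msat_sample_varN <- function(n, mu, sizes, change_time,
                                 p_single = 1, geom_p = 0.5) {
  br <- coal_branches_varN(n, sizes, change_time)
  S <- stats::rpois(1L, mu * sum(br$len))
  val <- integer(n)
  if (S > 0L) {
    hit <- sample.int(length(br$len), S, replace = TRUE, prob = br$len)
    sgn <- sample(c(-1L, 1L), S, replace = TRUE)
    size <- ifelse(stats::runif(S) < p_single, 1L, 1L + stats::rgeom(S, geom_p))
    for (s in seq_len(S)) {
      d <- br$desc[[hit[s]]]
      val[d] <- val[d] + sgn[s] * size[s]
    }
  }
  val
}

## one equilibrium sample of n genes under SMM/TPM: returns allele values
sim_msat_sample <- function(n, theta, p_single = 1, geom_p = 0.5) {
  br <- coal_branches(n)
  S <- stats::rpois(1L, theta / 2 * sum(br$len))
  val <- integer(n)
  if (S > 0L) {
    hit <- sample.int(length(br$len), S, replace = TRUE, prob = br$len)
    sgn <- sample(c(-1L, 1L), S, replace = TRUE)
    size <- ifelse(stats::runif(S) < p_single, 1L,
                   1L + stats::rgeom(S, geom_p))
    for (s in seq_len(S)) {
      d <- br$desc[[hit[s]]]
      val[d] <- val[d] + sgn[s] * size[s]
    }
  }
  val
}

## one equilibrium sample under IAM via the Hoppe urn: allele labels
sim_iam_sample <- function(n, theta) {
  lab <- integer(n)
  nxt <- 1L
  for (i in seq_len(n)) {
    if (stats::runif(1L) < theta / (theta + i - 1)) {
      lab[i] <- nxt; nxt <- nxt + 1L
    } else lab[i] <- lab[sample.int(i - 1L, 1L)]
  }
  lab
}

unbiased_he <- function(values) {
  T2 <- length(values)
  p <- as.numeric(table(values)) / T2
  T2 / (T2 - 1) * (1 - sum(p^2))
}

n_alleles <- function(values) length(unique(values))

## expected allele count under IAM (Ewens): E[K] = sum theta/(theta+i-1)
iam_expected_k <- function(n, theta) sum(theta / (theta + seq_len(n) - 1))

## tune theta so the expected allele count matches k_obs
tune_theta <- function(n, k_obs, simulate, n_pilot = 100L, iter = 12L) {
  lo <- log(1e-3); hi <- log(1e3)
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    kbar <- mean(replicate(n_pilot, n_alleles(simulate(exp(mid)))))
    if (kbar < k_obs) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Heterozygosity-excess bottleneck test
#'
#' For every population and every polymorphic locus, simulates `n_sim`
#' coalescent samples of the same number of gene copies conditioned on the
#' observed allele count `k` under the chosen mutation model (theta tuned by
#' bisection so the expected allele count matches `k`, then simulations
#' retained only when they produce exactly `k` alleles), yielding the
#' distribution of equilibrium heterozygosity `Heq`. A one-tailed Wilcoxon
#' signed-rank test across loci then asks whether observed (unbiased) `He`
#' exceeds `Heq` more often than expected at mutation-drift equilibrium.
#'
#' @param gt a [genotype_table()].
#' @param pm a [popmap()].
#' @param model mutation model: `"TPM"` (two-phase), `"SMM"` (strict
#'   stepwise) or `"IAM"` (infinite alleles).
#' @param tpm_p proportion of single-step mutations under TPM.
#' @param tpm_geom_p geometric parameter of the multi-step tail under TPM
#'   (multi-step size is `1 + Geometric(tpm_geom_p)`).
#' @param n_sim number of retained equilibrium simulations per locus.
#' @param seed optional integer seed.
#' @param tune_n_pilot,tune_iter pilot-simulation count and bisection
#'   iterations for the theta tuning step (SMM/TPM).
#' @details The across-locus test uses the probability-integral transform:
#'   for each locus the mid-p probability `P = Pr(Heq <= He)` is uniform at
#'   mutation-drift equilibrium, and a one-tailed Wilcoxon signed-rank test
#'   of `P - 1/2` detects systematic heterozygosity excess. (Testing
#'   `He - mean(Heq)` directly is anticonservative because the conditional
#'   `Heq` distribution is left-skewed.)
#' @return Object of class `BottleneckResult`: `per_locus` data.frame
#'   (`population, locus, n_genes, k, He, Heq_mean, Heq_sd, std_diff,
#'   p_heq`) and `tests` data.frame (`population, n_loci, p_excess,
#'   low_power`).
#' @export
bottleneck_test <- function(gt, pm, model = c("TPM", "SMM", "IAM"),
                            tpm_p = 0.9, tpm_geom_p = 0.5,
                            n_sim = 1000L, seed = NULL,
                            tune_n_pilot = 100L, tune_iter = 12L) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(pm, "PopulationMap"))
  model <- match.arg(model)
  per_locus <- list(); tests <- list()
  stream <- 0L
  for (pop in pm$populations) {
    i <- match(intersect(pop_samples(pm, pop), gt$sample_ids), gt$sample_ids)
    diffs <- numeric(0)
    for (j in seq_along(gt$locus_ids)) {
      a <- c(gt$a1[i, j], gt$a2[i, j]); a <- a[!is.na(a)]
      if (length(a) < 4L) next
      k_obs <- n_alleles(a)
      if (k_obs < 2L) next
      n_genes <- length(a)
      He <- unbiased_he(a)
      stream <- stream + 1L
      res <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, stream), {
        simulate <- switch(model,
          IAM = function(th) sim_iam_sample(n_genes, th),
          SMM = function(th) sim_msat_sample(n_genes, th, p_single = 1),
          TPM = function(th) sim_msat_sample(n_genes, th, p_single = tpm_p,
                                             geom_p = tpm_geom_p))
        theta <- if (model == "IAM") {
          lo <- 1e-4; hi <- 1e4
          for (it in 1:60) {
            mid <- sqrt(lo * hi)
            if (iam_expected_k(n_genes, mid) < k_obs) lo <- mid else hi <- mid
          }
          sqrt(lo * hi)
        } else tune_theta(n_genes, k_obs, simulate,
                          n_pilot = tune_n_pilot, iter = tune_iter)
        heq <- numeric(0); attempts <- 0L
        while (length(heq) < n_sim && attempts < 50L * n_sim) {
          attempts <- attempts + 1L
          v <- simulate(theta)
          if (n_alleles(v) == k_obs) heq[length(heq) + 1L] <- unbiased_he(v)
        }
        heq
      })
      if (length(res) < 20L) {
        warnf("locus %s / population %s: too few conditioned simulations",
              gt$locus_ids[j], pop)
        next
      }
      mu <- mean(res); sdv <- stats::sd(res)
      sd_use <- if (is.na(sdv) || sdv == 0) NA_real_ else sdv
      ## mid-p probability-integral transform: uniform at equilibrium
      p_heq <- (sum(res < He) + 0.5 * sum(res == He)) / length(res)
      per_locus[[length(per_locus) + 1L]] <- data.frame(
        population = pop, locus = gt$locus_ids[j], n_genes = n_genes,
        k = k_obs, He = He, Heq_mean = mu, Heq_sd = sdv,
        std_diff = (He - mu) / sd_use, p_heq = p_heq)
      diffs <- c(diffs, p_heq - 0.5)
    }
    p_exc <- if (length(diffs) >= 2L)
      suppressWarnings(stats::wilcox.test(diffs, mu = 0,
                                          alternative = "greater")$p.value)
    else NA_real_
    tests[[length(tests) + 1L]] <- data.frame(
      population = pop, n_loci = length(diffs), p_excess = p_exc,
      low_power = length(diffs) < 4L)
  }
  structure(list(per_locus = do.call(rbind, per_locus),
                 tests = do.call(rbind, tests),
                 model = model, n_sim = n_sim, seed = seed),
            class = "BottleneckResult")
}

#' @export
print.BottleneckResult <- function(x, ...) {
  cat(sprintf("Bottleneck heterozygosity-excess test (%s model):\n", x$model))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
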