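#' Simulate a structured-coalescent genealogy under a scenario
#'
#' Backward-in-time coalescent with demes: within deme `i` holding `k`
#' lineages the coalescence rate is `choose(k, 2) / (inheritance_scaler *
#' N_i)` per generation, so with `inheritance_scaler = 1` the expected
#' two-lineage TMRCA in a deme of size `N` is `N` generations. Use
#' `inheritance_scaler = 2` for autosomal diploid loci (2N gene copies) and
#' `0.25` for maternally inherited haploid loci. At a divergence event all
#' lineages of the derived deme move to the ancestral deme; at an admixture
#' event each recipient lineage moves to the donor with the event's
#' proportion.
#'
#' @param ps a [draw_params()] result.
#' @param sc the [scenario()] the parameters were drawn from.
#' @param samples_per_pop named integer vector: sampled gene copies per deme.
#' @param inheritance_scaler multiplier applied to deme sizes (see above).
#' @return Object of class `GeneTree`: `n_tips`, `tip_pop` (deme per tip),
#'   `parent` (parent index per node; 0 at the root), `node_time` (tips
#'   first, then internal nodes in coalescence order; generations).
#' @export
simulate_genealogy <- function(ps, sc, samples_per_pop, inheritance_scaler = 1) {
  if (!inherits(ps, "ParamSet") || !inherits(sc, "Scenario"))
    stopf("ps must be a ParamSet and sc a Scenario")
  pops <- sc$populations
  if (is.null(names(samples_per_pop)) ||
      !all(names(samples_per_pop) %in% pops))
    stopf("samples_per_pop must be named by scenario populations")
  if (any(ps$sizes <= 0)) stopf("effective sizes must be positive")
  n <- sum(samples_per_pop)
  ndeme <- length(pops)
  tip_pop <- rep(names(samples_per_pop), samples_per_pop)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  lin_nodes <- seq_len(n)
  lin_deme <- match(tip_pop, pops)
  sizes <- inheritance_scaler * as.numeric(ps$sizes[pops])
  events <- ps$events
  ev_i <- 1L
  t <- 0
  nxt <- n + 1L
  k <- tabulate(lin_deme, ndeme)
  while (length(lin_nodes) > 1L) {
    rates <- k * (k - 1) / 2 / sizes
    R <- sum(rates)
    t_event <- if (ev_i <= length(events)) events[[ev_i]]$time else Inf
    dt <- if (R > 0) -log(stats::runif(1L)) / R else Inf
    if (t + dt < t_event) {
      t <- t + dt
      d <- sample.int(ndeme, 1L, prob = rates)
      idx <- which(lin_deme == d)
      pair <- idx[sample.int(length(idx), 2L)]
      node_time[nxt] <- t
      parent[lin_nodes[pair]] <- nxt
      lin_nodes[pair[1L]] <- nxt
      lin_deme <- lin_deme[-pair[2L]]
      lin_nodes <- lin_nodes[-pair[2L]]
      lin_deme[pair[1L] - (pair[2L] < pair[1L])] <- d
      k[d] <- k[d] - 1L
      nxt <- nxt + 1L
    } else if (is.finite(t_event)) {
      t <- t_event
      ev <- events[[ev_i]]
      ev_i <- ev_i + 1L
      if (ev$type == "divergence") {
        from <- match(ev$derived, pops); to <- match(ev$ancestral, pops)
        lin_deme[lin_deme == from] <- to
      } else {
        from <- match(ev$recipient, pops); to <- match(ev$donor, pops)
        sel <- which(lin_deme == from)
        mv <- sel[stats::runif(length(sel)) < ev$prop]
        lin_deme[mv] <- to
      }
      k <- tabulate(lin_deme, ndeme)
    } else {
      stopf("scenario leaves %d lineages stranded in separate demes",
            length(lin_nodes))
    }
  }
  structure(list(n_tips = n, tip_pop = tip_pop, parent = parent,
                 node_time = node_time),
            class = "GeneTree")
}

## edges of a GeneTree ordered root-first (parent time descending)
genetree_edges <- function(gt) {
  child <- which(gt$parent > 0L)
  ord <- order(gt$node_time[gt$parent[child]], decreasing = TRUE)
  child <- child[ord]
  cbind(parent = gt$parent[child], child = child,
        length = gt$node_time[gt$parent[child]] - gt$node_time[child])
}

#' Simulate sequence evolution (HKY + gamma) on a gene tree
#'
#' Evolves `L` sites down the genealogy under the HKY substitution model
#' with continuous gamma rate multipliers per site (mean 1, shape
#' `gamma_shape`; `NULL` disables heterogeneity). The root sequence is
#' drawn from the stationary base frequencies and substitutions are placed
#' by uniformization, which is exact for the HKY chain. The substitution
#' rate is per site per generation; branch lengths are in generations.
#'
#' @param gtree a [simulate_genealogy()] result.
#' @param model list with `rate`, `kappa`, `base_freqs` (named `A,C,G,T`
#'   summing to 1) and optional `gamma_shape`.
#' @param L number of sites.
#' @param tip_labels optional tip names (default `seq1..seqN`).
#' @param locus_label locus name for the returned alignment.
#' @return An [alignment()] of the tip sequences.
#' @export
mutate_sequence <- function(gtree, model, L, tip_labels = NULL,
                            locus_label = "simulated") {
  stopifnot(inherits(gtree, "GeneTree"))
  f <- model$base_freqs
  if (is.null(names(f))) names(f) <- c("A", "C", "G", "T")
  f <- f[c("A", "C", "G", "T")]
  if (abs(sum(f) - 1) > 1e-8) stopf("base frequencies must sum to 1")
  if (model$rate < 0) stopf("substitution rate must be >= 0")
  kappa <- model$kappa %||% 1
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (i + j) %in% c(4, 6) && abs(i - j) == 2   # A<->G (1,3), C<->T (2,4)
    Q[i, j] <- f[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))                     # mean rate before scaling
  Q <- Q / mu                                 # mean rate 1
  lam <- max(-diag(Q))
  Rj <- diag(4) + Q / lam                     # uniformized jump matrix
  rates <- if (!is.null(model$gamma_shape) && is.finite(model$gamma_shape))
    stats::rgamma(L, shape = model$gamma_shape, rate = model$gamma_shape)
  else rep(1, L)

  n <- gtree$n_tips
  n_nodes <- 2L * n - 1L
  seqs <- matrix(NA_integer_, n_nodes, L)
  root <- which(gtree$parent == 0L)
  seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = f)
  edges <- genetree_edges(gtree)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]; t <- edges[e, 3L]
    s <- seqs[p, ]
    k <- stats::rpois(L, lam * model$rate * t * rates)
    todo <- which(k > 0L)
    while (length(todo)) {
      cur <- s[todo]                  # snapshot: one jump per site per round
      for (st in 1:4) {
        sel <- which(cur == st)
        if (length(sel))
          s[todo[sel]] <- sample.int(4L, length(sel), replace = TRUE,
                                     prob = Rj[st, ])
      }
      k[todo] <- k[todo] - 1L
      todo <- todo[k[todo] > 0L]
    }
    seqs[ch, ] <- s
  }
  bases <- c("A", "C", "G", "T")
  tips <- seqs[seq_len(n), , drop = FALSE]
  cm <- matrix(bases[tips], nrow = n)
  ids <- tip_labels %||% paste0("seq", seq_len(n))
  alignment_from_matrix(ids, cm, locus_label = locus_label)
}

#' Simulate microsatellite evolution (generalized stepwise) on a gene tree
#'
#' Mutations are Poisson with the given rate per generation along each
#' branch; each mutation changes the allele size by +/-1 with probability
#' `p_single`, otherwise by `1 + Geometric(geom_p)` repeat units, with
#' reflection at the allele-size bounds (applied mutation by mutation).
#'
#' @param gtree a [simulate_genealogy()] result.
#' @param rate mutation rate per generation.
#' @param p_single probability of a single-step mutation.
#' @param bounds integer allele-size range `c(lo, hi)` with `hi - lo >= 1`.
#' @param geom_p geometric parameter of the multi-step tail.
#' @return Integer vector of tip allele sizes.
#' @export
mutate_microsat <- function(gtree, rate, p_single, bounds = c(10L, 49L),
                            geom_p = 0.5) {
  if (!inherits(gtree, "GeneTree")) stopf("gtree must be a GeneTree")
  if (rate < 0) stopf("mutation rate must be >= 0")
  lo <- bounds[1L]; hi <- bounds[2L]
  if (hi - lo < 1L) stopf("allele-size bounds must span at least 2 states")
  n <- gtree$n_tips
  n_nodes <- 2L * n - 1L
  val <- integer(n_nodes)
  root <- which(gtree$parent == 0L)
  val[root] <- as.integer(round((lo + hi) / 2))
  edges <- genetree_edges(gtree)
  nE <- nrow(edges)
  m_all <- stats::rpois(nE, rate * edges[, 3L])
  tot <- sum(m_all)
  if (tot > 0L) {
    sz <- rep(1L, tot)
    multi <- stats::runif(tot) >= p_single
    nm <- sum(multi)
    if (nm > 0L) sz[multi] <- 1L + stats::rgeom(nm, geom_p)
    steps_all <- sz * (2L * (stats::runif(tot) < 0.5) - 1L)
    ends <- cumsum(m_all)
  }
  for (e in seq_len(nE)) {
    a <- val[edges[e, 1L]]
    m <- m_all[e]
    if (m > 0L) {
      steps <- steps_all[(ends[e] - m + 1L):ends[e]]
      path <- a + cumsum(steps)
      if (min(path) < lo || max(path) > hi) {
        for (s in steps) {
          a <- a + s
          while (a < lo || a > hi) {
            if (a > hi) a <- 2L * hi - a
            if (a < lo) a <- 2L * lo - a
          }
        }
      } else a <- path[m]
    }
    val[edges[e, 2L]] <- a
  }
  val[seq_len(n)]
}
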