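#' Simulate range evolution on a dated tree
#'
#' Forward simulation of a DEC-family model with concrete parameters: a
#' root range (uniform single area unless given), anagenetic
#' dispersal/extirpation as a continuous-time Markov chain using the
#' stratum in effect at each moment, and daughter ranges sampled from the
#' cladogenesis table at each node. Histories in which any lineage goes
#' extinct (null range) before its tip are rejected and redrawn, so the
#' returned tip ranges are always non-empty.
#'
#' @param dt a [dated_tree()].
#' @param model a [dec_model()] with concrete parameters.
#' @param strat a [stratified_dispersal()] covering the tree depth.
#' @param space optional [enumerate_ranges()].
#' @param root_state optional state index for the root range.
#' @param seed optional integer seed.
#' @param max_tries rejection budget for extinct histories.
#' @return Named list mapping tip labels to character vectors of areas.
#' @export
simulate_range_history <- function(dt, model, strat, space = NULL,
                                   root_state = NULL, seed = NULL,
                                   max_tries = 100L) {
  stopifnot(inherits(dt, "DatedTree"), inherits(model, "DECModel"))
  areas <- colnames(strat$matrices[[1L]])
  space <- space %||% enumerate_ranges(areas, include_null = TRUE)
  Qs <- lapply(strat$matrices, function(m) anagenetic_rates(space, model, m))
  clado <- cladogenesis_table(space, model)
  singles <- which(lengths(space$states) == 1L)
  b <- strat$boundaries
  tr <- dt$tree
  ntip <- length(tr$tip.label)
  ages <- dt$ages
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  null_state <- space$null_state
  evolve <- function(st, t_old, t_young) {
    ## forward in time: age decreasing from t_old to t_young
    t <- t_old
    while (t > t_young + 1e-12) {
      if (!is.na(null_state) && st == null_state) return(st)
      s <- max(which(b > t - 1e-12))           # stratum containing age t
      seg_end <- max(t_young, b[s + 1L])
      rate <- -Qs[[s]][st, st]
      while (TRUE) {
        dt_ev <- if (rate > 0) stats::rexp(1L, rate) else Inf
        if (t - dt_ev <= seg_end) { t <- seg_end; break }
        t <- t - dt_ev
        p <- Qs[[s]][st, ]; p[st] <- 0
        st <- sample.int(length(p), 1L, prob = p)
        rate <- -Qs[[s]][st, st]
        if (!is.na(null_state) && st == null_state) return(st)
      }
    }
    st
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      st0 <- root_state %||% sample(singles, 1L)
      state <- integer(2L * ntip - 1L)
      root <- ntip + 1L
      state[root] <- st0
      ok <- TRUE
      ## preorder: internal nodes by decreasing age
      ord <- order(ages[(ntip + 1L):(2L * ntip - 1L)], decreasing = TRUE) + ntip
      for (nd in ord) {
        tab <- clado[[state[nd]]]
        if (is.null(tab)) { ok <- FALSE; break }
        ev <- sample.int(nrow(tab), 1L, prob = tab$prob)
        ch <- children[[as.character(nd)]]
        dst <- c(tab$left[ev], tab$right[ev])
        for (ci in 1:2) {
          st <- evolve(dst[ci], ages[nd], ages[ch[ci]])
          if (!is.na(null_state) && st == null_state) { ok <- FALSE; break }
          state[ch[ci]] <- st
        }
        if (!ok) break
      }
      if (ok) {
        res <- lapply(seq_len(ntip), function(i) areas[space$states[[state[i]]]])
        names(res) <- tr$tip.label
        return(res)
      }
    }
    stopf("no surviving range history in %d tries (extinction too likely)", max_tries)
  })
}

#' Simulate a dated pure-birth tree
#'
#' Yule tree rescaled to a given root age; a convenience generator for
#' synthetic haplogroup trees.
#'
#' @param n_tips number of tips.
#' @param root_age age of the root (time units of the analysis).
#' @param seed optional integer seed.
#' @return A [dated_tree()].
#' @export
simulate_yule_tree <- function(n_tips, root_age, seed = NULL) {
  with_seed(seed, {
    tr <- ape::rcoal(n_tips)
    tr$edge.length <- tr$edge.length * root_age /
      max(ape::node.depth.edgelength(tr))
    dated_tree(tr, tol = 1e-6)
  })
}
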