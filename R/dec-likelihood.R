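## Anagenetic rates, cladogenesis tables, and the time-stratified pruning
## likelihood for DEC-family range-evolution models.

#' Anagenetic rate matrix over range states
#'
#' Dispersal: `rate(range -> range + {a}) = d * sum_{b in range} m[b, a]`;
#' extirpation: `rate(range -> range - {a}) = e` (multipliers scale
#' dispersal only). Expansions leading out of the state space (range-size
#' cap) are dropped; the null range, when present, is absorbing. Rows sum
#' to zero.
#'
#' @param space an [enumerate_ranges()] state space.
#' @param model a [dec_model()].
#' @param multipliers positive areas x areas dispersal multiplier matrix.
#' @return Square rate matrix (`n_states` x `n_states`).
#' @export
anagenetic_rates <- function(space, model, multipliers) {
  stopifnot(inherits(space, "RangeStateSpace"), inherits(model, "DECModel"))
  b <- anagenetic_basis(space, multipliers)
  model$d * b$A + model$e * b$B
}

## rate-matrix basis: Q(d, e) = d * A + e * B (diagonals included), so the
## optimizer can rebuild Q by scalar multiplication
anagenetic_basis <- function(space, multipliers) {
  multipliers <- as.matrix(multipliers)
  n_area <- length(space$areas)
  if (!all(dim(multipliers) == n_area) || any(multipliers <= 0))
    stopf("multipliers must be a positive %d x %d matrix", n_area, n_area)
  S <- space$n_states
  idx <- stats::setNames(seq_len(S), vapply(space$states, state_key, ""))
  A <- B <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  for (i in seq_len(S)) {
    rng <- space$states[[i]]
    if (length(rng) == 0L) next              # null range is absorbing
    for (a in setdiff(seq_len(n_area), rng)) {
      tgt <- idx[state_key(sort(c(rng, a)))]
      if (!is.na(tgt)) A[i, tgt] <- A[i, tgt] + sum(multipliers[rng, a])
    }
    for (a in rng) {
      tgt <- idx[state_key(setdiff(rng, a))]
      if (!is.na(tgt)) B[i, tgt] <- B[i, tgt] + 1
    }
  }
  diag(A) <- -rowSums(A)
  diag(B) <- -rowSums(B)
  list(A = A, B = B)
}

#' Cladogenetic event table
#'
#' Enumerates the ordered daughter-range pairs allowed at a speciation
#' event for each parent range, with normalized probabilities. `DEC`:
#' single-area sympatry, subset sympatry and narrow vicariance (one
#' single-area daughter, the other the complement). `DIVALIKE`:
#' single-area sympatry and unrestricted vicariance (any split into two
#' disjoint covering subsets). `BAYAREALIKE`: exact copy only. With
#' `founder_j`, jumps of one daughter to any single area outside the
#' parent range are added with weight `j` per event; all non-founder
#' events have weight 1, and weights are normalized per parent state.
#'
#' @param space an [enumerate_ranges()] state space.
#' @param model a [dec_model()].
#' @return List (one element per parent state) of data.frames with columns
#'   `left`, `right` (state indices) and `prob`; `NULL` for the null range.
#' @export
cladogenesis_table <- function(space, model) {
  stopifnot(inherits(space, "RangeStateSpace"), inherits(model, "DECModel"))
  ev <- clado_events(space, model$base)
  j <- if (model$founder_j) model$j else 0
  lapply(ev, function(tab) {
    if (is.null(tab)) return(NULL)
    w <- ifelse(tab$founder, j, 1)
    keep <- w > 0
    tab <- tab[keep, , drop = FALSE]; w <- w[keep]
    data.frame(left = tab$left, right = tab$right, prob = w / sum(w))
  })
}

## j-independent event structure per parent state (founder events flagged)
clado_events <- function(space, base) {
  n_area <- length(space$areas)
  idx <- stats::setNames(seq_len(space$n_states),
                         vapply(space$states, state_key, ""))
  ix <- function(s) {
    k <- state_key(sort(s))
    if (k %in% names(idx)) idx[[k]] else NULL
  }
  out <- vector("list", space$n_states)
  for (i in seq_len(space$n_states)) {
    rng <- space$states[[i]]
    if (length(rng) == 0L) next
    L <- integer(0); R <- integer(0); FO <- logical(0)
    seen <- character(0)
    add <- function(l, r, founder = FALSE) {
      li <- ix(l); ri <- ix(r)
      if (is.null(li) || is.null(ri)) return(invisible())
      key <- paste0(li, ":", ri)
      if (key %in% seen) return(invisible())   # each daughter pair once
      seen[length(seen) + 1L] <<- key
      L[length(L) + 1L] <<- li; R[length(R) + 1L] <<- ri
      FO[length(FO) + 1L] <<- founder
    }
    if (length(rng) == 1L) {
      add(rng, rng)
    } else if (base == "DEC") {
      for (a in rng) {
        add(a, rng); add(rng, a)                       # subset sympatry
        add(a, setdiff(rng, a)); add(setdiff(rng, a), a)  # vicariance
      }
    } else if (base == "DIVALIKE") {
      ## all ordered splits into two disjoint covering non-empty subsets
      m <- length(rng)
      for (code in 1:(2^m - 2L)) {
        sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1L)))
        add(rng[sel], rng[!sel])
      }
    } else {                                          # BAYAREALIKE
      add(rng, rng)
    }
    for (a in setdiff(seq_len(n_area), rng)) {
      add(rng, a, founder = TRUE); add(a, rng, founder = TRUE)
    }
    out[[i]] <- data.frame(left = L, right = R, founder = FO)
  }
  out
}

## matrix exponentials per stratum via eigendecomposition, with a
## scaling-and-squaring fallback when the eigenbasis is ill-conditioned
make_expm_cache <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eig <- FALSE
  Vi <- NULL
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      err <- max(Mod(eg$vectors %*% (eg$values * Vi) - Q))
      use_eig <- is.finite(err) && err < 1e-8 * max(1, max(abs(Q)))
    }
  }
  function(t) {
    if (t <= 0) return(diag(nrow(Q)))
    if (use_eig) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
      P[P < 0] <- 0
      return(P)
    }
    expm_ss(Q * t)
  }
}

## scaling-and-squaring matrix exponential (Taylor core)
expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:16) {
    term <- term %*% As / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Time-stratified DEC-family log-likelihood
#'
#' Felsenstein pruning on a dated ultrametric tree: each branch is split at
#' stratum boundaries, each segment's transition matrix is the exponential
#' of that stratum's anagenetic rate matrix, and cladogenesis weights are
#' applied at every internal node (including the root). Root states are
#' weighted uniformly over non-null states.
#'
#' @param dt a [dated_tree()] (branch lengths in the strata's time units).
#' @param tip_ranges named list (or vector) mapping every tip label to a
#'   character vector of occupied areas.
#' @param model a [dec_model()] with concrete `d`, `e`, `j`.
#' @param strat a [stratified_dispersal()] covering the tree depth.
#' @param space optional [enumerate_ranges()] (defaults to all non-null
#'   subsets of the strat matrix areas plus the null range).
#' @return Log-likelihood (scalar).
#' @export
stratified_loglik <- function(dt, tip_ranges, model, strat, space = NULL) {
  stopifnot(inherits(dt, "DatedTree"), inherits(model, "DECModel"),
            inherits(strat, "StratifiedDispersal"))
  prep <- dec_prep(dt, tip_ranges, strat, space, model$base)
  dec_eval(prep, model$d, model$e, if (model$founder_j) model$j else 0)
}

## precompute everything that does not depend on (d, e, j): rate-matrix
## bases per stratum, cladogenetic event structure, tip state vectors and
## the postorder traversal plan
dec_prep <- function(dt, tip_ranges, strat, space = NULL, base = "DEC") {
  areas <- colnames(strat$matrices[[1L]])
  if (is.null(areas)) stopf("stratum matrices must have area dimnames")
  space <- space %||% enumerate_ranges(areas, include_null = TRUE)
  if (dt$root_age > strat$boundaries[1L] + 1e-9)
    stopf("root age %.3g exceeds stratum coverage %.3g",
          dt$root_age, strat$boundaries[1L])
  tr <- dt$tree
  ntip <- length(tr$tip.label)
  tipmat <- matrix(0, ntip, space$n_states)
  for (tp in tr$tip.label) {
    ar <- tip_ranges[[tp]]
    if (is.null(ar)) stopf("tip '%s' has no range assignment", tp)
    si <- state_index(space, match(ar, space$areas))
    if (is.na(si) || any(is.na(match(ar, space$areas))))
      stopf("tip '%s' range not in state space", tp)
    tipmat[match(tp, tr$tip.label), si] <- 1
  }
  list(space = space, base = base,
       basis = lapply(strat$matrices, function(m) anagenetic_basis(space, m)),
       events = clado_events(space, base),
       boundaries = strat$boundaries,
       tipmat = tipmat, ntip = ntip, ages = dt$ages,
       ord = order(dt$ages[(ntip + 1L):(2L * ntip - 1L)]) + ntip,
       children = split(tr$edge[, 2L], tr$edge[, 1L]))
}

## likelihood for concrete (d, e, j) given a dec_prep() result
dec_eval <- function(prep, d, e, j) {
  space <- prep$space
  caches <- lapply(prep$basis, function(b)
    make_expm_cache(d * b$A + e * b$B))
  clado <- lapply(prep$events, function(tab) {
    if (is.null(tab)) return(NULL)
    w <- ifelse(tab$founder, j, 1)
    keep <- w > 0
    tab <- tab[keep, , drop = FALSE]; w <- w[keep]
    list(left = tab$left, right = tab$right, prob = w / sum(w))
  })
  ntip <- prep$ntip
  ages <- prep$ages
  b <- prep$boundaries
  part <- matrix(0, 2L * ntip - 1L, space$n_states)
  part[seq_len(ntip), ] <- prep$tipmat
  logscale <- 0
  propagate <- function(v, t_young, t_old) {
    t0 <- t_young
    while (t0 < t_old - 1e-12) {
      s <- max(which(b > t0 + 1e-12))          # stratum covering (b[s+1], b[s]]
      seg_top <- min(t_old, b[s])
      v <- caches[[s]](seg_top - t0) %*% v
      t0 <- seg_top
    }
    v
  }
  for (nd in prep$ord) {
    ch <- prep$children[[as.character(nd)]]
    w <- lapply(ch, function(c1)
      as.numeric(propagate(part[c1, ], ages[c1], ages[nd])))
    v <- numeric(space$n_states)
    for (i in seq_len(space$n_states)) {
      tab <- clado[[i]]
      if (is.null(tab)) next
      v[i] <- sum(tab$prob * w[[1L]][tab$left] * w[[2L]][tab$right])
    }
    mx <- max(v)
    if (mx <= 0) return(-Inf)
    part[nd, ] <- v / mx
    logscale <- logscale + log(mx)
  }
  root <- ntip + 1L
  nonnull <- setdiff(seq_len(space$n_states),
                     if (is.na(space$null_state)) integer(0) else space$null_state)
  log(sum(part[root, nonnull]) / length(nonnull)) + logscale
}
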