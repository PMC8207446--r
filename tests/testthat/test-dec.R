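test_that("range-state enumeration counts and ordering are deterministic", {
  s3 <- enumerate_ranges(c("A", "B", "C"), include_null = FALSE)
  expect_equal(s3$n_states, 7L)
  s6 <- enumerate_ranges(LETTERS[1:6], include_null = FALSE)
  expect_equal(s6$n_states, 63L)
  s62 <- enumerate_ranges(LETTERS[1:6], max_range_size = 2, include_null = FALSE)
  expect_equal(s62$n_states, 6L + 15L)
  sn <- enumerate_ranges(c("A", "B"), include_null = TRUE)
  expect_equal(sn$labels[1:4], c("()", "A", "B", "A+B"))
  expect_error(enumerate_ranges(LETTERS[1:11]), "10")
})

test_that("anagenetic rates follow the d/e formula and rows sum to zero", {
  sp <- enumerate_ranges(c("A", "B"), include_null = TRUE)
  m <- matrix(c(1, 0.01, 0.01, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  mod <- dec_model("DEC", d = 0.3, e = 0.07)
  Q <- anagenetic_rates(sp, mod, m)
  ## {A} -> {A,B} at d * m[A,B]
  expect_equal(Q["A", "A+B"], 0.3 * 0.01)
  ## {A,B} -> {A} and {B} at e each; {A} -> null at e
  expect_equal(Q["A+B", "A"], 0.07)
  expect_equal(Q["A", "()"], 0.07)
  expect_equal(unname(rowSums(Q)), rep(0, sp$n_states), tolerance = 1e-12)
  ## d = e = 0 -> zero matrix
  expect_true(all(anagenetic_rates(sp, dec_model("DEC", d = 0, e = 0), m) == 0))
  ## random parameters keep rows at zero
  set.seed(8)
  sp6 <- enumerate_ranges(LETTERS[1:4], include_null = TRUE)
  m6 <- matrix(runif(16, 0.01, 2), 4, 4)
  Q6 <- anagenetic_rates(sp6, dec_model("DIVALIKE", d = runif(1), e = runif(1)), m6)
  expect_equal(max(abs(rowSums(Q6))), 0, tolerance = 1e-12)
})

test_that("cladogenesis tables match the published event enumerations", {
  sp <- enumerate_ranges(c("A", "B"), include_null = TRUE)
  ## single-area parent, j = 0: pure sympatry
  for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    tab <- cladogenesis_table(sp, dec_model(base))
    pa <- tab[[which(sp$labels == "A")]]
    expect_equal(nrow(pa), 1L)
    expect_equal(sp$labels[pa$left], "A")
    expect_equal(pa$prob, 1)
  }
  ## DEC parent {A,B}: 4 subset-sympatry + 2 vicariance events, equal weight
  tab <- cladogenesis_table(sp, dec_model("DEC"))
  pab <- tab[[which(sp$labels == "A+B")]]
  got <- sort(paste(sp$labels[pab$left], sp$labels[pab$right], sep = "|"))
  expect_equal(got, sort(c("A|A+B", "A+B|A", "B|A+B", "A+B|B", "A|B", "B|A")))
  expect_equal(pab$prob, rep(1 / 6, 6))
  ## BAYAREALIKE parent {A,B}: exact copy only
  tb <- cladogenesis_table(sp, dec_model("BAYAREALIKE"))
  pb <- tb[[which(sp$labels == "A+B")]]
  expect_equal(nrow(pb), 1L)
  expect_equal(sp$labels[pb$left], "A+B")
  expect_equal(sp$labels[pb$right], "A+B")
  ## DIVALIKE parent {A,B}: the two ordered vicariant splits
  td <- cladogenesis_table(sp, dec_model("DIVALIKE"))
  pd <- td[[which(sp$labels == "A+B")]]
  expect_equal(sort(paste(sp$labels[pd$left], sp$labels[pd$right], sep = "|")),
               c("A|B", "B|A"))
  ## founder events appear with weight j, normalized
  sp3 <- enumerate_ranges(c("A", "B", "C"), include_null = TRUE)
  tj <- cladogenesis_table(sp3, dec_model("BAYAREALIKE", founder_j = TRUE,
                                          j = 0.5))
  pj <- tj[[which(sp3$labels == "A")]]
  ## copy (weight 1) + 4 jumps (weight 0.5 each): jumps to B and C, ordered
  expect_equal(nrow(pj), 5L)
  expect_equal(sum(pj$prob), 1)
  expect_equal(max(pj$prob), 1 / 3)       # the sympatric copy
})

test_that("one-area system with d = e = 0 has log-likelihood zero", {
  dt <- balanced_tree(4, root_age = 4)
  area <- "A"
  strat <- uniform_strat(area)
  tips <- setNames(rep(list("A"), 4), dt$tree$tip.label)
  ll <- stratified_loglik(dt, tips, dec_model("DEC", d = 0, e = 0), strat)
  expect_equal(ll, 0)
})

test_that("two-tip likelihood equals a dense matrix-exponential oracle", {
  tr <- ape::read.tree(text = "(t1:1.5,t2:1.5);")
  dt <- dated_tree(tr)
  areas <- c("X", "Y")
  mult <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(areas, areas))
  strat <- stratified_dispersal(c(6, 0), list(mult))
  mod <- dec_model("DEC", d = 0.23, e = 0.11)
  tips <- list(t1 = "X", t2 = "Y")
  got <- stratified_loglik(dt, tips, mod, strat)
  ## dense oracle built from first principles: states (),X,Y,XY
  d <- 0.23; e <- 0.11; m <- 0.4
  Q <- rbind(c(0, 0, 0, 0),
             c(e, -(e + d * m), 0, d * m),
             c(e, 0, -(e + d * m), d * m),
             c(0, e, e, -2 * e))
  P <- as.matrix(Matrix::expm(Q * 1.5))
  tipX <- c(0, 1, 0, 0); tipY <- c(0, 0, 1, 0)
  wl <- P %*% tipX; wr <- P %*% tipY
  ## DEC cladogenesis: X->(X,X); Y->(Y,Y); XY-> 6 events at 1/6
  Lroot <- c(0,
             wl[2] * wr[2],
             wl[3] * wr[3],
             (wl[2] * wr[4] + wl[4] * wr[2] + wl[3] * wr[4] +
                wl[4] * wr[3] + wl[2] * wr[3] + wl[3] * wr[2]) / 6)
  oracle <- log(sum(Lroot[2:4]) / 3)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("splitting a stratum with identical multipliers leaves lnL unchanged", {
  dt <- balanced_tree(6, root_age = 5)
  areas <- c("A", "B", "C")
  m <- matrix(runif(9, 0.5, 1.5), 3, 3, dimnames = list(areas, areas))
  set.seed(2)
  tips <- setNames(as.list(sample(areas, 6, TRUE)), dt$tree$tip.label)
  mod <- dec_model("DEC", d = 0.15, e = 0.05)
  one <- stratified_dispersal(c(6, 0), list(m))
  many <- stratified_dispersal(c(6, 3.1, 0.7, 0), list(m, m, m))
  expect_equal(stratified_loglik(dt, tips, mod, one),
               stratified_loglik(dt, tips, mod, many), tolerance = 1e-8)
})

test_that("segment transition matrices are stochastic", {
  sp <- enumerate_ranges(c("A", "B", "C"), include_null = TRUE)
  m <- matrix(runif(9, 0.2, 2), 3, 3)
  Q <- anagenetic_rates(sp, dec_model("DEC", d = 0.4, e = 0.2), m)
  cache <- stratpg:::make_expm_cache(Q)
  for (t in c(0.01, 0.5, 3, 20)) {
    P <- cache(t)
    expect_true(all(P >= -1e-10))
    expect_equal(unname(rowSums(P)), rep(1, sp$n_states), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to consistent area relabeling", {
  dt <- balanced_tree(4, root_age = 4)
  areas <- c("A", "B")
  m <- matrix(c(1, 0.3, 0.8, 1), 2, 2, dimnames = list(areas, areas))
  tips <- list(t1 = "A", t2 = "B", t3 = "A", t4 = "B")
  mod <- dec_model("DEC", d = 0.2, e = 0.02)
  ll1 <- stratified_loglik(dt, tips, mod, stratified_dispersal(c(6, 0), list(m)))
  ## swap labels everywhere: permute multiplier values, keep name slots
  m2 <- m[2:1, 2:1]
  dimnames(m2) <- dimnames(m)
  tips2 <- lapply(tips, function(a) setdiff(c("A", "B"), a))
  ll2 <- stratified_loglik(dt, tips2, mod, stratified_dispersal(c(6, 0), list(m2)))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("fitting: +J never hurts lnL; AICc >= AIC; weights sum to one", {
  dt <- simulate_yule_tree(8, 5, seed = 31)
  areas <- c("A", "B", "C")
  strat <- uniform_strat(areas)
  set.seed(32)
  tips <- simulate_range_history(dt, dec_model("DEC", d = 0.25, e = 0.02),
                                 strat, seed = 33)
  f0 <- fit_dec_model(dt, tips, "DEC", founder_j = FALSE, strat = strat,
                      n_starts = 2, seed = 1)
  fj <- fit_dec_model(dt, tips, "DEC", founder_j = TRUE, strat = strat,
                      n_starts = 2, seed = 1)
  expect_gte(fj$loglik, f0$loglik - 1e-6)
  expect_gte(f0$AICc, f0$AIC)
  cmp <- compare_dispersal_hypotheses(
    dt, tips, hypotheses = list(U1 = strat, U2 = strat),
    bases = c("DEC", "BAYAREALIKE"), founder = FALSE, n_starts = 1, seed = 2)
  expect_equal(sum(cmp$fits$weight), 1, tolerance = 1e-12)
  ## identical hypotheses -> identical lnL per base model
  for (b in unique(cmp$fits$model)) {
    ll <- cmp$fits$loglik[cmp$fits$model == b]
    expect_equal(ll[1], ll[2], tolerance = 1e-4)
  }
})

test_that("range-history simulation respects the state space and seed", {
  dt <- simulate_yule_tree(10, 5, seed = 41)
  areas <- c("A", "B", "C")
  strat <- uniform_strat(areas)
  t1 <- simulate_range_history(dt, dec_model("DEC", d = 0.3, e = 0.05),
                               strat, seed = 42)
  t2 <- simulate_range_history(dt, dec_model("DEC", d = 0.3, e = 0.05),
                               strat, seed = 42)
  expect_identical(t1, t2)
  expect_true(all(lengths(t1) >= 1))
  expect_true(all(unlist(t1) %in% areas))
})

test_that("stratified dispersal round-trips through the plain-text format", {
  hyps <- dispersal_hypotheses(c("Insular", "Western", "Central",
                                 "EasternRanges", "EasternCoastal", "Southern"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_stratified_dispersal(hyps$H2, path)
  back <- read_stratified_dispersal(path)
  expect_equal(back$boundaries, hyps$H2$boundaries)
  for (s in 1:3)
    expect_equal(back$matrices[[s]], hyps$H2$matrices[[s]])
  expect_error(read_stratified_dispersal(tempfile()), "not found")
})

test_that("dispersal hypotheses encode the barrier structure", {
  hyps <- dispersal_hypotheses(c("Insular", "Western", "Central",
                                 "EasternRanges", "EasternCoastal", "Southern"))
  expect_named(hyps, c("H0", "H1", "H2"))
  ## H0 open everywhere
  expect_true(all(hyps$H0$matrices[[2]] == 1))
  ## H1 middle epoch: Insular-Western restricted, within-Mainland open
  expect_equal(hyps$H1$matrices[[2]]["Insular", "Western"], 0.01)
  expect_equal(hyps$H1$matrices[[2]]["Western", "Central"], 1)
  ## H2 recent epoch: Mainland-Southeastern open, Southern-EasternCoastal closed
  expect_equal(hyps$H2$matrices[[3]]["Western", "Southern"], 1)
  expect_equal(hyps$H2$matrices[[3]]["Southern", "EasternCoastal"], 0.01)
  expect_equal(hyps$H2$matrices[[3]]["Insular", "Western"], 0.01)
})
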