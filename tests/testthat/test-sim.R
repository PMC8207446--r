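test_that("draw_params respects degenerate priors, ranges and ordering", {
  sc <- single_deme_scenario(N = 1234)
  ps <- draw_params(sc, seed = 1)
  expect_equal(unname(ps$sizes["A"]), 1234)
  ## uniform sampling: mean of 1e4 draws within 3 SE of midpoint
  sc2 <- scenario("u", "A",
                  priors = list(N_A = c(100, 200), mt_rate = c(1e-8, 1e-8),
                                msat_rate = c(1e-4, 1e-4), p_single = c(1, 1)),
                  events = list())
  draws <- with_seed <- vapply(1:10000, function(i)
    draw_params(sc2, seed = i)$sizes[["A"]], 0)
  se <- sqrt((100^2 / 12) / 10000)
  expect_lt(abs(mean(draws) - 150), 3 * se)
  ## nested ordering constraint always satisfied
  sc3 <- scenario("ord", c("A", "B"),
                  priors = list(N_A = c(100, 100), N_B = c(100, 100),
                                mt_rate = c(1e-8, 1e-8), msat_rate = c(1e-4, 1e-4),
                                p_single = c(1, 1),
                                T_child = c(0, 1000), T_parent = c(500, 1500)),
                  events = list(
                    list(type = "divergence", time_param = "T_child",
                         derived = "B", ancestral = "A"),
                    list(type = "divergence", time_param = "T_parent",
                         derived = "B", ancestral = "A",
                         older_than = "T_child")))
  for (i in 1:50) {
    v <- draw_params(sc3, seed = i)$values
    expect_lt(v[["T_child"]], v[["T_parent"]])
  }
  ## infeasible constraints error out
  sc4 <- scenario("bad", "A",
                  priors = list(N_A = c(100, 100), mt_rate = c(1e-8, 1e-8),
                                msat_rate = c(1e-4, 1e-4), p_single = c(1, 1),
                                T1 = c(10, 20), T2 = c(30, 40)),
                  events = list(list(type = "divergence", time_param = "T1",
                                     derived = "A", ancestral = "A",
                                     older_than = "T2")))
  expect_error(draw_params(sc4, seed = 1), "ordering")
})

test_that("two-lineage TMRCA matches the analytic expectation", {
  sc <- single_deme_scenario(N = 1000)
  ps <- draw_params(sc, seed = 1)
  set.seed(11)
  tm <- replicate(2000, max(simulate_genealogy(ps, sc, c(A = 2), 1)$node_time))
  expect_lt(abs(mean(tm) - 1000) / 1000, 0.05)
})

test_that("degenerate events are statistical no-ops", {
  ## divergence at time 0 == one deme
  sc2 <- scenario("z", c("A", "B"),
                  priors = list(N_A = c(800, 800), N_B = c(800, 800),
                                mt_rate = c(1e-8, 1e-8), msat_rate = c(1e-4, 1e-4),
                                p_single = c(1, 1), T0 = c(0, 0)),
                  events = list(list(type = "divergence", time_param = "T0",
                                     derived = "B", ancestral = "A")))
  ps2 <- draw_params(sc2, seed = 1)
  sc1 <- single_deme_scenario(N = 800)
  ps1 <- draw_params(sc1, seed = 1)
  set.seed(12)
  t_two <- replicate(600, max(simulate_genealogy(ps2, sc2, c(A = 2, B = 2), 1)$node_time))
  t_one <- replicate(600, max(simulate_genealogy(ps1, sc1, c(A = 4), 1)$node_time))
  expect_gt(suppressWarnings(ks.test(t_two, t_one)$p.value), 0.01)
  ## admixture with r = 1 == divergence rerouting
  sc_adm <- scenario("adm", c("A", "B"),
                     priors = list(N_A = c(800, 800), N_B = c(800, 800),
                                   mt_rate = c(1e-8, 1e-8), msat_rate = c(1e-4, 1e-4),
                                   p_single = c(1, 1), Tm = c(400, 400),
                                   r = c(1, 1), Tdeep = c(40000, 40000)),
                     events = list(
                       list(type = "admixture", time_param = "Tm",
                            recipient = "B", donor = "A", prop_param = "r"),
                       list(type = "divergence", time_param = "Tdeep",
                            derived = "B", ancestral = "A")))
  sc_div <- scenario("div", c("A", "B"),
                     priors = list(N_A = c(800, 800), N_B = c(800, 800),
                                   mt_rate = c(1e-8, 1e-8), msat_rate = c(1e-4, 1e-4),
                                   p_single = c(1, 1), Tm = c(400, 400)),
                     events = list(list(type = "divergence", time_param = "Tm",
                                        derived = "B", ancestral = "A")))
  psa <- draw_params(sc_adm, seed = 2); psd <- draw_params(sc_div, seed = 2)
  set.seed(13)
  ta <- replicate(600, max(simulate_genealogy(psa, sc_adm, c(A = 3, B = 3), 1)$node_time))
  td <- replicate(600, max(simulate_genealogy(psd, sc_div, c(A = 3, B = 3), 1)$node_time))
  expect_gt(suppressWarnings(ks.test(ta, td)$p.value), 0.01)
})

test_that("stranded lineages raise a scenario validation error", {
  sc <- scenario("stranded", c("A", "B"),
                 priors = list(N_A = c(100, 100), N_B = c(100, 100),
                               mt_rate = c(1e-8, 1e-8), msat_rate = c(1e-4, 1e-4),
                               p_single = c(1, 1)),
                 events = list())
  ps <- draw_params(sc, seed = 1)
  set.seed(1)
  expect_error(simulate_genealogy(ps, sc, c(A = 2, B = 2), 1), "stranded")
})

test_that("single-deme TMRCA distribution matches an independent coalescent", {
  ## oracle: inverse-cdf simulation of the 2-lineage exponential plus the
  ## analytic n=3 TMRCA (sum of independent exponentials), coded separately
  sc <- single_deme_scenario(N = 500)
  ps <- draw_params(sc, seed = 1)
  set.seed(14)
  t3 <- replicate(2000, max(simulate_genealogy(ps, sc, c(A = 3), 1)$node_time))
  oracle <- replicate(2000, 500 * (rexp(1, 3) + rexp(1, 1)))
  expect_gt(suppressWarnings(ks.test(t3, oracle)$p.value), 0.01)
})

test_that("sequence mutation honours rate 0, HKY expectations and gamma", {
  g <- structure(list(n_tips = 2L, tip_pop = c("A", "A"),
                      parent = c(3L, 3L, 0L), node_time = c(0, 0, 400)),
                 class = "GeneTree")
  mod0 <- list(rate = 0, kappa = 4, base_freqs = c(A = .25, C = .25, G = .25, T = .25),
               gamma_shape = NULL)
  set.seed(15)
  a0 <- mutate_sequence(g, mod0, 50)
  expect_equal(a0$seq[1, ], a0$seq[2, ])
  expect_error(mutate_sequence(g, list(rate = 1e-5, kappa = 1,
                                       base_freqs = c(A = .5, C = .5, G = .5, T = .5)),
                               10), "sum to 1")
  ## observed transition/transversion split matches the exact HKY kernel
  mod <- list(rate = 2e-5, kappa = 8,
              base_freqs = c(A = .3, C = .2, G = .2, T = .3), gamma_shape = NULL)
  set.seed(16)
  aln <- mutate_sequence(g, mod, 150000)
  enc <- stratpg:::encode_alignment(aln)
  a <- enc[1, ]; b <- enc[2, ]
  diff <- a != b
  ts <- diff & (abs(a - b) == 2L & (a + b) %in% c(4L, 6L))
  ## exact expectation from the 4x4 transition kernel over the pair distance
  f <- mod$base_freqs
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    is_ts <- abs(i - j) == 2 && (i + j) %in% c(4, 6)
    Q[i, j] <- f[j] * if (is_ts) mod$kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(f * diag(Q))
  P <- stratpg:::expm_ss(Q * mod$rate * 800)   # tip-to-tip distance
  exp_ts <- sum(vapply(1:4, function(i) f[i] *
    sum(P[i, ][abs(i - (1:4)) == 2 & (i + (1:4)) %in% c(4, 6)]), 0))
  exp_diff <- sum(vapply(1:4, function(i) f[i] * (1 - P[i, i]), 0))
  expect_lt(abs(mean(diff) - exp_diff) / exp_diff, 0.1)
  expect_lt(abs(mean(ts) - exp_ts) / exp_ts, 0.1)
  ## gamma heterogeneity concentrates substitutions on fast sites, so at a
  ## larger divergence the observed difference fraction drops measurably
  gdeep <- structure(list(n_tips = 2L, tip_pop = c("A", "A"),
                          parent = c(3L, 3L, 0L), node_time = c(0, 0, 2000)),
                     class = "GeneTree")
  set.seed(17)
  a_plain <- mutate_sequence(gdeep, mod, 120000)
  modg <- mod; modg$gamma_shape <- 0.25
  a_gam <- mutate_sequence(gdeep, modg, 120000)
  dp <- mean(stratpg:::encode_alignment(a_plain)[1, ] !=
               stratpg:::encode_alignment(a_plain)[2, ])
  dg <- mean(stratpg:::encode_alignment(a_gam)[1, ] !=
               stratpg:::encode_alignment(a_gam)[2, ])
  expect_lt(dg, dp * 0.97)
})

test_that("E[pi] = theta per site in single-deme simulations", {
  sc <- single_deme_scenario(N = 1000, mt_rate = 1e-5)
  ps <- draw_params(sc, seed = 1)
  theta <- 2 * 1000 * 1e-5
  set.seed(18)
  pis <- replicate(500, {
    gg <- simulate_genealogy(ps, sc, c(A = 10), 1)
    a <- mutate_sequence(gg, list(rate = 1e-5, kappa = 1,
                                  base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                                  gamma_shape = NULL), 200)
    stratpg:::mean_pairwise_diff(stratpg:::encode_alignment(a))$k_site
  })
  expect_lt(abs(mean(pis) - theta) / theta, 0.1)
})

test_that("microsatellite mutation: rate 0, bounds contract, SMM expectation", {
  g <- structure(list(n_tips = 2L, tip_pop = c("A", "A"),
                      parent = c(3L, 3L, 0L), node_time = c(0, 0, 1000)),
                 class = "GeneTree")
  set.seed(19)
  expect_equal(length(unique(mutate_microsat(g, 0, 1))), 1L)
  expect_error(mutate_microsat(g, 1e-3, 1, bounds = c(5, 5)), "2 states")
  ## reflecting bounds hold for heavy mutation pressure
  for (i in 1:20) {
    v <- mutate_microsat(g, 0.05, 0.7, bounds = c(10, 15))
    expect_true(all(v >= 10 & v <= 15))
  }
  ## E[(delta-mu)^2] ~ 2 mu t between demes split t generations (pure SMM)
  sc <- two_deme_scenario(N = 500, t_split = 5000, msat_rate = 5e-4)
  ps <- draw_params(sc, seed = 1)
  set.seed(20)
  dm <- replicate(200, {
    gg <- simulate_genealogy(ps, sc, c(A = 20, B = 20), 1)
    al <- mutate_microsat(gg, 5e-4, 1, bounds = c(1, 2000))
    (mean(al[gg$tip_pop == "A"]) - mean(al[gg$tip_pop == "B"]))^2
  })
  expected <- 2 * 5e-4 * 5000
  expect_lt(abs(mean(dm) - expected) / expected, 0.15)
})

test_that("synthetic study is reproducible and matches the sampling design", {
  ds1 <- make_synthetic_study("H1", seed = 77)
  ds2 <- make_synthetic_study("H1", seed = 77)
  expect_identical(ds1$mt_aln, ds2$mt_aln)
  expect_identical(ds1$genotypes, ds2$genotypes)
  expect_identical(ds1$params$values, ds2$params$values)
  mt_n <- table(ds1$mt_popmap$assignments)
  expect_equal(unname(mt_n[c("Insular", "Western", "Central", "EasternRanges",
                             "EasternCoastal", "Southern")]),
               c(21L, 25L, 9L, 16L, 8L, 11L), ignore_attr = TRUE)
  ms_n <- table(ds1$msat_popmap$assignments)
  expect_equal(unname(ms_n[c("Insular", "Western", "Central", "EasternRanges",
                             "EasternCoastal", "Southern")]),
               c(24L, 26L, 10L, 33L, 12L, 24L), ignore_attr = TRUE)
  expect_equal(ds1$mt_aln$length, 1029L)
  expect_equal(length(ds1$genotypes$locus_ids), 12L)
  expect_error(make_synthetic_study("H9", seed = 1), "unknown scenario")
})

test_that("lineage count decreases monotonically to one common ancestor", {
  sc <- two_deme_scenario()
  ps <- draw_params(sc, seed = 3)
  set.seed(21)
  g <- simulate_genealogy(ps, sc, c(A = 8, B = 8), 1)
  ## every node except the root has exactly one parent; the root is unique
  expect_equal(sum(g$parent == 0L), 1L)
  ## internal node times strictly increase with index (coalescence order)
  it <- g$node_time[(g$n_tips + 1L):(2L * g$n_tips - 1L)]
  expect_true(all(diff(it) > 0))
  ## each internal node has exactly two children
  kids <- table(g$parent[g$parent > 0L])
  expect_true(all(kids == 2L))
})

test_that("synthetic study writes and reads back from disk", {
  ds <- make_synthetic_study("H0", seed = 5)
  dir <- withr::local_tempdir()
  write_synthetic_study(ds, dir)
  aln <- read_fasta_alignment(file.path(dir, "mtdna.fasta"))
  expect_equal(aln$seq, ds$mt_aln$seq, ignore_attr = TRUE)
  gp <- read_genepop(file.path(dir, "msat.genepop"))
  ## GenePop 3-digit coding preserves the (bounded) allele sizes
  expect_equal(unname(gp$genotypes$a1), unname(ds$genotypes$a1))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$scenario_id, "H0")
})
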