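test_that("haplotype collapsing groups identical sequences and lists variable sites", {
  aln <- toy_alignment(); pm <- toy_popmap()
  ht <- collapse_haplotypes(aln, pm)
  expect_length(ht$haplotype_sequences, 4L)
  expect_equal(ht$variable_sites, c(1:5, 10L))
  expect_equal(unname(rowSums(ht$counts)), c(4L, 4L))
  ## 4 identical sequences -> 1 haplotype, 0 variable sites
  mono <- alignment(paste0("s", 1:4), rep("ACGTACGT", 4))
  hm <- collapse_haplotypes(mono, popmap(paste0("s", 1:4), rep("P", 4)))
  expect_length(hm$haplotype_sequences, 1L)
  expect_length(hm$variable_sites, 0L)
  ## {AAA, AAT, AAT} -> 2 haplotypes, variable site 3
  h3 <- collapse_haplotypes(alignment(c("x", "y", "z"), c("AAA", "AAT", "AAT")),
                            popmap(c("x", "y", "z"), rep("P", 3)))
  expect_length(h3$haplotype_sequences, 2L)
  expect_equal(h3$variable_sites, 3L)
})

test_that("samples with excess missing data are excluded; compatible ones merge", {
  aln <- alignment(c("s1", "s2", "s3"),
                   c("AAAAAAAAAA", "AAAAAAAAAN", "NNNNNNNNNA"))
  pm <- popmap(c("s1", "s2", "s3"), rep("P", 3))
  ht <- collapse_haplotypes(aln, pm, max_missing = 0.2)
  expect_identical(ht$excluded, "s3")
  ## s2 joins s1's haplotype (no mismatch at shared sites)
  expect_length(ht$haplotype_sequences, 1L)
})

test_that("diversity summary matches hand calculation on the toy fixture", {
  ds <- diversity_summary(toy_alignment(), toy_popmap())
  expect_equal(ds$h, c(0.5, 0.5))
  expect_equal(ds$h_sd, rep(0.2651650429, 2), tolerance = 1e-9)
  expect_equal(ds$pi, c(0.05, 0.05))
  expect_equal(ds$k, c(0.5, 0.5))
  expect_equal(ds$S, c(1L, 1L))
  ## monomorphic population -> h = pi = 0
  mono <- alignment(paste0("s", 1:5), rep("ACGT", 5))
  dm <- diversity_summary(mono, popmap(paste0("s", 1:5), rep("P", 5)))
  expect_equal(dm$h, 0); expect_equal(dm$pi, 0)
  ## 2 samples differing at 1 of 10 sites -> h = 1, pi = 0.1
  d2 <- diversity_summary(alignment(c("u", "v"), c("AAAAAAAAAA", "AAAAAAAAAT")),
                          popmap(c("u", "v"), c("P", "P")))
  expect_equal(d2$h, 1); expect_equal(d2$pi, 0.1)
})

test_that("h and pi are invariant to sample order and site permutation", {
  aln <- toy_alignment(); pm <- toy_popmap()
  base <- diversity_summary(aln, pm)
  set.seed(42)
  perm_samples <- sample(aln$sample_ids)
  a2 <- subset_alignment(aln, perm_samples)
  d2 <- diversity_summary(a2, pm)
  expect_equal(d2[order(d2$population), c("h", "pi")],
               base[order(base$population), c("h", "pi")],
               ignore_attr = TRUE)
  cols <- sample(aln$length)
  a3 <- alignment(aln$sample_ids,
                  apply(aln$seq[, cols, drop = FALSE], 1L, paste, collapse = ""))
  d3 <- diversity_summary(a3, pm)
  expect_equal(d3$h, base$h); expect_equal(d3$pi, base$pi)
})

test_that("pi via pairwise differences equals the site-heterozygosity form", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T"), 12 * 30, TRUE), 12, 30)
    aln <- alignment(paste0("s", 1:12), apply(m, 1, paste, collapse = ""))
    enc <- stratpg:::encode_alignment(aln)
    k1 <- stratpg:::mean_pairwise_diff(enc)$k_site
    ## site form: sum over sites of n/(n-1) * (1 - sum p^2) / L  (complete data)
    n <- nrow(enc)
    het <- apply(enc, 2L, function(col) {
      p <- table(col) / n
      n / (n - 1) * (1 - sum(p^2))
    })
    expect_equal(k1, sum(het) / ncol(enc), tolerance = 1e-12)
  }
})

test_that("Tamura distance: identical pair is 0, gamma limit matches plain", {
  aln <- toy_alignment()
  ## cross-population pairs saturate (Q = 0.5) on this fixture: warned NA
  expect_warning(D <- tamura_gamma_distance(aln, gamma_a = Inf), "saturated")
  expect_equal(unname(D["a1", "a2"]), 0)
  expect_true(isSymmetric(unclass(D)))
  expect_warning(Dg <- tamura_gamma_distance(aln, gamma_a = 1e7), "saturated")
  expect_equal(unclass(Dg), unclass(D), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(tamura_gamma_distance(aln, gamma_a = -1), "positive")
})

test_that("Tamura distance agrees with an independent T92 implementation", {
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, 5 * 400, TRUE, prob = c(.3, .25, .2, .25)), 5, 400)
  for (i in 2:5) { keep <- runif(400) < 0.93; m[i, keep] <- m[1, keep] }
  aln <- alignment(paste0("s", 1:5), apply(m, 1, paste, collapse = ""))
  D <- tamura_gamma_distance(aln, gamma_a = Inf)
  db <- ape::as.DNAbin(tolower(m)); rownames(db) <- aln$sample_ids
  Dape <- as.matrix(ape::dist.dna(db, model = "T92"))
  ## conventions differ slightly (pairwise vs alignment-wide GC content),
  ## so agreement is to ~1e-5 absolute, not machine precision
  expect_equal(unclass(D), Dape[rownames(D), colnames(D)],
               tolerance = 5e-4, ignore_attr = TRUE)
})

test_that("saturated pairs are reported NA with a warning", {
  aln <- alignment(c("x", "y"),
                   c("AGAGAGAGAGAGAGAGAGAG", "GAGAGAGAGAGAGAGAGAGA"))
  expect_warning(D <- tamura_gamma_distance(aln, gamma_a = Inf), "saturated")
  expect_true(is.na(D["x", "y"]))
})

test_that("AMOVA PhiST: fixed difference gives 1; toy value is stable", {
  a2 <- alignment(paste0("x", 1:8),
                  c(rep("AAAAAAAAAA", 4), rep("TTTTTTTTTT", 4)))
  pm <- popmap(paste0("x", 1:8), rep(c("P1", "P2"), each = 4))
  r <- amova_phist(a2, pm, n_perm = 99, seed = 5)
  expect_equal(r$overall, 1)
  expect_equal(r$pairwise["P1", "P2"], 1, ignore_attr = TRUE)
  r2 <- amova_phist(toy_alignment(), toy_popmap(), n_perm = 99, seed = 1)
  expect_equal(r2$overall, 0.9069767442, tolerance = 1e-9)
})

test_that("PhiST is near-invariant under dataset duplication", {
  ## the variance-components estimator carries finite-sample df corrections,
  ## so duplication invariance holds only asymptotically (here to ~0.02)
  aln <- toy_alignment(); pm <- toy_popmap()
  base <- amova_phist(aln, pm, n_perm = 0, seed = 1)
  dup <- alignment(c(aln$sample_ids, paste0(aln$sample_ids, "_d")),
                   rep(apply(aln$seq, 1, paste, collapse = ""), 2))
  pmd <- popmap(dup$sample_ids, rep(rep(c("P1", "P2"), each = 4), 2))
  r <- amova_phist(dup, pmd, n_perm = 0, seed = 1)
  expect_equal(r$overall, base$overall, tolerance = 0.02)
})

test_that("permutation p-values are reproducible and respond to relabeling", {
  aln <- toy_alignment(); pm <- toy_popmap()
  r1 <- amova_phist(aln, pm, n_perm = 199, seed = 7)
  r2 <- amova_phist(aln, pm, n_perm = 199, seed = 7)
  expect_identical(r1$overall_p, r2$overall_p)
  expect_identical(r1$pairwise_p, r2$pairwise_p)
  ## random labels: observed statistic should sit inside its own null
  set.seed(11)
  hits <- 0L
  for (b in 1:20) {
    pmr <- popmap(aln$sample_ids, sample(rep(c("P1", "P2"), each = 4)))
    rr <- amova_phist(aln, pmr, n_perm = 99, seed = b)
    if (rr$overall_p <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("haplotype-frequency FST hits the boundary cases", {
  ## identical haplotype frequencies -> FST ~ 0 (slightly negative allowed)
  cnt <- matrix(c(5L, 5L, 5L, 5L), 2, 2, dimnames = list(c("A", "B"), NULL))
  ht <- structure(list(haplotype_sequences = c("A", "T"),
                       variable_sites = 1L, counts = cnt,
                       assignments = NULL, excluded = character(0)),
                  class = "HaplotypeTable")
  r <- haplotype_fst(ht, n_perm = 0)
  ## exact finite-sample expectation for identical frequencies: -1/(n-1)
  expect_equal(r$overall, -1 / 9, tolerance = 1e-9)
  ## two pops fixed for different haplotypes -> FST = 1
  cnt2 <- matrix(c(6L, 0L, 0L, 6L), 2, 2, dimnames = list(c("A", "B"), NULL))
  ht$counts <- cnt2
  expect_equal(haplotype_fst(ht, n_perm = 0)$overall, 1)
  ## toy fixture value
  r3 <- haplotype_fst(collapse_haplotypes(toy_alignment(), toy_popmap()),
                      n_perm = 0)
  expect_equal(r3$overall, 0.5, tolerance = 1e-12)
})

test_that("Benjamini-Yekutieli correction matches brute-force enumeration", {
  by_oracle <- function(p, alpha) {
    ## direct step-up enumeration
    m <- length(p); cm <- sum(1 / seq_len(m))
    o <- order(p); ps <- p[o]
    imax <- 0L
    for (i in seq_len(m)) if (ps[i] <= i * alpha / (m * cm)) imax <- i
    if (imax == 0L) rep(FALSE, m) else p <= ps[imax]
  }
  set.seed(21)
  for (rep in 1:10) {
    p <- round(runif(15), 3)
    got <- fdr_correct(p, alpha = 0.05)
    expect_identical(got$significant, by_oracle(p, 0.05))
  }
  expect_true(all(fdr_correct(rep(0, 5))$significant))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
  ## 15 simultaneous tests at alpha 0.05: realized critical value
  ## 0.05 / sum(1/i) = 0.01507, the familiar "p < .015" threshold
  f <- fdr_correct(rep(1e-4, 15), alpha = 0.05)
  expect_equal(f$critical, 0.05 / sum(1 / (1:15)), tolerance = 1e-12)
  expect_equal(round(f$critical, 3), 0.015)
})
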