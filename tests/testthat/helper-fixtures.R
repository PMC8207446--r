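## Shared fixture builders: everything is generated in code at test time.

toy_alignment <- function() {
  ## 8 samples, 2 populations, 10 sites; P1 fixed except sample a4,
  ## P2 carries a distinct divergent haplotype
  alignment(
    c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
    c("AAAAAAAAAA",
      "AAAAAAAAAA",
      "AAAAAAAAAA",
      "AAAAAAAAAT",
      "TTTTTAAAAA",
      "TTTTTAAAAA",
      "TTTTTAAAAT",
      "TTTTTAAAAA"),
    locus_label = "toy")
}

toy_popmap <- function() {
  popmap(c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
         rep(c("P1", "P2"), each = 4))
}

## 2-population, 2-locus genotype table with hand-readable frequencies
toy_genotypes <- function() {
  genotype_table(
    sample_ids = c(paste0("p", 1:5), paste0("q", 1:5)),
    locus_ids = c("locA", "locB"),
    a1 = cbind(c(120, 120, 120, 124, 124, 128, 128, 128, 132, 132),
               c(10, 10, 10, 10, 10, 12, 12, 10, 12, 12)),
    a2 = cbind(c(120, 124, 124, 124, 128, 128, 132, 132, 132, 132),
               c(10, 10, 12, 10, 12, 12, 12, 12, 12, 12)))
}

toy_geno_popmap <- function() {
  popmap(c(paste0("p", 1:5), paste0("q", 1:5)), rep(c("A", "B"), each = 5))
}

## single-deme scenario with degenerate priors, for analytic checks
single_deme_scenario <- function(N = 1000, mt_rate = 1e-5, msat_rate = 1e-4) {
  scenario("single", "A",
           priors = list(N_A = c(N, N), mt_rate = c(mt_rate, mt_rate),
                         msat_rate = c(msat_rate, msat_rate),
                         p_single = c(1, 1)),
           events = list())
}

two_deme_scenario <- function(N = 500, t_split = 5000, msat_rate = 5e-4) {
  scenario("pair", c("A", "B"),
           priors = list(N_A = c(N, N), N_B = c(N, N),
                         mt_rate = c(1e-5, 1e-5),
                         msat_rate = c(msat_rate, msat_rate),
                         p_single = c(1, 1),
                         T_split = c(t_split, t_split)),
           events = list(list(type = "divergence", time_param = "T_split",
                              derived = "B", ancestral = "A")))
}

## small ultrametric tree with tips t1..tn (deterministic topology)
balanced_tree <- function(n_tips = 4, root_age = 1) {
  simulate_yule_tree(n_tips, root_age, seed = 424242 + n_tips)
}

## uniform multiplier stratified dispersal over given areas
uniform_strat <- function(areas, boundaries = c(6, 3, 0.2, 0)) {
  m <- matrix(1, length(areas), length(areas), dimnames = list(areas, areas))
  stratified_dispersal(boundaries, rep(list(m), length(boundaries) - 1L))
}
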