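#' Default synthetic study configuration
#'
#' The sampling design of the six-population study: per-population mtDNA
#' sample sizes 21, 25, 9, 16, 8, 11 and microsatellite sample sizes 24,
#' 26, 10, 33, 12, 24 (diploid individuals), a concatenated 652 + 377 bp
#' maternally inherited mtDNA locus (inheritance scaler 0.25 of the diploid
#' deme size) and 12 independent diploid microsatellite loci (inheritance
#' scaler 2).
#'
#' @param scenarios named list of [scenario()] objects (default
#'   [default_scenarios()]).
#' @return List of configuration settings.
#' @export
synthetic_config <- function(scenarios = default_scenarios()) {
  pops <- scenarios[[1L]]$populations
  list(scenarios = scenarios,
       mt_samples = stats::setNames(c(21L, 25L, 9L, 16L, 8L, 11L), pops),
       msat_samples = stats::setNames(c(24L, 26L, 10L, 33L, 12L, 24L), pops),
       mt_length = c(COI = 652L, CR = 377L),
       n_msat_loci = 12L,
       mt_scaler = 0.25,
       msat_scaler = 2)
}

#' Generate a complete synthetic two-marker study dataset
#'
#' Draws parameters from a scenario's priors, simulates one mtDNA genealogy
#' (COI + Control Region share it, as a single non-recombining locus) with
#' HKY+gamma mutation, and one independent genealogy per microsatellite
#' locus with generalized stepwise mutation, pairing consecutive gene
#' copies into diploid individuals. Fully reproducible from
#' `(scenario_id, seed)`.
#'
#' @param scenario_id one of the names of `config$scenarios`.
#' @param seed integer seed.
#' @param config a [synthetic_config()].
#' @param params optional pre-drawn [draw_params()] result (used by the ABC
#'   reference-table builder); when `NULL`, parameters are drawn here.
#' @return Object of class `SyntheticDataset`: `mt_aln`, `mt_popmap`,
#'   `genotypes`, `msat_popmap`, `scenario_id`, `params`, `seed`.
#' @export
make_synthetic_study <- function(scenario_id, seed, config = synthetic_config(),
                                 params = NULL) {
  sc <- config$scenarios[[scenario_id]]
  if (is.null(sc)) stopf("unknown scenario id '%s'", scenario_id)
  with_seed(derive_seed(seed, 1L), {
    ps <- params %||% draw_params(sc)
    mut <- ps$mutation
    ## mtDNA: one genealogy, concatenated locus
    mt_tree <- simulate_genealogy(ps, sc, config$mt_samples,
                                  inheritance_scaler = config$mt_scaler)
    ids <- paste0("mt_", mt_tree$tip_pop, "_",
                  stats::ave(seq_len(mt_tree$n_tips), mt_tree$tip_pop,
                             FUN = seq_along))
    mt_aln <- mutate_sequence(
      mt_tree,
      model = list(rate = mut$mt_rate, kappa = mut$kappa,
                   base_freqs = mut$base_freqs,
                   gamma_shape = mut$gamma_shape),
      L = sum(config$mt_length), tip_labels = ids, locus_label = "mtDNA_concat")
    mt_pm <- popmap(ids, mt_tree$tip_pop)
    ## microsatellites: independent genealogies, 2 gene copies per individual
    n_ind <- config$msat_samples
    gene_samples <- 2L * n_ind
    a1 <- a2 <- matrix(NA_integer_, sum(n_ind), config$n_msat_loci)
    for (l in seq_len(config$n_msat_loci)) {
      tr <- simulate_genealogy(ps, sc, gene_samples,
                               inheritance_scaler = config$msat_scaler)
      alle <- mutate_microsat(tr, rate = mut$msat_rate,
                              p_single = mut$p_single,
                              bounds = mut$msat_bounds)
      ## consecutive copies within a deme form one individual
      off <- 0L
      for (pop in names(n_ind)) {
        sel <- which(tr$tip_pop == pop)
        np <- n_ind[[pop]]
        a1[off + seq_len(np), l] <- alle[sel[2L * seq_len(np) - 1L]]
        a2[off + seq_len(np), l] <- alle[sel[2L * seq_len(np)]]
        off <- off + np
      }
    }
    ind_pop <- rep(names(n_ind), n_ind)
    ind_ids <- paste0("ind_", ind_pop, "_",
                      stats::ave(seq_along(ind_pop), ind_pop, FUN = seq_along))
    gt <- genotype_table(ind_ids, paste0("L", seq_len(config$n_msat_loci)),
                         a1, a2)
    structure(list(mt_aln = mt_aln, mt_popmap = mt_pm,
                   genotypes = gt, msat_popmap = popmap(ind_ids, ind_pop),
                   scenario_id = scenario_id, params = ps, seed = seed),
              class = "SyntheticDataset")
  })
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset (%s, seed %s): %d mtDNA sequences x %d bp, %d individuals x %d loci\n",
              x$scenario_id, format(x$seed), length(x$mt_aln$sample_ids),
              x$mt_aln$length, length(x$genotypes$sample_ids),
              length(x$genotypes$locus_ids)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the FASTA alignment, GenePop genotypes, both popmaps and a JSON
#' truth file (scenario, drawn parameters, seed).
#'
#' @param ds a [make_synthetic_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(ds, dir) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(ds$mt_aln, file.path(dir, "mtdna.fasta"))
  write_popmap(ds$mt_popmap, file.path(dir, "mtdna_popmap.tsv"))
  write_genepop(ds$genotypes, ds$msat_popmap, file.path(dir, "msat.genepop"))
  write_popmap(ds$msat_popmap, file.path(dir, "msat_popmap.tsv"))
  truth <- list(scenario_id = ds$scenario_id, seed = ds$seed,
                params = as.list(ds$params$values))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
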