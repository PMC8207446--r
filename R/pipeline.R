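#' Assemble a pipeline configuration
#'
#' Validated key-value configuration for [run_pipeline()]. Either
#' `synthetic` mode (a scenario id; inputs are generated) or explicit input
#' paths (FASTA + popmap for mtDNA, GenePop for microsatellites, Newick +
#' tip-area TSV for the dispersal stage).
#'
#' @param out_dir output directory for the report bundle.
#' @param seed global integer seed; every stage derives its own stream.
#' @param synthetic_scenario scenario id (`"H0"`, `"H1"`, `"H2"`) or `NULL`
#'   to use file inputs.
#' @param fasta,popmap_mt,genepop,tree,tip_areas input paths (file mode).
#' @param popmap_msat optional TSV popmap for the microsatellite samples;
#'   when absent, the population blocks implied by the GenePop file are
#'   used (populations then carry GenePop's first-sample names, which the
#'   ABC stage cannot match against the mtDNA populations).
#' @param stages character subset of
#'   `c("mtstats", "msatstats", "abc", "dec")`.
#' @param gamma_a gamma shape for the Tamura distance stage.
#' @param n_perm permutations for divergence tests.
#' @param rarefaction_g rarefaction size (gene copies).
#' @param abc_n_sims reference-table simulations per scenario.
#' @param abc_k nearest neighbours for the ABC posterior.
#' @param neutrality_n_sim coalescent replicates for neutrality p-values.
#' @param bottleneck_n_sim retained equilibrium simulations per locus for
#'   the bottleneck stage.
#' @param config a [synthetic_config()] (scenarios and sampling design).
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed,
                            synthetic_scenario = NULL,
                            fasta = NULL, popmap_mt = NULL, genepop = NULL,
                            popmap_msat = NULL,
                            tree = NULL, tip_areas = NULL,
                            stages = c("mtstats", "msatstats", "abc", "dec"),
                            gamma_a = 0.015, n_perm = 1000L,
                            rarefaction_g = 2L,
                            abc_n_sims = 500L, abc_k = 50L,
                            neutrality_n_sim = 1000L,
                            bottleneck_n_sim = 200L,
                            config = synthetic_config()) {
  bad <- setdiff(stages, c("mtstats", "msatstats", "abc", "dec"))
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.null(synthetic_scenario)) {
    for (p in c(fasta, popmap_mt, genepop, popmap_msat))
      if (!is.null(p) && !file.exists(p)) stopf("input not found: %s", p)
    if (any(c("mtstats", "abc") %in% stages) &&
        (is.null(fasta) || is.null(popmap_mt)))
      stopf("mtstats/abc stages need fasta + popmap_mt (or synthetic mode)")
    if (any(c("msatstats", "abc") %in% stages) && is.null(genepop))
      stopf("msatstats/abc stages need genepop (or synthetic mode)")
  }
  if ("dec" %in% stages) {
    for (p in c(tree, tip_areas))
      if (!is.null(p) && !file.exists(p)) stopf("input not found: %s", p)
  }
  structure(list(out_dir = out_dir, seed = seed,
                 synthetic_scenario = synthetic_scenario,
                 fasta = fasta, popmap_mt = popmap_mt, genepop = genepop,
                 popmap_msat = popmap_msat,
                 tree = tree, tip_areas = tip_areas, stages = stages,
                 gamma_a = gamma_a, n_perm = n_perm,
                 rarefaction_g = rarefaction_g,
                 abc_n_sims = abc_n_sims, abc_k = abc_k,
                 neutrality_n_sim = neutrality_n_sim,
                 bottleneck_n_sim = bottleneck_n_sim,
                 config = config),
            class = "PipelineConfig")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — per-population diversity and
#' divergence statistics for mtDNA, microsatellite diversity and
#' differentiation, ABC scenario choice, and the time-stratified dispersal
#' model comparison — writing every table as TSV/CSV into `out_dir` along
#' with a plain-text run log recording seeds and effective settings. A
#' stage failure aborts with a stage-tagged error; tables already written
#' are preserved.
#'
#' @param cfg a [pipeline_config()].
#' @return List of class `ReportBundle` with every computed result and
#'   `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_lines <- c(sprintf("stratpg pipeline run %s", format(Sys.time())),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[stage %s] %s", name, conditionMessage(e)))
  }
  ## ---- inputs --------------------------------------------------------------
  if (!is.null(cfg$synthetic_scenario)) {
    ds <- stage("simulate",
                make_synthetic_study(cfg$synthetic_scenario,
                                     derive_seed(cfg$seed, 11L),
                                     config = cfg$config))
    sdir <- file.path(cfg$out_dir, "synthetic_input")
    write_synthetic_study(ds, sdir)
    files <- c(files, list.files(sdir, full.names = TRUE))
    aln <- ds$mt_aln; pm <- ds$mt_popmap
    gt <- ds$genotypes; pm_ms <- ds$msat_popmap
    log_lines <- c(log_lines,
                   sprintf("synthetic scenario: %s", cfg$synthetic_scenario))
  } else {
    aln <- pm <- gt <- pm_ms <- NULL
    if (!is.null(cfg$fasta)) {
      aln <- stage("input", read_fasta_alignment(cfg$fasta))
      pm <- stage("input", read_popmap(cfg$popmap_mt))
    }
    if (!is.null(cfg$genepop)) {
      gp <- stage("input", read_genepop(cfg$genepop))
      gt <- gp$genotypes
      pm_ms <- if (!is.null(cfg$popmap_msat))
        stage("input", read_popmap(cfg$popmap_msat))
      else gp$popmap
    }
  }
  ## ---- mtDNA statistics ----------------------------------------------------
  if ("mtstats" %in% cfg$stages) {
    res$diversity <- stage("mtstats",
      neutrality_tests(aln, pm, n_sim = cfg$neutrality_n_sim,
                       seed = derive_seed(cfg$seed, 21L)))
    files <- c(files, write_tsv(res$diversity,
                                file.path(cfg$out_dir, "mtdna_diversity.tsv")))
    res$tamura <- stage("mtstats", suppressWarnings(
      tamura_gamma_distance(aln, gamma_a = cfg$gamma_a)))
    files <- c(files, write_matrix_tsv(round(unclass(res$tamura), 6),
                                       file.path(cfg$out_dir, "tamura_distances.tsv")))
    res$phist <- stage("mtstats",
      amova_phist(aln, pm, n_perm = cfg$n_perm,
                  seed = derive_seed(cfg$seed, 22L)))
    ht <- stage("mtstats", collapse_haplotypes(aln, pm))
    res$haplotypes <- ht
    res$hap_fst <- stage("mtstats",
      haplotype_fst(ht, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 23L)))
    ## Table-2-style matrix: FST below diagonal, PhiST above
    P <- nrow(res$phist$pairwise)
    tab2 <- matrix(NA_real_, P, P, dimnames = dimnames(res$phist$pairwise))
    tab2[upper.tri(tab2)] <- round(res$phist$pairwise[upper.tri(tab2)], 2)
    tab2[lower.tri(tab2)] <- round(res$hap_fst$pairwise[lower.tri(tab2)], 2)
    files <- c(files, write_matrix_tsv(tab2,
                                       file.path(cfg$out_dir, "mtdna_pairwise.tsv")))
    log_lines <- c(log_lines,
      sprintf("mtstats: overall PhiST = %.4f (p = %.4g), haplotype FST = %.4f (p = %.4g)",
              res$phist$overall, res$phist$overall_p,
              res$hap_fst$overall, res$hap_fst$overall_p))
  }
  ## ---- microsatellite statistics -------------------------------------------
  if ("msatstats" %in% cfg$stages) {
    res$locus_diversity <- stage("msatstats",
      locus_diversity(gt, pm_ms, g = cfg$rarefaction_g))
    files <- c(files,
               write_tsv(res$locus_diversity$per_population,
                         file.path(cfg$out_dir, "msat_diversity.tsv")))
    res$differentiation <- stage("msatstats",
      differentiation(gt, pm_ms, n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, 31L)))
    locus_tab <- cbind(locus = rownames(res$differentiation$per_locus),
                       round(res$differentiation$per_locus, 3))
    files <- c(files, write_tsv(locus_tab,
                                file.path(cfg$out_dir, "msat_locus_table.tsv")))
    for (nm in names(res$differentiation$pairwise))
      files <- c(files, write_matrix_tsv(round(res$differentiation$pairwise[[nm]], 3),
                                         file.path(cfg$out_dir,
                                                   sprintf("msat_pairwise_%s.tsv", nm))))
    res$dmu2 <- stage("msatstats", delta_mu_squared(gt, pm_ms))
    files <- c(files, write_matrix_tsv(round(unclass(res$dmu2), 3),
                                       file.path(cfg$out_dir, "msat_dmu2.tsv")))
    res$pcoa <- stage("msatstats", pcoa(sqrt(unclass(res$dmu2)), n_axes = 2L))
    utils::write.csv(data.frame(population = rownames(res$pcoa$coordinates),
                                res$pcoa$coordinates),
                     file.path(cfg$out_dir, "pcoa_coordinates.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(cfg$out_dir, "pcoa_coordinates.csv"))
    res$bottleneck <- stage("msatstats",
      bottleneck_test(gt, pm_ms, model = "TPM", n_sim = cfg$bottleneck_n_sim,
                      seed = derive_seed(cfg$seed, 32L),
                      tune_n_pilot = max(30L, cfg$bottleneck_n_sim %/% 2L),
                      tune_iter = 10L))
    files <- c(files, write_tsv(res$bottleneck$tests,
                                file.path(cfg$out_dir, "bottleneck.tsv")))
    log_lines <- c(log_lines,
      sprintf("msatstats: multilocus FST = %.3f, F'ST = %.3f, Jost's D = %.3f",
              res$differentiation$multilocus["Fst"],
              res$differentiation$multilocus["Fst_prime"],
              res$differentiation$multilocus["jost_d"]))
  }
  ## ---- ABC scenario choice -------------------------------------------------
  if ("abc" %in% cfg$stages) {
    obs <- stage("abc", compute_summary_stats(
      list(mt_aln = aln, mt_popmap = pm, genotypes = gt, msat_popmap = pm_ms)))
    tab <- stage("abc", build_reference_table(
      names(cfg$config$scenarios), cfg$abc_n_sims,
      seed = derive_seed(cfg$seed, 41L), config = cfg$config))
    res$abc <- stage("abc", direct_posterior(obs, tab, k = cfg$abc_k))
    post <- data.frame(scenario = names(res$abc$posterior),
                       posterior = as.numeric(res$abc$posterior))
    files <- c(files, write_tsv(post, file.path(cfg$out_dir, "abc_posterior.tsv")))
    log_lines <- c(log_lines,
      sprintf("abc: %d sims/scenario, k = %d, posterior = %s",
              cfg$abc_n_sims, cfg$abc_k,
              paste(sprintf("%s %.3f", post$scenario, post$posterior),
                    collapse = ", ")))
  }
  ## ---- DEC dispersal comparison --------------------------------------------
  if ("dec" %in% cfg$stages) {
    if (is.null(cfg$tree) || is.null(cfg$tip_areas))
      stopf("[stage dec] tree and tip_areas inputs required")
    dtree <- stage("dec", read_newick_dated(cfg$tree))
    tips <- stage("dec", read_tip_areas(cfg$tip_areas))
    default_areas <- c("Insular", "Western", "Central", "EasternRanges",
                       "EasternCoastal", "Southern")
    if (!all(unlist(tips) %in% default_areas))
      stopf("[stage dec] tip areas must use the six study region labels; for other area sets call compare_dispersal_hypotheses() directly")
    hyps <- dispersal_hypotheses(default_areas)
    res$dec <- stage("dec", compare_dispersal_hypotheses(
      dtree, tips, hyps, seed = derive_seed(cfg$seed, 51L)))
    files <- c(files, write_tsv(res$dec$fits,
                                file.path(cfg$out_dir, "dec_fits.tsv")))
    log_lines <- c(log_lines,
      sprintf("dec: hypothesis weights %s",
              paste(sprintf("%s %.3f", names(res$dec$hypothesis_weights),
                            res$dec$hypothesis_weights), collapse = ", ")))
  }
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)
  structure(c(res, list(files = files, config = cfg)), class = "ReportBundle")
}
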