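#' Construct an event-based demographic scenario
#'
#' A scenario is a set of demes, uniform priors over scalar parameters
#' (event times in generations, effective sizes, admixture proportions,
#' mutation rates), and an ordered set of divergence/admixture events
#' parameterized by those priors. Backward in time, a divergence event
#' moves every lineage of the derived deme into the ancestral deme; an
#' admixture event moves each lineage of the recipient deme to the donor
#' with the event's proportion.
#'
#' @param scenario_id scenario label (e.g. `"H0"`).
#' @param populations character vector of deme names.
#' @param priors named list of length-2 numeric ranges `c(lo, hi)`
#'   (degenerate ranges `c(x, x)` are allowed). Must include one
#'   `N_<population>` prior per deme plus `mt_rate`, `msat_rate` and
#'   `p_single`.
#' @param events list of events, each a list with `type`
#'   (`"divergence"`/`"admixture"`), `time_param` (prior name), and either
#'   `derived`/`ancestral` or `recipient`/`donor` plus `prop_param`;
#'   optional `older_than` names time parameters this event's time must
#'   exceed (enforced by rejection at draw time).
#' @param mutation fixed (non-prior) mutation settings: `kappa`,
#'   `base_freqs` (named A/C/G/T, summing to 1), `gamma_shape`,
#'   `msat_bounds` (allele-size range).
#' @return Object of class `Scenario`.
#' @export
scenario <- function(scenario_id, populations, priors, events,
                     mutation = list()) {
  stopifnot(is.character(scenario_id), length(populations) >= 1L)
  for (nm in c(paste0("N_", populations), "mt_rate", "msat_rate", "p_single"))
    if (is.null(priors[[nm]])) stopf("missing prior '%s'", nm)
  for (pr in priors)
    if (!(is.numeric(pr) && length(pr) == 2L && pr[1L] <= pr[2L] && pr[1L] >= 0))
      stopf("priors must be non-negative ranges c(lo, hi)")
  for (ev in events) {
    if (!ev$type %in% c("divergence", "admixture")) stopf("unknown event type")
    if (is.null(priors[[ev$time_param]])) stopf("event time prior '%s' missing", ev$time_param)
    if (ev$type == "divergence") {
      if (!all(c(ev$derived, ev$ancestral) %in% populations))
        stopf("divergence event references unknown population")
    } else {
      if (!all(c(ev$recipient, ev$donor) %in% populations))
        stopf("admixture event references unknown population")
      if (is.null(priors[[ev$prop_param]])) stopf("admixture proportion prior missing")
    }
  }
  mutation <- utils::modifyList(list(
    kappa = 8,
    base_freqs = c(A = 0.30, C = 0.32, G = 0.14, T = 0.24),
    gamma_shape = 0.25,
    msat_bounds = c(10L, 49L)), mutation)
  structure(list(scenario_id = scenario_id, populations = populations,
                 priors = priors, events = events, mutation = mutation),
            class = "Scenario")
}

#' @export
print.Scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: %d demes, %d events, %d priors\n",
              x$scenario_id, length(x$populations), length(x$events),
              length(x$priors)))
  invisible(x)
}

#' Default six-population divergence/admixture scenarios
#'
#' Builds the three competing histories for the six-deme island/mainland
#' study design. `H0`: all demes split from a single ancestor at one recent
#' time (panmixia until recently; no dispersal structure). `H1`: three old
#' regional lineages — Insular; Mainland (Western + Central + Eastern
#' Ranges); Southeastern (Eastern Coastal + Southern) — with the Insular
#' split at 1.2–2.5 mya and the Southeastern split at 1.7–6.7 mya
#' (priors from the dated-phylogeny node ages), and recent within-region
#' splits. `H2`: as H1 but with an older Southern/Eastern-Coastal split
#' (0.7–1.5 mya) and recent admixture pulses from the Mainland into the
#' Southern (strong) and Eastern Coastal (weaker) demes, i.e. a recent
#' breakdown of the Mainland/Southeastern barrier plus a new barrier
#' between the two southeastern demes.
#'
#' Times are converted to generations with `generation_time` years per
#' generation. Deme sizes have U\[1e2, 1e5\] priors; the mtDNA substitution
#' rate U\[1e-8, 1e-6\] per site per generation; the microsatellite rate
#' U\[1e-4, 1e-3\] with single-step probability U\[0.8, 1\].
#'
#' @param generation_time generation time in years.
#' @return Named list of three [scenario()] objects (`H0`, `H1`, `H2`).
#' @export
default_scenarios <- function(generation_time = 2) {
  gens <- function(mya) mya * 1e6 / generation_time
  pops <- c("Insular", "Western", "Central", "EasternRanges",
            "EasternCoastal", "Southern")
  base_priors <- c(
    stats::setNames(rep(list(c(1e2, 1e5)), 6L), paste0("N_", pops)),
    list(mt_rate = c(1e-8, 1e-6),
         msat_rate = c(1e-4, 1e-3),
         p_single = c(0.8, 1.0)))
  recent <- c(gens(0.01), gens(0.4))

  h0 <- scenario("H0", pops,
    priors = c(base_priors, list(T0 = c(gens(0.01), gens(0.4)))),
    events = list(
      list(type = "divergence", time_param = "T0", derived = "Insular",        ancestral = "Western"),
      list(type = "divergence", time_param = "T0", derived = "Central",        ancestral = "Western"),
      list(type = "divergence", time_param = "T0", derived = "EasternRanges",  ancestral = "Western"),
      list(type = "divergence", time_param = "T0", derived = "EasternCoastal", ancestral = "Western"),
      list(type = "divergence", time_param = "T0", derived = "Southern",       ancestral = "Western")))

  h1_events <- list(
    list(type = "divergence", time_param = "T_central",  derived = "Central",        ancestral = "Western"),
    list(type = "divergence", time_param = "T_eranges",  derived = "EasternRanges",  ancestral = "Western"),
    list(type = "divergence", time_param = "T_se_int",   derived = "EasternCoastal", ancestral = "Southern"),
    list(type = "divergence", time_param = "T_insular",  derived = "Insular",        ancestral = "Western",
         older_than = c("T_central", "T_eranges")),
    list(type = "divergence", time_param = "T_se",       derived = "Southern",       ancestral = "Western",
         older_than = c("T_insular", "T_se_int")))
  h1_priors <- c(base_priors, list(
    T_central = recent, T_eranges = recent, T_se_int = recent,
    T_insular = c(gens(1.2), gens(2.5)),
    T_se = c(gens(1.7), gens(6.7))))
  h1 <- scenario("H1", pops, priors = h1_priors, events = h1_events)

  h2_priors <- utils::modifyList(h1_priors, list(
    T_se_int = c(gens(0.7), gens(1.5)),
    T_adm_s = c(gens(0.002), gens(0.02)),
    T_adm_ec = c(gens(0.002), gens(0.02)),
    r_s = c(0.05, 0.5),
    r_ec = c(0.05, 0.25)))
  h2_events <- c(list(
    list(type = "admixture", time_param = "T_adm_s", recipient = "Southern",
         donor = "Western", prop_param = "r_s"),
    list(type = "admixture", time_param = "T_adm_ec", recipient = "EasternCoastal",
         donor = "Western", prop_param = "r_ec")),
    h1_events)
  h2 <- scenario("H2", pops, priors = h2_priors, events = h2_events)

  list(H0 = h0, H1 = h1, H2 = h2)
}

#' Draw a parameter set from a scenario's priors
#'
#' Independent uniform draws within each prior range; event-time ordering
#' constraints (`older_than`) are enforced by rejection and redraw of the
#' whole time vector.
#'
#' @param sc a [scenario()].
#' @param seed optional integer seed.
#' @return Object of class `ParamSet`: `values` (all drawn scalars),
#'   `sizes` (per deme), `events` (resolved, sorted by time) and `mutation`
#'   (rates and fixed substitution settings).
#' @export
draw_params <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "Scenario"))
  with_seed(seed, {
    draw_all <- function() {
      vapply(sc$priors, function(pr) stats::runif(1L, pr[1L], pr[2L]), 0)
    }
    ok <- FALSE
    for (try in seq_len(10000L)) {
      v <- draw_all()
      ok <- TRUE
      for (ev in sc$events) {
        for (parent in ev$older_than %||% character(0)) {
          if (!(v[[ev$time_param]] > v[[parent]])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) break
    }
    if (!ok) stopf("could not satisfy event-time ordering constraints (infeasible priors)")
    events <- lapply(sc$events, function(ev) {
      ev$time <- v[[ev$time_param]]
      if (ev$type == "admixture") ev$prop <- v[[ev$prop_param]]
      ev
    })
    events <- events[order(vapply(events, `[[`, 0, "time"))]
    structure(list(values = v,
                   sizes = stats::setNames(v[paste0("N_", sc$populations)],
                                           sc$populations),
                   events = events,
                   mutation = c(list(mt_rate = v[["mt_rate"]],
                                     msat_rate = v[["msat_rate"]],
                                     p_single = v[["p_single"]]),
                                sc$mutation)),
              class = "ParamSet")
  })
}
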