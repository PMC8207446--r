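#' Fit a DEC-family model by maximum likelihood
#'
#' Bounded multi-start maximization of [stratified_loglik()] over the
#' dispersal rate `d` and extirpation rate `e` (both in
#' `[1e-12, 5]`, searched on the log scale) and, for `+J` models, the
#' founder weight `j` in `[0, 3]`.
#'
#' @param dt a [dated_tree()].
#' @param tip_ranges named list of tip area vectors.
#' @param base base model name (see [dec_model()]).
#' @param founder_j fit the founder-event weight `j`.
#' @param strat a [stratified_dispersal()].
#' @param space optional [enumerate_ranges()].
#' @param n_starts number of optimization starts (first start from the
#'   conventional d = e = 0.01 initial point, the rest random).
#' @param seed optional integer seed for the random starts.
#' @return Object of class `DECFit`: `model`, `loglik`, `params`,
#'   `n_params`, `AIC`, `AICc` (sample size = number of tips), `n_tips`.
#' @export
fit_dec_model <- function(dt, tip_ranges, base = "DEC", founder_j = FALSE,
                          strat, space = NULL, n_starts = 5L, seed = NULL) {
  stopifnot(inherits(dt, "DatedTree"))
  areas <- colnames(strat$matrices[[1L]])
  space <- space %||% enumerate_ranges(areas, include_null = TRUE)
  lo_d <- log(1e-12); hi_d <- log(5)
  npar <- if (founder_j) 3L else 2L
  prep <- dec_prep(dt, tip_ranges, strat, space, base)
  obj <- function(par) {
    ll <- tryCatch(dec_eval(prep, exp(par[1L]), exp(par[2L]),
                            if (founder_j) par[3L] else 0),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(c(log(0.01), log(0.01), if (founder_j) 0.01))
  if (n_starts > 1L) {
    rnd <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      c(stats::runif(1L, log(1e-4), log(1)), stats::runif(1L, log(1e-6), log(1)),
        if (founder_j) stats::runif(1L, 0, 2.5))))
    starts <- c(starts, rnd)
  }
  lower <- c(lo_d, lo_d, if (founder_j) 0)
  upper <- c(hi_d, hi_d, if (founder_j) 3)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stopf("non-finite likelihood at all starts")
  ll <- -best$value
  n <- length(dt$tree$tip.label)
  aic <- 2 * npar - 2 * ll
  aicc <- aic + 2 * npar * (npar + 1) / max(n - npar - 1, 1e-12)
  params <- c(d = exp(best$par[1L]), e = exp(best$par[2L]),
              j = if (founder_j) best$par[3L] else NA_real_)
  structure(list(model = paste0(base, if (founder_j) "+J" else ""),
                 base = base, founder_j = founder_j,
                 loglik = ll, params = params, n_params = npar,
                 AIC = aic, AICc = aicc, n_tips = n),
            class = "DECFit")
}

#' @export
print.DECFit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.3f, d = %.4g, e = %.4g%s, AICc = %.2f\n",
              x$model, x$loglik, x$params["d"], x$params["e"],
              if (x$founder_j) sprintf(", j = %.3f", x$params["j"]) else "",
              x$AICc))
  invisible(x)
}

#' Compare dispersal hypotheses across DEC-family base models
#'
#' Fits every base model (with and without founder-event jumps by default)
#' under every dispersal hypothesis, computes AIC and AICc (sample size =
#' number of tips) for each fit, Akaike weights across the whole fit set,
#' and the summed weight per hypothesis. Failed fits are dropped with a
#' warning and weights renormalized.
#'
#' @param dt a [dated_tree()].
#' @param tip_ranges named list of tip area vectors.
#' @param hypotheses named list of [stratified_dispersal()] objects.
#' @param bases base models to include.
#' @param founder both plain and `+J` variants are fitted when `TRUE`.
#' @param criterion `"AICc"` (default) or `"AIC"` for the weights.
#' @param n_starts,seed,space passed to [fit_dec_model()].
#' @return List with `fits` (data.frame: hypothesis, model, loglik,
#'   n_params, AIC, AICc, weight), `hypothesis_weights` (named, sums to 1)
#'   and `fit_objects`.
#' @export
compare_dispersal_hypotheses <- function(dt, tip_ranges, hypotheses,
                                         bases = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                                         founder = TRUE,
                                         criterion = c("AICc", "AIC"),
                                         n_starts = 3L, seed = NULL,
                                         space = NULL) {
  criterion <- match.arg(criterion)
  areas <- colnames(hypotheses[[1L]]$matrices[[1L]])
  space <- space %||% enumerate_ranges(areas, include_null = TRUE)
  rows <- list(); objs <- list()
  fid <- 0L
  for (h in names(hypotheses)) for (b in bases)
    for (fj in if (founder) c(FALSE, TRUE) else FALSE) {
      fid <- fid + 1L
      fit <- tryCatch(
        fit_dec_model(dt, tip_ranges, base = b, founder_j = fj,
                      strat = hypotheses[[h]], space = space,
                      n_starts = n_starts,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, fid)),
        error = function(e) NULL)
      if (is.null(fit)) {
        warnf("fit failed: %s / %s%s", h, b, if (fj) "+J" else "")
        next
      }
      objs[[length(objs) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        hypothesis = h, model = fit$model, loglik = fit$loglik,
        n_params = fit$n_params, AIC = fit$AIC, AICc = fit$AICc)
    }
  if (length(rows) == 0L) stopf("all fits failed")
  fits <- do.call(rbind, rows)
  ic <- fits[[criterion]]
  w <- exp(-(ic - min(ic)) / 2)
  fits$weight <- w / sum(w)
  hw <- vapply(names(hypotheses), function(h)
    sum(fits$weight[fits$hypothesis == h]), 0)
  list(fits = fits, hypothesis_weights = hw, fit_objects = objs,
       criterion = criterion)
}
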