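#' Enumerate geographic range states
#'
#' Builds the state space of a DEC-family model: all non-empty subsets of
#' the area set (optionally capped at `max_range_size` areas), ordered by
#' subset size then lexicographically in area order, optionally preceded by
#' the null (empty) range used for extirpation paths.
#'
#' @param areas ordered character vector of area labels (at most 10).
#' @param max_range_size optional cap on range size.
#' @param include_null include the empty range as state 1.
#' @return Object of class `RangeStateSpace`: `areas`, `states` (list of
#'   integer area-index vectors; the null range is `integer(0)`),
#'   `labels`, `null_state` (index or `NA`), `n_states`.
#' @export
enumerate_ranges <- function(areas, max_range_size = NULL,
                             include_null = TRUE) {
  n <- length(areas)
  if (n < 1L || n > 10L)
    stopf("1 to 10 areas supported (state space grows as 2^n)")
  if (anyDuplicated(areas)) stopf("duplicate area labels")
  cap <- min(max_range_size %||% n, n)
  states <- list()
  if (include_null) states[[1L]] <- integer(0)
  for (sz in seq_len(cap)) {
    cmb <- utils::combn(n, sz)
    for (c1 in seq_len(ncol(cmb))) states[[length(states) + 1L]] <- cmb[, c1]
  }
  labels <- vapply(states, function(s)
    if (length(s) == 0L) "()" else paste(areas[s], collapse = "+"), "")
  structure(list(areas = areas, states = states, labels = labels,
                 null_state = if (include_null) 1L else NA_integer_,
                 n_states = length(states)),
            class = "RangeStateSpace")
}

## canonical lookup key for a range state ("-" for the null range, which
## must not collide with the empty string in named-vector lookups)
state_key <- function(s) if (length(s) == 0L) "-" else paste(s, collapse = ",")

## index of a state given an integer area-index vector (sorted)
state_index <- function(space, s) {
  s <- sort(s)
  for (i in seq_along(space$states))
    if (length(space$states[[i]]) == length(s) && all(space$states[[i]] == s))
      return(i)
  NA_integer_
}

#' Construct a time-stratified dispersal structure
#'
#' Per-epoch area-by-area dispersal multiplier matrices. Boundaries are
#' ages in time units (e.g. mya), strictly decreasing to 0; stratum `s`
#' spans ages `(boundaries[s+1], boundaries[s]]`.
#'
#' @param boundaries numeric vector of ages, strictly decreasing, last 0.
#' @param matrices list of `length(boundaries) - 1` positive multiplier
#'   matrices (areas x areas), oldest first.
#' @return Object of class `StratifiedDispersal`.
#' @export
stratified_dispersal <- function(boundaries, matrices) {
  if (length(boundaries) < 2L || any(diff(boundaries) >= 0) ||
      boundaries[length(boundaries)] != 0)
    stopf("boundaries must strictly decrease to 0")
  if (length(matrices) != length(boundaries) - 1L)
    stopf("need one multiplier matrix per stratum")
  for (m in matrices) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || any(m <= 0))
      stopf("multiplier matrices must be square and strictly positive")
  }
  structure(list(boundaries = boundaries, matrices = lapply(matrices, as.matrix)),
            class = "StratifiedDispersal")
}

#' Dispersal-hypothesis multiplier matrices for a three-region system
#'
#' Builds the three competing time-stratified dispersal structures on the
#' epochs 6-3, 3-0.2 and 0.2-0 mya. `H0`: no restrictions in any epoch
#' (all multipliers 1). `H1`: open during initial colonization (6-3), then
#' a barrier (multiplier `barrier`) between the three regions from 3 mya to
#' the present. `H2`: as H1 until 0.2 mya; in the most recent epoch the
#' Mainland/Southeastern barrier dissolves (multiplier 1) while the
#' Insular barrier persists and a new barrier separates the two
#' southeastern areas.
#'
#' @param areas area labels.
#' @param regions named list of three character vectors (`Insular`,
#'   `Mainland`, `Southeastern`) partitioning `areas`.
#' @param barrier restricted-dispersal multiplier (default 0.01).
#' @param boundaries stratum boundaries, oldest first, ending at 0.
#' @return Named list of three [stratified_dispersal()] objects.
#' @export
dispersal_hypotheses <- function(areas,
                                 regions = list(
                                   Insular = "Insular",
                                   Mainland = c("Western", "Central", "EasternRanges"),
                                   Southeastern = c("EasternCoastal", "Southern")),
                                 barrier = 0.01,
                                 boundaries = c(6, 3, 0.2, 0)) {
  if (!setequal(unlist(regions), areas))
    stopf("regions must partition the area set")
  n <- length(areas)
  open <- matrix(1, n, n, dimnames = list(areas, areas))
  region_of <- stats::setNames(rep(names(regions), lengths(regions)),
                               unlist(regions))[areas]
  between <- outer(region_of, region_of, "!=")
  closed <- open; closed[between] <- barrier
  ## H2 recent epoch: Mainland <-> Southeastern open, Insular barrier kept,
  ## new barrier between the two southeastern areas
  recent <- open
  ins <- region_of == "Insular"
  recent[ins, !ins] <- barrier; recent[!ins, ins] <- barrier
  se <- which(region_of == "Southeastern")
  if (length(se) >= 2L)
    for (i in se) for (j in se) if (i != j) recent[i, j] <- barrier
  list(H0 = stratified_dispersal(boundaries, list(open, open, open)),
       H1 = stratified_dispersal(boundaries, list(open, closed, closed)),
       H2 = stratified_dispersal(boundaries, list(open, closed, recent)))
}

#' Write a stratified dispersal structure as plain text
#'
#' One block per stratum: a header line `stratum <old_age> <young_age>`,
#' then an area-labelled multiplier matrix (tab-separated).
#'
#' @param strat a [stratified_dispersal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stratified_dispersal <- function(strat, path) {
  stopifnot(inherits(strat, "StratifiedDispersal"))
  con <- file(path, "w"); on.exit(close(con))
  b <- strat$boundaries
  for (s in seq_along(strat$matrices)) {
    writeLines(sprintf("stratum %g %g", b[s], b[s + 1L]), con)
    m <- strat$matrices[[s]]
    writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
    for (r in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[r], format(m[r, ], trim = TRUE)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a stratified dispersal structure from plain text
#'
#' Inverse of [write_stratified_dispersal()].
#'
#' @param path input path.
#' @return A [stratified_dispersal()].
#' @export
read_stratified_dispersal <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^stratum\\b", lines)
  if (length(hdr) == 0L) stopf("no stratum blocks in %s", path)
  bounds <- numeric(0)
  mats <- list()
  for (i in seq_along(hdr)) {
    parts <- strsplit(trimws(lines[hdr[i]]), "[ \t]+")[[1L]]
    if (length(parts) != 3L) stopf("malformed stratum header: '%s'", lines[hdr[i]])
    old <- as.numeric(parts[2L]); young <- as.numeric(parts[3L])
    end <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[(hdr[i] + 1L):end]
    areas <- strsplit(block[1L], "\t")[[1L]][-1L]
    rows <- lapply(block[-1L], function(l) strsplit(l, "\t")[[1L]])
    m <- matrix(NA_real_, length(areas), length(areas),
                dimnames = list(areas, areas))
    for (r in rows) m[r[1L], ] <- as.numeric(r[-1L])
    bounds <- c(bounds, old)
    if (i == length(hdr)) bounds <- c(bounds, young)
    mats[[i]] <- m
  }
  stratified_dispersal(bounds, mats)
}

#' Specify a DEC-family model
#'
#' @param base `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"` (cladogenetic
#'   repertoire; the anagenetic dispersal/extirpation process is shared).
#' @param founder_j add founder-event ("jump") speciation with weight `j`.
#' @param d,e,j dispersal rate, extirpation rate, founder weight.
#' @return Object of class `DECModel`.
#' @export
dec_model <- function(base = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                      founder_j = FALSE, d = 0.1, e = 0.01, j = 0) {
  base <- match.arg(base)
  if (d < 0 || e < 0 || j < 0) stopf("d, e, j must be non-negative")
  if (!founder_j && j != 0) stopf("j > 0 requires founder_j = TRUE")
  structure(list(base = base, founder_j = founder_j, d = d, e = e, j = j),
            class = "DECModel")
}
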