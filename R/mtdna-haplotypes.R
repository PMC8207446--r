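#' Collapse aligned sequences into haplotypes
#'
#' Groups identical sequences into haplotypes and tabulates their occurrence
#' per population. Samples missing data (gaps, `N`, IUPAC ambiguities) at
#' more than `max_missing` of sites are excluded. A sample with some missing
#' data joins the first haplotype it is compatible with (no mismatch at
#' jointly non-missing sites); assignment order is sample order, which makes
#' the grouping deterministic.
#'
#' @param aln an [alignment()] object.
#' @param pm a [popmap()] covering the alignment samples (samples absent
#'   from the map are dropped).
#' @param max_missing maximum tolerated fraction of missing sites per sample.
#' @return Object of class `HaplotypeTable`: list with
#'   `haplotype_sequences` (representative sequence strings),
#'   `variable_sites` (1-based positions varying among haplotypes),
#'   `counts` (population x haplotype matrix), `assignments` (named vector
#'   sample -> haplotype index) and `excluded` (sample ids dropped for
#'   missing data).
#' @export
collapse_haplotypes <- function(aln, pm, max_missing = 0.1) {
  stopifnot(inherits(aln, "Alignment"), inherits(pm, "PopulationMap"))
  ids <- intersect(aln$sample_ids, names(pm$assignments))
  if (length(ids) == 0L) stopf("no alignment samples present in the population map")
  enc <- encode_alignment(aln)[ids, , drop = FALSE]
  mfrac <- rowMeans(is.na(enc))
  excluded <- ids[mfrac > max_missing]
  keep <- setdiff(ids, excluded)
  if (length(keep) == 0L) stopf("all samples exceed the missing-data threshold")
  enc <- enc[keep, , drop = FALSE]

  reps <- list()            # representative encoded sequences
  assign <- integer(length(keep))
  for (i in seq_along(keep)) {
    s <- enc[i, ]
    hit <- 0L
    for (j in seq_along(reps)) {
      r <- reps[[j]]
      shared <- !is.na(s) & !is.na(r)
      if (!any(s[shared] != r[shared])) { hit <- j; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- s
      hit <- length(reps)
    } else {
      ## fill missing sites of the representative from the new member
      r <- reps[[hit]]
      fill <- is.na(r) & !is.na(s)
      r[fill] <- s[fill]
      reps[[hit]] <- r
    }
    assign[i] <- hit
  }
  H <- length(reps)
  repmat <- do.call(rbind, reps)
  nb <- apply(repmat, 2L, function(col) length(unique(col[!is.na(col)])))
  variable_sites <- which(nb >= 2L)
  bases <- c("A", "C", "G", "T")
  hseq <- apply(repmat, 1L, function(r) {
    ch <- ifelse(is.na(r), "N", bases[r])
    paste(ch, collapse = "")
  })
  pops <- pm$populations
  counts <- matrix(0L, length(pops), H,
                   dimnames = list(pops, paste0("H", seq_len(H))))
  popv <- pm$assignments[keep]
  for (i in seq_along(keep)) counts[popv[i], assign[i]] <- counts[popv[i], assign[i]] + 1L
  structure(list(haplotype_sequences = unname(hseq),
                 variable_sites = variable_sites,
                 counts = counts,
                 assignments = stats::setNames(assign, keep),
                 excluded = excluded),
            class = "HaplotypeTable")
}

#' @export
print.HaplotypeTable <- function(x, ...) {
  cat(sprintf("HaplotypeTable: %d haplotypes, %d variable sites, %d samples\n",
              length(x$haplotype_sequences), length(x$variable_sites),
              length(x$assignments)))
  invisible(x)
}
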