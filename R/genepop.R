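#' Construct a diploid genotype table
#'
#' Stores diploid microsatellite genotypes as two parallel allele-size
#' matrices (samples x loci). Genotypes are unordered pairs; alleles are
#' stored with `a1 <= a2`. Missing genotypes are `NA` in both matrices.
#'
#' @param sample_ids unique sample ids.
#' @param locus_ids unique locus ids.
#' @param a1,a2 integer matrices (samples x loci) of allele sizes
#'   (positive integers, e.g. repeat counts or fragment lengths); `NA` = missing.
#' @return An object of class `GenotypeTable`.
#' @export
genotype_table <- function(sample_ids, locus_ids, a1, a2) {
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids")
  if (anyDuplicated(locus_ids)) stopf("duplicate locus ids")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(length(sample_ids), length(locus_ids))) ||
      !all(dim(a2) == dim(a1)))
    stopf("allele matrices must be samples x loci")
  if (any(xor(is.na(a1), is.na(a2))))
    stopf("half-missing genotypes are not allowed")
  ok <- !is.na(a1)
  if (any(a1[ok] < 1) || any(a2[ok] < 1) ||
      any(a1[ok] != floor(a1[ok])) || any(a2[ok] != floor(a2[ok])))
    stopf("allele sizes must be positive integers")
  swap <- ok & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, locus_ids)
  structure(list(sample_ids = sample_ids, locus_ids = locus_ids,
                 a1 = a1, a2 = a2, ploidy = 2L),
            class = "GenotypeTable")
}

#' @export
print.GenotypeTable <- function(x, ...) {
  cat(sprintf("GenotypeTable: %d samples x %d loci (%.1f%% missing)\n",
              length(x$sample_ids), length(x$locus_ids),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Read a GenePop genotype file
#'
#' Parses the classical GenePop dialect: a title line, one locus name per
#' line (or one comma-separated line), then `Pop` blocks of
#' `sample_id ,  genotype genotype ...` rows with 2- or 3-digit allele
#' coding. `000`/`00` alleles denote missing data. Within a locus the coding
#' width must be consistent.
#'
#' @param path path to a GenePop file.
#' @return A list with elements `genotypes` (a [genotype_table()]) and
#'   `popmap` (a [popmap()] implied by the `Pop` blocks; populations are
#'   named after their first sample, the GenePop convention).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stopf("not a GenePop file (too short): %s", path)
  body <- lines[-1L]                      # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop == 1L)
    stopf("no locus names / no Pop block in %s", path)
  loc_lines <- trimws(body[seq_len(first_pop - 1L)])
  locus_ids <- trimws(unlist(strsplit(loc_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  nloc <- length(locus_ids)
  ids <- character(); pops <- character()
  rows1 <- list(); rows2 <- list()
  pop_idx <- 0L; pop_name <- NULL
  for (ln in body[first_pop:length(body)]) {
    if (toupper(trimws(ln)) == "POP") { pop_idx <- pop_idx + 1L; pop_name <- NULL; next }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L) stopf("malformed GenePop sample line: '%s'", ln)
    sid <- trimws(parts[1L])
    gstr <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[ \t]+")[[1L]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != nloc)
      stopf("sample '%s' has %d genotypes for %d loci", sid, length(gstr), nloc)
    w <- nchar(gstr)
    if (any(w != 4L & w != 6L))
      stopf("sample '%s': genotype strings must be 4 or 6 digits", sid)
    a1 <- a2 <- integer(nloc)
    for (j in seq_len(nloc)) {
      half <- w[j] / 2L
      x1 <- as.integer(substr(gstr[j], 1L, half))
      x2 <- as.integer(substr(gstr[j], half + 1L, w[j]))
      if (is.na(x1) || is.na(x2)) stopf("non-numeric genotype '%s'", gstr[j])
      a1[j] <- if (x1 == 0L) NA_integer_ else x1
      a2[j] <- if (x2 == 0L) NA_integer_ else x2
    }
    ## either allele 0 means the whole genotype is missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    if (is.null(pop_name)) pop_name <- sid
    ids <- c(ids, sid); pops <- c(pops, pop_name)
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
    attr(rows1[[length(rows1)]], "w") <- w
  }
  if (length(ids) == 0L) stopf("GenePop file has no samples: %s", path)
  ## per-locus consistent coding width
  wmat <- do.call(rbind, lapply(rows1, attr, "w"))
  if (any(apply(wmat, 2L, function(x) length(unique(x))) > 1L))
    stopf("mixed 2- and 3-digit allele coding within a locus")
  gt <- genotype_table(ids, locus_ids, do.call(rbind, rows1), do.call(rbind, rows2))
  list(genotypes = gt, popmap = popmap(ids, pops))
}

#' Write a GenePop genotype file
#'
#' @param gt a [genotype_table()].
#' @param pm a [popmap()] covering all samples of `gt`.
#' @param path output path.
#' @param title title line.
#' @param digits allele coding width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, pm, path, title = "stratpg genotypes", digits = 3L) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(pm, "PopulationMap"),
            digits %in% c(2L, 3L))
  mx <- suppressWarnings(max(gt$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stopf("allele size %d does not fit %d-digit coding", mx, digits)
  fmt <- function(a) {
    out <- formatC(a, width = digits, flag = "0")
    out[is.na(a)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, gt$locus_ids), con)
  for (pop in pm$populations) {
    writeLines("Pop", con)
    for (sid in intersect(names(pm$assignments)[pm$assignments == pop], gt$sample_ids)) {
      i <- match(sid, gt$sample_ids)
      g <- paste0(fmt(gt$a1[i, ]), fmt(gt$a2[i, ]))
      writeLines(paste0(sid, " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
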