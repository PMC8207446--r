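#' Construct a multiple sequence alignment
#'
#' An `Alignment` holds equal-length nucleotide sequences with unique sample
#' identifiers. Sequences may contain `A`, `C`, `G`, `T`, IUPAC ambiguity
#' codes, `N` and the gap character `-`; anything other than the four
#' unambiguous bases is treated as missing at the affected site by downstream
#' statistics.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param sequences character vector of equal-length sequence strings
#'   (case-insensitive), one per sample.
#' @param locus_label single string naming the locus (e.g. `"COI"`).
#' @return An object of class `Alignment`: a list with elements `sample_ids`,
#'   `seq` (n x L character matrix, upper case), `length` and `locus_label`.
#' @export
alignment <- function(sample_ids, sequences, locus_label = "locus") {
  sample_ids <- as.character(sample_ids)
  sequences <- toupper(as.character(sequences))
  if (length(sample_ids) != length(sequences))
    stopf("sample_ids (%d) and sequences (%d) differ in length",
          length(sample_ids), length(sequences))
  if (length(sequences) == 0L) stopf("alignment must contain >= 1 sequence")
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stopf("ragged alignment: sequence lengths %s",
          paste(sort(unique(lens)), collapse = ", "))
  L <- lens[1L]
  if (L < 1L) stopf("alignment length must be positive")
  bad <- grepl("[^ACGTURYSWKMBDHVN-]", sequences)
  if (any(bad))
    stopf("invalid characters in sequences: %s",
          paste(sample_ids[bad], collapse = ", "))
  m <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
              nrow = length(sequences), ncol = L, byrow = TRUE)
  rownames(m) <- sample_ids
  structure(list(sample_ids = sample_ids, seq = m, length = L,
                 locus_label = locus_label),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment '%s': %d sequences x %d sites\n",
              x$locus_label, length(x$sample_ids), x$length))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads aligned sequences from a FASTA file and validates that all records
#' have equal length.
#'
#' @param path path to a FASTA file.
#' @param expected_length optional integer; if given, an alignment of any
#'   other length is an error.
#' @param locus_label locus name stored in the returned object (defaults to
#'   the file base name).
#' @return An [alignment()] object.
#' @export
read_fasta_alignment <- function(path, expected_length = NULL,
                                 locus_label = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(trimws(lines[1L]), ">"))
    stopf("not a FASTA file (no records): %s", path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)   # first token of the header
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stopf("FASTA record with no sequence in %s", path)
  aln <- alignment(ids, unname(seqs),
                   locus_label = locus_label %||% sub("\\.[^.]*$", "", basename(path)))
  if (!is.null(expected_length) && aln$length != expected_length)
    stopf("alignment length %d != expected %d", aln$length, expected_length)
  aln
}

#' Write a FASTA alignment
#'
#' @param aln an [alignment()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "Alignment"))
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$sample_ids, "\n", seqs), path)
  invisible(path)
}

#' Subset an alignment by sample id
#'
#' Site (column) count is always conserved.
#'
#' @param aln an [alignment()] object.
#' @param ids sample ids to keep, in the order given.
#' @return An [alignment()] object.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "Alignment"))
  miss <- setdiff(ids, aln$sample_ids)
  if (length(miss)) stopf("samples not in alignment: %s", paste(miss, collapse = ", "))
  structure(list(sample_ids = as.character(ids),
                 seq = aln$seq[ids, , drop = FALSE],
                 length = aln$length, locus_label = aln$locus_label),
            class = "Alignment")
}

#' Concatenate alignments sample-wise
#'
#' Joins two or more loci into one alignment; only samples present in every
#' locus are kept (in the order of the first).
#'
#' @param ... two or more [alignment()] objects.
#' @param locus_label label for the concatenated locus.
#' @return An [alignment()] object of length equal to the summed lengths.
#' @export
concat_alignments <- function(..., locus_label = "concat") {
  alns <- list(...)
  if (length(alns) == 1L && is.list(alns[[1L]]) && !inherits(alns[[1L]], "Alignment"))
    alns <- alns[[1L]]
  stopifnot(all(vapply(alns, inherits, TRUE, "Alignment")))
  ids <- Reduce(intersect, lapply(alns, `[[`, "sample_ids"))
  if (length(ids) == 0L) stopf("no samples shared by all loci")
  m <- do.call(cbind, lapply(alns, function(a) a$seq[ids, , drop = FALSE]))
  alignment(ids, apply(m, 1L, paste, collapse = ""), locus_label = locus_label)
}

## fast internal constructor from a character matrix (no validation beyond
## structure; used by the simulator where content is known-valid)
alignment_from_matrix <- function(sample_ids, m, locus_label) {
  rownames(m) <- sample_ids
  structure(list(sample_ids = sample_ids, seq = m, length = ncol(m),
                 locus_label = locus_label),
            class = "Alignment")
}

## integer-encode an alignment: A=1, C=2, G=3, T=4, everything else NA
## (IUPAC ambiguity codes, N and gaps are treated as missing data).
encode_alignment <- function(aln) {
  m <- match(aln$seq, c("A", "C", "G", "T"))
  dim(m) <- dim(aln$seq)
  rownames(m) <- aln$sample_ids
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
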