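#' Construct a population map
#'
#' Maps sample ids to population labels. Population order is the order of
#' first appearance, which is preserved in every downstream table.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param populations character vector of population labels, parallel to
#'   `sample_ids`.
#' @return An object of class `PopulationMap`: list with `assignments`
#'   (named character vector sample -> population) and `populations`
#'   (ordered unique labels).
#' @export
popmap <- function(sample_ids, populations) {
  sample_ids <- as.character(sample_ids)
  populations <- as.character(populations)
  if (length(sample_ids) != length(populations))
    stopf("sample_ids and populations differ in length")
  if (length(sample_ids) == 0L) stopf("empty population map")
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids in population map: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  structure(list(assignments = stats::setNames(populations, sample_ids),
                 populations = unique(populations)),
            class = "PopulationMap")
}

#' @export
print.PopulationMap <- function(x, ...) {
  cat(sprintf("PopulationMap: %d samples in %d populations (%s)\n",
              length(x$assignments), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Read a two-column TSV population map
#'
#' Expects `sample_id<TAB>population`, no header. A sample listed twice is an
#' error (even with the same population).
#'
#' @param path path to the TSV file.
#' @return A [popmap()] object.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "",
                         quote = "", blank.lines.skip = TRUE)
  if (ncol(d) < 2L) stopf("popmap must have two tab-separated columns: %s", path)
  popmap(d[[1L]], d[[2L]])
}

#' Write a population map as TSV
#'
#' @param pm a [popmap()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  stopifnot(inherits(pm, "PopulationMap"))
  utils::write.table(data.frame(names(pm$assignments), unname(pm$assignments)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## samples of one population, in map order
pop_samples <- function(pm, pop) names(pm$assignments)[pm$assignments == pop]
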