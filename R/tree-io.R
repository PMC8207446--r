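#' Construct a dated ultrametric tree
#'
#' Wraps an `ape::phylo` tree whose branch lengths are in units of time
#' (million years in the study design). All tips must be contemporaneous
#' (age 0) within tolerance; node ages are derived from branch lengths.
#'
#' @param tree an `ape::phylo` object, rooted and binary, with branch
#'   lengths.
#' @param tol relative ultrametricity tolerance: the maximum allowed tip-age
#'   deviation is `tol * root_age`.
#' @return Object of class `DatedTree`: list with `tree` (the phylo),
#'   `root_age`, and `ages` (named vector of node ages, tips first).
#' @export
dated_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stopf("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  if (!ape::is.binary(tree)) stopf("tree must be binary")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth[seq_len(n)])
  if (root_age <= 0) stopf("tree has zero height")
  dev <- max(abs(depth[seq_len(n)] - root_age))
  if (dev > tol * root_age)
    stopf("tree is not ultrametric: max tip-age deviation %.3g (tolerance %.3g)",
          dev, tol * root_age)
  ages <- root_age - depth
  ages[seq_len(n)] <- 0
  names(ages) <- c(tree$tip.label, paste0("node", (n + 1L):(2L * n - 1L)))
  structure(list(tree = tree, root_age = root_age, ages = ages),
            class = "DatedTree")
}

#' @export
print.DatedTree <- function(x, ...) {
  cat(sprintf("DatedTree: %d tips, root age %.4g\n",
              length(x$tree$tip.label), x$root_age))
  invisible(x)
}

#' Read a dated ultrametric tree from a Newick file
#'
#' @param path path to a Newick file (branch lengths required, in time
#'   units such as mya).
#' @param tol relative ultrametricity tolerance (see [dated_tree()]).
#' @return A [dated_tree()] object.
#' @export
read_newick_dated <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse Newick file: %s", path)
  dated_tree(tr, tol = tol)
}

#' Write a dated tree as Newick
#'
#' @param dt a [dated_tree()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick_dated <- function(dt, path) {
  stopifnot(inherits(dt, "DatedTree"))
  ape::write.tree(dt$tree, file = path)
  invisible(path)
}

#' Read a tip-to-area assignment table
#'
#' Two-column TSV: `tip_label<TAB>comma-separated area labels`.
#'
#' @param path path to the TSV file.
#' @return Named list mapping tip label to a character vector of areas.
#' @export
read_tip_areas <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "", quote = "")
  if (ncol(d) < 2L) stopf("tip-area file must have two tab-separated columns")
  if (anyDuplicated(d[[1L]])) stopf("duplicate tip in tip-area file")
  stats::setNames(lapply(strsplit(d[[2L]], ","), trimws), d[[1L]])
}
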