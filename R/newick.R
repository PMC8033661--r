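## Newick tree input/output (thin wrappers around ape, with the validation
## the pipeline relies on: unique leaf names, support labels preserved).

#' Read a Newick tree
#'
#' @param path file path; standard Newick with optional branch lengths and
#'   internal-node support labels.
#' @return `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0) || utils::tail(depth, 1) != 0)
    stop("unbalanced parentheses at character offset ",
         if (any(depth < 0)) which(depth < 0)[1] else nchar(txt))
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names")
  tree
}

#' Write a Newick tree
#'
#' Branch lengths written to 6 decimals; internal support labels preserved.
#'
#' @param tree `ape::phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
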