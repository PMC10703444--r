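#' Read a rooted phylogeny from newick text or a file
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be rooted
#' (a basal polytomy is allowed), carry a branch length on every edge unless
#' `default_length` supplies one, and have unique tip labels. The declared
#' branch-length units ("subst/site" or "My") are stored as an attribute and
#' propagated by the downstream machinery.
#'
#' @param x a newick string, or the path of a file holding one tree.
#' @param units declared branch-length units, `"subst/site"` or `"My"`.
#' @param default_length optional length substituted for missing branch
#'   lengths; if `NULL` (default) missing lengths are an error.
#' @return an object of class `phylo` with a `units` attribute.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)
#' @export
read_newick <- function(x, units = c("subst/site", "My"), default_length = NULL) {
  units <- match.arg(units)
  if (length(x) != 1L || !is.character(x)) {
    validation_error("'x' must be a single newick string or file path")
  }
  text <- if (!grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) cladiv_error("malformed newick input", "cladiv_parse_error")
  if (anyDuplicated(tree$tip.label)) {
    validation_error(paste0("duplicate tip labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    if (is.null(default_length)) {
      validation_error("tree has no branch lengths and no default_length was given")
    }
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_length)) {
      validation_error("tree has missing branch lengths and no default_length was given")
    }
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) validation_error("negative branch lengths")
  attr(tree, "units") <- units
  tree
}

# Cheap structural scan so parse failures carry a character offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      cladiv_error(sprintf("malformed newick: unbalanced ')' at character %d", i),
                   "cladiv_parse_error")
    }
  }
  if (depth != 0L) {
    cladiv_error(sprintf(
      "malformed newick: %d unclosed '(' at end of input (length %d)",
      depth, length(chars)), "cladiv_parse_error")
  }
  if (!grepl(";", text)) {
    cladiv_error(sprintf("malformed newick: missing ';' terminator at character %d",
                         length(chars) + 1L), "cladiv_parse_error")
  }
  invisible(TRUE)
}

#' Write a phylogeny as newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Define a crown group by its tip set
#'
#' @param name clade name.
#' @param tips character vector of tip labels spanning the crown group.
#' @return a `clade_definition` object.
#' @export
clade_definition <- function(name, tips) {
  tips <- as.character(tips)
  if (length(tips) == 0) validation_error("clade tip set is empty")
  if (anyDuplicated(tips)) tips <- unique(tips)
  structure(list(name = name, tips = tips), class = "clade_definition")
}

#' Locate the crown node (MRCA) of a clade
#'
#' Resolves the most recent common ancestor of the clade's tip set and
#' exposes the stem branch (the edge from the MRCA's parent). When the MRCA
#' is the root there is no stem branch and the result is flagged.
#'
#' @param tree a `phylo` object.
#' @param clade a [clade_definition()] or a character vector of tip labels.
#' @return a list with elements `node` (ape node id), `stem_edge` (row index
#'   into `tree$edge`, `NA` at the root), `at_root` (logical), and `tips`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' find_crown_node(tr, c("A", "B"))$at_root
#' @export
find_crown_node <- function(tree, clade) {
  if (is.character(clade)) clade <- clade_definition("clade", clade)
  unknown <- setdiff(clade$tips, tree$tip.label)
  if (length(unknown) > 0) {
    validation_error(paste0("unknown tip labels: ", paste(unknown, collapse = ", ")))
  }
  node <- if (length(clade$tips) == 1L) {
    match(clade$tips, tree$tip.label)
  } else {
    ape::getMRCA(tree, clade$tips)
  }
  root <- length(tree$tip.label) + 1L
  at_root <- node == root
  stem_edge <- if (at_root) NA_integer_ else which(tree$edge[, 2L] == node)
  list(node = node, stem_edge = stem_edge, at_root = at_root,
       name = clade$name, tips = clade$tips)
}
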