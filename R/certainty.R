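#' Internode certainty of a reference tree against replicate trees
#'
#' For every non-trivial internal branch of the reference tree, computes the
#' frequency `p1` of its (unrooted) bipartition among replicate trees and the
#' frequency `p2` of the most prevalent bipartition that conflicts with it.
#' With normalized frequencies `p1' = p1/(p1+p2)` and `p2' = p2/(p1+p2)` the
#' internode certainty is the complement of the two-split entropy,
#' `IC = 1 + p1' log2 p1' + p2' log2 p2'` (zero-frequency terms contribute 0),
#' given a negative sign when the conflicting split is the more prevalent one
#' (`p2 > p1`). Trees are compared as unrooted bipartition sets, so replicates
#' that differ from the reference only in rooting do not count as conflict.
#'
#' @param reference a rooted or unrooted `phylo` reference tree.
#' @param replicates a list of `phylo` trees (or a `multiPhylo`) sharing the
#'   reference tip set.
#' @return a `data.frame` of class `split_support` with columns `split`
#'   (pipe-joined tip labels of the bipartition side not holding the first
#'   tip, alphabetically), `p1`, `p2`, and `ic`.
#' @seealso [tree_certainty()]
#' @export
internode_certainty <- function(reference, replicates) {
  if (inherits(replicates, "phylo")) replicates <- list(replicates)
  if (length(replicates) < 1) validation_error("need at least one replicate tree")
  labs <- sort(reference$tip.label)
  for (rep in replicates) {
    if (!setequal(rep$tip.label, labs)) {
      validation_error("replicate tree tip set differs from the reference")
    }
  }
  ref_splits <- tree_splits(reference, labs)
  if (ncol(ref_splits) == 0) {
    validation_error("reference tree has no non-trivial internal branch")
  }
  counts <- new.env(parent = emptyenv())
  all_keys <- character(0)
  all_masks <- list()
  for (rep in replicates) {
    sp <- tree_splits(rep, labs)
    keys <- apply(sp, 2L, split_key, labs = labs)
    for (j in seq_along(keys)) {
      k <- keys[j]
      if (is.null(counts[[k]])) {
        counts[[k]] <- 0L
        all_masks[[k]] <- sp[, j]
      }
      counts[[k]] <- counts[[k]] + 1L
    }
  }
  nrep <- length(replicates)
  keys <- names(all_masks)
  freq <- vapply(keys, function(k) counts[[k]] / nrep, numeric(1))
  mask_mat <- if (length(keys)) do.call(cbind, all_masks) else
    matrix(logical(0), nrow = length(labs), ncol = 0)

  res <- data.frame(split = character(0), p1 = numeric(0), p2 = numeric(0),
                    ic = numeric(0), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ref_splits))) {
    s <- ref_splits[, j]
    key <- split_key(s, labs)
    p1 <- if (!is.null(counts[[key]])) counts[[key]] / nrep else 0
    p2 <- 0
    if (ncol(mask_mat) > 0) {
      conf <- vapply(seq_len(ncol(mask_mat)),
                     function(i) splits_conflict(s, mask_mat[, i]), logical(1))
      if (any(conf)) p2 <- max(freq[conf])
    }
    res <- rbind(res, data.frame(split = key, p1 = p1, p2 = p2,
                                 ic = ic_value(p1, p2), stringsAsFactors = FALSE))
  }
  class(res) <- c("split_support", "data.frame")
  res
}

# IC from the two competing split frequencies.
ic_value <- function(p1, p2) {
  tot <- p1 + p2
  if (tot <= 0) return(0)
  q1 <- p1 / tot
  q2 <- p2 / tot
  h <- 0
  if (q1 > 0) h <- h + q1 * log2(q1)
  if (q2 > 0) h <- h + q2 * log2(q2)
  ic <- 1 + h
  if (p2 > p1) ic <- -ic
  ic
}

# Non-trivial unrooted bipartitions as logical membership masks over the
# sorted tip label set; each column is the side not containing labs[1].
tree_splits <- function(tree, labs) {
  ntip <- length(tree$tip.label)
  n <- length(labs)
  bp <- ape::prop.part(tree)
  idx_of <- match(tree$tip.label, labs)
  masks <- list()
  for (part in bp) {
    m <- rep(FALSE, n)
    m[idx_of[part]] <- TRUE
    if (m[1L]) m <- !m
    sz <- sum(m)
    if (sz < 2L || sz > n - 2L) next
    masks[[split_key(m, labs)]] <- m
  }
  if (length(masks) == 0) {
    return(matrix(logical(0), nrow = n, ncol = 0))
  }
  do.call(cbind, masks)
}

split_key <- function(mask, labs) paste(labs[mask], collapse = "|")

# Two bipartitions (on the same tip set) conflict iff they cannot coexist in
# one tree: all four intersections of their sides are non-empty.
splits_conflict <- function(a, b) {
  any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b)
}

#' Relative tree certainty
#'
#' The arithmetic mean of the internode certainty values over the internal
#' branches of the reference tree, in `[-1, 1]`; 1 means every reference
#' bipartition is recovered in every replicate with no conflict.
#'
#' @param table a `split_support` table from [internode_certainty()].
#' @return a single numeric value.
#' @export
tree_certainty <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    validation_error("empty split support table")
  }
  mean(table$ic)
}

#' Write a split support table as TSV
#' @param table a `split_support` table.
#' @param file output path.
#' @export
write_split_support <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
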