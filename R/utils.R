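#' @useDynLib cladiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim runif rexp rnorm rpois setNames var wilcox.test p.adjust aggregate
#' @importFrom utils read.delim write.table
NULL

cladiv_error <- function(msg, class) {
  stop(structure(class = c(class, "cladiv_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(msg) cladiv_error(msg, "cladiv_validation_error")

#' Deterministic RNG substream seed
#'
#' Hashes an arbitrary set of keys (integers/strings) together with a base
#' seed into a 31-bit integer, so that per-unit random streams (one per
#' gene family and sampler kind, say) do not depend on execution order.
#'
#' @param seed base integer seed.
#' @param ... keys coerced to character and folded into the hash.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (key in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(key)))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Edge arrays (postorder) handed to the C++ kernels.
tree_arrays <- function(tree) {
  if (is.null(tree$edge.length)) {
    validation_error("tree has no branch lengths")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  list(parent = po$edge[, 1L], child = po$edge[, 2L],
       elen = po$edge.length, ntip = ntip,
       nnodes = ntip + po$Nnode, root = ntip + 1L,
       tip_label = po$tip.label, edge = po$edge)
}

# Tip states as an integer vector in tree tip order.
order_tip_states <- function(tree, tips) {
  labs <- tree$tip.label
  if (is.null(names(tips))) {
    if (length(tips) != length(labs)) {
      validation_error("unnamed tip states must match the number of tips")
    }
    return(as.integer(tips))
  }
  miss <- setdiff(labs, names(tips))
  if (length(miss) > 0) {
    validation_error(paste0("missing tip states for: ",
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  as.integer(tips[labs])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
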