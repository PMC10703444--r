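#' Sample a gain/loss history conditional on tip data (stochastic mapping)
#'
#' Draws node states from their joint conditional distribution given the
#' observed presence/absence pattern (backward pruning partials, pre-order
#' forward sampling), then fills in each branch with an endpoint-conditioned
#' path sampled exactly by uniformization. The returned history reproduces
#' the tip data exactly.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tips named 0/1 tip-state vector.
#' @param model a [two_state_model()]; both rates must be positive (apply the
#'   rate floor of [fit_ard()] first).
#' @return a `mapped_history`: list with `node_state` (integer vector over
#'   ape node ids), `events` (data.frame `edge`, `offset`, `to_state`,
#'   ordered within each branch, offsets measured from the parent end), and
#'   `edge` (the edge matrix the `edge` column indexes).
#' @export
sample_conditional_history <- function(tree, tips, model) {
  sample_history(tree, tips, model, conditional = TRUE)
}

#' Sample an unconditional constant-rate null history
#'
#' Simulates the fitted gain/loss process forward from the root prior down
#' every branch by exponential waiting times, ignoring the observed tip
#' states — the constant-rate null against which stochastic-mapping gains
#' are compared.
#'
#' @inheritParams sample_conditional_history
#' @return a `mapped_history` (tip states are whatever the simulation
#'   produces).
#' @export
sample_unconditional_history <- function(tree, model) {
  sample_history(tree, tips = NULL, model, conditional = FALSE)
}

sample_history <- function(tree, tips, model, conditional) {
  if (model$q01 <= 0 || model$q10 <= 0) {
    validation_error("history sampling needs strictly positive rates (use the rate floor)")
  }
  ta <- tree_arrays(tree)
  st <- if (conditional) order_tip_states_po(ta, tree, tips) else
    integer(ta$ntip)
  h <- cpp_sample_history(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                          ta$root, st, model$q01, model$q10,
                          model$root_prior, conditional)
  node_state <- h$node_state
  names(node_state) <- node_names(tree, ta)
  events <- data.frame(edge = h$ev_edge, offset = h$ev_time,
                       to_state = h$ev_state)
  events <- events[order(events$edge, events$offset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(node_state = node_state, events = events,
                 edge = ta$edge, edge_length = ta$elen,
                 conditional = conditional),
            class = "mapped_history")
}

# tips reordered to the postorder tree's tip indexing (identical to the
# original tree's: reorder.phylo preserves node numbering)
order_tip_states_po <- function(ta, tree, tips) order_tip_states(tree, tips)

node_names <- function(tree, ta) {
  c(tree$tip.label, paste0("n", (ta$ntip + 1L):ta$nnodes))
}

#' Gain indicator of a history at a crown node
#'
#' Default (`mode = "net"`): 1 iff the crown node's parent is in state 0 and
#' the crown node in state 1, i.e. a net gain across the stem branch.
#' `mode = "events"` instead counts 0 -> 1 transition events on the stem
#' branch, which can exceed 1 and can be positive even when the net change
#' is absent.
#'
#' @param history a `mapped_history`.
#' @param crown crown node id (ape numbering) or the result of
#'   [find_crown_node()].
#' @param mode `"net"` or `"events"`.
#' @return integer gain indicator (net mode) or event count (events mode).
#' @export
gain_indicator <- function(history, crown, mode = c("net", "events")) {
  mode <- match.arg(mode)
  node <- if (is.list(crown)) crown$node else crown
  stem <- which(history$edge[, 2L] == node)
  if (length(stem) == 0) {
    validation_error("crown node is the root: no stem branch exists (configure a root-gain policy upstream)")
  }
  parent <- history$edge[stem, 1L]
  if (mode == "net") {
    as.integer(history$node_state[parent] == 0L && history$node_state[node] == 1L)
  } else {
    ev <- history$events
    sum(ev$edge == stem & ev$to_state == 1L)
  }
}

#' Replicate gain tables for the mapped and null samplers
#'
#' For every family, draws `n` conditional (stochastic-mapping) histories and
#' `n` unconditional (constant-rate null) histories under that family's
#' fitted model and reduces each to a crown-node gain indicator. Per-family
#' RNG substreams are derived from `(seed, family id, sampler kind)`, so the
#' tables do not depend on family execution order. Families whose sampling
#' fails are excluded from both tables symmetrically and recorded in the
#' `failed` attribute.
#'
#' @param tree rooted `phylo`.
#' @param mat 0/1 presence/absence matrix (families x taxa).
#' @param models named list of fitted `two_state_model`s (see
#'   [fit_ard_many()]), one per matrix row.
#' @param crown crown node id or [find_crown_node()] result; must not be the
#'   root.
#' @param n replicates per sampler (default 100).
#' @param seed integer base seed.
#' @param mode gain semantics, `"net"` (default) or `"events"`.
#' @return list with `mapped` and `null` gain tables (data.frames `sampler`,
#'   `replicate`, `family_id`, `gain`), each `n * nfamilies` rows.
#' @export
run_replicates <- function(tree, mat, models, crown, n = 100, seed = 1,
                           mode = c("net", "events")) {
  mode <- match.arg(mode)
  node <- if (is.list(crown)) crown$node else crown
  ta <- tree_arrays(tree)
  stem <- which(ta$child == node)
  if (length(stem) == 0) {
    validation_error("crown node is the root: no stem branch exists")
  }
  fams <- rownames(mat)
  miss <- setdiff(fams, names(models))
  if (length(miss) > 0) {
    validation_error(paste0("no fitted model for families: ",
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  imode <- if (mode == "net") 0L else 1L
  res_mapped <- vector("list", length(fams))
  res_null <- vector("list", length(fams))
  failed <- character(0)
  for (i in seq_along(fams)) {
    f <- fams[i]
    m <- models[[f]]
    st <- order_tip_states(tree, setNames(mat[f, tree$tip.label], tree$tip.label))
    g <- tryCatch({
      set.seed(substream_seed(seed, f, "mapped"))
      gm <- cpp_sample_gains(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                             ta$root, st, m$q01, m$q10, m$root_prior,
                             TRUE, n, stem, imode)
      set.seed(substream_seed(seed, f, "null"))
      gn <- cpp_sample_gains(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                             ta$root, st, m$q01, m$q10, m$root_prior,
                             FALSE, n, stem, imode)
      list(gm = gm, gn = gn)
    }, error = function(e) NULL)
    if (is.null(g)) {
      failed <- c(failed, f)
      next
    }
    res_mapped[[i]] <- data.frame(sampler = "mapped", replicate = seq_len(n),
                                  family_id = f, gain = g$gm,
                                  stringsAsFactors = FALSE)
    res_null[[i]] <- data.frame(sampler = "null", replicate = seq_len(n),
                                family_id = f, gain = g$gn,
                                stringsAsFactors = FALSE)
  }
  keep <- !vapply(res_mapped, is.null, logical(1))
  mapped <- do.call(rbind, res_mapped[keep])
  null <- do.call(rbind, res_null[keep])
  rownames(mapped) <- rownames(null) <- NULL
  out <- list(mapped = mapped, null = null)
  attr(out, "failed") <- failed
  out
}

#' Write a gain table as TSV
#' @param gains data.frame from [run_replicates()] (`mapped` or `null`).
#' @param file output path.
#' @export
write_gain_table <- function(gains, file) {
  write.table(gains, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
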