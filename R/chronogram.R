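#' Define a set of node-age calibrations
#'
#' Each calibration selects a node by the tip set whose MRCA it is and
#' constrains that node's age (in My) by a minimum, a maximum, or both —
#' the form geological anchors such as the Great Oxidation Event take.
#'
#' @param tips list of character vectors (one tip set per calibration).
#' @param min_age numeric vector of minimum ages in My (`NA` for none).
#' @param max_age numeric vector of maximum ages in My (`NA` for none).
#' @param label optional character labels.
#' @return data.frame of class `calibration_set`.
#' @export
calibration_set <- function(tips, min_age, max_age, label = NULL) {
  if (!is.list(tips)) tips <- list(tips)
  n <- length(tips)
  min_age <- rep_len(as.numeric(min_age), n)
  max_age <- rep_len(as.numeric(max_age), n)
  if (is.null(label)) label <- paste0("cal", seq_len(n))
  bad <- which(!is.na(min_age) & !is.na(max_age) & min_age > max_age)
  if (length(bad) > 0) {
    validation_error(paste0("calibration min > max: ", paste(label[bad], collapse = ", ")))
  }
  if (any(c(min_age, max_age) < 0, na.rm = TRUE)) {
    validation_error("calibration ages must be >= 0")
  }
  out <- data.frame(label = label, min_age = min_age, max_age = max_age,
                    stringsAsFactors = FALSE)
  out$tips <- tips
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Read calibrations from TSV (clade_tips comma-separated, min_my, max_my, label)
#' @param file TSV path.
#' @return a `calibration_set`.
#' @export
read_calibrations <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  calibration_set(tips = strsplit(tab$clade_tips, ","),
                  min_age = tab$min_my, max_age = tab$max_my,
                  label = tab$label)
}

#' Reduce a calibration set to its minimum-evidence subset
#'
#' Keeps only calibrations carrying a finite minimum age (the root bounds and
#' fossil/geochemical minima), dropping maximum-only constraints — the
#' "priors set 2" sensitivity configuration that removes oxygen-derived
#' ceilings from strictly aerobic clades.
#'
#' @param calibrations a [calibration_set()].
#' @return the filtered `calibration_set`.
#' @export
priors_set2 <- function(calibrations) {
  out <- calibrations[!is.na(calibrations$min_age), , drop = FALSE]
  if (nrow(out) == 0) validation_error("no calibration with a finite minimum remains")
  class(out) <- class(calibrations)
  out
}

resolve_calibrations <- function(tree, calibrations) {
  nodes <- vapply(seq_len(nrow(calibrations)), function(i) {
    find_crown_node(tree, clade_definition(calibrations$label[i],
                                           calibrations$tips[[i]]))$node
  }, integer(1))
  ntip <- length(tree$tip.label)
  if (any(nodes <= ntip)) {
    validation_error("calibrations must select internal nodes (tip ages are fixed at 0)")
  }
  data.frame(label = calibrations$label, node = nodes,
             min_age = calibrations$min_age, max_age = calibrations$max_age,
             stringsAsFactors = FALSE)
}

# Static tree/count context shared by the PL objective, fit and CV.
chrono_setup <- function(tree, sites) {
  if (sites <= 0) validation_error("'sites' (alignment length) must be positive")
  ta <- tree_arrays(tree)
  ne <- length(ta$elen)
  x <- pmax(round(ta$elen * sites), 0)
  parent_edge <- match(ta$parent, ta$child)     # NA when parent is the root
  root_children <- which(is.na(parent_edge))
  internal <- (ta$ntip + 1L):ta$nnodes
  # reversed postorder edges are a valid preorder: each node appears as a
  # child only after its parent already has
  pre_internal <- setdiff(unique(c(ta$root, rev(ta$child))), seq_len(ta$ntip))
  list(ta = ta, ne = ne, x = x, parent_edge = parent_edge,
       root_children = root_children, internal = internal,
       pre_internal = pre_internal, sites = sites)
}

pl_penalty <- function(rates, ctx) {
  pe <- ctx$parent_edge
  has_parent <- !is.na(pe)
  phi <- sum((rates[has_parent] - rates[pe[has_parent]])^2)
  rc <- rates[ctx$root_children]
  if (length(rc) > 1) phi <- phi + var(rc)
  phi
}

# Poisson terms with `rates` on the count scale (subst/My over the whole
# alignment, i.e. per-site rate times sites)
pl_poisson <- function(x, rates, dur, weights = NULL) {
  t_eff <- pmax(dur, 1e-12)
  ll <- x * log(rates * t_eff) - rates * dur - lgamma(x + 1)
  ll[x == 0] <- (-rates * dur)[x == 0]          # 0*log(0) -> 0
  if (!is.null(weights)) ll <- ll * weights
  sum(ll)
}

#' Penalized-likelihood dating objective
#'
#' The branch-wise Poisson log-likelihood of the implied substitution counts
#' minus `lambda` times the rate-smoothness penalty:
#' `sum_i [x_i log(m_i) - m_i - log(x_i!)] - lambda * Phi`, where
#' `x_i = round(b_i * sites)` is the implied substitution count,
#' `m_i = r_i t_i sites` its Poisson mean under the candidate ages (`t_i` the
#' implied duration, `r_i` in substitutions/site/My), and `Phi` sums squared
#' differences between each branch's count-scale rate (`r_i sites`) and its
#' parent branch's, plus the variance of the root's child-branch rates.
#' Candidate ages violating parent > child ordering yield `-Inf` (an
#' infeasibility marker, not an error).
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param ages numeric vector of node ages in My indexed by ape node id
#'   (length `ntip + Nnode`; tip entries 0).
#' @param rates positive per-branch rates (subst/site/My) in `tree$edge`
#'   row order.
#' @param lambda smoothing weight (>= 0).
#' @param sites alignment length used to convert branch lengths to counts.
#' @return the penalized log-likelihood (or `-Inf` when infeasible).
#' @export
pl_objective <- function(tree, ages, rates, lambda, sites) {
  ctx <- chrono_setup(tree, sites)
  # reorder user-supplied rates (original edge order) to postorder
  key_po <- paste(ctx$ta$parent, ctx$ta$child)
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  r_po <- rates[match(key_po, key_in)]
  if (any(!is.finite(r_po)) || any(r_po <= 0)) {
    validation_error("rates must be positive, one per edge of the tree")
  }
  dur <- ages[ctx$ta$parent] - ages[ctx$ta$child]
  if (any(dur < 0) || any(ages[seq_len(ctx$ta$ntip)] != 0)) return(-Inf)
  r_cnt <- r_po * sites
  pl_poisson(ctx$x, r_cnt, dur) - lambda * pl_penalty(r_cnt, ctx)
}

# Feasible-by-construction age map: pre-order proportional placement of each
# internal node between its effective floor (its own and its descendants'
# minimum calibrations) and the smaller of its parent's age and its ceiling.
make_age_map <- function(ctx, cal_resolved, root_cap_mult = 5) {
  ta <- ctx$ta
  nn <- ta$nnodes
  node_min <- rep(0, nn); node_max <- rep(Inf, nn)
  if (nrow(cal_resolved) > 0) {
    for (i in seq_len(nrow(cal_resolved))) {
      nd <- cal_resolved$node[i]
      if (!is.na(cal_resolved$min_age[i]))
        node_min[nd] <- max(node_min[nd], cal_resolved$min_age[i])
      if (!is.na(cal_resolved$max_age[i]))
        node_max[nd] <- min(node_max[nd], cal_resolved$max_age[i])
    }
  }
  minfloor <- node_min
  for (e in seq_len(ctx$ne)) {                  # postorder: child first
    p <- ta$parent[e]; c <- ta$child[e]
    minfloor[p] <- max(minfloor[p], minfloor[c])
  }
  maxceil <- node_max
  for (e in rev(seq_len(ctx$ne))) {             # preorder
    p <- ta$parent[e]; c <- ta$child[e]
    maxceil[c] <- min(maxceil[c], maxceil[p])
  }
  viol <- which(minfloor > maxceil + 1e-9)
  if (length(viol) > 0) {
    validation_error(sprintf(
      "infeasible calibrations: node %d requires age >= %g but is capped at %g by an ancestor",
      viol[1], minfloor[viol[1]], maxceil[viol[1]]))
  }
  root <- ta$root
  if (!is.finite(maxceil[root])) {
    finite_vals <- c(node_min[is.finite(node_min) & node_min > 0],
                     node_max[is.finite(node_max)])
    if (length(finite_vals) == 0) {
      validation_error("at least one finite calibration bound is required")
    }
    maxceil[root] <- root_cap_mult * max(finite_vals, minfloor[root])
  }
  pre <- ctx$pre_internal
  ages_from_p <- function(p) {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    ages <- numeric(nn)
    for (k in seq_along(pre)) {
      v <- pre[k]
      lo <- minfloor[v]
      hi <- if (v == root) maxceil[root] else {
        pa <- ta$parent[match(v, ta$child)]
        min(ages[pa], maxceil[v])
      }
      ages[v] <- if (hi <= lo) lo else lo + p[k] * (hi - lo)
    }
    ages
  }
  p_from_ages <- function(target) {
    p <- numeric(length(pre))
    ages <- numeric(nn)
    for (k in seq_along(pre)) {
      v <- pre[k]
      lo <- minfloor[v]
      hi <- if (v == root) maxceil[root] else {
        pa <- ta$parent[match(v, ta$child)]
        min(ages[pa], maxceil[v])
      }
      pk <- if (hi <= lo) 0.5 else (target[v] - lo) / (hi - lo)
      p[k] <- pmin(pmax(pk, 0.02), 0.98)
      ages[v] <- if (hi <= lo) lo else lo + p[k] * (hi - lo)
    }
    p
  }
  list(ages_from_p = ages_from_p, p_from_ages = p_from_ages,
       minfloor = minfloor, maxceil = maxceil, pre = pre, n_par = length(pre))
}

#' Fit a penalized-likelihood chronogram
#'
#' Converts a substitutions/site tree into node ages (My) and per-branch
#' rates by maximizing [pl_objective()] under min/max age calibrations.
#' Feasibility is built into the parameterization: internal ages are placed
#' pre-order as proportions between each node's effective floor (descendant
#' minima) and ceiling (parent age / ancestor maxima), so every iterate — and
#' the returned chronogram — satisfies all calibrations and parent > child
#' ordering. Rates are optimized in log space; three deterministic starts
#' guard against local optima.
#'
#' @param tree rooted `phylo`, branch lengths in substitutions/site.
#' @param calibrations a [calibration_set()]; at least one finite bound.
#' @param lambda smoothing weight.
#' @param sites alignment length (converts branch lengths to counts).
#' @param clock if `TRUE`, a single rate is shared by all branches (the
#'   strict-clock limit).
#' @param weights optional per-edge 0/1 weights on the Poisson terms
#'   (postorder edge order; used by cross-validation holdouts).
#' @param control optional list: `maxit` (default 2000), `n_starts` (3).
#' @return a `chronogram` object: list with `ages` (named, My), `rates`
#'   (subst/site/My per postorder edge), `edge`, `lambda`, `objective`, `compliance`
#'   (per-calibration flags), `tree_my` (a `phylo` with My branch lengths),
#'   `convergence`.
#' @export
fit_chronogram <- function(tree, calibrations, lambda, sites, clock = FALSE,
                           weights = NULL, control = list()) {
  ctx <- chrono_setup(tree, sites)
  cal <- resolve_calibrations(tree, calibrations)
  amap <- make_age_map(ctx, cal)
  ta <- ctx$ta
  np <- amap$n_par
  nr <- if (clock) 1L else ctx$ne
  maxit <- control$maxit %||% 2000
  n_starts <- control$n_starts %||% 3
  polish <- control$polish %||% TRUE

  objective <- function(par) {
    ages <- amap$ages_from_p(par[seq_len(np)])
    r <- exp(par[np + seq_len(nr)])
    if (clock) r <- rep(r, ctx$ne)
    dur <- ages[ta$parent] - ages[ta$child]
    val <- pl_poisson(ctx$x, r, dur, weights)
    if (!clock && lambda > 0) val <- val - lambda * pl_penalty(r, ctx)
    if (!is.finite(val)) return(1e12)
    -val
  }

  # initial ages: substitution depth scaled into the feasible window
  depth <- numeric(ta$nnodes)
  for (e in seq_len(ctx$ne)) {
    p <- ta$parent[e]; c <- ta$child[e]
    depth[p] <- max(depth[p], depth[c] + ta$elen[e])
  }
  root_guess <- mean(c(amap$minfloor[ta$root],
                       min(amap$maxceil[ta$root], 4 * amap$minfloor[ta$root] + 1)))
  init_ages <- depth / max(depth[ta$root], 1e-12) * root_guess
  p0 <- amap$p_from_ages(init_ages)
  total_dur <- max(sum(pmax(init_ages[ta$parent] - init_ages[ta$child], 1e-8)), 1e-8)
  r0 <- log(rep(max(sum(ctx$x) / total_dur / ctx$ne * 2, 1e-10), nr))
  starts <- list(c(p0, r0))
  if (n_starts >= 2) starts[[2]] <- c(0.5 * p0 + 0.25, r0 + 0.7)
  if (n_starts >= 3) starts[[3]] <- c(0.5 * p0 + 0.1, r0 - 0.7)
  # heavily smoothed fits sit on an ill-conditioned ridge; seed them at the
  # strict-clock solution, whose neighbourhood contains the optimum
  if (!clock && isTRUE(control$clock_start %||% (lambda >= 100))) {
    cfit <- fit_chronogram(tree, calibrations, lambda = 0, sites = sites,
                           clock = TRUE, weights = weights,
                           control = list(n_starts = 1, polish = FALSE,
                                          maxit = maxit, clock_start = FALSE))
    # near-clock surface is unimodal around this start; extra starts only
    # crawl the ill-conditioned penalty region
    starts <- list(c(amap$p_from_ages(unname(cfit$ages)),
                     rep(log(cfit$rates[1] * sites), nr)))
  }

  lower <- c(rep(1e-7, np), rep(log(1e-12), nr))
  upper <- c(rep(1 - 1e-7, np), rep(log(1e6), nr))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s0, lower), upper), objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e5,
                           ndeps = rep(1e-7, np + nr))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (polish) {   # restart from the incumbent for tighter convergence
      fit2 <- tryCatch(
        optim(fit$par, objective, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = maxit, factr = 1e1,
                             ndeps = rep(1e-8, np + nr))),
        error = function(e) fit)
      if (fit2$value <= fit$value) fit <- fit2
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    cladiv_error("chronogram optimization failed from every start", "cladiv_optim_error")
  }
  ages <- amap$ages_from_p(best$par[seq_len(np)])
  rates <- exp(best$par[np + seq_len(nr)]) / sites   # back to subst/site/My
  if (clock) rates <- rep(rates, ctx$ne)
  names(ages) <- node_names(tree, ta)
  compliance <- data.frame(
    label = cal$label, node = cal$node, age = ages[cal$node],
    min_age = cal$min_age, max_age = cal$max_age,
    ok = (is.na(cal$min_age) | ages[cal$node] >= cal$min_age - 1e-6) &
         (is.na(cal$max_age) | ages[cal$node] <= cal$max_age + 1e-6),
    stringsAsFactors = FALSE)
  tree_my <- ape::reorder.phylo(tree, "postorder")
  tree_my$edge.length <- ages[ta$parent] - ages[ta$child]
  structure(list(ages = ages, rates = rates, edge = ta$edge,
                 lambda = lambda, objective = -best$value,
                 compliance = compliance, tree_my = tree_my,
                 convergence = best$convergence, clock = clock,
                 sites = sites),
            class = "chronogram")
}

#' Cross-validate the smoothing parameter
#'
#' For each smoothing value, terminal branches are held out (each one in turn
#' for `scheme = "cv"`; random subsets for `scheme = "randomcv"`), the
#' chronogram is refit without the held-out branches' substitution counts,
#' and each hidden count is predicted as the parent-side rate times the
#' fitted duration of the hidden branch. Prediction error is the chi-squared
#' sum `(x_obs - x_pred)^2 / x_pred`; the chosen smoothing value minimizes it
#' on the grid.
#'
#' @inheritParams fit_chronogram
#' @param lambda_grid non-empty numeric grid of smoothing values.
#' @param scheme `"cv"` (leave one terminal out) or `"randomcv"`.
#' @param seed seed for the random holdout subsets.
#' @param n_random number of random subsets (randomcv).
#' @param holdout_frac fraction of terminals per random subset.
#' @return a `cv_report`: data.frame `lambda`, `error` with attributes
#'   `chosen` and `scheme`.
#' @export
cross_validate <- function(tree, calibrations, lambda_grid,
                           scheme = c("cv", "randomcv"), sites, seed = 1,
                           n_random = 5, holdout_frac = 0.2) {
  scheme <- match.arg(scheme)
  if (length(lambda_grid) == 0) validation_error("empty lambda grid")
  ctx <- chrono_setup(tree, sites)
  if (ctx$ta$ntip < 4) validation_error("cross-validation needs at least 4 tips")
  terminal <- which(ctx$ta$child <= ctx$ta$ntip)
  holdouts <- if (scheme == "cv") {
    as.list(terminal)
  } else {
    k <- max(1L, round(holdout_frac * length(terminal)))
    set.seed(substream_seed(seed, "randomcv"))
    lapply(seq_len(n_random), function(i) sample(terminal, k))
  }
  errors <- vapply(lambda_grid, function(lam) {
    err <- 0
    for (H in holdouts) {
      w <- rep(1, ctx$ne); w[H] <- 0
      fit <- fit_chronogram(tree, calibrations, lambda = lam, sites = sites,
                            weights = w,
                            control = list(n_starts = 1, polish = FALSE,
                                           maxit = 500))
      dur <- fit$ages[ctx$ta$parent] - fit$ages[ctx$ta$child]
      for (e in H) {
        pe <- ctx$parent_edge[e]
        r_side <- if (!is.na(pe)) fit$rates[pe] else
          mean(fit$rates[setdiff(ctx$root_children, e)])
        x_pred <- r_side * sites * dur[e]
        err <- err + (ctx$x[e] - x_pred)^2 / max(x_pred, 1e-8)
      }
    }
    err
  }, numeric(1))
  report <- data.frame(lambda = lambda_grid, error = errors)
  attr(report, "chosen") <- lambda_grid[which.min(errors)]
  attr(report, "scheme") <- scheme
  class(report) <- c("cv_report", "data.frame")
  report
}

#' Compare full calibrations against the minimum-evidence subset
#'
#' Fits the chronogram under the full calibration set and under
#' [priors_set2()] and reports per-node age differences — a sensitivity
#' harness for the influence of maximum-only (oxygen-ceiling) calibrations.
#'
#' @inheritParams fit_chronogram
#' @return data.frame `node`, `age_set1`, `age_set2`, `delta`.
#' @export
compare_prior_sets <- function(tree, calibrations, lambda, sites) {
  f1 <- fit_chronogram(tree, calibrations, lambda, sites)
  f2 <- fit_chronogram(tree, priors_set2(calibrations), lambda, sites)
  data.frame(node = seq_along(f1$ages), age_set1 = unname(f1$ages),
             age_set2 = unname(f2$ages),
             delta = unname(f2$ages - f1$ages))
}

#' Write chronogram outputs (newick in My + node-age TSV)
#' @param chrono a `chronogram`.
#' @param newick_file,ages_file output paths (either may be `NULL`).
#' @export
write_chronogram <- function(chrono, newick_file = NULL, ages_file = NULL) {
  if (!is.null(newick_file)) write_newick(chrono$tree_my, newick_file)
  if (!is.null(ages_file)) {
    write.table(data.frame(node = names(chrono$ages), age_my = unname(chrono$ages)),
                ages_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(chrono)
}
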