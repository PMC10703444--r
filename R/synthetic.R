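#' Specification of a synthetic analysis bundle
#'
#' Collects every knob of the synthetic-data generator: a pure-birth tree, a
#' presence/absence matrix of families evolving by gain/loss CTMCs with one
#' focal crown node carrying planted stem gains in one functional category,
#' noisy per-protein annotations resolved by majority rule, and (for dating
#' fixtures) true node ages in My with geological-style calibrations. The
#' defaults are the conditions the package's validation suite exercises:
#' 64 tips, 300 families of which 30 are planted with stem-gain probability
#' 0.8, 10 categories, per-family rates log-uniform on `[0.01, 0.3]` per unit
#' branch length on a depth-1 tree, and 5% annotation noise.
#'
#' @param seed integer; fixes every downstream draw.
#' @param n_tips number of tips (>= 4).
#' @param n_families number of gene families.
#' @param n_categories number of functional categories (1 planted + rest
#'   background).
#' @param n_planted number of planted families.
#' @param planted_gain_prob probability a planted family truly gains on the
#'   focal stem branch.
#' @param planted_category label of the planted category.
#' @param focal_fraction target fraction of tips inside the focal clade.
#' @param rate_range log-uniform bounds for per-family (q01, q10).
#' @param annotation_noise fraction of proteins mislabeled.
#' @param paralog_mult expected extra proteins per present taxon (stresses
#'   majority rule; 0 = one protein per present taxon).
#' @param depth trait-tree root depth (branch-length units of the CTMC).
#' @param depth_my root age (My) of dating fixtures.
#' @param subst_rate true substitution rate (subst/site/My) of dating
#'   fixtures.
#' @param sites alignment length for count conversion.
#' @param clock `"strict"` or `"lognormal"` per-branch rate multipliers.
#' @param clock_sigma lognormal sigma (0 reduces to the strict clock).
#' @param noiseless if `TRUE`, dating-fixture node ages are snapped to the
#'   grid on which substitution counts are exact integers, so the true ages
#'   are exactly recoverable.
#' @param newick optional fixed topology (newick string) instead of the
#'   pure-birth draw.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1, n_tips = 64, n_families = 300,
                           n_categories = 10, n_planted = 30,
                           planted_gain_prob = 0.8,
                           planted_category = "planted",
                           focal_fraction = 0.25,
                           rate_range = c(0.01, 0.3),
                           annotation_noise = 0.05,
                           paralog_mult = 0,
                           depth = 1,
                           depth_my = 4000, subst_rate = 5e-5, sites = 10000,
                           clock = c("strict", "lognormal"), clock_sigma = 0.3,
                           noiseless = FALSE, newick = NULL) {
  clock <- match.arg(clock)
  stopifnot(n_tips >= 4, n_families >= 1, n_planted >= 0,
            n_planted <= n_families, n_categories >= 2,
            planted_gain_prob >= 0, planted_gain_prob <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            rate_range[1] > 0, rate_range[2] >= rate_range[1])
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate the study tree
#'
#' Pure-birth topology (or the fixed newick in the spec), rescaled so the
#' root sits at `spec$depth` (trait mode) or `spec$depth_my` (dating mode).
#' In dating mode branch lengths are true duration times a strict or
#' lognormal per-branch rate, and the true node ages are attached as the
#' `true_ages` attribute for oracle use. The focal crown clade — the internal
#' node whose tip count is closest to `focal_fraction * n_tips` — is attached
#' as `focal_tips`.
#'
#' @param spec a [synthetic_spec()].
#' @param dating if `TRUE`, produce the dating fixture.
#' @return a `phylo` with attributes `focal_tips`, `units`, and (dating)
#'   `true_ages`, `true_rates`.
#' @export
simulate_tree <- function(spec, dating = FALSE) {
  # one topology underlies both unit systems (trait depth vs My), so clades
  # defined on the trait tree resolve identically on the dating fixture
  set.seed(substream_seed(spec$seed, "tree"))
  tree <- if (!is.null(spec$newick)) {
    read_newick(spec$newick)
  } else {
    tr <- ape::rphylo(spec$n_tips, birth = 1, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(spec$n_tips))
    tr
  }
  ntip <- length(tree$tip.label)
  nnodes <- ntip + tree$Nnode
  depth_target <- if (dating) spec$depth_my else spec$depth
  dist_root <- ape::node.depth.edgelength(tree)
  ages <- max(dist_root[seq_len(ntip)]) - dist_root
  ages <- ages / ages[ntip + 1L] * depth_target
  ages[seq_len(ntip)] <- 0
  if (dating && spec$noiseless) {
    grid <- 1 / (spec$subst_rate * spec$sites)
    ages <- round(ages / grid) * grid
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in seq_len(nrow(po$edge))) {  # bump parents above children
      p <- po$edge[e, 1]; c <- po$edge[e, 2]
      if (ages[p] <= ages[c]) ages[p] <- ages[c] + grid
    }
  }
  dur <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (dating) {
    mult <- if (spec$clock == "lognormal" && spec$clock_sigma > 0) {
      exp(rnorm(nrow(tree$edge), -spec$clock_sigma^2 / 2, spec$clock_sigma))
    } else rep(1, nrow(tree$edge))
    rates <- spec$subst_rate * mult
    tree$edge.length <- dur * rates
    attr(tree, "true_ages") <- ages
    attr(tree, "true_rates") <- rates
    attr(tree, "units") <- "subst/site"
  } else {
    tree$edge.length <- dur
    attr(tree, "units") <- "subst/site"
  }
  sizes <- vapply((ntip + 1L):nnodes, function(v)
    length(tips_under(tree, v)), integer(1))
  target <- round(spec$focal_fraction * ntip)
  cand <- (ntip + 1L):nnodes
  cand <- cand[cand != ntip + 1L]              # exclude the root
  sz <- sizes[cand - ntip]
  focal <- cand[which.min(abs(sz - target))]
  attr(tree, "focal_tips") <- tips_under(tree, focal)
  tree
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[ape::prop.part(tree)[[node - ntip]]]
}

#' Focal clade of a simulated tree
#' @param tree output of [simulate_tree()].
#' @return a [clade_definition()].
#' @export
focal_clade <- function(tree) {
  tips <- attr(tree, "focal_tips")
  if (is.null(tips)) validation_error("tree carries no focal clade attribute")
  clade_definition("focal", tips)
}

#' Simulate gene families with a planted crown-node gain signal
#'
#' Background families evolve by the unconditional gain/loss CTMC with
#' per-family rates drawn log-uniform from `spec$rate_range`. Planted
#' families are forced to state 0 at the focal crown's parent node and to
#' state 1 at the crown with probability `spec$planted_gain_prob`, the rest
#' of the tree evolving forward from those endpoints — the planting acts on
#' the true history, not on tip patterns. All-absent tip patterns are
#' resimulated (with a warning counter in the truth table attributes).
#'
#' @param spec a [synthetic_spec()].
#' @param tree trait tree from [simulate_tree()].
#' @return list with `matrix` (0/1 families x taxa), `truth` (data.frame
#'   `family_id`, `q01`, `q10`, `planted`, `stem_gain`), `node_states`
#'   (families x nodes integer matrix of true node states), and `crown`
#'   (the focal [find_crown_node()] result).
#' @export
simulate_families <- function(spec, tree) {
  crown <- find_crown_node(tree, focal_clade(tree))
  if (crown$at_root) validation_error("focal crown node must not be the root")
  ta <- tree_arrays(tree)
  stem_parent <- ta$parent[which(ta$child == crown$node)]
  set.seed(substream_seed(spec$seed, "families"))
  nfam <- spec$n_families
  fams <- sprintf("F%04d", seq_len(nfam))
  lr <- log(spec$rate_range)
  mat <- matrix(0L, nfam, ta$ntip, dimnames = list(fams, tree$tip.label))
  states <- matrix(0L, nfam, ta$nnodes, dimnames = list(fams, NULL))
  q01 <- q10 <- numeric(nfam)
  planted <- seq_len(nfam) <= spec$n_planted
  stem_gain <- logical(nfam)
  n_regen <- 0L
  for (i in seq_len(nfam)) {
    q01[i] <- exp(runif(1, lr[1], lr[2]))
    q10[i] <- exp(runif(1, lr[1], lr[2]))
    force_gain <- planted[i] && (runif(1) < spec$planted_gain_prob)
    for (try in seq_len(50)) {
      st <- sim_states_forced(ta, q01[i], q10[i],
                              forced = if (planted[i]) {
                                f <- c(0L); names(f) <- stem_parent
                                if (force_gain) { f <- c(f, 1L); names(f) <- c(stem_parent, crown$node) }
                                f
                              } else NULL)
      if (any(st[seq_len(ta$ntip)] == 1L)) break
      n_regen <- n_regen + 1L
      if (try == 50) warning("family ", fams[i], " stayed all-absent after 50 draws")
    }
    states[i, ] <- st
    mat[i, ] <- st[seq_len(ta$ntip)]
    stem_gain[i] <- st[stem_parent] == 0L && st[crown$node] == 1L
  }
  truth <- data.frame(family_id = fams, q01 = q01, q10 = q10,
                      planted = planted, stem_gain = stem_gain,
                      stringsAsFactors = FALSE)
  attr(truth, "n_regenerated") <- n_regen
  list(matrix = mat, truth = truth, node_states = states, crown = crown)
}

# Forward node-state simulation down the tree with optional forced states
# (named integer vector: node id -> state).
sim_states_forced <- function(ta, q01, q10, forced = NULL) {
  st <- integer(ta$nnodes)
  pick <- function(node, w0, w1) {
    if (!is.null(forced)) {
      f <- forced[as.character(node)]
      if (!is.na(f)) return(as.integer(f))
    }
    if (runif(1) * (w0 + w1) < w0) 0L else 1L
  }
  st[ta$root] <- pick(ta$root, 0.5, 0.5)
  q <- q01 + q10
  pi1 <- q01 / q; pi0 <- q10 / q
  ne <- length(ta$elen)
  for (e in ne:1) {                             # preorder
    a <- st[ta$parent[e]]
    el <- exp(-q * ta$elen[e])
    if (a == 0L) {
      p1 <- pi1 * (1 - el)
      st[ta$child[e]] <- pick(ta$child[e], 1 - p1, p1)
    } else {
      p0 <- pi0 * (1 - el)
      st[ta$child[e]] <- pick(ta$child[e], p0, 1 - p0)
    }
  }
  st
}

#' Emulate ortholog membership, noisy annotations, and the category map
#'
#' One protein per (family, present taxon) — plus optional paralogs — each
#' annotated with the family's true KO with probability
#' `1 - spec$annotation_noise` and a random other KO otherwise. Scores are
#' drawn so the true KO wins the majority vote in expectation, and a fraction
#' of proteins carry an extra lower-scored decoy row to exercise the
#' best-score filter. Planted families map to the planted category,
#' background families round-robin over the background categories.
#'
#' @param spec a [synthetic_spec()].
#' @param mat presence/absence matrix from [simulate_families()].
#' @return list with `membership`, `annotations`, `ko_category`, and
#'   `true_ko` (data.frame `family_id`, `ko_id`).
#' @export
emulate_annotation_table <- function(spec, mat) {
  set.seed(substream_seed(spec$seed, "annotation"))
  fams <- rownames(mat)
  kos <- sprintf("K%05d", seq_along(fams))
  names(kos) <- fams
  n_bg <- spec$n_categories - 1L
  planted <- seq_along(fams) <= spec$n_planted
  cats <- ifelse(planted, spec$planted_category,
                 sprintf("BG%02d", (seq_along(fams) - spec$n_planted - 1L) %% n_bg + 1L))
  ko_category <- data.frame(ko_id = kos, category_id = cats,
                            stringsAsFactors = FALSE, row.names = NULL)
  mrows <- list(); arows <- list()
  k <- 0L
  for (i in seq_along(fams)) {
    taxa <- colnames(mat)[mat[i, ] == 1L]
    for (tx in taxa) {
      n_prot <- 1L + (if (spec$paralog_mult > 0) rpois(1, spec$paralog_mult) else 0L)
      for (j in seq_len(n_prot)) {
        k <- k + 1L
        pid <- paste0(fams[i], "_", tx, if (j > 1) paste0(".", j) else "")
        mrows[[k]] <- data.frame(cluster_id = fams[i], taxon_id = tx,
                                 protein_id = pid, stringsAsFactors = FALSE)
        ko <- if (runif(1) < spec$annotation_noise && length(fams) > 1) {
          sample(kos[-i], 1)
        } else kos[i]
        score <- round(runif(1, 80, 150), 1)
        ann <- data.frame(protein_id = pid, ko_id = ko, score = score,
                          stringsAsFactors = FALSE)
        if (runif(1) < 0.3 && length(fams) > 1) {
          ann <- rbind(ann, data.frame(protein_id = pid,
                                       ko_id = sample(kos[-i], 1),
                                       score = round(score - runif(1, 5, 40), 1),
                                       stringsAsFactors = FALSE))
        }
        arows[[k]] <- ann
      }
    }
  }
  membership <- as_cluster_membership(do.call(rbind, mrows))
  annotations <- do.call(rbind, arows)
  rownames(annotations) <- NULL
  list(membership = membership, annotations = annotations,
       ko_category = ko_category,
       true_ko = data.frame(family_id = fams, ko_id = unname(kos),
                            stringsAsFactors = FALSE))
}

#' Table-style calibrations for a dating fixture
#'
#' Builds a calibration set in the mould of geological anchors: a root
#' min/max pair (defaults 3460/4400 My) and, where the fixture's true ages
#' allow, one internal minimum-age and one internal maximum-age constraint at
#' a Great-Oxidation-style bound (2320 My), each guaranteed consistent with
#' the generating ages.
#'
#' @param tree dating tree from `simulate_tree(spec, dating = TRUE)`.
#' @param root_bounds numeric min/max for the root (My).
#' @param event_age internal anchor age (My).
#' @return a [calibration_set()].
#' @export
fixture_calibrations <- function(tree, root_bounds = c(3460, 4400),
                                 event_age = 2320) {
  ages <- attr(tree, "true_ages")
  if (is.null(ages)) validation_error("tree carries no true ages (not a dating fixture)")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (ages[root] < root_bounds[1] || ages[root] > root_bounds[2]) {
    validation_error("fixture root age falls outside the requested root bounds")
  }
  tips <- list(tree$tip.label)
  mins <- root_bounds[1]; maxs <- root_bounds[2]; labs <- "root"
  internal <- setdiff((ntip + 1L):(ntip + tree$Nnode), root)
  above <- internal[ages[internal] >= event_age]
  below <- internal[ages[internal] < event_age]
  if (length(above) > 0) {
    nd <- above[which.min(ages[above])]
    tips <- c(tips, list(tips_under(tree, nd)))
    mins <- c(mins, event_age); maxs <- c(maxs, NA); labs <- c(labs, "event_min")
  }
  if (length(below) > 0) {
    nd <- below[which.max(ages[below])]
    tips <- c(tips, list(tips_under(tree, nd)))
    mins <- c(mins, NA); maxs <- c(maxs, event_age); labs <- c(labs, "event_max")
  }
  calibration_set(tips, mins, maxs, labs)
}

#' Generate a full synthetic bundle in memory
#'
#' @param spec a [synthetic_spec()].
#' @param dating also build the dating fixture (tree in subst/site, true
#'   ages, calibrations).
#' @return a `synthetic_bundle` list: `spec`, `tree`, `matrix`, `truth`,
#'   `node_states`, `crown`, `membership`, `annotations`, `ko_category`,
#'   `true_ko`, and optionally `dating_tree`, `calibrations`.
#' @export
generate_bundle <- function(spec, dating = FALSE) {
  tree <- simulate_tree(spec)
  fam <- simulate_families(spec, tree)
  ann <- emulate_annotation_table(spec, fam$matrix)
  out <- c(list(spec = spec, tree = tree), fam, ann)
  if (dating) {
    out$dating_tree <- simulate_tree(spec, dating = TRUE)
    out$calibrations <- fixture_calibrations(out$dating_tree)
  }
  class(out) <- "synthetic_bundle"
  out
}

#' Write a synthetic bundle as the pipeline's file dialects
#'
#' Writes `tree.nwk`, `matrix.tsv`, `membership.tsv`, `annotations.tsv`,
#' `ko_category.tsv`, `clade.txt` (focal tips, one per line), optionally
#' `dating_tree.nwk` + `calibrations.tsv`, and `manifest.json` recording the
#' spec and the true oracles (per-family rates and stem-gain indicators).
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_newick(bundle$tree, p("tree.nwk"))
  write_trait_matrix(bundle$matrix, p("matrix.tsv"))
  write.table(bundle$membership, p("membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$annotations, p("annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$ko_category, p("ko_category.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(attr(bundle$tree, "focal_tips"), p("clade.txt"))
  write.table(bundle$true_ko, p("family_ko.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$dating_tree)) {
    write_newick(bundle$dating_tree, p("dating_tree.nwk"))
    cal <- bundle$calibrations
    write.table(data.frame(
      clade_tips = vapply(cal$tips, paste, character(1), collapse = ","),
      min_my = cal$min_age, max_my = cal$max_age, label = cal$label),
      p("calibrations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    spec = bundle$spec[setdiff(names(bundle$spec), "newick")],
    truth = bundle$truth,
    n_regenerated = attr(bundle$truth, "n_regenerated"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
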