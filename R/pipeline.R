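#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults mirror the
#' analysis constants of the method: 100 replicate histories per sampler,
#' per-category significance level 0.01, rate floor 0.00001, net stem-branch
#' gain semantics, uniform root prior.
#'
#' @param tree path to the rooted newick tree.
#' @param clade_tips character vector of crown-clade tip labels, or path to a
#'   one-label-per-line file.
#' @param out_dir output directory for stage files.
#' @param matrix path to a presence/absence TSV (or `NULL` to build it from
#'   `membership`).
#' @param membership,annotations,ko_category paths to the membership,
#'   annotation, and KO-category TSVs (used when `matrix` is `NULL` for the
#'   matrix, and for the category map).
#' @param family_ko optional TSV (`family_id`, `ko_id`) mapping families to
#'   KOs directly — the matrix-input alternative to deriving KOs from
#'   `membership` + `annotations` by majority rule.
#' @param calibrations path to a calibration TSV (needed when
#'   `run_chronogram`).
#' @param replicate_trees path to a multi-line newick file of replicate trees
#'   (needed when `run_tc`).
#' @param n_replicates replicates per sampler (default 100).
#' @param alpha significance level (default 0.01).
#' @param rate_floor post-fit rate floor (default 0.00001).
#' @param gain_mode `"net"` or `"events"`.
#' @param root_prior length-2 prior or `"stationary"`.
#' @param seed integer seed.
#' @param sites alignment length for dating.
#' @param lambda_grid smoothing grid for cross-validation.
#' @param run_chronogram,run_tc optional stages.
#' @param force rerun stages whose outputs already exist.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tree, clade_tips, out_dir,
                            matrix = NULL, membership = NULL,
                            annotations = NULL, ko_category = NULL,
                            family_ko = NULL,
                            calibrations = NULL, replicate_trees = NULL,
                            n_replicates = 100, alpha = 0.01,
                            rate_floor = 0.00001,
                            gain_mode = c("net", "events"),
                            root_prior = c(0.5, 0.5), seed = 1,
                            sites = 10000, lambda_grid = c(0.1, 1, 10, 100),
                            run_chronogram = FALSE, run_tc = FALSE,
                            force = FALSE) {
  gain_mode <- match.arg(gain_mode)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

#' Read a pipeline configuration from YAML
#' @param file YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(pipeline_config, vals)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$matrix) && is.null(cfg$membership)) {
    validation_error("config needs either 'matrix' or 'membership'")
  }
  if (is.null(cfg$ko_category) || is.null(cfg$annotations)) {
    if (is.null(cfg$matrix) || is.null(cfg$ko_category)) {
      validation_error("config needs 'ko_category' (and 'annotations' with 'membership') for category mapping")
    }
  }
  if (isTRUE(cfg$run_chronogram) && is.null(cfg$calibrations)) {
    validation_error("chronogram stage enabled but no calibration file given")
  }
  if (isTRUE(cfg$run_tc) && is.null(cfg$replicate_trees)) {
    validation_error("tree-certainty stage enabled but no replicate tree file given")
  }
  paths <- c(cfg$tree, cfg$matrix, cfg$membership, cfg$annotations,
             cfg$ko_category, cfg$family_ko, cfg$calibrations,
             cfg$replicate_trees)
  if (length(cfg$clade_tips) == 1 && file.exists(cfg$clade_tips)) {
    paths <- c(paths, cfg$clade_tips)
  }
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    validation_error(paste0("input files not found: ", paste(missing, collapse = ", ")))
  }
  cfg
}

#' Run the crown-gain enrichment pipeline
#'
#' Executes the stages in order — gene content, per-family ARD fits, mapped
#' and null history replicates, category aggregation and enrichment testing,
#' then the optional chronogram and tree-certainty stages — writing one TSV
#' per stage into `out_dir`, a machine-readable `summary.json`, and a run
#' log. A rerun with an identical configuration reuses completed stage
#' outputs unless `force = TRUE`.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return the summary list, invisibly; stage outputs live in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, files, fun) {
    if (!cfg$force && all(file.exists(out(files)))) {
      log_line("stage ", name, ": reusing existing outputs")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        cladiv_error(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                     "cladiv_stage_error")
      }),
      message = function(m) { invokeRestart("muffleMessage") })
    log_line(sprintf("stage %s: done in %.1fs", name,
                     proc.time()[["elapsed"]] - t0))
  }
  log_line("run_pipeline seed=", cfg$seed, " package cladiv ",
           as.character(utils::packageVersion("cladiv")))

  tree <- read_newick(cfg$tree)
  clade_tips <- if (length(cfg$clade_tips) == 1 && file.exists(cfg$clade_tips)) {
    readLines(cfg$clade_tips)
  } else cfg$clade_tips
  crown <- find_crown_node(tree, clade_definition("crown", clade_tips))

  # -- content ---------------------------------------------------------
  stage("content", c("matrix.tsv", "family_categories.tsv"), function() {
    if (!is.null(cfg$matrix)) {
      mat <- read_trait_matrix(cfg$matrix)
    } else {
      memb <- read_cluster_membership(cfg$membership)
      mat <- build_matrix(memb, tree$tip.label)
    }
    keep <- intersect(colnames(mat), tree$tip.label)
    if (!setequal(colnames(mat), tree$tip.label)) {
      validation_error("matrix taxa do not match tree tips")
    }
    kocat <- read_ko_categories(cfg$ko_category)
    if (!is.null(cfg$membership) && !is.null(cfg$annotations)) {
      memb <- read_cluster_membership(cfg$membership)
      ann <- best_scored_annotation(read_annotation_table(cfg$annotations))
      mr <- majority_rule_ko(memb, ann)
      fmap <- category_map(mr$assignments, kocat)
      writeLines(mr$discarded, out("discarded_families.txt"))
    } else if (!is.null(cfg$family_ko)) {
      fmap <- category_map(read.delim(cfg$family_ko, stringsAsFactors = FALSE),
                           kocat)
    } else {
      # matrix-only input without a family_ko table: family ids are KO ids
      fmap <- category_map(data.frame(family_id = rownames(mat),
                                      ko_id = rownames(mat),
                                      stringsAsFactors = FALSE), kocat)
    }
    write_trait_matrix(mat, out("matrix.tsv"))
    write.table(fmap, out("family_categories.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  mat <- read_trait_matrix(out("matrix.tsv"))
  fmap <- read.delim(out("family_categories.tsv"), stringsAsFactors = FALSE)

  # -- fit -------------------------------------------------------------
  stage("fit", "fits.tsv", function() {
    fits <- fit_ard_many(tree, mat, floor = cfg$rate_floor,
                         root_prior = cfg$root_prior)
    write.table(fits$table, out("fits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  fits <- read.delim(out("fits.tsv"), stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(fits)), function(i) {
    two_state_model(fits$q01[i], fits$q10[i],
                    if (identical(cfg$root_prior, "stationary")) "stationary"
                    else cfg$root_prior)
  })
  names(models) <- fits$family_id

  # -- sample ----------------------------------------------------------
  stage("sample", c("gains_mapped.tsv", "gains_null.tsv"), function() {
    gains <- run_replicates(tree, mat, models, crown, n = cfg$n_replicates,
                            seed = cfg$seed, mode = cfg$gain_mode)
    write_gain_table(gains$mapped, out("gains_mapped.tsv"))
    write_gain_table(gains$null, out("gains_null.tsv"))
  })
  gains <- list(mapped = read.delim(out("gains_mapped.tsv"), stringsAsFactors = FALSE),
                null = read.delim(out("gains_null.tsv"), stringsAsFactors = FALSE))

  # -- test ------------------------------------------------------------
  stage("test", c("category_counts.tsv", "enrichment.tsv"), function() {
    counts <- aggregate_category_counts(gains, fmap)
    res <- call_enrichment(counts, alpha = cfg$alpha)
    write_enrichment(counts, out("category_counts.tsv"))
    write_enrichment(res, out("enrichment.tsv"))
  })
  enrichment <- read.delim(out("enrichment.tsv"), stringsAsFactors = FALSE)

  # -- optional: chronogram -------------------------------------------
  if (isTRUE(cfg$run_chronogram)) {
    stage("chronogram", c("chronogram.nwk", "node_ages.tsv", "cv_report.tsv"),
          function() {
      cal <- read_calibrations(cfg$calibrations)
      cv <- cross_validate(tree, cal, cfg$lambda_grid, scheme = "cv",
                           sites = cfg$sites, seed = cfg$seed)
      chrono <- fit_chronogram(tree, cal, lambda = attr(cv, "chosen"),
                               sites = cfg$sites)
      write_chronogram(chrono, out("chronogram.nwk"), out("node_ages.tsv"))
      write.table(cv, out("cv_report.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # -- optional: tree certainty ---------------------------------------
  if (isTRUE(cfg$run_tc)) {
    stage("tc", "tree_certainty.tsv", function() {
      reps <- ape::read.tree(cfg$replicate_trees)
      if (inherits(reps, "phylo")) reps <- list(reps)
      ict <- internode_certainty(tree, reps)
      write_split_support(ict, out("split_support.tsv"))
      write.table(data.frame(tc = tree_certainty(ict), n_replicates = length(reps)),
                  out("tree_certainty.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # -- summary ---------------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    n_families = nrow(mat),
    n_replicates = cfg$n_replicates,
    alpha = cfg$alpha,
    gain_mode = cfg$gain_mode,
    crown_node = crown$node,
    n_categories = nrow(enrichment),
    enriched_categories = enrichment$category_id[enrichment$enriched],
    min_p = if (nrow(enrichment)) min(enrichment$p_value) else NA
  )
  if (isTRUE(cfg$run_tc)) {
    tc <- read.delim(out("tree_certainty.tsv"))
    summary$tree_certainty <- tc$tc[1]
  }
  if (isTRUE(cfg$run_chronogram)) {
    ages <- read.delim(out("node_ages.tsv"))
    summary$root_age_my <- ages$age_my[ages$node == paste0("n", length(tree$tip.label) + 1L)]
  }
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("pipeline complete: ", length(summary$enriched_categories),
           " enriched categories")
  invisible(summary)
}
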