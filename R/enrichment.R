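#' Aggregate per-replicate gains by functional category
#'
#' Sums gain indicators over a category's annotated families for every
#' replicate of each sampler. Families without a category (unannotated, or a
#' KO missing from the category table) are excluded; categories with no
#' annotated family are omitted. Exclusions are recorded in attributes.
#'
#' @param gains list with `mapped` and `null` gain tables from
#'   [run_replicates()], or a single long gain table holding both samplers.
#' @param map data.frame with `family_id` and `category_id` (see
#'   [category_map()]); `NA` categories are treated as unannotated.
#' @return data.frame `category_id`, `sampler`, `replicate`, `count`, with
#'   attributes `excluded_families` and `n_families` (per-category family
#'   counts).
#' @export
aggregate_category_counts <- function(gains, map) {
  tab <- if (is.data.frame(gains)) gains else rbind(gains$mapped, gains$null)
  cat_of <- setNames(as.character(map$category_id), map$family_id)
  fam_cat <- cat_of[tab$family_id]
  excluded <- sort(unique(tab$family_id[is.na(fam_cat)]))
  if (length(excluded) > 0) {
    message(length(excluded), " families without category excluded from aggregation")
  }
  keep <- !is.na(fam_cat)
  tab <- tab[keep, , drop = FALSE]
  fam_cat <- fam_cat[keep]
  agg <- stats::aggregate(tab$gain,
                          by = list(category_id = fam_cat, sampler = tab$sampler,
                                    replicate = tab$replicate),
                          FUN = sum)
  names(agg)[names(agg) == "x"] <- "count"
  agg <- agg[order(agg$category_id, agg$sampler, agg$replicate), , drop = FALSE]
  rownames(agg) <- NULL
  nfam <- tapply(tab$family_id, fam_cat, function(v) length(unique(v)))
  attr(agg, "excluded_families") <- excluded
  attr(agg, "n_families") <- nfam
  agg
}

#' One-tailed two-sample rank-sum test (mapped greater than null)
#'
#' Wilcoxon/Mann-Whitney rank-sum test of the alternative that the mapped
#' per-replicate gain counts are stochastically greater than the null
#' counts. The p-value is exact (full enumeration) when both samples have at
#' most 10 values and no ties are present; otherwise the normal approximation
#' with tie and continuity correction is used. When every value in both
#' samples is identical the comparison is degenerate and `p = 1` is reported
#' with a flag.
#'
#' @param mapped numeric vector of mapped counts.
#' @param null numeric vector of null counts.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`, default) the
#'   exact enumeration.
#' @return list with `statistic` (Mann-Whitney W), `p_value`, `exact`,
#'   `degenerate`.
#' @export
rank_sum_one_tailed <- function(mapped, null, exact = NULL) {
  if (length(mapped) == 0 || length(null) == 0) {
    validation_error("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(mapped, null)) > 0
  if (length(unique(c(mapped, null))) == 1L) {
    return(list(statistic = length(mapped) * length(null) / 2,
                p_value = 1, exact = FALSE, degenerate = TRUE))
  }
  if (is.null(exact)) exact <- length(mapped) <= 10 && length(null) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(mapped, null, alternative = "greater",
                exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact && !ties, degenerate = FALSE)
}

#' Call category enrichment against the constant-rate null
#'
#' Runs the one-tailed rank-sum comparison per category and flags a category
#' as enriched when `p < alpha` and its mapped median is at least the null
#' median (the mapped-greater direction). No multiple-testing correction is
#' applied by default; `adjust = "BH"` adds Benjamini-Hochberg adjusted
#' p-values and bases the call on them.
#'
#' @param counts category count table from [aggregate_category_counts()].
#' @param alpha significance level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `category_id`, `n_families`, `statistic`, `p_value`
#'   (and `p_adjusted` when requested), `enriched`, `mapped_median`,
#'   `null_median`, `degenerate`, sorted by p-value then category id.
#' @export
call_enrichment <- function(counts, alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cats <- sort(unique(counts$category_id))
  nfam <- attr(counts, "n_families")
  rows <- lapply(cats, function(cg) {
    m <- counts$count[counts$category_id == cg & counts$sampler == "mapped"]
    nu <- counts$count[counts$category_id == cg & counts$sampler == "null"]
    rs <- rank_sum_one_tailed(m, nu)
    data.frame(category_id = cg,
               n_families = if (!is.null(nfam)) unname(nfam[cg]) else NA_integer_,
               statistic = rs$statistic, p_value = rs$p_value,
               mapped_median = median(m), null_median = median(nu),
               degenerate = rs$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_used <- res$p_value
  if (adjust == "BH") {
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
    p_used <- res$p_adjusted
  }
  res$enriched <- p_used < alpha & res$mapped_median >= res$null_median &
    !res$degenerate
  res <- res[order(res$p_value, res$category_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results / ridge data as TSV
#' @param x enrichment result or category count data.frame.
#' @param file output path.
#' @export
write_enrichment <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
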