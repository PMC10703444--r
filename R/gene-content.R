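#' Read ortholog-cluster membership from TSV
#'
#' Expects columns `cluster_id`, `taxon_id`, `protein_id`. A protein may
#' belong to at most one cluster.
#'
#' @param file path to a TSV file.
#' @return a `data.frame` of class `cluster_membership`.
#' @export
read_cluster_membership <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  as_cluster_membership(tab)
}

#' Coerce a data.frame to cluster membership
#' @param tab data.frame with columns cluster_id, taxon_id, protein_id.
#' @return a validated `cluster_membership` data.frame.
#' @export
as_cluster_membership <- function(tab) {
  need <- c("cluster_id", "taxon_id", "protein_id")
  if (!all(need %in% names(tab))) {
    validation_error(paste0("membership table needs columns: ",
                            paste(need, collapse = ", ")))
  }
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  if (length(dup) > 0) {
    per <- unique(tab[, c("cluster_id", "protein_id")])
    if (anyDuplicated(per$protein_id)) {
      validation_error("a protein belongs to more than one cluster")
    }
    tab <- unique(tab)
  }
  class(tab) <- c("cluster_membership", "data.frame")
  tab
}

#' Build the binary gene-family presence/absence matrix
#'
#' A family (ortholog cluster) is present in a taxon iff the cluster holds at
#' least one protein from that taxon. Families absent from every taxon are
#' dropped and recorded in the `dropped` attribute.
#'
#' @param membership a `cluster_membership` table.
#' @param taxa character vector of taxon ids (typically the tree tip labels).
#' @return an integer 0/1 matrix, families as rows, taxa as columns, with
#'   attribute `dropped` listing all-absent family ids.
#' @export
build_matrix <- function(membership, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(unique(membership$taxon_id), taxa)
  if (length(unknown) > 0) {
    validation_error(paste0("membership references unknown taxa: ",
                            paste(utils::head(unknown, 5), collapse = ", ")))
  }
  fams <- sort(unique(as.character(membership$cluster_id)))
  mat <- matrix(0L, nrow = length(fams), ncol = length(taxa),
                dimnames = list(fams, taxa))
  if (nrow(membership) == 0) {
    warning("empty cluster membership: empty presence/absence matrix")
    attr(mat, "dropped") <- character(0)
    return(mat)
  }
  mat[cbind(as.character(membership$cluster_id),
            as.character(membership$taxon_id))] <- 1L
  drop_all_absent(mat)
}

drop_all_absent <- function(mat) {
  absent <- rownames(mat)[rowSums(mat) == 0]
  if (length(absent) > 0) {
    message(length(absent), " all-absent families dropped")
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  }
  attr(mat, "dropped") <- absent
  mat
}

#' Read / write a presence-absence matrix (families x taxa TSV)
#' @param file TSV path; first column `family_id`, remaining columns taxa.
#' @return integer 0/1 matrix with attribute `dropped`.
#' @export
read_trait_matrix <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) validation_error("matrix entries must be 0/1")
  drop_all_absent(mat)
}

#' @rdname read_trait_matrix
#' @param mat 0/1 matrix.
#' @export
write_trait_matrix <- function(mat, file) {
  out <- data.frame(family_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Keep the best-scored annotation per protein
#'
#' Mirrors the filtering of profile-search output where a protein may hit
#' several KEGG orthologs: only the row with the maximal bit score survives.
#' Ties resolve to the lexicographically smaller KO id, so the result is
#' deterministic.
#'
#' @param table data.frame with columns `protein_id`, `ko_id`, `score`.
#' @return the filtered table, one row per protein.
#' @export
best_scored_annotation <- function(table) {
  need <- c("protein_id", "ko_id", "score")
  if (!all(need %in% names(table))) {
    validation_error(paste0("annotation table needs columns: ",
                            paste(need, collapse = ", ")))
  }
  if (nrow(table) == 0) return(table)
  if (any(!is.finite(table$score))) validation_error("non-finite annotation score")
  ord <- order(table$protein_id, -table$score, table$ko_id)
  tab <- table[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$protein_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Majority-rule KO assignment per family
#'
#' Assigns each ortholog cluster the most frequent KO among its member
#' proteins' (filtered) annotations. A frequency tie resolves to the KO with
#' the larger mean score, then lexicographically. Families whose members
#' carry no annotation are excluded and reported.
#'
#' @param membership a `cluster_membership` table.
#' @param filtered an annotation table with at most one row per protein
#'   (see [best_scored_annotation()]).
#' @return a list with `assignments` (data.frame `family_id`, `ko_id`,
#'   `n_annotated`) and `discarded` (character vector of unannotated
#'   family ids).
#' @export
majority_rule_ko <- function(membership, filtered) {
  if (anyDuplicated(filtered$protein_id)) {
    validation_error("filtered annotation table has multiple rows per protein")
  }
  idx <- match(membership$protein_id, filtered$protein_id)
  memb <- membership
  memb$ko_id <- filtered$ko_id[idx]
  memb$score <- filtered$score[idx]
  fams <- sort(unique(as.character(membership$cluster_id)))
  rows <- vector("list", length(fams))
  discarded <- character(0)
  for (i in seq_along(fams)) {
    f <- fams[i]
    sub <- memb[memb$cluster_id == f & !is.na(memb$ko_id), , drop = FALSE]
    if (nrow(sub) == 0) {
      discarded <- c(discarded, f)
      next
    }
    cnt <- table(sub$ko_id)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1) {
      means <- vapply(top, function(k) mean(sub$score[sub$ko_id == k]), numeric(1))
      top <- top[means == max(means)]
      top <- sort(top)[1]
    }
    rows[[i]] <- data.frame(family_id = f, ko_id = top,
                            n_annotated = nrow(sub), stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments)) {
    assignments <- data.frame(family_id = character(0), ko_id = character(0),
                              n_annotated = integer(0), stringsAsFactors = FALSE)
  }
  rownames(assignments) <- NULL
  list(assignments = assignments, discarded = discarded)
}

#' Map families to KEGG categories through their KO
#'
#' @param family_ko data.frame `family_id`, `ko_id` (from [majority_rule_ko()]).
#' @param ko_category data.frame `ko_id`, `category_id`.
#' @return data.frame `family_id`, `ko_id`, `category_id`; families whose KO
#'   has no category get `NA` and are excluded by the aggregation step.
#' @export
category_map <- function(family_ko, ko_category) {
  if (anyDuplicated(ko_category$ko_id)) {
    validation_error("a KO maps to more than one category")
  }
  out <- family_ko
  out$category_id <- ko_category$category_id[match(out$ko_id, ko_category$ko_id)]
  out
}

#' @rdname category_map
#' @param file TSV with columns `ko_id`, `category_id`.
#' @export
read_ko_categories <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("ko_id", "category_id") %in% names(tab))) {
    validation_error("KO category table needs columns ko_id, category_id")
  }
  tab
}

#' Read a protein annotation table (protein_id, ko_id, score TSV)
#' @param file TSV path.
#' @param evalue_max optional e-value ceiling re-applied when the file has an
#'   `evalue` column (upstream searches normally pre-filter).
#' @return data.frame.
#' @export
read_annotation_table <- function(file, evalue_max = NULL) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!is.null(evalue_max) && "evalue" %in% names(tab)) {
    tab <- tab[tab$evalue <= evalue_max, , drop = FALSE]
  }
  tab
}
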