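#' Run nanoRF against many target complexes
#'
#' One independent fractionation per training set, each with a per-column
#' seed offset (`cfg$seed + column index`) so forests are independent but the
#' whole matrix is reproducible. Per-complex quality (AUC, best MCC) is
#' retained so poorly separating targets can be flagged and, if desired,
#' excluded before clustering.
#'
#' @param profile an imputed `dependence_profile`.
#' @param sets list of at least 2 `training_set`s.
#' @param cfg an [rf_config()]; base seed.
#' @return A `multi_rf`: `scores` (proteins x complexes), `thresholds`,
#'   `qualities` (data.frame complex/auc/mcc), `in_training` (character
#'   matrix), `seeds`.
#' @export
run_multi <- function(profile, sets, cfg = rf_config()) {
  stopifnot(inherits(profile, "dependence_profile"))
  if (length(sets) < 2) {
    nrf_validation_error("run_multi needs >= 2 training sets")
  }
  ids <- sort(rownames(profile$values))
  # validate all sets up front so one bad set fails loudly, none silently drop
  bad <- character(0)
  for (s in sets) {
    if (!inherits(s, "training_set")) nrf_validation_error("sets must be training_set objects")
    if (length(intersect(s$positives, ids)) < 2 ||
        length(intersect(s$negatives, ids)) < 2) {
      bad <- c(bad, s$name)
    }
  }
  if (length(bad)) {
    nrf_training_error(paste0(
      "training set(s) with < 2 positives or negatives present in profile: ",
      paste(bad, collapse = ", ")))
  }
  cxs <- unname(vapply(sets, `[[`, character(1), "name"))
  if (anyDuplicated(cxs)) nrf_validation_error("duplicate complex names in sets")
  scores <- matrix(NA_real_, length(ids), length(sets),
                   dimnames = list(ids, cxs))
  labels <- matrix("unlabeled", length(ids), length(sets),
                   dimnames = list(ids, cxs))
  thresholds <- stats::setNames(numeric(length(sets)), cxs)
  seeds <- stats::setNames(cfg$seed + seq_along(sets), cxs)
  qual <- data.frame(complex = cxs, auc = NA_real_, mcc = NA_real_,
                     stringsAsFactors = FALSE)
  results <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    cfg_k <- cfg
    cfg_k$seed <- seeds[[k]]
    res <- fractionate(profile, sets[[k]], cfg_k)
    scores[, k] <- res$scores[ids]
    labels[, k] <- res$in_training[ids]
    thresholds[k] <- res$threshold
    qual$auc[k] <- res$auc
    qual$mcc[k] <- res$best_mcc
    results[[k]] <- res
  }
  structure(
    list(scores = scores, thresholds = thresholds, qualities = qual,
         in_training = labels, seeds = seeds, base_config = cfg,
         results = stats::setNames(results, cxs)),
    class = "multi_rf"
  )
}

#' @export
print.multi_rf <- function(x, ...) {
  cat(sprintf("multi_rf: %d proteins x %d complexes\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$qualities, row.names = FALSE)
  invisible(x)
}

#' Cluster multi-nanoRF score profiles into branches
#'
#' Agglomerative clustering of the protein rows of the score matrix, cut to
#' exactly `n_branches`. Rows are in canonical `protein_id` order and the
#' merge tree is deterministic given the matrix, so branch assignment does
#' not depend on input row order. Branch indices are renumbered by dendrogram
#' leaf order, so branch blocks are contiguous in a leaf-ordered heat map.
#'
#' @param matrix a `multi_rf`.
#' @param n_branches number of branches to cut (the number is data-specific;
#'   no default is imposed).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson between score
#'   rows; undefined correlations from constant rows are treated as 0).
#' @param linkage `"ward"`, `"average"`, or `"complete"`.
#' @return A `branch_partition`: `assignment` (named branch index per
#'   protein), `n_branches`, `tree` (hclust), `leaf_order`.
#' @export
cluster_branches <- function(matrix, n_branches,
                             distance = c("euclidean", "correlation"),
                             linkage = c("ward", "average", "complete")) {
  stopifnot(inherits(matrix, "multi_rf"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- matrix$scores
  x <- x[order(rownames(x)), , drop = FALSE]  # row-order independence
  n_branches <- as.integer(n_branches)
  if (n_branches < 1L || n_branches > nrow(x)) {
    nrf_validation_error(sprintf("n_branches must be in 1..%d (got %d)",
                                 nrow(x), n_branches))
  }
  d <- if (distance == "euclidean") {
    stats::dist(x)
  } else {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[!is.finite(cc)] <- 0
    stats::as.dist(1 - cc)
  }
  tree <- stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                           average = "average",
                                           complete = "complete"))
  raw <- stats::cutree(tree, k = n_branches)
  leaf_order <- tree$labels[tree$order]
  # renumber branches in order of first appearance along the dendrogram leaves
  first_seen <- unique(raw[leaf_order])
  assignment <- stats::setNames(match(raw, first_seen), names(raw))
  structure(
    list(assignment = assignment, n_branches = n_branches, tree = tree,
         leaf_order = leaf_order, distance = distance, linkage = linkage),
    class = "branch_partition"
  )
}

#' @export
print.branch_partition <- function(x, ...) {
  cat(sprintf("branch_partition: %d proteins in %d branches (sizes: %s)\n",
              length(x$assignment), x$n_branches,
              paste(tabulate(x$assignment, x$n_branches), collapse = ", ")))
  invisible(x)
}

#' Nominate candidate members of a target complex
#'
#' Unlabeled proteins that land in a branch containing at least half of the
#' target complex's training positives, ranked by their RF score in the
#' target complex's column. Training members (positives and negatives) are
#' excluded.
#'
#' @param matrix a `multi_rf` containing the target complex.
#' @param partition a `branch_partition` computed from `matrix`.
#' @param ts the target `training_set` (its `name` must be a matrix column).
#' @return data.frame with `protein_id`, `branch`, `score`, ranked by
#'   decreasing score (ties by protein_id).
#' @export
predict_candidates <- function(matrix, partition, ts) {
  stopifnot(inherits(matrix, "multi_rf"), inherits(partition, "branch_partition"),
            inherits(ts, "training_set"))
  if (!ts$name %in% colnames(matrix$scores)) {
    nrf_validation_error(paste0("complex not in matrix: ", ts$name))
  }
  ids <- rownames(matrix$scores)
  if (!setequal(ids, names(partition$assignment))) {
    nrf_validation_error("partition does not cover the matrix proteins")
  }
  pos <- intersect(ts$positives, ids)
  counts <- table(partition$assignment[pos])
  keep_branches <- as.integer(names(counts)[counts >= length(pos) / 2])
  cand <- ids[partition$assignment[ids] %in% keep_branches]
  cand <- setdiff(cand, c(ts$positives, ts$negatives))
  if (!length(cand)) {
    return(data.frame(protein_id = character(0), branch = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  score <- matrix$scores[cand, ts$name]
  ord <- order(-score, cand)
  data.frame(protein_id = cand[ord],
             branch = unname(partition$assignment[cand[ord]]),
             score = unname(score[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a branch-ordered heat-map table
#'
#' Tab-separated, one row per protein in dendrogram leaf order (branch blocks
#' contiguous): `protein_id`, `branch`, one score column per complex. Output
#' is byte-identical across re-exports of the same inputs.
#'
#' @param matrix a `multi_rf`.
#' @param partition a matching `branch_partition`.
#' @param path output file path.
#' @export
export_heatmap <- function(matrix, partition, path) {
  stopifnot(inherits(matrix, "multi_rf"), inherits(partition, "branch_partition"))
  if (!setequal(rownames(matrix$scores), names(partition$assignment))) {
    nrf_validation_error("matrix and partition cover different proteins")
  }
  ids <- partition$leaf_order
  out <- data.frame(protein_id = ids,
                    branch = unname(partition$assignment[ids]),
                    stringsAsFactors = FALSE)
  for (cx in colnames(matrix$scores)) {
    out[[cx]] <- fmt_num(matrix$scores[ids, cx])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Export the branch dendrogram as Newick
#'
#' @param partition a `branch_partition`.
#' @param path output file path.
#' @export
export_newick <- function(partition, path) {
  stopifnot(inherits(partition, "branch_partition"))
  ape::write.tree(ape::as.phylo(partition$tree), file = path)
  invisible(NULL)
}
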