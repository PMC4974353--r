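# Small in-code fixtures shared across test files.

# Hand-written proteinGroups-style TSV, independent of the package writer.
write_pg_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

toy_design <- function(experiments = c("KO1_r1", "KO1_r2"),
                       condition = "KO1",
                       orientation = "ko_over_wt") {
  experiment_design(
    experiment = experiments,
    condition = rep_len(condition, length(experiments)),
    replicate = stats::ave(seq_along(experiments),
                           rep_len(condition, length(experiments)),
                           FUN = seq_along),
    orientation = orientation
  )
}

toy_quant <- function(ratios, ids = sprintf("P%02d", seq_len(nrow(ratios)))) {
  quant_table(
    data.frame(protein_id = ids, gene_name = ids,
               is_reverse = FALSE, is_contaminant = FALSE,
               stringsAsFactors = FALSE),
    ratios
  )
}

# Build a complete dependence_profile straight from a values matrix.
profile_from_matrix <- function(values) {
  ids <- rownames(values)
  structure(
    list(
      proteins = data.frame(protein_id = ids, gene_name = ids,
                            is_reverse = FALSE, is_contaminant = FALSE,
                            stringsAsFactors = FALSE),
      conditions = colnames(values),
      values = values,
      replicate_counts = matrix(1L, nrow(values), ncol(values),
                                dimnames = dimnames(values))
    ),
    class = "dependence_profile"
  )
}

# Well-separated planted profile: positives depleted, negatives/background flat.
separable_profile <- function(n_pos = 5, n_neg = 10, n_bg = 20, n_cond = 3,
                              pos_mean = -3, sd = 0.1, seed = 42) {
  set.seed(seed)
  ids <- c(sprintf("POS%02d", seq_len(n_pos)), sprintf("NEG%02d", seq_len(n_neg)),
           sprintf("BG%03d", seq_len(n_bg)))
  mu <- c(rep(pos_mean, n_pos), rep(0, n_neg + n_bg))
  values <- matrix(stats::rnorm(length(ids) * n_cond, mean = mu, sd = sd),
                   length(ids), n_cond,
                   dimnames = list(ids, paste0("C", seq_len(n_cond))))
  list(
    profile = profile_from_matrix(values),
    ts = training_set("planted", sprintf("POS%02d", seq_len(n_pos)),
                      sprintf("NEG%02d", seq_len(n_neg)))
  )
}

# Minimal fractionation_result stub for writer/scatter tests.
fr_stub <- function(name, scores, labels = NULL, threshold = 0.5) {
  labels <- labels %||% stats::setNames(rep("unlabeled", length(scores)),
                                        names(scores))
  structure(
    list(complex_name = name, scores = scores, in_training = labels,
         threshold = threshold, auc = NA_real_, best_mcc = NA_real_,
         roc_points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
         oob_fallback = character(0), config = rf_config(seed = 0)),
    class = "fractionation_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
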