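#' Construct a quantification table
#'
#' A `quant_table` holds one row per protein group and one column per SILAC
#' experiment. Stored ratios always mean knockout/wild-type abundance after
#' label-orientation correction, so a value of 0.25 reads "25% of wild-type
#' level remains on knockout chromosomes".
#'
#' @param proteins data.frame with columns `protein_id` (unique, non-empty),
#'   `gene_name`, `is_reverse`, `is_contaminant`. Missing metadata columns are
#'   filled with defaults.
#' @param ratios numeric matrix, rows matching `proteins`, named columns (one
#'   per experiment). All non-missing values must be strictly positive.
#' @return A `quant_table` object.
#' @export
quant_table <- function(proteins, ratios) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (is.null(proteins$protein_id)) {
    nrf_validation_error("proteins must have a protein_id column")
  }
  proteins$protein_id <- as.character(proteins$protein_id)
  proteins$gene_name <- as.character(proteins$gene_name %||% rep("", nrow(proteins)))
  proteins$is_reverse <- as.logical(proteins$is_reverse %||% rep(FALSE, nrow(proteins)))
  proteins$is_contaminant <- as.logical(proteins$is_contaminant %||% rep(FALSE, nrow(proteins)))
  if (any(!nzchar(proteins$protein_id))) {
    nrf_validation_error("protein_id must be non-empty")
  }
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup)) {
    nrf_format_error(paste0("duplicate protein_id: ", paste(unique(dup), collapse = ", ")))
  }
  ratios <- as.matrix(ratios)
  storage.mode(ratios) <- "double"
  if (nrow(ratios) != nrow(proteins)) {
    nrf_validation_error("ratio matrix rows must match proteins")
  }
  if (is.null(colnames(ratios)) || anyDuplicated(colnames(ratios))) {
    nrf_validation_error("experiment names must be present and unique")
  }
  if (any(ratios <= 0, na.rm = TRUE)) {
    bad <- which(ratios <= 0, arr.ind = TRUE)[1, ]
    nrf_value_error(sprintf(
      "non-positive ratio for protein '%s' in experiment '%s'",
      proteins$protein_id[bad[1]], colnames(ratios)[bad[2]]
    ))
  }
  rownames(ratios) <- proteins$protein_id
  structure(
    list(proteins = proteins, experiments = colnames(ratios), ratios = ratios),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf(
    "quant_table: %d proteins x %d experiments (%d flagged, %.1f%% missing)\n",
    nrow(x$ratios), ncol(x$ratios),
    sum(x$proteins$is_reverse | x$proteins$is_contaminant),
    100 * mean(is.na(x$ratios))
  ))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$ratios)

#' Drop decoy and contaminant protein groups
#'
#' Reverse-database (decoy) hits and annotated contaminants are carried
#' through parsing but must not enter training or scoring; downstream
#' modules drop them by default.
#'
#' @param table a `quant_table`.
#' @return A `quant_table` without flagged rows.
#' @export
drop_flagged <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  keep <- !(table$proteins$is_reverse | table$proteins$is_contaminant)
  quant_table(table$proteins[keep, , drop = FALSE],
              table$ratios[keep, , drop = FALSE])
}

#' Construct an experiment design
#'
#' Maps each SILAC ratio column to a knockout condition, a biological
#' replicate, and the label orientation of the stored ratio. `ko_over_wt`
#' means the column already reads knockout/wild-type; `wt_over_ko` columns
#' are inverted on import.
#'
#' @param experiment character, unique experiment (column) names.
#' @param condition character, knockout condition label per experiment.
#' @param replicate integer replicate index (>= 1).
#' @param orientation `"ko_over_wt"` or `"wt_over_ko"` per experiment.
#' @return An `experiment_design` data.frame.
#' @export
experiment_design <- function(experiment, condition, replicate,
                              orientation = "ko_over_wt") {
  d <- data.frame(
    experiment = as.character(experiment),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    orientation = rep_len(as.character(orientation), length(experiment)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$experiment)) {
    nrf_validation_error("experiment names must be unique in the design")
  }
  if (anyDuplicated(d[, c("condition", "replicate")])) {
    nrf_validation_error("(condition, replicate) pairs must be unique")
  }
  if (any(d$replicate < 1L)) nrf_validation_error("replicate index must be >= 1")
  bad <- setdiff(unique(d$orientation), c("ko_over_wt", "wt_over_ko"))
  if (length(bad)) {
    nrf_validation_error(paste0("unknown orientation: ", paste(bad, collapse = ", ")))
  }
  class(d) <- c("experiment_design", "data.frame")
  d
}

#' Read an experiment design table
#'
#' Tab-separated with header columns `experiment`, `condition`, `replicate`,
#' `orientation`.
#'
#' @param path file path.
#' @return An `experiment_design`.
#' @export
read_experiment_design <- function(path) {
  if (!file.exists(path)) nrf_io_error(paste0("design file not found: ", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("experiment", "condition", "replicate", "orientation")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    nrf_format_error(paste0("design is missing columns: ", paste(miss, collapse = ", ")))
  }
  experiment_design(d$experiment, d$condition, d$replicate, d$orientation)
}

#' Write an experiment design table
#' @param design an `experiment_design`.
#' @param path file path.
#' @export
write_experiment_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

missing_tokens <- c("", "NaN", "NA")

#' Read a proteinGroups-style quantification table
#'
#' Parses the tab-separated protein-group output dialect of common MS search
#' engines: a `Protein IDs` column (semicolon-separated group members; the
#' first, "razor", accession becomes the `protein_id`), optional `Gene names`,
#' `Reverse` and `Potential contaminant` flag columns (`+` = flagged), and one
#' ratio column per designed experiment named `"<column_prefix> <experiment>"`.
#'
#' Empty cells and the tokens `NaN`/`NA` become missing. Experiments declared
#' `wt_over_ko` in the design have their ratios inverted so that every stored
#' ratio means knockout/wild-type. Decoy/contaminant rows are retained but
#' flagged (see [drop_flagged()]).
#'
#' @param path file path to the tab-separated table.
#' @param design an `experiment_design`; every designed experiment must have a
#'   matching ratio column.
#' @param column_prefix ratio column prefix, default `"Ratio H/L normalized"`.
#' @return A `quant_table` with experiments in design order.
#' @export
read_protein_groups <- function(path, design,
                                column_prefix = "Ratio H/L normalized") {
  if (!file.exists(path)) nrf_io_error(paste0("quantification file not found: ", path))
  stopifnot(inherits(design, "experiment_design"))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "",
                           na.strings = character(0))
  id_col <- intersect(c("Protein IDs", "Majority protein IDs", "protein_id"),
                      names(raw))[1]
  if (is.na(id_col)) {
    nrf_format_error("no protein identifier column ('Protein IDs' or 'protein_id') found")
  }
  ids <- vapply(strsplit(raw[[id_col]], ";", fixed = TRUE),
                function(x) if (length(x)) x[[1]] else "", character(1))
  flag <- function(col) {
    if (col %in% names(raw)) raw[[col]] == "+" else rep(FALSE, nrow(raw))
  }
  proteins <- data.frame(
    protein_id = ids,
    gene_name = if ("Gene names" %in% names(raw)) raw[["Gene names"]] else "",
    is_reverse = flag("Reverse"),
    is_contaminant = flag("Potential contaminant") | flag("Contaminant"),
    stringsAsFactors = FALSE
  )
  wanted <- paste(column_prefix, design$experiment)
  miss <- wanted[!wanted %in% names(raw)]
  if (length(miss)) {
    nrf_format_error(paste0("missing ratio column(s): ", paste(miss, collapse = ", ")))
  }
  ratios <- matrix(NA_real_, nrow(raw), nrow(design),
                   dimnames = list(NULL, design$experiment))
  for (j in seq_len(nrow(design))) {
    cell <- trimws(raw[[wanted[j]]])
    present <- !(is.na(cell) | cell %in% missing_tokens)
    val <- suppressWarnings(as.numeric(cell[present]))
    if (anyNA(val)) {
      row <- which(present)[which(is.na(val))[1]]
      nrf_value_error(sprintf("unparseable ratio '%s' at row %d, column '%s'",
                              cell[present][is.na(val)][1], row, wanted[j]))
    }
    if (any(val <= 0)) {
      row <- which(present)[which(val <= 0)[1]]
      nrf_value_error(sprintf("non-positive ratio at row %d, column '%s'",
                              row, wanted[j]))
    }
    if (design$orientation[j] == "wt_over_ko") val <- 1 / val
    ratios[which(present), j] <- val
  }
  quant_table(proteins, ratios)
}

#' Write a quantification table in the proteinGroups dialect
#'
#' Inverse of [read_protein_groups()] for `ko_over_wt` designs: emits
#' `Protein IDs`, `Gene names`, flag columns, and one
#' `"<column_prefix> <experiment>"` ratio column per experiment. Values
#' round-trip at 6 significant digits.
#'
#' @param table a `quant_table`.
#' @param path output file path.
#' @param column_prefix ratio column prefix.
#' @export
write_quant_table <- function(table, path,
                              column_prefix = "Ratio H/L normalized") {
  stopifnot(inherits(table, "quant_table"))
  out <- data.frame(
    `Protein IDs` = table$proteins$protein_id,
    `Gene names` = table$proteins$gene_name,
    Reverse = ifelse(table$proteins$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(table$proteins$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (e in table$experiments) {
    out[[paste(column_prefix, e)]] <- fmt_num(table$ratios[, e])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a training set
#'
#' A named complex's known members (positives) and a shared background set of
#' negatives — typically curated cytoplasmic/ribosomal contaminants that
#' hitchhike on chromosome preparations.
#'
#' @param name complex name.
#' @param positives character vector of member protein IDs.
#' @param negatives character vector of background protein IDs.
#' @return A `training_set` object.
#' @export
training_set <- function(name, positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (!length(positives)) {
    nrf_validation_error(paste0("training set '", name, "' has no positives"))
  }
  both <- intersect(positives, negatives)
  if (length(both)) {
    nrf_validation_error(sprintf(
      "training set '%s': protein(s) listed as both positive and negative: %s",
      name, paste(both, collapse = ", ")))
  }
  structure(list(name = as.character(name), positives = positives,
                 negatives = negatives),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set '%s': %d positives, %d shared negatives\n",
              x$name, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Read training-set definitions
#'
#' YAML with a `negatives` list (shared background) and a `complexes` mapping
#' of complex name to member ID list:
#'
#' ```yaml
#' negatives: [RPL3, RPL4, EEF2]
#' complexes:
#'   condensin_I: [SMC2, SMC4, CAPD2, CAPG, CAPH]
#'   cohesin: [SMC1, SMC3, SCC1, SA1, SA2]
#' ```
#'
#' @param path file path.
#' @return Named list of `training_set`s, in file order, sharing `negatives`.
#' @export
read_training_sets <- function(path) {
  if (!file.exists(path)) nrf_io_error(paste0("training-set file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$complexes) || !length(cfg$complexes)) {
    nrf_validation_error("training-set file must define at least one complex")
  }
  negatives <- as.character(unlist(cfg$negatives %||% character(0)))
  sets <- lapply(names(cfg$complexes), function(nm) {
    training_set(nm, as.character(unlist(cfg$complexes[[nm]])), negatives)
  })
  names(sets) <- names(cfg$complexes)
  sets
}

#' Write training-set definitions
#' @param sets list of `training_set`s sharing a negative set.
#' @param path file path.
#' @export
write_training_sets <- function(sets, path) {
  if (!length(sets)) nrf_validation_error("no training sets to write")
  cfg <- list(
    negatives = as.list(sets[[1]]$negatives),
    complexes = lapply(sets, function(s) as.list(s$positives))
  )
  names(cfg$complexes) <- vapply(sets, `[[`, character(1), "name")
  yaml::write_yaml(cfg, path)
  invisible(NULL)
}

#' Write RF score tables
#'
#' Serializes one or more [fractionate()] results, or a [run_multi()] score
#' matrix, as a tab-separated table: one row per protein; per complex a
#' `<name>.score` column, a `<name>.label` column (positive / negative /
#' unlabeled training status), and a `<name>.call` column (score above the
#' complex's MCC-optimal threshold). Scores round-trip at 6 significant
#' digits (see [read_scores_table()]).
#'
#' @param results a `fractionation_result`, a list of them, or a `multi_rf`.
#' @param path output file path.
#' @export
write_scores_table <- function(results, path) {
  if (inherits(results, "fractionation_result")) results <- list(results)
  if (inherits(results, "multi_rf")) {
    ids <- rownames(results$scores)
    cols <- colnames(results$scores)
    get_score <- function(cx) results$scores[, cx]
    get_label <- function(cx) results$in_training[, cx]
    get_thr <- function(cx) results$thresholds[[cx]]
  } else {
    if (!length(results)) nrf_validation_error("no results to write")
    ok <- vapply(results, inherits, logical(1), "fractionation_result")
    if (!all(ok)) nrf_validation_error("results must be fractionation_result objects")
    ids <- names(results[[1]]$scores)
    cols <- vapply(results, `[[`, character(1), "complex_name")
    names(results) <- cols
    get_score <- function(cx) results[[cx]]$scores[ids]
    get_label <- function(cx) results[[cx]]$in_training[ids]
    get_thr <- function(cx) results[[cx]]$threshold
  }
  if (!length(ids)) nrf_validation_error("no proteins to write")
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (cx in cols) {
    s <- get_score(cx)
    out[[paste0(cx, ".score")]] <- fmt_num(s)
    out[[paste0(cx, ".label")]] <- as.character(get_label(cx))
    out[[paste0(cx, ".call")]] <- ifelse(s > get_thr(cx), "above", "below")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# threshold\t",
                    paste(cols, fmt_num(vapply(cols, get_thr, numeric(1))),
                          sep = "=", collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read back a score table written by [write_scores_table()]
#'
#' @param path file path.
#' @return List with `scores` (proteins x complexes matrix), `labels`
#'   (character matrix), and `thresholds` (named numeric).
#' @export
read_scores_table <- function(path) {
  if (!file.exists(path)) nrf_io_error(paste0("score table not found: ", path))
  header <- readLines(path, n = 1)
  thresholds <- numeric(0)
  skip <- 0
  if (startsWith(header, "# threshold")) {
    kv <- strsplit(strsplit(header, "\t")[[1]][-1], "=", fixed = TRUE)
    thresholds <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
    names(thresholds) <- vapply(kv, `[`, character(1), 1)
    skip <- 1
  }
  d <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                         check.names = FALSE)
  score_cols <- grep("\\.score$", names(d), value = TRUE)
  cx <- sub("\\.score$", "", score_cols)
  scores <- as.matrix(d[, score_cols, drop = FALSE])
  colnames(scores) <- cx
  rownames(scores) <- d$protein_id
  labels <- as.matrix(d[, paste0(cx, ".label"), drop = FALSE])
  colnames(labels) <- cx
  rownames(labels) <- d$protein_id
  list(scores = scores, labels = labels, thresholds = thresholds)
}
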