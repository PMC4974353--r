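#' Normalize all ratios to a reference protein
#'
#' Chromosome preparations from knockouts with fragile chromosomes recover
#' less material overall; dividing every protein's SILAC ratio by that of an
#' invariant reference (canonically histone H4) in the same experiment removes
#' this per-experiment yield effect. The reference's own ratios become exactly
#' 1.
#'
#' @param table a `quant_table` oriented knockout/wild-type.
#' @param reference_id accession of the reference protein; must be quantified
#'   in every experiment.
#' @return A normalized `quant_table`.
#' @export
normalize_to_reference <- function(table, reference_id) {
  stopifnot(inherits(table, "quant_table"))
  i <- match(reference_id, table$proteins$protein_id)
  if (is.na(i)) {
    nrf_value_error(paste0("reference protein not found: ", reference_id))
  }
  ref <- table$ratios[i, ]
  absent <- table$experiments[is.na(ref)]
  if (length(absent)) {
    nrf_value_error(sprintf(
      "reference '%s' has no ratio in experiment(s): %s",
      reference_id, paste(absent, collapse = ", ")))
  }
  ratios <- sweep(table$ratios, 2, ref, "/")
  ratios[i, ] <- 1  # exact, not subject to rounding of x/x
  quant_table(table$proteins, ratios)
}

#' Compute per-condition dependence profiles
#'
#' The dependence of a protein on a knocked-out factor is the mean
#' log2(knockout/wild-type) ratio across that condition's biological
#' replicates (a geometric mean of ratios — ratio data are multiplicative).
#' Negative values mean the protein is depleted from knockout chromosomes,
#' i.e. requires the factor for chromosomal association.
#'
#' @param table a `quant_table` oriented knockout/wild-type.
#' @param design an `experiment_design` covering the table's experiments.
#' @param exclude_flagged drop decoy/contaminant rows first (default TRUE).
#' @return A `dependence_profile`: proteins x conditions matrix of mean log2
#'   ratios (`values`, NA where no replicate was quantified) plus matching
#'   `replicate_counts`.
#' @export
compute_dependence <- function(table, design, exclude_flagged = TRUE) {
  stopifnot(inherits(table, "quant_table"), inherits(design, "experiment_design"))
  if (exclude_flagged) table <- drop_flagged(table)
  unknown <- setdiff(design$experiment, table$experiments)
  if (length(unknown)) {
    nrf_design_error(paste0("designed experiment(s) absent from table: ",
                            paste(unknown, collapse = ", ")))
  }
  conditions <- unique(design$condition)
  logr <- log2(table$ratios)
  values <- matrix(NA_real_, nrow(logr), length(conditions),
                   dimnames = list(rownames(logr), conditions))
  counts <- matrix(0L, nrow(logr), length(conditions),
                   dimnames = list(rownames(logr), conditions))
  for (cond in conditions) {
    exps <- design$experiment[design$condition == cond]
    if (!length(exps)) nrf_design_error(paste0("condition has no experiments: ", cond))
    sub <- logr[, exps, drop = FALSE]
    n <- rowSums(!is.na(sub))
    counts[, cond] <- as.integer(n)
    values[, cond] <- ifelse(n >= 1, rowMeans(sub, na.rm = TRUE), NA_real_)
  }
  structure(
    list(proteins = table$proteins, conditions = conditions,
         values = values, replicate_counts = counts),
    class = "dependence_profile"
  )
}

#' @export
print.dependence_profile <- function(x, ...) {
  cat(sprintf("dependence_profile: %d proteins x %d conditions (%.1f%% missing)\n",
              nrow(x$values), length(x$conditions), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Residual abundance as a percentage
#'
#' Maps a log2 dependence value back to "percent of wild-type level
#' remaining": `100 * 2^value`, the geometric mean of replicate ratios times
#' 100 (a residual of 8.0 means 8% of the wild-type level remains).
#'
#' @param value log2 dependence value(s).
#' @return Residual percentage(s).
#' @export
residual_percent <- function(value) 100 * 2^value

#' Impute missing dependence values by condition median
#'
#' Each missing cell is replaced by the median of the present values in the
#' same condition column; present cells and replicate counts are untouched.
#' Idempotent. Downstream RF scoring requires a complete matrix.
#'
#' @param profile a `dependence_profile`.
#' @return An imputed `dependence_profile`.
#' @export
impute_missing <- function(profile) {
  stopifnot(inherits(profile, "dependence_profile"))
  values <- profile$values
  for (j in seq_len(ncol(values))) {
    pres <- !is.na(values[, j])
    if (!any(pres)) {
      nrf_value_error(paste0("condition has no present values to impute from: ",
                             colnames(values)[j]))
    }
    values[!pres, j] <- stats::median(values[pres, j])
  }
  out <- profile
  out$values <- values
  out
}

#' Per-protein volcano statistics for one knockout condition
#'
#' For every protein quantified in at least 2 of the condition's replicates:
#' mean log2(knockout/wild-type) ratio and a two-sided one-sample t-test of
#' the replicate log2 ratios against 0, Benjamini-Hochberg adjusted across
#' proteins. Proteins with fewer than 2 present replicates, or with zero
#' replicate variance (t undefined), get missing p-values.
#'
#' @param table a `quant_table` oriented knockout/wild-type.
#' @param design an `experiment_design`.
#' @param condition condition label with >= 2 designed replicates.
#' @param exclude_flagged drop decoy/contaminant rows first (default TRUE).
#' @return data.frame with `protein_id`, `mean_log2_ratio`, `n_replicates`,
#'   `p_value`, `adj_p_value`.
#' @export
volcano_table <- function(table, design, condition, exclude_flagged = TRUE) {
  stopifnot(inherits(table, "quant_table"), inherits(design, "experiment_design"))
  if (!condition %in% design$condition) {
    nrf_design_error(paste0("unknown condition: ", condition))
  }
  exps <- design$experiment[design$condition == condition]
  if (length(exps) < 2) {
    nrf_design_error(paste0("condition needs >= 2 replicates for a volcano: ",
                            condition))
  }
  if (exclude_flagged) table <- drop_flagged(table)
  logr <- log2(table$ratios[, exps, drop = FALSE])
  n <- rowSums(!is.na(logr))
  m <- ifelse(n >= 1, rowMeans(logr, na.rm = TRUE), NA_real_)
  p <- rep(NA_real_, nrow(logr))
  for (i in which(n >= 2)) {
    x <- logr[i, !is.na(logr[i, ])]
    s <- stats::sd(x)
    if (s > 0) {
      tstat <- mean(x) / (s / sqrt(length(x)))
      p[i] <- 2 * stats::pt(-abs(tstat), df = length(x) - 1)
    }
  }
  data.frame(
    protein_id = table$proteins$protein_id,
    mean_log2_ratio = m,
    n_replicates = as.integer(n),
    p_value = p,
    adj_p_value = bh_adjust(p),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around [stats::p.adjust()] (`method = "BH"`) that preserves
#' missing values; the adjustment is computed over the non-missing p-values
#' only.
#'
#' @param p numeric p-values, may contain NA.
#' @return Adjusted p-values, NA where input was NA.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Write a dependence profile as TSV
#'
#' One row per protein: dependence values per condition plus replicate
#' counts.
#'
#' @param profile a `dependence_profile`.
#' @param path output file path.
#' @export
write_dependence_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dependence_profile"))
  out <- data.frame(protein_id = rownames(profile$values),
                    stringsAsFactors = FALSE)
  for (cond in profile$conditions) {
    out[[cond]] <- fmt_num(profile$values[, cond])
    out[[paste0(cond, ".n")]] <- profile$replicate_counts[, cond]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
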