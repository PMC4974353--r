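#' Random-Forest configuration for nanoRF
#'
#' @param n_trees number of trees (>= 100 recommended for reported results;
#'   default 1000).
#' @param features_per_split candidate conditions per split; `"auto"` uses the
#'   classification default `floor(sqrt(p))`.
#' @param seed RNG seed; recorded in every result.
#' @param class_weighting `"balanced"` (inverse class frequency; default — a
#'   complex's positives can number under 10 against a much larger background)
#'   or `"none"`.
#' @return An `rf_config` object.
#' @export
rf_config <- function(n_trees = 1000, features_per_split = "auto", seed = 1,
                      class_weighting = c("balanced", "none")) {
  class_weighting <- match.arg(class_weighting)
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) nrf_validation_error("n_trees must be positive")
  if (!identical(features_per_split, "auto")) {
    features_per_split <- as.integer(features_per_split)
    if (features_per_split < 1L) nrf_validation_error("features_per_split must be positive")
  }
  structure(list(n_trees = n_trees, features_per_split = features_per_split,
                 seed = as.integer(seed), class_weighting = class_weighting),
            class = "rf_config")
}

#' In-silico fractionation of one complex by nanoRF
#'
#' Grows a Random Forest on the labeled rows of a complete dependence profile
#' (the target complex's known members versus a shared background set) and
#' scores every protein's co-fractionation with the complex:
#'
#' * labeled proteins get the *adjusted* RF score — the fraction of trees in
#'   whose bootstrap sample they were **out-of-bag** that vote positive, so
#'   training members are scored on the same self-fit-free footing as
#'   candidates;
#' * unlabeled proteins get the fraction of all trees voting positive.
#'
#' Fractionation quality is summarized over the labeled proteins' adjusted
#' scores: the ROC curve and its AUC, and the threshold maximizing the
#' Matthews correlation coefficient. Rows are canonically sorted by
#' `protein_id` before fitting, so results depend only on profile content,
#' training set, and seed — never on input row order.
#'
#' @param profile an imputed `dependence_profile` (no missing cells; see
#'   [impute_missing()]).
#' @param ts a `training_set`; at least 2 positives and 2 negatives must be
#'   present in the profile.
#' @param cfg an [rf_config()].
#' @return A `fractionation_result`: `scores` (named, all proteins, in
#'   `[0,1]`), `in_training` (positive/negative/unlabeled), `threshold`,
#'   `auc`, `best_mcc`, `roc_points`, `oob_fallback` (labeled proteins never
#'   out-of-bag, scored by the full forest with a warning), and the config.
#' @export
fractionate <- function(profile, ts, cfg = rf_config()) {
  stopifnot(inherits(profile, "dependence_profile"), inherits(ts, "training_set"),
            inherits(cfg, "rf_config"))
  x <- profile$values
  if (anyNA(x)) {
    nrf_value_error("profile has missing cells; run impute_missing() first")
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  pos <- intersect(ts$positives, rownames(x))
  neg <- intersect(ts$negatives, rownames(x))
  if (length(pos) < 2 || length(neg) < 2) {
    nrf_training_error(sprintf(
      "training set '%s' needs >= 2 positives and >= 2 negatives in the profile (has %d, %d)",
      ts$name, length(pos), length(neg)))
  }
  labeled <- rownames(x)[rownames(x) %in% c(pos, neg)]
  y <- factor(ifelse(labeled %in% pos, "positive", "negative"),
              levels = c("negative", "positive"))
  mtry <- if (identical(cfg$features_per_split, "auto")) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    min(cfg$features_per_split, ncol(x))
  }
  classwt <- if (cfg$class_weighting == "balanced") {
    c(negative = 1 / length(neg), positive = 1 / length(pos))
  } else {
    NULL
  }
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = x[labeled, , drop = FALSE], y = y,
    ntree = cfg$n_trees, mtry = mtry, classwt = classwt
  )
  oob <- rf$votes[, "positive"]  # norm.votes: fraction of OOB trees
  names(oob) <- labeled
  fallback <- labeled[!is.finite(oob)]
  scores <- stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
  scores[labeled] <- oob
  unlabeled <- setdiff(rownames(x), labeled)
  if (length(unlabeled)) {
    scores[unlabeled] <- predict(rf, x[unlabeled, , drop = FALSE],
                                 type = "vote")[, "positive"]
  }
  if (length(fallback)) {
    warning(sprintf("%d labeled protein(s) were never out-of-bag; using full-forest votes: %s",
                    length(fallback), paste(fallback, collapse = ", ")))
    scores[fallback] <- predict(rf, x[fallback, , drop = FALSE],
                                type = "vote")[, "positive"]
  }
  in_training <- stats::setNames(rep("unlabeled", nrow(x)), rownames(x))
  in_training[pos] <- "positive"
  in_training[neg] <- "negative"
  lab_scores <- scores[labeled]
  lab_pos <- labeled %in% pos
  bt <- best_threshold(lab_scores, lab_pos)
  structure(
    list(complex_name = ts$name,
         scores = scores,
         in_training = in_training,
         threshold = bt$threshold,
         auc = roc_auc(lab_scores, lab_pos),
         best_mcc = bt$mcc,
         roc_points = roc_points(lab_scores, lab_pos),
         oob_fallback = fallback,
         config = cfg),
    class = "fractionation_result"
  )
}

#' @export
print.fractionation_result <- function(x, ...) {
  cat(sprintf(
    "nanoRF fractionation '%s': %d proteins | AUC %.3f | best MCC %.3f at score > %.3f\n",
    x$complex_name, length(x$scores), x$auc, x$best_mcc, x$threshold))
  invisible(x)
}

check_labeled <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    nrf_validation_error("scores and labels differ in length")
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    nrf_validation_error("need at least one positive and one negative label")
  }
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties counted one half. Invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible), TRUE = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_labeled(scores, labels)
  r <- rank(scores)  # midranks handle ties as 1/2
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Step curve from (0,0) to (1,1) over the distinct score thresholds,
#' prediction rule `score > threshold`.
#'
#' @inheritParams roc_auc
#' @return data.frame with `fpr` and `tpr`, monotone non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labeled(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] > t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Matthews correlation coefficient at a score threshold
#'
#' Prediction rule is `score > threshold`. Returns 0 whenever a factor of the
#' denominator is 0 (all predictions, or all labels, on one side).
#'
#' @inheritParams roc_auc
#' @param threshold classification threshold.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_at_threshold <- function(scores, labels, threshold) {
  labels <- check_labeled(scores, labels)
  pred <- scores > threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' MCC-maximizing score threshold
#'
#' Evaluates the midpoints between consecutive distinct sorted scores plus
#' the sentinels 0 and 1 (MCC is step-constant between observed scores, so
#' this grid contains an exact optimum); ties are broken toward the smallest
#' threshold.
#'
#' @inheritParams roc_auc
#' @return List with `threshold` and `mcc`.
#' @export
best_threshold <- function(scores, labels) {
  labels <- check_labeled(scores, labels)
  s <- sort(unique(scores))
  grid <- sort(unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1)))
  mccs <- vapply(grid, function(t) mcc_at_threshold(scores, labels, t), numeric(1))
  i <- which.max(mccs)  # first max = smallest threshold
  list(threshold = grid[i], mcc = mccs[i])
}

#' Pair two fractionations for a 2-D score scatter
#'
#' Joins two results over their common protein universe, the table behind the
#' classic two-complex RF-score scatter plots; proteins above both
#' MCC-optimal thresholds (or thresholds you supply) are flagged in
#' `above_both`.
#'
#' @param a,b `fractionation_result`s computed on the same proteins.
#' @param thresholds optional numeric length-2 override `c(a, b)`.
#' @return data.frame with `protein_id`, `score_a`, `score_b`, `label_a`,
#'   `label_b`, `above_both`.
#' @export
scatter_pairs <- function(a, b, thresholds = NULL) {
  stopifnot(inherits(a, "fractionation_result"), inherits(b, "fractionation_result"))
  ids <- intersect(names(a$scores), names(b$scores))
  if (!length(ids)) nrf_validation_error("results share no proteins")
  ids <- sort(ids)
  ta <- (thresholds %||% c(a$threshold, b$threshold))[1]
  tb <- (thresholds %||% c(a$threshold, b$threshold))[2]
  data.frame(
    protein_id = ids,
    score_a = a$scores[ids],
    score_b = b$scores[ids],
    label_a = a$in_training[ids],
    label_b = b$in_training[ids],
    above_both = a$scores[ids] > ta & b$scores[ids] > tb,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a fractionation result as TSV (scores plus ROC points)
#'
#' @param result a `fractionation_result`.
#' @param path scores file path.
#' @param roc_path optional path for the ROC points TSV.
#' @export
write_fractionation <- function(result, path, roc_path = NULL) {
  write_scores_table(result, path)
  if (!is.null(roc_path)) {
    out <- data.frame(fpr = fmt_num(result$roc_points$fpr),
                      tpr = fmt_num(result$roc_points$tpr))
    utils::write.table(out, roc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
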