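#' Rank-based AUC (Mann-Whitney, ties counted one half)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties contributing 1/2. Computed from midranks, so it equals
#' exhaustive pairwise comparison exactly.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Positive-class indicator: logical, 0/1 numeric, or a factor
#'   whose second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) {
    abort("`scores` and `labels` must have equal length.")
  }
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]
  lab <- lab[ok]
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC needs both classes present.")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) {
    return(as.integer(labels))
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    known <- c(presence = 1L, pseudo_absence = 0L, background = 0L,
               absence = 0L, "1" = 1L, "0" = 0L)
    if (!all(labels %in% names(known))) {
      abort("Character labels must be presence/pseudo_absence/background/absence or 0/1.")
    }
    return(unname(known[labels]))
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    return(as.integer(labels))
  }
  abort("Unsupported label type.")
}

#' AUC of a binary presence-only model
#'
#' For binary scores the rank AUC reduces to
#' `(sensitivity + specificity) / 2` against the background sample; this
#' helper keeps the two score groups explicit, as presence-only model
#' assessment supplies them.
#'
#' @param presence_scores Scores of the held-out presence records.
#' @param background_scores Scores of the background sample.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_binary_auc <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0L || length(background_scores) == 0L) {
    abort("Both score groups must be non-empty.")
  }
  auc_score(
    c(presence_scores, background_scores),
    c(rep(1L, length(presence_scores)), rep(0L, length(background_scores)))
  )
}

#' Validation metrics at a fixed threshold
#'
#' Prediction rule: positive iff `score >= threshold`. Reports AUC,
#' sensitivity, specificity, the true skill statistic
#' `TSS = sensitivity + specificity - 1`, and the correct-classification
#' rate `(TP + TN) / N` (misclassification is its complement).
#'
#' @param scores Numeric scores.
#' @param labels Positive-class indicator (see [auc_score()]).
#' @param threshold Decision threshold.
#' @param tag Optional season/species tag recorded on the row.
#' @return A one-row tibble of class `validation_report` with columns `tag`,
#'   `auc`, `threshold`, `sensitivity`, `specificity`, `tss`,
#'   `correct_classification`, `misclassification`.
#' @export
validation_report <- function(scores, labels, threshold, tag = NA_character_) {
  lab <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) abort("Validation needs both classes present.")
  sens <- sum(pred == 1L & lab == 1L) / n1
  spec <- sum(pred == 0L & lab == 0L) / n0
  cc <- mean(pred == lab)
  out <- tibble(
    tag = as.character(tag),
    auc = auc_score(scores, lab),
    threshold = threshold,
    sensitivity = sens,
    specificity = spec,
    tss = sens + spec - 1,
    correct_classification = cc,
    misclassification = 1 - cc
  )
  class(out) <- unique(c("validation_report", class(out)))
  out
}

#' TSS-maximizing threshold
#'
#' Searches the exact candidate set — midpoints of consecutive sorted unique
#' scores — for the threshold maximizing the true skill statistic under the
#' rule `positive iff score >= threshold`. Ties are broken toward the
#' smallest threshold, which yields the larger predicted-positive area (the
#' risk-conservative choice for hazard and habitat mapping).
#'
#' @inheritParams validation_report
#' @return A one-row `validation_report` tibble evaluated at the selected
#'   threshold (column `threshold` carries it).
#' @export
tss_threshold <- function(scores, labels, tag = NA_character_) {
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) {
    abort("`scores` and `labels` must have equal length.")
  }
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    abort("All scores are identical; no informative threshold exists.")
  }
  cand <- (u[-length(u)] + u[-1L]) / 2
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) abort("Threshold search needs both classes present.")
  tss <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & lab == 1L) / n1 + sum(!pred & lab == 0L) / n0 - 1
  }, numeric(1))
  best <- cand[which.max(tss)] # which.max returns the first (smallest) maximizer
  validation_report(scores, lab, threshold = best, tag = tag)
}

#' Binarize a probability map at a threshold
#'
#' Cell value 1 iff probability `>= threshold` (the same boundary convention
#' as everywhere else in the package); nodata propagates.
#'
#' @param map Probability `raster_grid` with values in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`.
#' @return A binary `raster_grid` (values 0/1, `NA` for nodata).
#' @export
binarize <- function(map, threshold) {
  if (!is_raster_grid(map)) abort("`map` must be a raster_grid.")
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  v <- ifelse(is.na(map$values), NA_real_, as.numeric(map$values >= threshold))
  raster_grid(
    matrix(v, nrow(map$values), ncol(map$values)),
    map$cell_size, map$origin, map$crs
  )
}
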