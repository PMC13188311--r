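## Confusion-matrix comparison of TABS categorization against a
## thresholded continuous metric: PPV/NPV, threshold sweeps, optimal
## threshold and flexibility categories.
##
## Orientation (fixed and documented): TABS equality of a conformer pair
## is the condition (ground truth), the thresholded metric is the
## predictor.  For a similarity metric the pair is predicted "same" when
## value >= threshold; for a distance metric when value <= threshold.

#' Confusion counts over conformer pairs
#'
#' @param TP,FP,TN,FN non-negative pair tallies.
#' @return object of class `ConfusionCounts` (a named integer vector).
#' @export
confusionCounts <- function(TP = 0L, FP = 0L, TN = 0L, FN = 0L) {
  x <- c(TP = as.integer(TP), FP = as.integer(FP),
         TN = as.integer(TN), FN = as.integer(FN))
  stopifnot(all(x >= 0L))
  class(x) <- "ConfusionCounts"
  x
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x[["TP"]], x[["FP"]], x[["TN"]], x[["FN"]], sum(x)))
  invisible(x)
}

#' Positive and negative predictive value
#'
#' `PPV = TP / (TP + FP)` and `NPV = TN / (TN + FN)`.  When a denominator
#' is zero the corresponding value is undefined and reported as `NA`,
#' never coerced to 0 or 1.  PPV = NPV = 1 means the two categorizations
#' agree completely.
#'
#' @param counts a [confusionCounts()] object (or named vector with
#'   TP/FP/TN/FN).
#' @return named numeric vector `c(PPV =, NPV =)`, possibly containing NA.
#' @examples
#' ppvNpv(confusionCounts(TP = 3, FP = 1, TN = 4, FN = 1))  # 0.75, 0.80
#' @export
ppvNpv <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0L) tn / (tn + fn) else NA_real_
  c(PPV = ppv, NPV = npv)
}

.predict_same <- function(values, threshold, direction) {
  direction <- match.arg(direction, c("similarity", "distance"))
  if (direction == "similarity") values >= threshold else values <= threshold
}

#' Confusion counts of a pair table at one threshold
#'
#' Every unordered conformer pair is labeled same/different twice: by TABS
#' equality (condition) and by the thresholded metric (prediction).
#' TP = same by both, TN = different by both, FP = metric-same but
#' TABS-different, FN = metric-different but TABS-same.
#'
#' @param pairs data.frame with columns `i`, `j` (conformer ids) and
#'   `value` (metric value), one row per unordered pair.
#' @param labels named character vector mapping conformer id to TABS label.
#' @param threshold metric threshold.
#' @param direction `"similarity"` (higher = more similar, predict same
#'   when value >= threshold) or `"distance"` (predict same when
#'   value <= threshold).
#' @return a [confusionCounts()] object.
#' @export
confusionAtThreshold <- function(pairs, labels, threshold,
                                 direction = c("similarity", "distance")) {
  direction <- match.arg(direction)
  stopifnot(all(c("i", "j", "value") %in% names(pairs)))
  ids <- unique(c(as.character(pairs$i), as.character(pairs$j)))
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("conformers without TABS labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  truth_same <- labels[as.character(pairs$i)] == labels[as.character(pairs$j)]
  pred_same <- .predict_same(pairs$value, threshold, direction)
  confusionCounts(TP = sum(truth_same & pred_same),
                  FP = sum(!truth_same & pred_same),
                  TN = sum(!truth_same & !pred_same),
                  FN = sum(truth_same & !pred_same))
}

#' Sweep PPV/NPV over a threshold grid
#'
#' @inheritParams confusionAtThreshold
#' @param grid sorted numeric vector of thresholds; by default 101 evenly
#'   spaced points over the observed metric range.
#' @return data.frame with one row per threshold: `threshold`, `TP`, `FP`,
#'   `TN`, `FN`, `PPV`, `NPV` (undefined values as NA).
#' @export
sweepThresholds <- function(pairs, labels, grid = NULL,
                            direction = c("similarity", "distance")) {
  direction <- match.arg(direction)
  if (is.null(grid))
    grid <- seq(min(pairs$value), max(pairs$value), length.out = 101L)
  stopifnot(length(grid) >= 1L, !is.unsorted(grid))
  rows <- lapply(grid, function(th) {
    cc <- confusionAtThreshold(pairs, labels, th, direction)
    pn <- ppvNpv(cc)
    data.frame(threshold = th, TP = cc[["TP"]], FP = cc[["FP"]],
               TN = cc[["TN"]], FN = cc[["FN"]],
               PPV = pn[["PPV"]], NPV = pn[["NPV"]])
  })
  do.call(rbind, rows)
}

#' Optimal metric threshold from a sweep table
#'
#' Selects the threshold that jointly maximizes PPV and NPV.  The default
#' criterion is the symmetric scalarization max over thresholds of
#' min(PPV, NPV); `"product"` maximizes PPV * NPV, and `"fixed-npv"`
#' maximizes PPV among rows with NPV >= `npvFloor`.  Rows with an
#' undefined PPV or NPV are excluded.  Ties are broken toward the larger
#' threshold for similarity metrics (the stricter "same" call) and toward
#' the smaller threshold for distance metrics.
#'
#' @param sweep a data.frame from [sweepThresholds()].
#' @param direction `"similarity"` or `"distance"` (tie-break side).
#' @param criterion `"min"`, `"product"` or `"fixed-npv"`.
#' @param npvFloor NPV floor for `criterion = "fixed-npv"`.
#' @return the selected threshold (numeric scalar).
#' @export
optimalThreshold <- function(sweep, direction = c("similarity", "distance"),
                             criterion = c("min", "product", "fixed-npv"),
                             npvFloor = 0.9) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  ok <- !is.na(sweep$PPV) & !is.na(sweep$NPV)
  if (criterion == "fixed-npv") ok <- ok & sweep$NPV >= npvFloor
  if (!any(ok))
    stop("no threshold with both PPV and NPV defined", call. = FALSE)
  sub <- sweep[ok, , drop = FALSE]
  score <- switch(criterion,
                  "min" = pmin(sub$PPV, sub$NPV),
                  "product" = sub$PPV * sub$NPV,
                  "fixed-npv" = sub$PPV)
  best <- which(score == max(score))
  th <- sub$threshold[best]
  if (direction == "similarity") max(th) else min(th)
}

#' Flexibility category of a molecule from its nTABS
#'
#' Molecules are grouped as low flexibility (nTABS < 500), medium
#' (500 <= nTABS < 10,000) or high (nTABS >= 10,000).
#'
#' @param ntabs an nTABS value: numeric or [bigInteger()].
#' @return one of `"low"`, `"medium"`, `"high"`.
#' @examples
#' flexibilityCategory(499)    # "low"
#' flexibilityCategory(500)    # "medium"
#' flexibilityCategory(10000)  # "high"
#' @export
flexibilityCategory <- function(ntabs) {
  x <- bigInteger(ntabs)
  if (biCompare(x, bigInteger(1)) < 0L) stop("nTABS must be >= 1", call. = FALSE)
  if (biCompare(x, bigInteger(500)) < 0L) return("low")
  if (biCompare(x, bigInteger(10000)) < 0L) return("medium")
  "high"
}

#' Read a pairwise score table from CSV
#'
#' Expected columns: `conf_i`, `conf_j`, `value` (or `i`, `j`, `value`).
#'
#' @param path CSV path.
#' @return data.frame with columns `i`, `j`, `value`.
#' @export
readPairScores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("conf_i", "conf_j") %in% names(df))) {
    df <- data.frame(i = df$conf_i, j = df$conf_j, value = df$value,
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("i", "j", "value") %in% names(df)))
  df
}
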