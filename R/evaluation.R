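## Evaluation: confusion matrices (rows = predicted, columns = true),
## per-class and macro precision/recall/F1, replicate mean +/- SE.

#' Build a confusion matrix
#'
#' `counts[p, t]` counts samples of true class `t` predicted as `p`: rows
#' are the predicted category, columns the true category, so column sums are
#' the per-class test counts.
#'
#' @param trueLabels,predictedLabels Equal-length label vectors.
#' @param classOrder Class order of both dimensions; defaults to the sorted
#'   union of observed labels.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, classOrder = NULL) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stopf("label vectors must have equal length")
  if (is.null(classOrder))
    classOrder <- sort(unique(c(trueLabels, predictedLabels)))
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), classOrder)
  if (length(unknown))
    stopf("labels not in classOrder: %s", paste(unknown, collapse = ", "))
  K <- length(classOrder)
  m <- matrix(0L, K, K, dimnames = list(predicted = classOrder,
                                        true = classOrder))
  t <- table(factor(predictedLabels, classOrder),
             factor(trueLabels, classOrder))
  m[] <- as.integer(t)
  new("ConfusionMatrix", countsMatrix = m, classOrder = classOrder)
}

#' Per-class and macro precision, recall and F1
#'
#' For class `k`: `TP = counts[k, k]`, `FP = rowSum_k - TP`,
#' `FN = colSum_k - TP`; `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`. A 0/0 ratio is defined as 0 with a warning, and such
#' never-predicted-never-present classes are flagged in the `excluded`
#' column. Macro averages are unweighted means over all classes; micro
#' averages (equal to accuracy for single-label classification) are also
#' reported.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return A [MetricsReport-class].
#' @export
precisionRecallF1 <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- counts(cm)
  K <- nrow(m)
  tp <- diag(m)
  fp <- rowSums(m) - tp
  fn <- colSums(m) - tp
  ratio0 <- function(num, den, what) {
    r <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning(sprintf("%s undefined (0/0) for %d class(es); reported as 0",
                      what, sum(den == 0)), call. = FALSE)
    r
  }
  P <- ratio0(tp, tp + fp, "precision")
  R <- ratio0(tp, tp + fn, "recall")
  F1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  excluded <- (tp + fp + fn) == 0
  perClass <- data.frame(class = classOrder(cm), precision = P, recall = R,
                         f1 = F1, support = colSums(m), excluded = excluded,
                         row.names = NULL, stringsAsFactors = FALSE)
  micro <- sum(tp) / sum(m)
  new("MetricsReport", perClass = perClass,
      macro = c(precision = mean(P), recall = mean(R), f1 = mean(F1)),
      micro = c(precision = micro, recall = micro, f1 = micro),
      accuracy = sum(tp) / sum(m))
}

#' Replicate mean and standard error
#'
#' @param values Numeric vector of replicate results (`n >= 2`).
#' @param convention `"sample"` (default): SE = sample SD (n-1 denominator)
#'   / sqrt(n); `"population"`: population SD (n denominator) / sqrt(n).
#'   Published mean +/- SE tables do not always state which SD they used, so
#'   both are available.
#' @return Named numeric: `mean`, `se`, `n`.
#' @export
replicateSummary <- function(values, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  n <- length(values)
  if (n < 2L) stopf("replicateSummary: need at least 2 values")
  s <- switch(convention,
    sample = sd(values),
    population = sqrt(mean((values - mean(values))^2)))
  c(mean = mean(values), se = s / sqrt(n), n = n)
}

#' Write metrics to JSON and CSV
#'
#' @param report A [MetricsReport-class].
#' @param cm Optional [ConfusionMatrix-class] to include.
#' @param jsonPath,csvPath Output paths (either may be `NULL`).
#' @return `jsonPath`, invisibly.
#' @export
writeMetrics <- function(report, cm = NULL, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(csvPath)) write.csv(report@perClass, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    out <- list(accuracy = report@accuracy, macro = as.list(report@macro),
                micro = as.list(report@micro), perClass = report@perClass)
    if (!is.null(cm))
      out$confusion <- list(classOrder = classOrder(cm),
                            counts = counts(cm))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(jsonPath)
}

#' Export a confusion-matrix heatmap as PNG
#'
#' Column-normalized counts rendered on a white-to-blue ramp, upscaled by
#' `cell` pixels per class.
#'
#' @param cm A [ConfusionMatrix-class].
#' @param path Output PNG path.
#' @param cell Pixels per matrix cell.
#' @return `path`, invisibly.
#' @export
writeConfusionHeatmap <- function(cm, path, cell = 12L) {
  m <- counts(cm)
  cs <- colSums(m)
  norm <- sweep(m, 2L, pmax(cs, 1L), "/")
  ramp <- colorRampPalette(c("white", "#2166ac"))(256L)
  idx <- matrix(pmin(255L, as.integer(norm * 255)) + 1L, nrow(m))
  rgbv <- col2rgb(ramp[idx]) / 255
  K <- nrow(m)
  img <- array(0, c(K, K, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgbv[ch, ], K, K)
  big <- img[rep(seq_len(K), each = cell), rep(seq_len(K), each = cell), ,
             drop = FALSE]
  writeImageFile(big, path)
}
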