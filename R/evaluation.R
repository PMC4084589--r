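# Accuracy, binary and one-versus-all AUC, and the two testing protocols
# (stratified 10-fold cross-validation; fixed train/test split), with an
# audit log proving that normalization and tuning never touch test rows.

#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return Fraction of correctly classified samples.
#' @export
accuracyScore <- function(predicted, truth) {
  if (!length(truth)) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  mean(as.character(predicted) == as.character(truth))
}

#' Binary area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half; higher scores
#' indicate the positive class.
#'
#' @param scores numeric scores.
#' @param truth logical (or two-level) vector; `TRUE` / the second level is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
aucBinary <- function(scores, truth) {
  if (is.logical(truth)) pos <- truth else {
    f <- as.factor(truth)
    if (nlevels(f) != 2L) stop("binary AUC needs exactly two classes present")
    pos <- f == levels(f)[2]
  }
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' One-versus-all multiclass AUC
#'
#' The unweighted mean of per-class one-vs-rest binary AUCs; classes absent
#' from the truth are skipped with a warning.
#'
#' @param scoreMatrix n x K score matrix with class-named columns.
#' @param truth label vector.
#' @return Mean one-vs-rest AUC.
#' @export
aucOvr <- function(scoreMatrix, truth) {
  truth <- as.character(truth)
  classes <- colnames(scoreMatrix)
  if (is.null(classes)) stop("score matrix must have class-named columns")
  aucs <- c()
  for (cl in classes) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) {
      warning("class '", cl, "' absent from truth (or exhaustive); skipped")
      next
    }
    aucs <- c(aucs, aucBinary(scoreMatrix[, cl], pos))
  }
  if (!length(aucs)) stop("no evaluable classes")
  mean(aucs)
}

#' Stratified cross-validation fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold ids (1..k), class-stratified and size-balanced
#'   within one sample.
#' @export
cvFolds <- function(labels, k = 10L, seed = 1L) {
  stratifiedFolds(labels, k, seed)
}

#' Run a testing protocol over a fusion recipe
#'
#' Cross-validation (`"cv10"`) or fixed train/test split (`"holdout"`).
#' Within every fold the per-component normalizers and the SVM grid search
#' are (re)fit on the training portion only; test rows are used exactly
#' once, for scoring. The audit log records the row sets each training
#' stage touched, so train/test isolation is assertable.
#'
#' @param tables named list of feature matrices (all rows), e.g. from
#'   [ensembleFeatureTables()]; a single matrix is treated as a one-table
#'   list.
#' @param labels class labels, one per row.
#' @param weights numeric fusion weights, one per table (default: equal).
#' @param protocol `"cv10"` or `"holdout"`.
#' @param seed integer seed (fold assignment, tuning, SVM fits).
#' @param split for `"holdout"`: character vector of `"train"` / `"test"`
#'   per row.
#' @param folds number of cross-validation folds (default 10).
#' @param ... passed to [trainClassifier()] (grid, tuneFolds, scoreType).
#' @return An [EvaluationResult-class]; per-fold metrics are averaged into
#'   the headline accuracy and one-versus-all AUC.
#' @export
runProtocol <- function(tables, labels, weights = NULL,
                        protocol = c("cv10", "holdout"), seed = 1L,
                        split = NULL, folds = 10L, ...) {
  protocol <- match.arg(protocol)
  if (is.matrix(tables) || is.data.frame(tables)) tables <- list(as.matrix(tables))
  tables <- lapply(tables, as.matrix)
  labels <- as.factor(labels)
  n <- length(labels)
  if (any(vapply(tables, nrow, integer(1)) != n))
    stop("all feature tables must have one row per label")
  if (is.null(weights)) weights <- rep(1, length(tables))
  if (length(weights) != length(tables))
    stop("one weight per feature table required")

  if (protocol == "cv10") {
    fold <- cvFolds(labels, folds, seed)
    if (min(table(labels)) < folds)
      warning("some folds will miss a class: smallest class has fewer ",
              "samples than folds")
    foldIds <- sort(unique(fold))
  } else {
    if (is.null(split)) stop("holdout protocol requires a declared split")
    if (!all(split %in% c("train", "test")))
      stop("split entries must be 'train' or 'test'")
    fold <- ifelse(split == "test", 1L, 0L)
    foldIds <- 1L
  }

  audit <- data.frame(fold = integer(0), component = character(0),
                      stage = character(0), rows = character(0))
  note <- function(f, comp, stage, rows) {
    audit <<- rbind(audit, data.frame(
      fold = f, component = comp, stage = stage,
      rows = paste(rows, collapse = ",")))
  }
  perFold <- data.frame(fold = integer(0), accuracy = numeric(0),
                        auc = numeric(0))
  for (f in foldIds) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    if (nlevels(droplevels(labels[trainIdx])) < nlevels(labels) ||
        nlevels(droplevels(labels[testIdx])) < 1L)
      stop("stratification failure: a class is missing from fold ", f)
    scoreMats <- vector("list", length(tables))
    for (ti in seq_along(tables)) {
      comp <- if (!is.null(names(tables))) names(tables)[ti] else
        paste0("table", ti)
      norm <- fitNormalizer(tables[[ti]][trainIdx, , drop = FALSE])
      note(f, comp, "normalizer", trainIdx)
      xtr <- applyNormalizer(norm, tables[[ti]][trainIdx, , drop = FALSE])
      model <- trainClassifier(xtr, labels[trainIdx], seed = seed, ...)
      note(f, comp, "grid_search_and_fit", trainIdx)
      xte <- applyNormalizer(norm, tables[[ti]][testIdx, , drop = FALSE])
      scoreMats[[ti]] <- predictScores(model, xte)
      note(f, comp, "score_test", testIdx)
    }
    fused <- weightedSumFusion(scoreMats, weights)
    pred <- colnames(fused)[max.col(fused, ties.method = "first")]
    acc <- accuracyScore(pred, labels[testIdx])
    auc <- if (nlevels(labels) == 2L) {
      aucBinary(fused[, levels(labels)[2]],
                labels[testIdx] == levels(labels)[2])
    } else {
      aucOvr(fused, labels[testIdx])
    }
    perFold <- rbind(perFold, data.frame(fold = f, accuracy = acc, auc = auc))
  }
  new("EvaluationResult",
      accuracy = mean(perFold$accuracy),
      auc = mean(perFold$auc),
      perFold = perFold,
      protocol = protocol,
      audit = audit)
}

#' Audit log of an evaluation
#' @param result an [EvaluationResult-class].
#' @return data.frame with columns fold, component, stage, rows.
#' @export
auditLog <- function(result) {
  stopifnot(is(result, "EvaluationResult"))
  result@audit
}

#' Count train/test leaks recorded in an audit log
#'
#' For every fold, checks that no training stage (normalizer fitting, grid
#' search, model fitting) touched a row that the same fold scored as test.
#'
#' @param result an [EvaluationResult-class].
#' @return Number of leaked row usages (0 means clean isolation).
#' @export
auditLeakCount <- function(result) {
  audit <- auditLog(result)
  leaks <- 0L
  for (f in unique(audit$fold)) {
    a <- audit[audit$fold == f, ]
    testRows <- unique(unlist(lapply(
      strsplit(a$rows[a$stage == "score_test"], ","), as.integer)))
    trainStages <- a[a$stage != "score_test", ]
    for (i in seq_len(nrow(trainStages))) {
      used <- as.integer(strsplit(trainStages$rows[i], ",")[[1]])
      leaks <- leaks + length(intersect(used, testRows))
    }
  }
  leaks
}
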