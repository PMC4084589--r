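# Per-descriptor SVM training with train-only [0,1] normalization and
# grid-search tuning, one-versus-all multiclass, and weighted sum-rule
# fusion of classifier score matrices.

#' Fit a [0,1] normalizer on training rows
#'
#' Learns per-column minima and maxima from the training rows only; see
#' [applyNormalizer()] for the mapping.
#'
#' @param train numeric feature matrix (training rows only).
#' @return A [NormalizerState-class].
#' @export
fitNormalizer <- function(train) {
  train <- as.matrix(train)
  if (!nrow(train)) stop("cannot fit a normalizer on an empty table")
  new("NormalizerState",
      min = apply(train, 2, min),
      max = apply(train, 2, max))
}

#' Apply a fitted [0,1] normalizer
#'
#' Maps each column linearly so the training range becomes `[0, 1]`;
#' values outside the training range are clipped, and columns that were
#' constant in training map to 0 everywhere (keeping column alignment
#' across splits).
#'
#' @param state a [NormalizerState-class] from [fitNormalizer()].
#' @param table numeric feature matrix.
#' @return Normalized matrix of the same shape.
#' @export
applyNormalizer <- function(state, table) {
  table <- as.matrix(table)
  if (ncol(table) != length(state@min))
    stop("table has ", ncol(table), " columns; normalizer expects ",
         length(state@min))
  span <- state@max - state@min
  out <- sweep(table, 2, state@min)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], "/")
  out[, !nz] <- 0
  clamp(out, 0, 1)
}

#' The hyperparameter grid for SVM tuning
#'
#' Default is the classical coarse grid: cost 2^-5..2^15 and RBF kernel
#' width 2^-15..2^3, both in powers of 4. A gamma entry of `NA` stands for
#' the reciprocal feature dimension (1/ncol), resolved at training time —
#' convenient when one grid serves descriptors of very different widths.
#'
#' @param cost,gamma numeric vectors of candidate values.
#' @return List with `cost` and `gamma`.
#' @export
svmGrid <- function(cost = 2^seq(-5, 15, by = 2),
                    gamma = 2^seq(-15, 3, by = 2)) {
  list(cost = as.numeric(cost), gamma = as.numeric(gamma))
}

# stratified k-fold assignment (a permutation within each class, dealt
# round-robin into folds)
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# fit one-vs-all binary SVMs, one per class
fitOva <- function(x, y, cost, gamma, probability = FALSE, seed = NULL) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    withSeed(seed,
      e1071::svm(x, yy, type = "C-classification", kernel = "radial",
                 cost = cost, gamma = gamma, probability = probability,
                 scale = FALSE))
  })
  names(models) <- classes
  models
}

ovaScores <- function(models, x, scoreType) {
  classes <- names(models)
  out <- sapply(classes, function(cl) {
    fit <- models[[cl]]
    if (scoreType == "probability") {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      pr[, "pos"]
    } else {
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")
      # orient so larger means "pos"
      if (colnames(dv)[1] == "pos/rest") dv[, 1] else -dv[, 1]
    }
  })
  out <- matrix(out, nrow = nrow(as.matrix(x)), dimnames = list(NULL, classes))
  out
}

#' Train a tuned one-versus-all SVM classifier
#'
#' Radial-basis-kernel SVMs (libsvm via e1071), one binary machine per
#' class, with hyperparameters chosen by internal stratified
#' cross-validated grid search on the training rows only. Ties are broken
#' toward the smallest cost, then the smallest kernel width. Feature
#' normalization is the caller's responsibility (see [fitNormalizer()]).
#'
#' @param x numeric feature matrix (training rows).
#' @param y class labels (>= 2 classes).
#' @param seed integer seed driving fold assignment and the SVM fits.
#' @param grid hyperparameter grid from [svmGrid()].
#' @param tuneFolds internal cross-validation folds (default 5).
#' @param scoreType score scale for [predictScores()]: `"probability"`
#'   (Platt class-posterior estimates, the default, so that heterogeneous
#'   classifiers are commensurable under the sum rule) or `"decision"`
#'   (raw margin values).
#' @return An object of class `"svmOvaClassifier"`.
#' @export
trainClassifier <- function(x, y, seed = 1L, grid = svmGrid(),
                            tuneFolds = 5L,
                            scoreType = c("probability", "decision")) {
  scoreType <- match.arg(scoreType)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  tuneFolds <- min(tuneFolds, min(table(y)))
  grid$gamma[is.na(grid$gamma)] <- 1 / ncol(x)
  combos <- expand.grid(gamma = grid$gamma, cost = grid$cost)
  combos <- combos[order(combos$cost, combos$gamma), , drop = FALSE]
  best <- combos[1, ]
  if (nrow(combos) > 1L && tuneFolds >= 2L) {
    fold <- stratifiedFolds(y, tuneFolds, seed)
    acc <- vapply(seq_len(nrow(combos)), function(ci) {
      hits <- 0L
      for (f in seq_len(tuneFolds)) {
        tr <- fold != f
        models <- fitOva(x[tr, , drop = FALSE], y[tr],
                         cost = combos$cost[ci], gamma = combos$gamma[ci],
                         seed = seed)
        sc <- ovaScores(models, x[!tr, , drop = FALSE], "decision")
        pred <- colnames(sc)[max.col(sc, ties.method = "first")]
        hits <- hits + sum(pred == as.character(y[!tr]))
      }
      hits / length(y)
    }, numeric(1))
    best <- combos[which.max(acc), ]   # first max: smallest cost, then gamma
  }
  models <- fitOva(x, y, cost = best$cost, gamma = best$gamma,
                   probability = scoreType == "probability", seed = seed)
  structure(list(models = models, classes = levels(y),
                 cost = best$cost, gamma = best$gamma,
                 scoreType = scoreType, dim = ncol(x), seed = seed),
            class = "svmOvaClassifier")
}

#' @export
print.svmOvaClassifier <- function(x, ...) {
  cat(sprintf(
    "One-vs-all RBF SVM: %d classes, %d features, cost = %g, gamma = %g (%s scores)\n",
    length(x$classes), x$dim, x$cost, x$gamma, x$scoreType))
  invisible(x)
}

#' Per-class score matrix of a trained classifier
#'
#' @param model a classifier from [trainClassifier()] or
#'   [propertyEnsemble()].
#' @param table numeric feature matrix (already normalized like the
#'   training table).
#' @return n x K numeric matrix of per-class scores (columns named by
#'   class).
#' @export
predictScores <- function(model, table) UseMethod("predictScores")

#' @export
predictScores.svmOvaClassifier <- function(model, table) {
  table <- as.matrix(table)
  if (ncol(table) != model$dim)
    stop("feature dimension ", ncol(table), " does not match model (",
         model$dim, ")")
  ovaScores(model$models, table, model$scoreType)
}

#' Weighted sum-rule fusion of score matrices
#'
#' `fused = sum_c w_c * scores_c`; all matrices must share shape and class
#' columns.
#'
#' @param scoreMatrices list of n x K score matrices.
#' @param weights numeric weights, one per matrix.
#' @return Fused n x K score matrix.
#' @export
weightedSumFusion <- function(scoreMatrices, weights) {
  if (length(scoreMatrices) != length(weights))
    stop("one weight per score matrix required")
  ref <- dim(scoreMatrices[[1]])
  for (m in scoreMatrices) {
    if (!identical(dim(m), ref)) stop("score matrices differ in shape")
  }
  Reduce(`+`, Map(function(m, w) w * m, scoreMatrices, weights))
}

#' Ensemble over randomly selected physicochemical properties
#'
#' Trains one classifier per property on the property-specific variant of
#' a descriptor and fuses the components with unit weights. Each
#' component gets its own train-only normalizer.
#'
#' @param seqs list of [ProteinRecord-class] (or strings).
#' @param labels class labels, one per sequence.
#' @param descriptorFun function `(seq, property) ->`
#'   [DescriptorVector-class] (e.g. [autocovarianceDescriptor()]).
#' @param properties list of [PhysicochemicalProperty-class] objects.
#' @param seed integer seed.
#' @param ... passed to [trainClassifier()].
#' @return An object of class `"propertyEnsembleClassifier"`.
#' @export
propertyEnsemble <- function(seqs, labels, descriptorFun, properties,
                             seed = 1L, ...) {
  if (!length(properties)) stop("empty property list")
  components <- lapply(properties, function(d) {
    feats <- t(vapply(seqs, function(s) featureValues(descriptorFun(s, d)),
                      featureValues(descriptorFun(seqs[[1]], d))))
    norm <- fitNormalizer(feats)
    model <- trainClassifier(applyNormalizer(norm, feats), labels,
                             seed = seed, ...)
    list(property = d, normalizer = norm, model = model,
         descriptorFun = descriptorFun)
  })
  structure(list(components = components, seed = seed),
            class = "propertyEnsembleClassifier")
}

#' @export
predictScores.propertyEnsembleClassifier <- function(model, table) {
  # table: list of sequences
  mats <- lapply(model$components, function(comp) {
    feats <- t(vapply(table,
                      function(s) featureValues(comp$descriptorFun(s, comp$property)),
                      numeric(comp$model$dim)))
    predictScores(comp$model, applyNormalizer(comp$normalizer, feats))
  })
  weightedSumFusion(mats, rep(1, length(mats)))
}

#' The FUS1 fusion recipe
#'
#' Eight components over three representations with fixed weights:
#' 2 x AAS(AC) + 2 x PSSM(SAN) + 4 x PSSM(PP) + PSSM(LHF_G) + PSSM(BGR) +
#' PSSM(TGR) + SMR(PP) + SMR(BGR).
#'
#' @return An [EnsembleSpec-class].
#' @export
fus1Spec <- function() {
  EnsembleSpec(
    representation = c("AAS", "PSSM", "PSSM", "PSSM", "PSSM", "PSSM",
                       "SMR", "SMR"),
    descriptor = c("AC", "SAN", "PP", "LHF_G", "BGR", "TGR", "PP", "BGR"),
    weight = c(2, 2, 4, 1, 1, 1, 1, 1))
}

#' The FUS2 fusion recipe
#'
#' FUS1 plus a ninth component from the tertiary-structure distance
#' matrix: `FUS1 + 2 x DM(LPQ_G)`. Requires backbone coordinates.
#'
#' @return An [EnsembleSpec-class].
#' @export
fus2Spec <- function() {
  comp <- ensembleComponents(fus1Spec())
  EnsembleSpec(
    representation = c(comp$representation, "DM"),
    descriptor = c(comp$descriptor, "LPQ_G"),
    weight = c(comp$weight, 2))
}

#' The reduced-alphabet n-gram fusion recipe
#'
#' Five components, one per reduced alphabet A1..A5, fused with weights
#' (1, 1, 1, 0.5, 0.25).
#'
#' @return An [EnsembleSpec-class].
#' @export
ngFusionSpec <- function() {
  EnsembleSpec(
    representation = rep("AAS", 5),
    descriptor = paste0("NG-A", 1:5),
    weight = c(1, 1, 1, 0.5, 0.25))
}

#' Compute the feature tables required by a fusion recipe
#'
#' Maps every (representation, descriptor) component of an
#' [EnsembleSpec-class] onto the package's extractors and returns one
#' feature matrix per component, keyed `"REP(DESC)"`. Components sharing a
#' key reuse the same table.
#'
#' @param records list of [ProteinRecord-class].
#' @param spec an [EnsembleSpec-class].
#' @param profiles list of [ProfileMatrix-class] PSSMs matched to
#'   `records` (required for PSSM components).
#' @param property a [PhysicochemicalProperty-class] for property-based
#'   descriptors (AC).
#' @param substitution a [SubstitutionMatrix-class] for SMR components
#'   (default [dayhoffMatrix()]).
#' @param backbones list of coordinate matrices for DM components.
#' @return Named list of numeric feature matrices.
#' @export
ensembleFeatureTables <- function(records, spec, profiles = NULL,
                                  property = NULL,
                                  substitution = dayhoffMatrix(),
                                  backbones = NULL) {
  comp <- ensembleComponents(spec)
  keys <- unique(paste0(comp$representation, "(", comp$descriptor, ")"))
  stackDesc <- function(lst) do.call(rbind, lapply(lst, featureValues))
  repMatrix <- function(rep, i) {
    switch(rep,
      PSSM = {
        if (is.null(profiles)) stop("PSSM components need profile matrices")
        profiles[[i]]
      },
      SMR = buildSmr(records[[i]], substitution),
      stop("unsupported representation: ", rep))
  }
  out <- lapply(keys, function(key) {
    rep <- sub("\\(.*$", "", key)
    desc <- sub("^.*\\(", "", sub("\\)$", "", key))
    n <- length(records)
    if (rep == "AAS" && desc == "AC") {
      if (is.null(property)) stop("AAS(AC) needs a physicochemical property")
      stackDesc(lapply(records, autocovarianceDescriptor, d = property))
    } else if (rep == "DM" && desc == "LPQ_G") {
      if (is.null(backbones)) stop("DM components need backbone coordinates")
      stackDesc(lapply(backbones, function(b) lpq(buildDm(b))))
    } else {
      stackDesc(lapply(seq_len(n), function(i) {
        mat <- repMatrix(rep, i)
        switch(desc,
          SAN = singleAverage(mat, records[[i]], normalize = TRUE),
          SA = singleAverage(mat, records[[i]]),
          PP = pseudoPssm(mat),
          AB = averageBlocks(mat),
          AM = autocovarianceMatrix(mat),
          LHF_G = lbpHf(mat),
          LPQ_G = lpq(mat),
          BGR = ngramMatrix(mat)$bgr,
          TGR = ngramMatrix(mat)$tgr,
          stop("unsupported descriptor: ", desc))
      }))
    }
  })
  names(out) <- keys
  out
}
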