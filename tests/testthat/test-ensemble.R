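smallGrid <- svmGrid(cost = c(1, 8), gamma = c(NA, 0.5))

test_that("the [0,1] normalizer learns from training rows and clips test values", {
  tr <- cbind(c(0, 5, 10), c(3, 3, 3))
  st <- fitNormalizer(tr)
  out <- applyNormalizer(st, tr)
  expect_equal(out[, 1], c(0, 0.5, 1))
  expect_equal(out[, 2], c(0, 0, 0))   # constant column maps to 0
  te <- applyNormalizer(st, cbind(c(-2, 12), c(9, 1)))
  expect_equal(te[, 1], c(0, 1))       # clipped
  expect_true(all(te >= 0 & te <= 1))
  expect_error(applyNormalizer(st, cbind(1)), "columns")
  expect_error(fitNormalizer(matrix(nrow = 0, ncol = 2)), "empty")
})

test_that("grid-searched SVMs separate a constructed two-blob problem", {
  set.seed(51)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 5), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  st <- fitNormalizer(x)
  model <- trainClassifier(applyNormalizer(st, x), y, seed = 2,
                           grid = smallGrid, tuneFolds = 3)
  sc <- predictScores(model, applyNormalizer(st, x))
  expect_identical(dim(sc), c(100L, 2L))
  expect_true(all(is.finite(sc)))
  expect_equal(accuracyScore(colnames(sc)[max.col(sc)], y), 1)
  # same seed twice: identical selected hyperparameters
  model2 <- trainClassifier(applyNormalizer(st, x), y, seed = 2,
                            grid = smallGrid, tuneFolds = 3)
  expect_identical(c(model$cost, model$gamma), c(model2$cost, model2$gamma))
  expect_error(trainClassifier(x, rep("a", 100)), "single class")
})

test_that("shuffled labels give chance-level internal accuracy", {
  set.seed(52)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- sample(rep(c("a", "b"), each = 100))
  res <- runProtocol(x, y, protocol = "cv10", seed = 4,
                     grid = svmGrid(cost = 1, gamma = NA))
  # binomial noise around 0.5 at n = 200
  expect_gt(res@auc, 0.35)
  expect_lt(res@auc, 0.65)
})

test_that("weighted sum fusion obeys its algebra", {
  a <- matrix(1:6, 3, 2, dimnames = list(NULL, c("x", "y")))
  b <- matrix(6:1, 3, 2, dimnames = list(NULL, c("x", "y")))
  expect_equal(weightedSumFusion(list(a), 1), a)
  expect_equal(weightedSumFusion(list(a, b), c(1, 0)), a)
  f <- weightedSumFusion(list(a, b), c(2, 3))
  expect_equal(f, 2 * a + 3 * b)
  # positive rescaling keeps decisions
  g <- weightedSumFusion(list(a, b), c(4, 6))
  expect_identical(max.col(f), max.col(g))
  # commutative under equal weights
  expect_equal(weightedSumFusion(list(b, a), c(1, 1)),
               weightedSumFusion(list(a, b), c(1, 1)))
  expect_error(weightedSumFusion(list(a, b[1:2, ]), c(1, 1)), "shape")
  expect_error(weightedSumFusion(list(a, b), 1), "weight")
})

test_that("property ensembles fuse per-property classifiers additively", {
  ds <- twoClassDataset(nPerClass = 15, lengthRange = c(30, 40), seed = 53)
  props <- selectRandomProperties(aaindexProperties(), 2, seed = 54)
  single <- propertyEnsemble(ds$records, ds$labels, autocovarianceDescriptor,
                             props[1], seed = 5, grid = svmGrid(cost = 8, gamma = NA))
  dup <- propertyEnsemble(ds$records, ds$labels, autocovarianceDescriptor,
                          c(props[1], props[1]), seed = 5,
                          grid = svmGrid(cost = 8, gamma = NA))
  s1 <- predictScores(single, ds$records)
  s2 <- predictScores(dup, ds$records)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
  both <- propertyEnsemble(ds$records, ds$labels, autocovarianceDescriptor,
                           props, seed = 5, grid = svmGrid(cost = 8, gamma = NA))
  expect_length(both$components, 2)
  expect_error(propertyEnsemble(ds$records, ds$labels,
                                autocovarianceDescriptor, list(), seed = 1),
               "empty")
})

test_that("the published fusion recipes carry the printed components and weights", {
  f1 <- ensembleComponents(fus1Spec())
  expect_identical(nrow(f1), 8L)
  expect_equal(f1$weight, c(2, 2, 4, 1, 1, 1, 1, 1))
  expect_identical(f1$descriptor,
                   c("AC", "SAN", "PP", "LHF_G", "BGR", "TGR", "PP", "BGR"))
  expect_identical(f1$representation,
                   c("AAS", "PSSM", "PSSM", "PSSM", "PSSM", "PSSM", "SMR", "SMR"))
  f2 <- ensembleComponents(fus2Spec())
  expect_identical(nrow(f2), 9L)
  expect_identical(f2[1:8, ], f1)
  expect_identical(f2$representation[9], "DM")
  expect_identical(f2$descriptor[9], "LPQ_G")
  expect_equal(f2$weight[9], 2)
  ng <- ensembleComponents(ngFusionSpec())
  expect_identical(nrow(ng), 5L)
  expect_equal(ng$weight, c(1, 1, 1, 0.5, 0.25))
  expect_true(all(f1$weight >= 0) && all(f2$weight >= 0) && all(ng$weight >= 0))
})

test_that("feature tables for a recipe have the declared widths", {
  ds <- twoClassDataset(nPerClass = 3, lengthRange = c(40, 50), seed = 55)
  prop <- realProperty()
  tabs <- ensembleFeatureTables(ds$records, fus1Spec(), profiles = ds$profiles,
                                property = prop)
  expect_identical(sort(names(tabs)),
                   sort(c("AAS(AC)", "PSSM(SAN)", "PSSM(PP)", "PSSM(LHF_G)",
                          "PSSM(BGR)", "PSSM(TGR)", "SMR(PP)", "SMR(BGR)")))
  widths <- vapply(tabs, ncol, integer(1))
  expect_equal(unname(widths[c("AAS(AC)", "PSSM(SAN)", "PSSM(PP)",
                               "PSSM(LHF_G)", "PSSM(BGR)", "PSSM(TGR)")]),
               c(40L, 400L, 320L, 176L, 400L, 8000L))
  expect_true(all(vapply(tabs, nrow, integer(1)) == 6L))
  expect_error(ensembleFeatureTables(ds$records, fus1Spec(), property = prop),
               "profile")
  expect_error(ensembleFeatureTables(ds$records, fus2Spec(),
                                     profiles = ds$profiles, property = prop),
               "backbone")
})
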