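# Literal nested-loop transcriptions of the printed formulas, kept
# deliberately naive and separate from the vectorized implementations.

abOracle <- function(m) {
  n <- nrow(m)
  b <- round((0:20) * n / 20)
  out <- numeric(400)
  for (i in 1:20) for (j in 1:20) {
    rows <- (b[i] + 1):b[i + 1]
    out[j + 20 * (i - 1)] <- mean(m[rows, j])
  }
  out
}

amOracle <- function(m) {
  n <- nrow(m)
  out <- numeric(300)
  for (j in 1:20) for (lag in 1:15) {
    mu <- mean(m[, j])
    s <- 0
    for (i in 1:(n - lag)) s <- s + (m[i, j] - mu) * (m[i + lag, j] - mu)
    out[j + 20 * (lag - 1)] <- s / (n - lag)
  }
  out
}

ppOracle <- function(m, strict = FALSE) {
  n <- nrow(m)
  E <- matrix(0, n, 20)
  for (i in 1:n) {
    mu <- mean(m[i, ])
    v <- mean((m[i, ] - mu)^2)
    den <- if (strict) v else sqrt(v)
    if (den > 0) E[i, ] <- (m[i, ] - mu) / den
  }
  out <- numeric(320)
  for (j in 1:20) out[j] <- mean(E[, j])
  for (j in 1:20) for (lag in 1:15) {
    s <- 0
    for (i in 1:(n - lag)) s <- s + (E[i, j] - E[i + lag, j])^2
    out[20 + j + 20 * (lag - 1)] <- s / (n - lag)
  }
  out
}

bgrTgrOracle <- function(m) {
  n <- nrow(m)
  bgr <- numeric(400)
  for (i in 1:20) for (j in 1:20) {
    s <- 0
    for (z in 1:(n - 1)) s <- s + m[z, i] * m[z + 1, j]
    bgr[(i - 1) * 20 + j] <- s
  }
  tgr <- numeric(8000)
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    s <- 0
    for (z in 1:(n - 2)) s <- s + m[z, i] * m[z + 1, j] * m[z + 2, k]
    tgr[(i - 1) * 400 + (j - 1) * 20 + k] <- s
  }
  list(bgr = bgr, tgr = tgr)
}

test_that("average blocks equal block means and shift with constants", {
  cmat <- matrix(4.2, 37, 20)
  expect_equal(featureValues(averageBlocks(cmat)), rep(4.2, 400))
  m <- randomMatrix(40, seed = 21)
  ab <- featureValues(averageBlocks(m))
  expect_length(ab, 400)
  expect_equal(ab, abOracle(m), tolerance = 1e-12)
  # N = 40: each block averages exactly two rows
  expect_equal(ab[1], mean(m[1:2, 1]))
  # commutes with adding a constant
  expect_equal(featureValues(averageBlocks(m + 3)), ab + 3, tolerance = 1e-12)
  # odd sizes still give 20 nonempty blocks
  for (n in c(20, 23, 59)) {
    expect_length(featureValues(averageBlocks(randomMatrix(n, seed = n))), 400)
  }
  expect_error(averageBlocks(randomMatrix(19)), "20")
})

test_that("single average groups rows by residue, with sigmoid variant", {
  v <- rnorm(20)
  m <- matrix(v, 4, 20, byrow = TRUE)
  sa <- featureValues(singleAverage(m, "AAAA"))
  expect_equal(sa[1:20], v)
  expect_equal(sa[21:400], rep(0, 380))
  # grouping is position blind
  m2 <- randomMatrix(10, seed = 22)
  s <- "ACDCAYYKLM"
  perm <- sample(10)
  expect_equal(
    featureValues(singleAverage(m2[perm, ], paste(strsplit(s, "")[[1]][perm], collapse = ""))),
    featureValues(singleAverage(m2, s)))
  # sigmoid normalization maps zeros to 1/2
  san <- featureValues(singleAverage(matrix(0, 4, 20), "AAAA", normalize = TRUE))
  expect_equal(san[1:20], rep(0.5, 20))
  expect_error(singleAverage(m2, "AC"), "match")
})

test_that("matrix autocovariance matches its printed double loop", {
  m <- randomMatrix(30, seed = 23)
  am <- featureValues(autocovarianceMatrix(m))
  expect_length(am, 300)
  expect_equal(am, amOracle(m), tolerance = 1e-12)
  # constant column contributes zero at every lag
  m[, 5] <- 2
  am2 <- featureValues(autocovarianceMatrix(m))
  expect_equal(am2[5 + 20 * (0:14)], rep(0, 15))
  expect_error(autocovarianceMatrix(randomMatrix(15)), "15")
})

test_that("pseudo-PSSM standardizes rows and accumulates squared lag differences", {
  m <- randomMatrix(30, seed = 24)
  pp <- featureValues(pseudoPssm(m))
  expect_length(pp, 320)
  expect_equal(pp, ppOracle(m), tolerance = 1e-12)
  expect_equal(featureValues(pseudoPssm(m, strict = TRUE)), ppOracle(m, TRUE),
               tolerance = 1e-12)
  # identical rows: all lag differences vanish
  same <- matrix(rnorm(20), 25, 20, byrow = TRUE)
  expect_equal(featureValues(pseudoPssm(same))[21:320], rep(0, 300),
               tolerance = 1e-12)
  # invariance to a per-row additive constant (absorbed by centering)
  shift <- m + matrix(rnorm(30), 30, 20) * 0 + rnorm(30)
  expect_equal(featureValues(pseudoPssm(shift))[21:320], pp[21:320],
               tolerance = 1e-9)
  # zero-variance rows map to zero with a warning
  m[3, ] <- 7
  expect_warning(ppz <- pseudoPssm(m), "zero-variance")
  expect_true(all(is.finite(featureValues(ppz))))
})

test_that("singular values are ordered, padded, and energy preserving", {
  expect_equal(featureValues(svdDescriptor(diag(20))), rep(1, 20))
  u <- rnorm(15); v <- rnorm(8)
  sv <- featureValues(svdDescriptor(outer(u, v)))
  expect_equal(sv[1], sqrt(sum(u^2)) * sqrt(sum(v^2)), tolerance = 1e-9)
  expect_equal(sv[-1], rep(0, 7), tolerance = 1e-9)
  m <- randomMatrix(26, seed = 25)
  d <- featureValues(svdDescriptor(m, padTo = 25))
  expect_length(d, 25)
  expect_equal(sum(d^2), sum(m^2), tolerance = 1e-9)
  expect_false(is.unsorted(rev(d)))
})

test_that("the cosine transform keeps the low-frequency block and is orthonormal", {
  expect_length(featureValues(dctDescriptor(randomMatrix(30, seed = 26))), 400)
  cmat <- matrix(3, 25, 20)
  dc <- featureValues(dctDescriptor(cmat))
  expect_gt(abs(dc[1]), 0)
  expect_equal(dc[-1], rep(0, 399), tolerance = 1e-9)
  # full-transform round trip
  m <- randomMatrix(24, seed = 27)
  expect_equal(protclass:::idct2(protclass:::dct2(m)), m, tolerance = 1e-9)
  # small matrices are zero-padded
  expect_length(featureValues(dctDescriptor(randomMatrix(8, 5, seed = 28))), 400)
})

test_that("profile n-grams match the printed accumulation and recover hard counts", {
  m <- randomMatrix(18, seed = 29)
  got <- ngramMatrix(m)
  oracle <- bgrTgrOracle(m)
  expect_equal(featureValues(got$bgr), oracle$bgr, tolerance = 1e-12)
  expect_equal(featureValues(got$tgr), oracle$tgr, tolerance = 1e-12)
  # one-hot rows: the soft 2-gram equals raw pair counts of the sequence
  s <- "ACDCAYKL"
  res <- strsplit(s, "")[[1]]
  onehot <- matrix(0, length(res), 20)
  onehot[cbind(seq_along(res), aaIndexOf(res))] <- 1
  bgr <- matrix(featureValues(ngramMatrix(onehot)$bgr), 20, 20, byrow = TRUE)
  h <- matrix(0, 20, 20)
  for (p in 1:(length(res) - 1)) {
    i <- aaIndexOf(res[p]); j <- aaIndexOf(res[p + 1])
    h[i, j] <- h[i, j] + 1
  }
  expect_equal(bgr, h)
  # bilinearity of the 2-gram accumulation: B(a+2b) expands as the
  # bilinear form B(x, y) = sum_z x(z,i) y(z+1,j) demands
  crossBgr <- function(x, y) {
    n <- nrow(x)
    as.vector(t(t(x[1:(n - 1), ]) %*% y[2:n, ]))
  }
  a <- randomMatrix(12, seed = 30); b <- randomMatrix(12, seed = 31)
  expect_equal(featureValues(ngramMatrix(a + 2 * b)$bgr),
               crossBgr(a, a) + 2 * crossBgr(a, b) + 2 * crossBgr(b, a) +
                 4 * crossBgr(b, b),
               tolerance = 1e-9)
  expect_equal(featureValues(ngramMatrix(matrix(0, 5, 20))$tgr), rep(0, 8000))
  expect_error(ngramMatrix(randomMatrix(2)), "3 rows")
})

test_that("matrix descriptor oracles agree across many random profiles", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(16:60, 1)
    m <- matrix(rnorm(n * 20), n, 20)
    if (n >= 20) expect_equal(featureValues(averageBlocks(m)), abOracle(m),
                              tolerance = 1e-12)
    expect_equal(featureValues(autocovarianceMatrix(m)), amOracle(m),
                 tolerance = 1e-12)
    expect_equal(featureValues(pseudoPssm(m)), ppOracle(m), tolerance = 1e-12)
    o <- bgrTgrOracle(m)
    got <- ngramMatrix(m)
    expect_equal(featureValues(got$bgr), o$bgr, tolerance = 1e-10)
    expect_equal(featureValues(got$tgr), o$tgr, tolerance = 1e-10)
  }
})
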