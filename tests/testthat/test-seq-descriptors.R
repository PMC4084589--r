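# Independent brute-force counting oracles, written against the raw
# residue strings rather than the package's tabulation code.

countPairsOracle <- function(res, m = 1) {
  h <- matrix(0, 20, 20, dimnames = list(aaAlphabet(), aaAlphabet()))
  n <- length(res)
  if (n > m) for (p in 1:(n - m)) {
    h[res[p], res[p + m]] <- h[res[p], res[p + m]] + 1
  }
  h
}

test_that("amino-acid composition counts fractions over the fixed alphabet", {
  expect_equal(featureValues(aacDescriptor("AAAA")), c(1, rep(0, 19)))
  v <- featureValues(aacDescriptor("ACDC"))
  expect_equal(v[1:3], c(0.25, 0.5, 0.25))
  for (s in randomSequences(20, seed = 1)) {
    f <- featureValues(aacDescriptor(s))
    expect_equal(sum(f), 1)
    # permutation invariance
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(featureValues(aacDescriptor(perm)), f)
  }
})

test_that("2-gram counts match a brute-force substring oracle and are order sensitive", {
  g <- featureValues(twoGramDescriptor("AAA"))
  expect_length(g, 400)
  expect_equal(g[1], 2 / 3)
  expect_equal(sum(g), 2 / 3)
  for (s in randomSequences(60, seed = 2)) {
    res <- strsplit(s, "")[[1]]
    expected <- as.vector(t(countPairsOracle(res))) / length(res)
    expect_equal(featureValues(twoGramDescriptor(s)), expected)
    expect_equal(sum(featureValues(twoGramDescriptor(s))),
                 (length(res) - 1) / length(res))
  }
  # a transposition changes the descriptor (unlike composition)
  expect_false(isTRUE(all.equal(featureValues(twoGramDescriptor("ACD")),
                                featureValues(twoGramDescriptor("ADC")))))
})

test_that("the quasi-residue couple accumulates property sums over three orders", {
  d <- toyProperty(1:20)
  q <- featureValues(qrcDescriptor("AAAA", d))
  expect_length(q, 1200)
  expect_equal(q[1], 2 * 1)   # (A,A) at m=1: (x + x) * 3 / 3 with x = 1
  # blocks for m = 2, 3 of "AAAA": counts 2/2 and 1/1 -> also 2x
  expect_equal(q[401], 2)
  expect_equal(q[801], 2)
  # absent couples stay zero
  expect_equal(q[2], 0)
  # brute-force oracle on random sequences
  v <- propertyValues(d)
  for (s in randomSequences(10, lengths = 5:30, seed = 3)) {
    res <- strsplit(s, "")[[1]]
    got <- featureValues(qrcDescriptor(s, d))
    for (m in 1:3) {
      h <- countPairsOracle(res, m)
      expected <- (h * outer(v, v, `+`)) / (length(res) - m)
      expect_equal(got[(400 * (m - 1) + 1):(400 * m)],
                   as.vector(t(expected)), tolerance = 1e-12)
    }
  }
  expect_error(qrcDescriptor("AAA", d), "at least 4")
})

test_that("the autocovariance descriptor extends composition with lag terms", {
  d <- realProperty()
  rec <- randomProtein(50, seed = 4)
  ac <- featureValues(autocovarianceDescriptor(rec, d))
  expect_length(ac, 40)
  expect_equal(ac[1:20], featureValues(aacDescriptor(rec)))
  # brute-force lag terms
  st <- propertyStats(d)
  x <- propertyValues(d)[strsplit(proteinSequence(rec), "")[[1]]] - st[["mu"]]
  n <- length(x)
  for (lag in c(1, 7, 20)) {
    expected <- sum(x[1:(n - lag)] * x[(1 + lag):n]) / (st[["sigma"]] * (n - lag))
    expect_equal(ac[20 + lag], expected, tolerance = 1e-12)
  }
  # residues sitting exactly at the property mean: lag terms vanish
  dmean <- toyProperty(c(11, 2:20), "MEANA")   # mean of all 20 values is 11
  acc <- featureValues(autocovarianceDescriptor(strrep("A", 30), dmean))
  expect_equal(acc[21:40], rep(0, 20))
  expect_error(autocovarianceDescriptor(rec, toyProperty(rep(1, 20))),
               "degenerate")
  expect_error(autocovarianceDescriptor(randomProtein(20, seed = 1), d), "length")
})

test_that("AAIndexLoc concatenates composition, weighted composition, and group dipeptides", {
  d <- realProperty()
  rec <- randomProtein(40, seed = 5)
  aa <- featureValues(aaindexLocDescriptor(rec, d))
  expect_length(aa, 65)
  expect_equal(aa[1:20], featureValues(aacDescriptor(rec)))
  expect_equal(aa[21:40],
               featureValues(aacDescriptor(rec)) * unname(propertyValues(d)))
  expect_equal(sum(aa[41:65]), 1)   # (N-1) group pairs, normalized
  # pure-A sequence: weighted block has index(A, d) at A only
  aaA <- featureValues(aaindexLocDescriptor("AAAA", d))
  expect_equal(aaA[21], unname(propertyValues(d)["A"]))
  expect_equal(aaA[22:40], rep(0, 19))
  # deterministic across calls (seeded k-means)
  expect_equal(featureValues(aaindexLocDescriptor(rec, d)), aa)
})

test_that("global encoding enumerates 10 partitions with consistent measures", {
  parts <- globalEncodingPartitions()
  expect_length(parts, 10)
  expect_true(all(vapply(parts, function(p) p[1] == 1 && length(p) == 3, TRUE)))
  ge <- featureValues(globalEncodingDescriptor("ACDC"))
  expect_length(ge, 40)
  # freq(0) + freq(1) = 1 per characteristic sequence
  for (p in 1:10) expect_equal(ge[4 * p - 3] + ge[4 * p - 2], 1)
  # all-A: class A1 is always in the first subset, so all-ones, no transitions
  geA <- featureValues(globalEncodingDescriptor(strrep("A", 12)))
  for (p in 1:10) {
    expect_equal(geA[4 * p - 2], 1)            # freq of 1s
    expect_equal(geA[4 * p - 1] + geA[4 * p], 0)  # transitions
  }
  # segmentation depth grows the dimension as 40 (2^depth - 1)
  expect_length(featureValues(globalEncodingDescriptor(randomProtein(30), depth = 2)), 120)
})

test_that("physicochemical 2-grams weight pair counts by the property", {
  d <- toyProperty(1:20)
  p <- featureValues(p2gDescriptor("AA", d))
  expect_length(p, 800)
  expect_equal(p[1], 1)   # h(A,A) * index(A) / (N-1) = 1 * 1 / 1
  expect_equal(p[2], 1)
  expect_equal(sum(p != 0), 2)
  # brute-force oracle
  v <- propertyValues(d)
  for (s in randomSequences(40, seed = 6)) {
    res <- strsplit(s, "")[[1]]
    h <- countPairsOracle(res)
    n <- length(res)
    exp1 <- as.vector(t(h * outer(unname(v), rep(1, 20)))) / (n - 1)
    exp2 <- as.vector(t(h * outer(rep(1, 20), unname(v)))) / (n - 1)
    got <- featureValues(p2gDescriptor(s, d))
    expect_equal(got[seq(1, 799, 2)], exp1, tolerance = 1e-12)
    expect_equal(got[seq(2, 800, 2)], exp2, tolerance = 1e-12)
  }
})

test_that("reduced-alphabet n-grams have the published dimensions and match counting oracles", {
  dims <- c(A1 = 400, A2 = 225, A3 = 512, A4 = 125, A5 = 64)
  rec <- randomProtein(40, seed = 7)
  for (a in names(dims)) {
    expect_length(featureValues(ngramDescriptor(rec, a)), dims[[a]])
  }
  # A1 is the full alphabet: equals the 2-gram descriptor after mapping the
  # group ordering back to alphabetical
  a1order <- c("G", "I", "V", "F", "Y", "W", "A", "L", "M", "E",
               "Q", "R", "K", "P", "N", "D", "H", "S", "T", "C")
  perm <- match(a1order, aaAlphabet())
  for (s in randomSequences(20, seed = 8)) {
    ng <- matrix(featureValues(ngramDescriptor(s, "A1")), 20, 20, byrow = TRUE)
    tg <- matrix(featureValues(twoGramDescriptor(s)), 20, 20, byrow = TRUE)
    expect_equal(ng, tg[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  }
  # residues all in the LVIMC group collapse onto the (1,1,1) cell
  lv <- featureValues(ngramDescriptor("LVLVL", "A3"))
  expect_equal(sum(lv != 0), 1)
  expect_equal(lv[1], 3 / 5)   # three 3-grams, normalized by N
  # brute-force 3-gram oracle for A4
  groupsA4 <- list(c("L","V","I","M","C"), c("A","S","G","T","P"),
                   c("F","Y","W"), c("E","D","N","Q"), c("K","R","H"))
  gmap <- integer(20); names(gmap) <- aaAlphabet()
  for (g in seq_along(groupsA4)) gmap[groupsA4[[g]]] <- g
  for (s in randomSequences(20, lengths = 3:40, seed = 9)) {
    res <- strsplit(s, "")[[1]]
    g <- gmap[res]
    counts <- numeric(125)
    for (p in 1:(length(g) - 2)) {
      l <- (g[p] - 1) * 25 + (g[p + 1] - 1) * 5 + g[p + 2]
      counts[l] <- counts[l] + 1
    }
    expect_equal(featureValues(ngramDescriptor(s, "A4")), counts / length(g),
                 tolerance = 1e-12)
  }
})

test_that("split composition cuts N-terminus, middle, and C-terminus", {
  s <- paste0(strrep("A", 20), strrep("C", 10), strrep("D", 20))
  v <- featureValues(sacDescriptor(s))
  expect_length(v, 60)
  expect_equal(v[1], 1)    # N-terminal block pure A
  expect_equal(v[20 + 2], 1)  # middle block pure C
  expect_equal(v[40 + 3], 1)  # C-terminal block pure D
  expect_equal(sum(v[1:20]), 1)
  expect_equal(sum(v[41:60]), 1)
  # short sequence: empty middle encodes as zeros
  short <- featureValues(sacDescriptor(strrep("A", 30)))
  expect_equal(short[21:40], rep(0, 20))
  expect_equal(sum(short[1:20]), 1)
})

test_that("the discrete-wavelet descriptor has 13 features per level with the expected structure", {
  d <- realProperty()
  rec <- randomProtein(60, seed = 10)
  dw <- featureValues(discreteWaveletDescriptor(rec, d))
  expect_length(dw, 52)
  # constant profile: all detail statistics vanish
  flat <- featureValues(discreteWaveletDescriptor(strrep("A", 40),
                                                  toyProperty(rep(3, 20))))
  for (l in 0:3) {
    expect_equal(flat[l * 13 + 10:13], rep(0, 4), tolerance = 1e-12)
  }
  # linearity: scaling the property scales all features (std by |c|)
  d3 <- PhysicochemicalProperty("x", propertyValues(d) * 2.5)
  expect_equal(featureValues(discreteWaveletDescriptor(rec, d3)), dw * 2.5,
               tolerance = 1e-9)
  expect_error(discreteWaveletDescriptor(strrep("A", 10), d), "16")
})

test_that("the biorthogonal filter bank reproduces an independently computed decomposition", {
  # frozen from an independent PyWavelets evaluation: dwt(1:20, 'bior3.3',
  # mode='symmetric')
  dec <- protclass:::bior33Dwt(as.numeric(1:20), levels = 1L)
  expect_equal(dec$approx[[1]],
               c(3.535533905932738, 0.7071067811865477, 3.535533905932738,
                 6.3639610306789285, 9.19238815542512, 12.020815280171309,
                 14.849242404917495, 17.67766952966369, 20.506096654409877,
                 23.33452377915607, 26.16295090390226, 28.991378028648448,
                 26.162950903902264), tolerance = 1e-12)
  expect_equal(dec$detail[[1]], rep(0, 13), tolerance = 1e-12)
  # second frozen case: two-level decomposition of a sine-plus-ramp signal
  x <- sin((0:31) * 0.3) + (0:31) * 0.1
  dec2 <- protclass:::bior33Dwt(x, levels = 2L)
  expect_equal(dec2$approx[[2]][1:5],
               c(-0.3292299359, 1.6683611471, -0.3292299359, 3.3461935187,
                 3.0153524293), tolerance = 1e-8)
  expect_equal(dec2$detail[[2]][1:5],
               c(-0.4368739722, 0, 0.4368739722, 0.0113833513, -0.0443163126),
               tolerance = 1e-8)
})

test_that("sequence descriptors are finite on random canonical sequences", {
  d <- realProperty()
  for (s in randomSequences(20, lengths = 41:80, seed = 11)) {
    vals <- c(featureValues(aacDescriptor(s)),
              featureValues(twoGramDescriptor(s)),
              featureValues(qrcDescriptor(s, d)),
              featureValues(autocovarianceDescriptor(s, d)),
              featureValues(aaindexLocDescriptor(s, d)),
              featureValues(globalEncodingDescriptor(s)),
              featureValues(p2gDescriptor(s, d)),
              featureValues(sacDescriptor(s)),
              featureValues(discreteWaveletDescriptor(s, d)))
    expect_true(all(is.finite(vals)))
  }
})
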