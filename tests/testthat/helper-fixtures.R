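# Shared fixtures, all built in code. Deterministic via fixed seeds.

toyProperty <- function(values = 1:20, id = "TOY") {
  PhysicochemicalProperty(id, values)
}

# a real, well-behaved amino-acid index (hydration-like scale) from the
# bundled table, for tests that want realistic magnitudes
realProperty <- function(i = 2L) {
  aaindexProperties()[[i]]
}

randomSequences <- function(n, lengths = 2:50, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(lengths, 1)
    paste(sample(aaAlphabet(), len, replace = TRUE), collapse = "")
  })
}

randomMatrix <- function(n, m = 20, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m)
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

gaussBlur <- function(m, sigma = 1) {
  x <- -3:3
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- 3
  mp <- m[c(rep(1, pad), seq_len(nrow(m)), rep(nrow(m), pad)),
          c(rep(1, pad), seq_len(ncol(m)), rep(ncol(m), pad))]
  protclass:::sepFilterValid(mp, k, k)
}

chisqDist <- function(p, q) sum((p - q)^2 / (p + q + 1e-12))

extdata <- function(file) system.file("extdata", file, package = "protclass")
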