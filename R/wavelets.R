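# Wavelet machinery: Meyer continuous transform (frequency-domain
# definition) and a biorthogonal 3.3 discrete filter bank. No wavelet
# package is required; both constructions are small and fully deterministic.

# Meyer auxiliary polynomial, C^3 smooth on [0, 1].
meyerNu <- function(x) {
  x <- clamp(x, 0, 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Magnitude of the Meyer mother wavelet in the frequency domain; supported
# on 2*pi/3 <= |w| <= 8*pi/3 and vanishing at w = 0 (so constants transform
# to exactly zero).
meyerPsiHat <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  b1 <- aw >= 2 * pi / 3 & aw <= 4 * pi / 3
  b2 <- aw > 4 * pi / 3 & aw <= 8 * pi / 3
  out[b1] <- sin(pi / 2 * meyerNu(3 * aw[b1] / (2 * pi) - 1))
  out[b2] <- cos(pi / 2 * meyerNu(3 * aw[b2] / (4 * pi) - 1))
  out / sqrt(2 * pi)
}

#' Continuous Meyer wavelet transform over a set of scales
#'
#' Computed in the Fourier domain with circular boundary handling:
#' coefficient row a is Re(ifft(fft(x) * sqrt(a) * conj(psiHat(a w)))).
#'
#' @param x numeric signal.
#' @param scales numeric vector of scales.
#' @return length(scales) x length(x) coefficient matrix.
#' @keywords internal
meyerCwt <- function(x, scales) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  w <- 2 * pi * k / n
  w[w > pi] <- w[w > pi] - 2 * pi
  out <- matrix(0, length(scales), n)
  for (s in seq_along(scales)) {
    a <- scales[s]
    filt <- sqrt(a) * meyerPsiHat(a * w)
    out[s, ] <- Re(stats::fft(X * filt, inverse = TRUE)) / n
  }
  out
}

# Biorthogonal 3.3 analysis filter bank (exact rationals times sqrt(2)):
# lowpass sqrt(2)/64 * (3,-9,-7,45,45,-7,-9,3),
# highpass sqrt(2)/8 * (0,0,-1,3,-3,1,0,0).
bior33DecLo <- function() sqrt(2) / 64 * c(3, -9, -7, 45, 45, -7, -9, 3)
bior33DecHi <- function() sqrt(2) / 8 * c(0, 0, -1, 3, -3, 1, 0, 0)

# One analysis step: half-point symmetric padding by (filter length - 1),
# full convolution, then downsampling by two starting at the filter length
# + 1 phase. Output length is floor((n + filterLength - 1) / 2).
dwtStep <- function(x, filt) {
  n <- length(x)
  p <- length(filt) - 1L
  left <- rev(x[seq_len(min(p, n))])
  right <- rev(x[seq.int(max(1L, n - p + 1L), n)])
  while (length(left) < p) left <- c(left, rev(left))[seq_len(p)]
  while (length(right) < p) right <- c(right, rev(right))[seq_len(p)]
  xp <- c(left, x, right)
  z <- stats::convolve(xp, rev(filt), type = "open")
  z[seq.int(length(filt) + 1L, by = 2L, length.out = (n + p) %/% 2L)]
}

#' Multilevel biorthogonal 3.3 wavelet decomposition
#'
#' @param x numeric signal (length >= 2^levels recommended).
#' @param levels number of decomposition levels.
#' @return List with `approx` and `detail`, each a list of per-level
#'   coefficient vectors (level 1 = finest).
#' @keywords internal
bior33Dwt <- function(x, levels = 4L) {
  lo <- bior33DecLo()
  hi <- bior33DecHi()
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    if (length(cur) < 2L)
      stop("signal too short for ", levels, "-level wavelet decomposition")
    approx[[l]] <- dwtStep(cur, lo)
    detail[[l]] <- dwtStep(cur, hi)
    cur <- approx[[l]]
  }
  list(approx = approx, detail = detail)
}
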