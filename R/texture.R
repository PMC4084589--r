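# Image-texture descriptors on protein matrices treated as grayscale
# images: rotation-invariant LBP histogram Fourier features and
# blur-robust local phase quantization, each extracted globally or on
# three horizontal subwindows.

#' Scale a protein matrix to an 8-bit-range grayscale image
#'
#' Min-max scales any numeric matrix to the `[0, 255]` intensity range
#' expected by the texture operators; a constant matrix maps to mid-gray
#' (127.5).
#'
#' @param mat matrix, [ProfileMatrix-class], [SquareProteinImage-class] or
#'   [Scalogram-class].
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
asGrayImage <- function(mat) {
  m <- if (is(mat, "Scalogram")) scalogramImage(mat) else as.matrix(mat)
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(127.5, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

padToSize <- function(img, minRows, minCols) {
  if (nrow(img) >= minRows && ncol(img) >= minCols) return(img)
  out <- matrix(0, max(nrow(img), minRows), max(ncol(img), minCols))
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

# Interpolated neighbor plane: img sampled at (i + dy, j + dx) for every
# interior center (i, j), bilinear interpolation.
sampleShifted <- function(img, dy, dx, rows, cols) {
  y <- rows + dy
  x <- cols + dx
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0;   fx <- x - x0
  # tolerate exact-integer offsets at the image border
  y0 <- pmin(y0, nrow(img) - 1L); x0 <- pmin(x0, ncol(img) - 1L)
  fy <- y - y0; fx <- x - x0
  w00 <- outer(1 - fy, 1 - fx)
  w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx)
  w11 <- outer(fy, fx)
  img[y0, x0, drop = FALSE] * w00 + img[y0, x0 + 1L, drop = FALSE] * w01 +
    img[y0 + 1L, x0, drop = FALSE] * w10 + img[y0 + 1L, x0 + 1L, drop = FALSE] * w11
}

# Orbit-structured uniform LBP histogram for one (P, R) parameterization:
# a (P - 1) x P matrix of uniform-pattern bins h[n, r] (n ones starting at
# rotation r) plus the all-zeros, all-ones, and non-uniform bins.
lbpOrbitHistogram <- function(img, P, R) {
  pad <- ceiling(R) + 1L
  if (nrow(img) < 2 * pad + 1L || ncol(img) < 2 * pad + 1L)
    stop("image too small for LBP with radius ", R)
  rows <- (pad + 1L):(nrow(img) - pad)
  cols <- (pad + 1L):(ncol(img) - pad)
  center <- img[rows, cols, drop = FALSE]
  nc <- length(rows) * length(cols)
  bits <- matrix(0L, nc, P)
  eps <- 1e-9
  for (k in 0:(P - 1)) {
    theta <- 2 * pi * k / P
    dy <- -R * sin(theta)
    dx <- R * cos(theta)
    nb <- sampleShifted(img, dy, dx, rows, cols)
    bits[, k + 1L] <- as.integer(nb >= center - eps)
  }
  nxt <- cbind(bits[, 2:P, drop = FALSE], bits[, 1, drop = FALSE])
  transitions <- rowSums(bits != nxt)
  ones <- rowSums(bits)
  h <- matrix(0, P - 1, P)     # h[n, r]: run of n ones starting at offset r
  uniform <- transitions <= 2L
  run <- uniform & ones > 0L & ones < P
  if (any(run)) {
    # start of the run of ones: bit k is 1 and predecessor is 0
    prev <- cbind(bits[, P, drop = FALSE], bits[, 1:(P - 1), drop = FALSE])
    isStart <- bits == 1L & prev == 0L
    startIdx <- max.col(isStart[run, , drop = FALSE], ties.method = "first") - 1L
    tab <- table(factor(ones[run], levels = 1:(P - 1)),
                 factor(startIdx, levels = 0:(P - 1)))
    h <- h + matrix(as.numeric(tab), P - 1, P)
  }
  list(h = h / nc,
       zeros = sum(uniform & ones == 0L) / nc,
       onesFull = sum(uniform & ones == P) / nc,
       nonUniform = sum(!uniform) / nc)
}

#' LBP histogram Fourier descriptor (176 values)
#'
#' Uniform local-binary-pattern histograms are made rotation invariant by
#' taking discrete-Fourier-transform magnitudes along each orbit of
#' rotated uniform patterns: per parameterization (P, R) this gives
#' `(P - 1)(P/2 + 1)` magnitudes plus the all-zeros, all-ones, and
#' non-uniform bins. The default parameterizations (P = 16, R = 2) and
#' (P = 8, R = 1) contribute 138 + 38 = 176 features.
#'
#' @param img a [SquareProteinImage-class], [ProfileMatrix-class],
#'   [Scalogram-class] or numeric matrix; intensities are min-max scaled
#'   via [asGrayImage()]. Small matrices are zero-padded to the minimum
#'   window size.
#' @param params list of `c(P, R)` parameterizations.
#' @return A [DescriptorVector-class] (tag "LHF").
#' @export
lbpHf <- function(img, params = list(c(16, 2), c(8, 1))) {
  g <- asGrayImage(img)
  feats <- unlist(lapply(params, function(pr) {
    P <- as.integer(pr[1]); R <- pr[2]
    minSide <- 2L * (ceiling(R) + 1L) + 1L
    hist <- lbpOrbitHistogram(padToSize(g, minSide, minSide), P, R)
    mags <- unlist(lapply(seq_len(P - 1), function(n) {
      Mod(stats::fft(hist$h[n, ]))[1:(P / 2 + 1)]
    }))
    c(mags, hist$zeros, hist$onesFull, hist$nonUniform)
  }))
  DescriptorVector(feats, "LHF")
}

# 1-D Gaussian-windowed STFT filters at relative frequency alpha for a
# window of half-width r.
lpqFilters <- function(r) {
  x <- -r:r
  winSize <- 2 * r + 1
  alpha <- 1 / winSize
  sigma <- winSize / 4
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  w1 <- g * exp(-2i * pi * x * alpha)
  list(w0 = g + 0i, w1 = w1)
}

lpqCodes <- function(img, r, whiten = FALSE, rho = 0.9) {
  f <- lpqFilters(r)
  # four frequency points: (a, 0), (0, a), (a, a), (a, -a)
  resp <- list(
    sepFilterValid(img, f$w1, f$w0),
    sepFilterValid(img, f$w0, f$w1),
    sepFilterValid(img, f$w1, f$w1),
    sepFilterValid(img, f$w1, Conj(f$w1)))
  vals <- do.call(cbind, lapply(resp, function(m) cbind(Re(as.vector(m)),
                                                        Im(as.vector(m)))))
  if (whiten) {
    x <- -r:r
    n <- length(x)
    pos <- expand.grid(y = x, x = x)
    C <- rho^as.matrix(stats::dist(pos))        # pixel correlation model
    filt2d <- list(outer(f$w1, f$w0), outer(f$w0, f$w1),
                   outer(f$w1, f$w1), outer(f$w1, Conj(f$w1)))
    M <- do.call(rbind, lapply(filt2d, function(k) {
      v <- as.vector(k)
      rbind(Re(v), Im(v))
    }))
    D <- M %*% C %*% t(M)
    V <- svd(D)$u
    vals <- vals %*% V
  }
  bits <- vals >= 0
  as.vector(bits %*% 2^(0:7))
}

#' Local phase quantization descriptor (512 values)
#'
#' Short-term Fourier phase is estimated in a Gaussian-windowed
#' neighborhood around every pixel at four low frequencies; the signs of
#' the 8 real/imaginary parts are packed into a byte and collected into a
#' normalized 256-bin histogram. The histograms for the two window radii
#' (default 3 and 5) are concatenated (2 x 256 = 512).
#'
#' @param img image input as in [lbpHf()]; zero-padded to the minimum
#'   window size if smaller.
#' @param radii window radii.
#' @param whiten apply the decorrelation/whitening transform (correlation
#'   coefficient `rho`); off by default for determinism.
#' @param rho pixel correlation coefficient used when whitening.
#' @return A [DescriptorVector-class] (tag "LPQ").
#' @export
lpq <- function(img, radii = c(3, 5), whiten = FALSE, rho = 0.9) {
  g <- asGrayImage(img)
  feats <- unlist(lapply(radii, function(r) {
    win <- 2L * r + 1L
    codes <- lpqCodes(padToSize(g, win, win), r, whiten = whiten, rho = rho)
    tabulate(codes + 1L, nbins = 256L) / length(codes)
  }))
  DescriptorVector(feats, "LPQ")
}

#' Local (three-subwindow) texture extraction
#'
#' Splits the image into three equal horizontal bands (remainder rows go to
#' the last band), applies a global texture operator to each band, and
#' concatenates the three descriptors top to bottom.
#'
#' @param img image input as in [lbpHf()].
#' @param baseOp a function taking an image matrix and returning a
#'   [DescriptorVector-class] (e.g. [lbpHf()] or [lpq()]).
#' @param ... passed to `baseOp`.
#' @return A [DescriptorVector-class] of three times the base dimension,
#'   tag "<base>_L".
#' @export
local3 <- function(img, baseOp, ...) {
  g <- if (is(img, "Scalogram")) scalogramImage(img) else as.matrix(img)
  n <- nrow(g)
  if (n < 3L) stop("local texture extraction needs at least 3 rows")
  third <- n %/% 3L
  bands <- list(g[1:third, , drop = FALSE],
                g[(third + 1):(2 * third), , drop = FALSE],
                g[(2 * third + 1):n, , drop = FALSE])
  parts <- lapply(bands, function(b) baseOp(b, ...))
  DescriptorVector(unlist(lapply(parts, featureValues)),
                   paste0(descriptorId(parts[[1]]), "_L"))
}
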