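#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package functions never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to run with the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear resize of a numeric matrix
#'
#' Align-corners bilinear interpolation: target pixel (r, c) samples the
#' source at ((r-1)(R-1)/(nr-1)+1, (c-1)(C-1)/(nc-1)+1). Because rows and
#' columns use the same mapping, symmetric square matrices stay symmetric
#' exactly (up to floating point).
#'
#' @param mat numeric matrix.
#' @param nrow,ncol target size.
#' @return `nrow` x `ncol` numeric matrix.
#' @keywords internal
bilinearResize <- function(mat, nrow, ncol) {
  weights1d <- function(nsrc, ntarget) {
    if (ntarget == 1 || nsrc == 1) {
      w <- matrix(0, ntarget, nsrc)
      w[, 1] <- 1
      return(w)
    }
    pos <- (seq_len(ntarget) - 1) * (nsrc - 1) / (ntarget - 1) + 1
    lo <- pmin(floor(pos), nsrc - 1)
    frac <- pos - lo
    w <- matrix(0, ntarget, nsrc)
    w[cbind(seq_len(ntarget), lo)] <- w[cbind(seq_len(ntarget), lo)] + (1 - frac)
    w[cbind(seq_len(ntarget), lo + 1)] <- w[cbind(seq_len(ntarget), lo + 1)] + frac
    w
  }
  wr <- weights1d(base::nrow(mat), nrow)
  wc <- weights1d(base::ncol(mat), ncol)
  wr %*% mat %*% t(wc)
}

#' Orthonormal DCT-II matrix
#' @param n transform length.
#' @return n x n matrix `C` such that `C %*% x` is the orthonormal DCT-II of x.
#' @keywords internal
dctMatrix <- function(n) {
  k <- 0:(n - 1)
  m <- 0:(n - 1)
  C <- cos(pi * outer(k, 2 * m + 1) / (2 * n))
  C <- C * sqrt(2 / n)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

dct1 <- function(x) as.numeric(dctMatrix(length(x)) %*% x)

#' 2-D orthonormal DCT-II (and inverse)
#' @param mat numeric matrix.
#' @return transformed matrix of the same size.
#' @keywords internal
dct2 <- function(mat) {
  dctMatrix(nrow(mat)) %*% mat %*% t(dctMatrix(ncol(mat)))
}

#' @rdname dct2
#' @keywords internal
idct2 <- function(mat) {
  t(dctMatrix(nrow(mat))) %*% mat %*% dctMatrix(ncol(mat))
}

#' Valid-region 2-D convolution with a separable (possibly complex) kernel
#'
#' Correlation form: out(i, j) = sum_{u,v} img(i+u-1, j+v-1) ky(u) kx(v),
#' keeping only positions where the window fits entirely inside the image.
#'
#' @param img numeric matrix.
#' @param ky,kx column and row kernels (numeric or complex vectors).
#' @return (nrow - length(ky) + 1) x (ncol - length(kx) + 1) matrix.
#' @keywords internal
sepFilterValid <- function(img, ky, kx) {
  bandApply <- function(m, k, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    len <- length(k)
    out <- NULL
    for (u in seq_len(len)) {
      idx <- u:(n - len + u)
      piece <- if (along == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      out <- if (is.null(out)) k[u] * piece else out + k[u] * piece
    }
    out
  }
  bandApply(bandApply(img, ky, 1L), kx, 2L)
}
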