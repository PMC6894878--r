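## Sliding-window per-pixel features. Six descriptors per RGB channel
## (18 total, channel-major order): window minimum, maximum, mean,
## population variance, edge factor, and the center pixel value.
##
## Edge handling is symmetric reflection (the border pixel is repeated:
## [a b c] padded by 2 becomes [b a | a b c | c b]), iterated as needed, so
## windows are defined for any radius. The edge factor is the window mean of
## the gradient magnitude, where the gradient is the horizontal and vertical
## central difference (f(x+1) - f(x-1)) / 2 computed on the padded channel.

# Symmetric reflection indices for positions (1-r)..(n+r) of a length-n axis.
.reflectIndex <- function(n, r) {
  k <- seq.int(1L - r, n + r)
  m <- (k - 1L) %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m < n, m + 1L, 2L * n - m)
}

.padSymmetric <- function(m, r) {
  m[.reflectIndex(nrow(m), r), .reflectIndex(ncol(m), r), drop = FALSE]
}

.featureNames18 <- function(config) {
  as.vector(t(outer(config@channels, config@featureNames, paste, sep = ".")))
}

#' Features of a single window (naive reference)
#'
#' Computes the 18 sliding-window features at one pixel by direct
#' enumeration of the window. [featureMap] is the accelerated equivalent and
#' is contractually identical to calling this at every pixel.
#'
#' @param image a [RasterImage-class].
#' @param center numeric `c(row, col)`, 0-based, inside the image.
#' @param config a [FeatureConfig-class].
#' @return Named numeric vector of 18 features, channel-major
#'   (`R.min`, `R.max`, ..., `B.center`).
#' @export
windowFeatures <- function(image, center, config = featureConfig()) {
  stopifnot(is(image, "RasterImage"), is(config, "FeatureConfig"))
  px <- image@pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  i <- center[1]; j <- center[2]
  if (i < 0 || i > H - 1 || j < 0 || j > W - 1)
    stop("window center (", i, ", ", j, ") lies outside the image")
  r <- config@windowRadius
  out <- numeric(0)
  for (ch in 1:3) {
    pad1 <- .padSymmetric(matrix(as.numeric(px[, , ch]), H, W), r + 1L)
    # window rows/cols in pad1 coordinates (origin shifted by r + 1)
    rows <- (i - r):(i + r) + r + 2L
    cols <- (j - r):(j + r) + r + 2L
    win <- pad1[rows, cols, drop = FALSE]
    mu <- mean(win)
    gx <- (pad1[rows, cols + 1L, drop = FALSE] -
           pad1[rows, cols - 1L, drop = FALSE]) / 2
    gy <- (pad1[rows + 1L, cols, drop = FALSE] -
           pad1[rows - 1L, cols, drop = FALSE]) / 2
    out <- c(out, min(win), max(win), mu, mean((win - mu)^2),
             mean(sqrt(gx^2 + gy^2)), px[i + 1L, j + 1L, ch])
  }
  names(out) <- .featureNames18(config)
  out
}

# Window sums of a (H+2r) x (W+2r) padded matrix -> H x W, via integral image.
.boxSum <- function(mp, r, H, W) {
  k <- 2L * r + 1L
  cs <- apply(mp, 2L, cumsum)        # cumulative down rows
  cs <- t(apply(cs, 1L, cumsum))     # then across columns
  S <- matrix(0, nrow(mp) + 1L, ncol(mp) + 1L)
  S[-1L, -1L] <- cs
  ra <- 1:H; ca <- 1:W
  S[ra + k, ca + k, drop = FALSE] - S[ra, ca + k, drop = FALSE] -
    S[ra + k, ca, drop = FALSE] + S[ra, ca, drop = FALSE]
}

# Running extreme over axis windows of width 2r+1; mp is (H+2r) x (W+2r).
.boxExtreme <- function(mp, r, H, W, fun) {
  k <- 2L * r
  rowpass <- Reduce(fun, lapply(0:k, function(o)
    mp[(1L + o):(H + o), , drop = FALSE]))
  Reduce(fun, lapply(0:k, function(o)
    rowpass[, (1L + o):(W + o), drop = FALSE]))
}

#' Per-pixel feature map
#'
#' The full `H x W x 18` grid of sliding-window features, equal pixel-for-
#' pixel to [windowFeatures] at every location, computed with separable
#' window passes and integral images.
#'
#' @inheritParams windowFeatures
#' @return Numeric `H x W x 18` array; the third dimension is named
#'   channel-major (`R.min` ... `B.center`).
#' @export
featureMap <- function(image, config = featureConfig()) {
  stopifnot(is(image, "RasterImage"), is(config, "FeatureConfig"))
  px <- image@pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  r <- config@windowRadius
  nwin <- (2L * r + 1L)^2
  out <- array(0, c(H, W, 18L), dimnames = list(NULL, NULL,
                                                .featureNames18(config)))
  for (ch in 1:3) {
    m <- matrix(as.numeric(px[, , ch]), H, W)
    pad1 <- .padSymmetric(m, r + 1L)
    np <- nrow(pad1); mp <- ncol(pad1)
    padr <- pad1[2:(np - 1L), 2:(mp - 1L), drop = FALSE]
    gx <- (pad1[2:(np - 1L), 3:mp, drop = FALSE] -
           pad1[2:(np - 1L), 1:(mp - 2L), drop = FALSE]) / 2
    gy <- (pad1[3:np, 2:(mp - 1L), drop = FALSE] -
           pad1[1:(np - 2L), 2:(mp - 1L), drop = FALSE]) / 2
    mag <- sqrt(gx^2 + gy^2)
    s1 <- .boxSum(padr, r, H, W)
    s2 <- .boxSum(padr^2, r, H, W)
    mu <- s1 / nwin
    b <- (ch - 1L) * 6L
    out[, , b + 1L] <- .boxExtreme(padr, r, H, W, pmin)
    out[, , b + 2L] <- .boxExtreme(padr, r, H, W, pmax)
    out[, , b + 3L] <- mu
    out[, , b + 4L] <- pmax(s2 / nwin - mu^2, 0)
    out[, , b + 5L] <- .boxSum(mag, r, H, W) / nwin
    out[, , b + 6L] <- m
  }
  out
}

# Feature matrix (n x 18) at given 0-based pixel locations, from a
# precomputed feature map.
.featuresAt <- function(fmap, rows, cols) {
  H <- dim(fmap)[1]
  idx <- (cols) * H + rows + 1L  # linear index into one feature slice
  n <- length(idx)
  out <- matrix(0, n, dim(fmap)[3])
  sliceLen <- H * dim(fmap)[2]
  for (f in seq_len(dim(fmap)[3]))
    out[, f] <- fmap[(f - 1L) * sliceLen + idx]
  colnames(out) <- dimnames(fmap)[[3]]
  out
}
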