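# Derivative-of-Gaussian jet and seven-class Basic Image Feature (BIF)
# pixel classification. Linear collagen fibers appear as locally dark ridges
# on H&E, so the dark-line BIF class is the fiber proxy.

# Discrete Gaussian-derivative kernels, renormalized so that polynomial
# inputs give exact responses (unit ramp -> 1 for the first derivative,
# x^2/2 -> 1 for the second).
gaussian_kernels <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  g0 <- exp(-x^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  g1 <- -x * g0 / sigma^2
  g1 <- g1 / sum(g1 * x)                 # unit response to I = x
  g2 <- (x^2 - sigma^2) * g0 / sigma^4
  g2 <- g2 - mean(g2)                    # zero response to constants
  g2 <- g2 / sum(g2 * x^2 / 2)           # response to I = x^2/2 is exactly 1
  list(g0 = g0, g1 = g1, g2 = g2, radius = r)
}

# Valid-region 1D correlation operator as a sparse band matrix:
# (op %*% padded)[i] = sum_j kern[j] padded[i + j - 1].
band_operator <- function(n_out, kern) {
  w <- length(kern)
  Matrix::bandSparse(n_out, n_out + w - 1L, k = 0:(w - 1L),
                     diagonals = lapply(kern, rep, n_out))
}

# Mirror-pad an image by `radius` on every side (reflective boundary).
reflect_pad <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(pmin(radius:1 + 1, nr), 1:nr, nr - pmin(1:radius, nr - 1))
  cidx <- c(pmin(radius:1 + 1, nc), 1:nc, nc - pmin(1:radius, nc - 1))
  img[ridx, cidx]
}

#' Gaussian derivative jet of a gray image
#'
#' Computes the Gaussian-smoothed image and its first and second derivatives
#' at one scale by separable convolution with reflective boundary handling,
#' plus the scale-normalized rotation invariants used by the BIF classifier:
#' the Laplacian \code{lambda = sigma^2 (Lxx + Lyy)}, the shear magnitude
#' \code{gamma = sigma^2 sqrt((Lxx - Lyy)^2 + 4 Lxy^2)} and the gradient
#' magnitude \code{eta = sigma sqrt(Lx^2 + Ly^2)}. The x axis is the column
#' (horizontal) axis and the y axis is the row axis.
#'
#' @param gray single-channel numeric matrix (typically unit-normalized
#'   luminance).
#' @param sigma_px Gaussian scale in pixels (>= 1).
#' @return An object of class \code{JetResponse}: list of maps \code{L, Lx,
#'   Ly, Lxx, Lxy, Lyy, lambda, gamma, eta} and the scale \code{sigma}.
#' @export
gaussian_jet <- function(gray, sigma_px = 2) {
  stopifnot(is.matrix(gray))
  if (sigma_px < 1) stop("'sigma_px' must be >= 1", call. = FALSE)
  k <- gaussian_kernels(sigma_px)
  if (2 * k$radius + 1 > min(dim(gray))) {
    stop("sigma too large for the image", call. = FALSE)
  }
  # separable passes on the mirror-padded image: three vertical passes
  # (along rows, y axis) are shared by the six jet maps, then a horizontal
  # pass (along columns, x axis) finishes each one
  padded <- reflect_pad(gray, k$radius)
  nr <- nrow(gray); nc <- ncol(gray)
  vop <- lapply(list(k$g0, k$g1, k$g2), function(kk) band_operator(nr, kk))
  hop <- lapply(list(k$g0, k$g1, k$g2),
                function(kk) Matrix::t(band_operator(nc, kk)))
  v0 <- vop[[1]] %*% padded
  v1 <- vop[[2]] %*% padded
  v2 <- vop[[3]] %*% padded
  L   <- as.matrix(v0 %*% hop[[1]])
  Lx  <- as.matrix(v0 %*% hop[[2]])
  Ly  <- as.matrix(v1 %*% hop[[1]])
  Lxx <- as.matrix(v0 %*% hop[[3]])
  Lyy <- as.matrix(v2 %*% hop[[1]])
  Lxy <- as.matrix(v1 %*% hop[[2]])
  s2 <- sigma_px^2
  structure(list(
    L = L, Lx = Lx, Ly = Ly, Lxx = Lxx, Lxy = Lxy, Lyy = Lyy,
    lambda = s2 * (Lxx + Lyy),
    gamma = s2 * sqrt((Lxx - Lyy)^2 + 4 * Lxy^2),
    eta = sigma_px * sqrt(Lx^2 + Ly^2),
    sigma = sigma_px), class = "JetResponse")
}

BIF_CLASSES <- c("flat", "slope", "dark_blob", "light_blob",
                 "dark_line", "light_line", "saddle")

#' Classify pixels into the seven Basic Image Feature classes
#'
#' Each pixel is assigned the class with the largest score among
#' \code{flat: epsilon * L}, \code{slope: 2 eta}, \code{dark_blob: +lambda},
#' \code{light_blob: -lambda}, \code{dark_line: (gamma + lambda)/sqrt(2)},
#' \code{light_line: (gamma - lambda)/sqrt(2)} and \code{saddle: gamma}.
#' With image intensity increasing towards bright, a locally dark ridge has
#' a positive Laplacian across the ridge, so it scores highest as
#' \code{dark_line}. Ties are broken by the fixed class priority
#' flat, slope, dark_blob, light_blob, dark_line, light_line, saddle.
#'
#' @param jet a \code{\link{gaussian_jet}} response.
#' @param epsilon flatness gain (> 0); on unit-normalized luminance the
#'   default 0.05 leaves blank background flat-classified at typical noise.
#' @return integer matrix of class \code{BifLabelMap} with levels attribute;
#'   values index \code{BIF_CLASSES}.
#' @export
classify_bif <- function(jet, epsilon = 0.05) {
  stopifnot(inherits(jet, "JetResponse"), epsilon > 0)
  s <- list(
    flat = epsilon * jet$L,
    slope = 2 * jet$eta,
    dark_blob = jet$lambda,
    light_blob = -jet$lambda,
    dark_line = (jet$gamma + jet$lambda) / sqrt(2),
    light_line = (jet$gamma - jet$lambda) / sqrt(2),
    saddle = jet$gamma)
  # running argmax; strict > keeps the earlier class on ties, which makes
  # the BIF_CLASSES order the tie-break priority
  best <- s[[1]]
  lab <- matrix(1L, nrow(best), ncol(best))
  for (i in 2:7) {
    upd <- s[[i]] > best
    lab[upd] <- i
    best[upd] <- s[[i]][upd]
  }
  structure(lab, levels = BIF_CLASSES, class = "BifLabelMap")
}

#' @export
print.BifLabelMap <- function(x, ...) {
  cat("BifLabelMap", nrow(x), "x", ncol(x), "px\n")
  print(table(factor(BIF_CLASSES[x], levels = BIF_CLASSES)))
  invisible(x)
}
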