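#' Multi-scale Hessian vesselness filter
#'
#' Frangi-type tubularity response for bright vessels: at each Gaussian
#' scale the image is smoothed, the scale-normalized Hessian (second
#' differences multiplied by sigma^2) is computed per voxel, and its
#' eigenvalues sorted by absolute value (|l1| <= |l2| <= |l3|) enter the
#' classic response combining the plate/line ratio Ra = |l2|/|l3|, the
#' blob ratio Rb = |l1|/sqrt(|l2 l3|) and the structure norm S, with
#' bright-tube sign convention (l2, l3 < 0). The final response is the
#' voxelwise maximum over scales, in [0, 1].
#'
#' @param volume an [ImageVolume-class].
#' @param scales_mm positive Gaussian scales in mm (default
#'   `c(1, 1.5, 2, 3, 4)`); scales below the largest voxel size are
#'   clamped with a warning.
#' @param alpha,beta Frangi sensitivity parameters (default 0.5).
#' @param gamma structure-norm scale; `NULL` (default) uses half the
#'   maximum Hessian norm at each scale.
#' @return an [ImageVolume-class] with the response in [0, 1].
#' @export
vesselness <- function(volume, scales_mm = c(1, 1.5, 2, 3, 4),
                       alpha = 0.5, beta = 0.5, gamma = NULL) {
  stopifnot(is(volume, "ImageVolume"))
  if (length(scales_mm) < 1 || any(scales_mm <= 0))
    stop("need at least one positive scale")
  vox <- max(volume@spacing)
  if (any(scales_mm < vox)) {
    warning("scales below the voxel size were clamped to ", vox, " mm")
    scales_mm <- pmax(scales_mm, vox)
  }
  scales_mm <- unique(scales_mm)
  v <- volume@values
  best <- array(0, dim(v))
  for (sig in scales_mm) {
    resp <- .frangi_single_scale(v, volume@spacing, sig, alpha, beta, gamma)
    best <- pmax(best, resp)
  }
  imageVolume(best, spacing = volume@spacing, origin = volume@origin)
}

.frangi_single_scale <- function(v, spacing, sigma, alpha, beta, gamma) {
  sm <- .gaussian_smooth(v, sigma_mm = sigma, spacing = spacing)
  H <- .hessian_components(sm, spacing)
  s2 <- sigma^2
  for (k in seq_along(H)) H[[k]] <- H[[k]] * s2
  ev <- .eigen_sym3(H)
  l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
  S2 <- l1^2 + l2^2 + l3^2
  cpar <- if (is.null(gamma)) sqrt(max(S2)) / 2 else gamma
  if (cpar <= 0) return(array(0, dim(v)))
  a23 <- abs(l2 * l3)
  Ra2 <- ifelse(l3 != 0, (l2 / l3)^2, 0)
  Rb2 <- ifelse(a23 > 0, l1^2 / a23, 0)
  resp <- (1 - exp(-Ra2 / (2 * alpha^2))) *
    exp(-Rb2 / (2 * beta^2)) *
    (1 - exp(-S2 / (2 * cpar^2)))
  resp[l2 > 0 | l3 > 0] <- 0
  array(pmin(pmax(resp, 0), 1), dim(v))
}

# second-derivative components of a (pre-smoothed) volume by central
# differences; returns list(xx, yy, zz, xy, xz, yz)
.hessian_components <- function(f, spacing) {
  sh <- function(a1, k1, a2 = NULL, k2 = NULL) {
    out <- .shift_axis_clamped(f, a1, k1)
    if (!is.null(a2)) out <- .shift_axis_clamped(out, a2, k2)
    out
  }
  h <- spacing
  list(
    xx = (sh(1, 1) - 2 * f + sh(1, -1)) / h[1]^2,
    yy = (sh(2, 1) - 2 * f + sh(2, -1)) / h[2]^2,
    zz = (sh(3, 1) - 2 * f + sh(3, -1)) / h[3]^2,
    xy = (sh(1, 1, 2, 1) + sh(1, -1, 2, -1) - sh(1, 1, 2, -1) -
            sh(1, -1, 2, 1)) / (4 * h[1] * h[2]),
    xz = (sh(1, 1, 3, 1) + sh(1, -1, 3, -1) - sh(1, 1, 3, -1) -
            sh(1, -1, 3, 1)) / (4 * h[1] * h[3]),
    yz = (sh(2, 1, 3, 1) + sh(2, -1, 3, -1) - sh(2, 1, 3, -1) -
            sh(2, -1, 3, 1)) / (4 * h[2] * h[3]))
}

# closed-form eigenvalues of symmetric 3x3 matrices (vectorized),
# returned sorted by absolute value |l1| <= |l2| <= |l3|
.eigen_sym3 <- function(H) {
  a <- H$xx; b <- H$yy; c <- H$zz
  d <- H$xy; e <- H$yz; f <- H$xz
  q <- (a + b + c) / 3
  p1 <- d^2 + f^2 + e^2
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-300
  pe <- ifelse(ok, p, 1)
  B11 <- (a - q) / pe; B22 <- (b - q) / pe; B33 <- (c - q) / pe
  B12 <- d / pe; B23 <- e / pe; B13 <- f / pe
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
    B13 * (B12 * B23 - B22 * B13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  M <- cbind(as.vector(e1), as.vector(e2), as.vector(e3))
  A <- abs(M)
  n <- nrow(M)
  i3 <- max.col(A, ties.method = "first")
  i1 <- max.col(-A, ties.method = "last")
  same <- i1 == i3
  if (any(same)) i1[same] <- (i1[same] %% 3L) + 1L
  l3 <- M[cbind(seq_len(n), i3)]
  l1 <- M[cbind(seq_len(n), i1)]
  l2 <- rowSums(M) - l1 - l3
  dm <- dim(H$xx)
  list(l1 = array(l1, dm), l2 = array(l2, dm), l3 = array(l3, dm))
}

#' Otsu threshold
#'
#' Exhaustive maximization of the between-class variance over a 256-bin
#' histogram of the input values.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold; values strictly above it are foreground.
#' @examples
#' otsuThreshold(c(rnorm(100, 0), rnorm(100, 5)))
#' @export
otsuThreshold <- function(values, n_bins = 256L) {
  x <- values[is.finite(values)]
  rng <- range(x)
  if (length(x) < 2 || rng[1] == rng[2])
    stop("constant input: threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, n_bins)
  w <- h / sum(h)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * centers)
  mt <- cm[n_bins]
  # between-class variance for threshold after bin k
  valid <- cw > 0 & cw < 1
  bc <- rep(-Inf, n_bins)
  bc[valid] <- (mt * cw[valid] - cm[valid])^2 /
    (cw[valid] * (1 - cw[valid]))
  k <- which.max(bc)
  edges[k + 1L]
}
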