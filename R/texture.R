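# the 13 unique 3D direction offsets at Chebyshev distance 1
.directions13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, ])
}

# quantized ROI as a cropped array with NA outside the mask
.quantized_roi <- function(volume, mask, n_bins) {
  v <- if (is(volume, "ImageVolume")) volume@values else volume
  m <- if (is(mask, "RoiMask")) mask@values else mask
  stopifnot(identical(dim(v), dim(m)))
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  vc <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mc <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  q <- array(NA_integer_, dim(vc))
  q[mc] <- quantize(vc[mc], n_bins)
  q
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of quantized gray levels over the 13
#' unique 3D direction offsets at distance 1 (direction-merged),
#' symmetrizes, and normalizes to sum 1.
#'
#' @param q integer 3D array of gray levels with NA outside the ROI.
#' @param n_bins number of gray levels.
#' @return an n_bins x n_bins matrix summing to 1.
#' @export
glcmMatrix <- function(q, n_bins = 64L) {
  d <- dim(q)
  dirs <- .directions13()
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    sx <- .crop_pair(d[1], off[1]); sy <- .crop_pair(d[2], off[2])
    sz <- .crop_pair(d[3], off[3])
    a <- q[sx$a, sy$a, sz$a, drop = FALSE]
    b <- q[sx$b, sy$b, sz$b, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- (a[ok] - 1L) * n_bins + b[ok]
    tab <- tabulate(code, n_bins * n_bins)
    counts <- counts + matrix(tab, n_bins, n_bins, byrow = TRUE)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot < 2) stop("fewer than 2 in-mask voxel pairs")
  counts / tot
}

.crop_pair <- function(n, off) {
  if (off >= 0) list(a = seq_len(n - off), b = seq_len(n - off) + off)
  else list(a = seq_len(n + off) - off, b = seq_len(n + off))
}

#' GLCM texture features
#'
#' Twenty-two second-order texture statistics of the normalized,
#' symmetrized co-occurrence matrix (direction-merged over the 13 unique
#' 3D offsets at distance 1). Logarithms use base 2; the correlation of a
#' degenerate (single-cell) matrix is 1 by convention.
#'
#' @param volume an [ImageVolume-class] or 3D array.
#' @param mask a [RoiMask-class] or logical array.
#' @param n_bins quantization levels (default 64).
#' @return named numeric vector of length 22.
#' @export
glcmFeatures <- function(volume, mask, n_bins = 64L) {
  q <- .quantized_roi(volume, mask, n_bins)
  P <- glcmMatrix(q, n_bins)
  .glcm_features_from_matrix(P)
}

.glcm_features_from_matrix <- function(P) {
  K <- nrow(P)
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(K) * px); muy <- sum(seq_len(K) * py)
  sx <- sqrt(sum((seq_len(K) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(K) - muy)^2 * py))
  plog <- function(p) ifelse(p > 0, log2(p), 0)
  ent <- -sum(P * plog(P))
  # diagonal (difference) and cross (sum) distributions
  dvals <- 0:(K - 1)
  pd <- vapply(dvals, function(k) sum(P[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * K)
  ps <- vapply(svals, function(k) sum(P[(i + j) == k]), numeric(1))
  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - ent))))
  da <- sum(dvals * pd)
  sa <- sum(svals * ps)
  c(autocorrelation = sum(i * j * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = ent,
    homogeneity = sum(P / (1 + (i - j)^2)),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    imc1 = imc1,
    imc2 = imc2,
    joint_average = mux,
    joint_variance = sum((i - mux)^2 * P),
    max_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(ps * plog(ps)),
    sum_variance = sum((svals - sa)^2 * ps),
    difference_entropy = -sum(pd * plog(pd)),
    difference_variance = sum((dvals - da)^2 * pd))
}

#' Gray-level run-length matrix over one direction
#'
#' Scans all lattice lines parallel to `direction` and counts maximal
#' runs of equal gray level among in-mask voxels; a gap in the mask
#' terminates a run.
#'
#' @param q integer 3D array with NA outside the ROI.
#' @param direction integer(3) offset with entries in -1..1.
#' @param n_bins number of gray levels.
#' @return an n_bins x max_run_length matrix of run counts.
#' @export
glrlmMatrix <- function(q, direction, n_bins = 64L) {
  d <- dim(q)
  idx <- which(!is.na(q), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  g <- q[!is.na(q)]
  dvec <- as.integer(direction)
  step2 <- sum(dvec^2)
  t <- as.vector((idx - 1L) %*% dvec)
  # line key: |d|^2 * p - t * d is constant along a lattice line
  key_mat <- (idx - 1L) * step2 - outer(t, dvec)
  key <- paste(key_mat[, 1], key_mat[, 2], key_mat[, 3], sep = ",")
  ord <- order(key, t)
  keyo <- key[ord]; to <- t[ord]; go <- g[ord]
  newrun <- c(TRUE, keyo[-1] != keyo[-length(keyo)] |
                to[-1] != to[-length(to)] + step2 |
                go[-1] != go[-length(go)])
  run_id <- cumsum(newrun)
  run_len <- tabulate(run_id)
  run_gray <- go[newrun]
  max_len <- max(run_len)
  counts <- matrix(0, n_bins, max_len)
  tab <- table(factor(run_gray, levels = seq_len(n_bins)),
               factor(run_len, levels = seq_len(max_len)))
  counts[] <- as.numeric(tab)
  counts
}

#' GLRLM texture features
#'
#' Eleven run-length statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
#' SRLGE, SRHGE, LRLGE, LRHGE), each computed per direction over the 13
#' unique 3D directions and averaged.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of length 11.
#' @export
glrlmFeatures <- function(volume, mask, n_bins = 64L) {
  q <- .quantized_roi(volume, mask, n_bins)
  npix <- sum(!is.na(q))
  dirs <- .directions13()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- glrlmMatrix(q, dirs[r, ], n_bins)
    f <- .glrlm_features_from_matrix(R, npix)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

.glrlm_features_from_matrix <- function(R, npix) {
  nr <- sum(R)
  gl <- seq_len(nrow(R))
  rl <- seq_len(ncol(R))
  G <- matrix(gl, nrow(R), ncol(R))
  L <- matrix(rl, nrow(R), ncol(R), byrow = TRUE)
  c(sre = sum(R / L^2) / nr,
    lre = sum(R * L^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / npix,
    lgre = sum(R / G^2) / nr,
    hgre = sum(R * G^2) / nr,
    srlge = sum(R / (G^2 * L^2)) / nr,
    srhge = sum(R * G^2 / L^2) / nr,
    lrlge = sum(R * L^2 / G^2) / nr,
    lrhge = sum(R * G^2 * L^2) / nr)
}

#' Local binary pattern features
#'
#' For every in-mask voxel whose full 26-neighborhood lies inside the
#' grid, counts how many of the 26 neighbors are strictly greater than
#' the center. The count (0..26) is rotation invariant and is pooled into
#' 16 bins; the normalized 16-bin histogram plus its entropy give 17
#' features. A constant region puts all mass in the first bin with
#' entropy 0.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of length 17 (16 bins + entropy).
#' @export
lbpFeatures <- function(volume, mask) {
  v <- if (is(volume, "ImageVolume")) volume@values else volume
  m <- if (is(mask, "RoiMask")) mask@values else mask
  d <- dim(v)
  if (any(d < 3)) stop("mask has no interior voxel")
  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  sel <- m & interior
  if (!any(sel)) stop("mask has no interior voxel")
  counts <- array(0L, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- .shift_axis_fill(v, 1L, dx, fill = 0)
    nb <- .shift_axis_fill(nb, 2L, dy, fill = 0)
    nb <- .shift_axis_fill(nb, 3L, dz, fill = 0)
    counts <- counts + (nb > v)
  }
  cc <- counts[sel]
  bin <- pmin(floor(cc * 16 / 27) + 1L, 16L)
  h <- tabulate(bin, 16L)
  p <- h / sum(h)
  pp <- p[p > 0]
  out <- c(p, -sum(pp * log2(pp)))
  names(out) <- .lbp_feature_names
  out
}
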