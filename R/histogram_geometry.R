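# population skewness; 0 for degenerate input by convention
.skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (n < 2 || s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# population excess kurtosis; 0 for degenerate input by convention
.kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (length(x) < 2 || s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

.summary5 <- function(x) {
  if (length(x) == 0) return(c(mean = 0, sd = 0, skewness = 0,
                               kurtosis = 0, median = 0))
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
    skewness = .skewness(x), kurtosis = .kurtosis(x), median = median(x))
}

#' Intensity histogram features
#'
#' First-order statistics of the in-mask intensities: mean, SD, variance
#' (population convention), skewness, excess kurtosis, median, min, max,
#' range, interquartile range, energy (sum of squares), entropy of the
#' 64-bin intensity histogram, and the 10th/90th percentiles. Skewness
#' and kurtosis of a constant region are 0 by convention.
#'
#' @param volume an [ImageVolume-class] or 3D array.
#' @param mask a [RoiMask-class] or logical array, nonempty.
#' @param n_bins bins for the entropy histogram (default 64).
#' @return named numeric vector of length 14.
#' @export
histogramFeatures <- function(volume, mask, n_bins = 64L) {
  v <- if (is(volume, "ImageVolume")) volume@values else volume
  m <- if (is(mask, "RoiMask")) mask@values else mask
  x <- v[m]
  if (length(x) == 0) stop("empty mask")
  q <- quantize(x, n_bins)
  p <- tabulate(q, n_bins) / length(q)
  p <- p[p > 0]
  c(mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    variance = mean((x - mean(x))^2),
    skewness = .skewness(x),
    kurtosis = .kurtosis(x),
    median = median(x),
    min = min(x),
    max = max(x),
    range = max(x) - min(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    p10 = unname(quantile(x, 0.10)),
    p90 = unname(quantile(x, 0.90)))
}

#' Fixed-bin-count quantization
#'
#' Maps intensities to integer labels 1..n_bins over the min-max range of
#' the input. A constant input maps entirely to bin 1.
#'
#' @param x numeric vector (typically the in-ROI intensities).
#' @param n_bins number of bins (>= 2).
#' @return integer vector of labels in 1..n_bins.
#' @export
quantize <- function(x, n_bins = 64L) {
  if (length(x) == 0) stop("empty input")
  if (n_bins < 2) stop("n_bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(as.integer(q), as.integer(n_bins))
}

# marching-tetrahedra surface area of a binary mask. The indicator is
# first smoothed with a one-voxel Gaussian; each grid cell is split into
# 6 Kuhn tetrahedra and the 0.5 iso-surface is triangulated with
# linearly interpolated edge vertices, which removes the staircase bias
# of a binary mesh (a digitized ball's area comes out within ~2%).
.surface_area_mt <- function(mask, spacing) {
  d <- dim(mask)
  f0 <- .gaussian_smooth(array(as.numeric(mask), d),
                         sigma_mm = min(spacing), spacing = spacing)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f0
  dp <- d + 1L   # cells per axis
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  corner_pos <- corners * matrix(spacing, 8, 3, byrow = TRUE)
  tets <- rbind(c(1, 2, 6, 8), c(1, 6, 5, 8), c(1, 5, 7, 8),
                c(1, 7, 3, 8), c(1, 3, 4, 8), c(1, 4, 2, 8))
  vals <- vector("list", 8L)
  for (k in 1:8)
    vals[[k]] <- as.vector(pad[(1:dp[1]) + corners[k, 1],
                               (1:dp[2]) + corners[k, 2],
                               (1:dp[3]) + corners[k, 3], drop = FALSE])
  iso <- 0.5
  # active cells only
  vmin <- pmin(vals[[1]], vals[[2]], vals[[3]], vals[[4]],
               vals[[5]], vals[[6]], vals[[7]], vals[[8]])
  vmax <- pmax(vals[[1]], vals[[2]], vals[[3]], vals[[4]],
               vals[[5]], vals[[6]], vals[[7]], vals[[8]])
  active <- which(vmin < iso & vmax >= iso)
  if (!length(active)) return(0)
  V <- lapply(vals, function(v) v[active])
  tri_area_vec <- function(p1, p2, p3) {
    a1 <- p2[[1]] - p1[[1]]; a2 <- p2[[2]] - p1[[2]]; a3 <- p2[[3]] - p1[[3]]
    b1 <- p3[[1]] - p1[[1]]; b2 <- p3[[2]] - p1[[2]]; b3 <- p3[[3]] - p1[[3]]
    0.5 * sqrt((a2 * b3 - a3 * b2)^2 + (a3 * b1 - a1 * b3)^2 +
                 (a1 * b2 - a2 * b1)^2)
  }
  total <- 0
  for (t in 1:6) {
    cid <- tets[t, ]
    tv <- V[cid]
    tp <- corner_pos[cid, , drop = FALSE]
    inside <- lapply(tv, function(v) v >= iso)
    code <- inside[[1]] + 2L * inside[[2]] + 4L * inside[[3]] +
      8L * inside[[4]]
    edge_vertex <- function(sel, i, o) {
      va <- tv[[i]][sel]; vb <- tv[[o]][sel]
      tt <- (iso - va) / (vb - va)
      lapply(1:3, function(ax) tp[i, ax] + tt * (tp[o, ax] - tp[i, ax]))
    }
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      ins <- which(as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L))))
      out <- setdiff(1:4, ins)
      if (length(ins) == 1 || length(ins) == 3) {
        apex <- if (length(ins) == 1) ins else out
        oth <- if (length(ins) == 1) out else ins
        p1 <- edge_vertex(sel, apex, oth[1])
        p2 <- edge_vertex(sel, apex, oth[2])
        p3 <- edge_vertex(sel, apex, oth[3])
        total <- total + sum(tri_area_vec(p1, p2, p3))
      } else {
        p1 <- edge_vertex(sel, ins[1], out[1])
        p2 <- edge_vertex(sel, ins[1], out[2])
        p3 <- edge_vertex(sel, ins[2], out[2])
        p4 <- edge_vertex(sel, ins[2], out[1])
        total <- total + sum(tri_area_vec(p1, p2, p3)) +
          sum(tri_area_vec(p1, p3, p4))
      }
    }
  }
  total
}

#' Mask geometry features
#'
#' Seventeen shape descriptors of a tumor mask: physical volume, surface
#' area (marching-tetrahedra mesh over the binary mask), surface-to-volume
#' ratio, maximum 3D diameter (largest pairwise surface-voxel distance
#' plus the voxel diagonal, so a single voxel yields its diagonal),
#' axis-aligned extents, equivalent-sphere diameter, sphericity,
#' compactness, spherical disproportion, PCA axis lengths, elongation,
#' flatness and the bounding-box fill fraction.
#'
#' @param mask a [RoiMask-class] or logical array, nonempty.
#' @param spacing voxel spacing in mm (taken from the mask if a
#'   `RoiMask`).
#' @return named numeric vector of length 17.
#' @export
geometryFeatures <- function(mask, spacing = NULL) {
  if (is(mask, "RoiMask")) {
    spacing <- mask@spacing
    m <- mask@values
  } else m <- mask
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  nvox <- nrow(idx)
  vol <- nvox * prod(spacing)
  area <- .surface_area_mt(m, spacing)
  # surface voxels: those with at least one 6-neighbor outside the mask
  surf <- .surface_voxels(m)
  sidx <- which(surf, arr.ind = TRUE)
  pts <- sweep(sidx - 1, 2, spacing, `*`)
  diag_vox <- sqrt(sum(spacing^2))
  maxd <- .max_pairwise_distance(pts) + diag_vox
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * spacing
  eqd <- (6 * vol / pi)^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  all_pts <- sweep(idx - 1, 2, spacing, `*`)
  if (nvox > 1) {
    cv <- stats::cov(all_pts) * (nvox - 1) / nvox
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    axes <- c(0, 0, 0); elong <- 1; flat <- 1
  }
  c(volume_mm3 = vol,
    surface_area_mm2 = area,
    surface_to_volume = area / vol,
    max_diameter_3d_mm = maxd,
    extent_x_mm = unname(ext[1]),
    extent_y_mm = unname(ext[2]),
    extent_z_mm = unname(ext[3]),
    equivalent_diameter_mm = eqd,
    sphericity = sphericity,
    compactness = vol / (sqrt(pi) * area^1.5),
    spherical_disproportion = 1 / sphericity,
    major_axis_mm = axes[1],
    minor_axis_mm = axes[2],
    least_axis_mm = axes[3],
    elongation = elong,
    flatness = flat,
    bbox_fill_fraction = vol / prod(ext))
}

.surface_voxels <- function(m) {
  d <- dim(m)
  inner <- m
  for (axis in 1:3) {
    for (k in c(-1L, 1L)) {
      shifted <- .shift_axis_fill(m, axis, k, fill = FALSE)
      inner <- inner & shifted
    }
  }
  m & !inner
}

.shift_axis_fill <- function(arr, axis, k, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  if (k > 0) { src[[axis]] <- (1 + k):n; dst[[axis]] <- 1:(n - k) }
  if (k < 0) { src[[axis]] <- 1:(n + k); dst[[axis]] <- (1 - k):n }
  out_idx <- do.call(`[<-`, c(list(out), dst,
                              list(do.call(`[`, c(list(arr), src,
                                                  list(drop = FALSE))))))
  out_idx
}

.max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(0)
  if (n > 4000) {   # deterministic thinning for very large surfaces
    keep <- seq(1, n, by = ceiling(n / 4000))
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
  }
  best <- 0
  chunk <- 500L
  for (i0 in seq(1, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(rowSums(pts[ii, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[ii, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
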