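#' Curvature, torsion and shape of a branch centerline
#'
#' Resamples the branch at uniform arc steps, smooths each coordinate
#' with a Gaussian along arc length (torsion needs third derivatives and
#' is noise-dominated without smoothing), and evaluates the discrete
#' Frenet formulas kappa = |r' x r''| / |r'|^3 and
#' tau = (r' x r'') . r''' / |r' x r''|^2 by central differences. The
#' summary `mean_torsion` uses the curvature-weighted signed estimator
#' |sum (r' x r'') . r'''| / sum |r' x r''|^2: the raw pointwise tau is
#' ill-conditioned wherever curvature vanishes, while the weighted form
#' is exact for a helix (constant tau) and lets discretization noise of
#' opposite signs cancel on near-straight branches. Torsion magnitudes
#' |tau| feed the pointwise profile features, since the sign flips with
#' traversal direction. The first and last three samples are excluded
#' from all summaries to avoid boundary-difference artifacts.
#'
#' @param points n-by-3 matrix of centerline coordinates (mm), n >= 3
#'   (>= 5 for torsion).
#' @param smoothing_mm Gaussian smoothing scale along the curve (default
#'   1 mm; 0 disables).
#' @param step_mm resampling arc step (default 0.5 mm).
#' @return a list: `kappa`, `tau` (per-sample profiles, 1/mm), and the
#'   per-branch scalars `mean_curvature`, `max_curvature`, `mean_torsion`,
#'   `max_torsion`, `length`, `straightness`, `curvature_skewness`,
#'   `torsion_skewness`, `inflection_count` (sign changes of signed
#'   torsion), `total_curvature`, `total_torsion`. Branches too short for
#'   torsion get `NA` torsion entries.
#' @examples
#' helix <- generateVesselBranch(c(0, 0, 0), c(0, 0, 1), 40, 5, 2)
#' g <- branchGeometry(helix)
#' c(g$mean_curvature, 5 / 29)
#' @export
branchGeometry <- function(points, smoothing_mm = 1, step_mm = 0.5) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (nrow(points) < 3) stop("too-short branch: need >= 3 points")
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  total_len <- arc[length(arc)]
  if (total_len <= 0) stop("degenerate branch of zero length")
  n_out <- max(7L, ceiling(total_len / step_mm) + 1L)
  s_out <- seq(0, total_len, length.out = n_out)
  h <- s_out[2] - s_out[1]
  r <- vapply(1:3, function(k)
    approx(arc, points[, k], xout = s_out, ties = "ordered")$y,
    numeric(n_out))
  if (smoothing_mm > 0) {
    sig <- smoothing_mm / h
    r <- apply(r, 2, .smooth1d_reflect, sigma = sig)
  }
  d1 <- .cdiff(r, h, 1L)
  d2 <- .cdiff(r, h, 2L)
  d3 <- .cdiff(r, h, 3L)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  cr_n2 <- rowSums(cr^2)
  sp1 <- sqrt(rowSums(d1^2))
  kappa <- ifelse(sp1 > 1e-12, sqrt(cr_n2) / sp1^3, 0)
  tau_num <- rowSums(cr * d3)
  tau_signed <- ifelse(cr_n2 > 1e-12, tau_num / cr_n2, 0)
  keep <- seq_len(n_out) > 3 & seq_len(n_out) <= n_out - 3
  if (!any(keep)) keep <- rep(TRUE, n_out)
  k_in <- kappa[keep]
  t_in <- tau_signed[keep]
  # curvature floor: curves flatter than a 50 mm radius carry no usable
  # torsion signal, so the weighted estimator is shrunk toward 0 there
  kappa_floor <- 0.02
  reg <- sum(keep) * (kappa_floor * mean(sp1[keep])^3)^2
  tau_weighted <- abs(sum(tau_num[keep])) / (sum(cr_n2[keep]) + reg)
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  has_torsion <- nrow(points) >= 5
  sign_t <- sign(t_in[abs(t_in) > 1e-9])
  inflections <- if (length(sign_t) > 1) sum(diff(sign_t) != 0) else 0
  list(kappa = kappa, tau = abs(tau_signed),
       mean_curvature = mean(k_in),
       max_curvature = max(k_in),
       mean_torsion = if (has_torsion) tau_weighted else NA_real_,
       max_torsion = if (has_torsion) max(abs(t_in)) else NA_real_,
       length = total_len,
       straightness = min(1, chord / total_len),
       curvature_skewness = .skewness(k_in),
       torsion_skewness = if (has_torsion) .skewness(abs(t_in))
                          else NA_real_,
       inflection_count = as.numeric(inflections),
       total_curvature = sum(k_in) * h,
       total_torsion = if (has_torsion) tau_weighted * total_len
                       else NA_real_)
}

# Gaussian smoothing of a 1D signal with reflected boundary
.smooth1d_reflect <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  rr <- min(max(1L, ceiling(3 * sigma)), n - 1L)
  k <- dnorm(seq(-rr, rr), sd = sigma)
  k <- k / sum(k)
  xp <- c(x[(rr + 1):2], x, x[(n - 1):(n - rr)])
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(rr + 1):(rr + n)])
}

# central differences of order 1..3 on a uniformly sampled matrix of
# column signals; one-sided at the boundary rows
.cdiff <- function(r, h, order) {
  n <- nrow(r)
  out <- matrix(0, n, ncol(r))
  i <- 2:(n - 1)
  if (order == 1L) {
    out[i, ] <- (r[i + 1, , drop = FALSE] - r[i - 1, , drop = FALSE]) /
      (2 * h)
    out[1, ] <- (r[2, ] - r[1, ]) / h
    out[n, ] <- (r[n, ] - r[n - 1, ]) / h
  } else if (order == 2L) {
    out[i, ] <- (r[i + 1, , drop = FALSE] - 2 * r[i, , drop = FALSE] +
                   r[i - 1, , drop = FALSE]) / h^2
    out[1, ] <- out[2, ]
    out[n, ] <- out[n - 1, ]
  } else {
    j <- 3:(n - 2)
    out[j, ] <- (r[j + 2, , drop = FALSE] - 2 * r[j + 1, , drop = FALSE] +
                   2 * r[j - 1, , drop = FALSE] -
                   r[j - 2, , drop = FALSE]) / (2 * h^3)
    out[2, ] <- out[3, ]; out[1, ] <- out[3, ]
    out[n - 1, ] <- out[n - 2, ]; out[n, ] <- out[n - 2, ]
  }
  out
}
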