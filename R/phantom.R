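#' Phantom specification
#'
#' Parameters of a synthetic chest-CT-like phantom: a heterogeneous
#' bright tumor inside a low-intensity lung, surrounded by a binary
#' branching vessel tree with helically perturbed centerlines whose
#' curvature and torsion are known in closed form.
#'
#' The `tortuosity` parameter t controls the helical perturbation of the
#' centerlines: the helix amplitude is a = min(t, 1) mm and the pitch is
#' coupled as b = 3 / t (mm per radian), so that both the analytic
#' curvature a/(a^2+b^2) and torsion b/(a^2+b^2) increase monotonically
#' with t over the working range (0, 3] while the perturbation wavelength
#' stays resolvable at branch scale. `tortuosity = 0` gives straight
#' branches.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param spacing_mm numeric(3), voxel size in mm.
#' @param tumor_center_mm numeric(3) or NULL (grid center).
#' @param tumor_radius_mm tumor radius in mm.
#' @param heterogeneity nonnegative amplitude of intratumoral texture
#'   noise relative to the mean tumor intensity.
#' @param n_branches number of vessel branches.
#' @param tortuosity nonnegative helical perturbation amplitude (mm).
#' @param vessel_radius_mm vessel tube radius in mm (> 0).
#' @param noise_sd standard deviation of additive image noise.
#' @param seed integer seed; identical specs give bit-identical phantoms.
#' @return a list of class `PhantomSpec`.
#' @export
phantomSpec <- function(grid_shape = c(64L, 64L, 64L),
                        spacing_mm = c(1, 1, 1),
                        tumor_center_mm = NULL,
                        tumor_radius_mm = 8,
                        heterogeneity = 0.3,
                        n_branches = 8L,
                        tortuosity = 0.5,
                        vessel_radius_mm = 2,
                        noise_sd = 0.02,
                        seed = 1L) {
  if (is.null(tumor_center_mm))
    tumor_center_mm <- (grid_shape - 1) * spacing_mm / 2
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               tumor_center_mm = as.numeric(tumor_center_mm),
               tumor_radius_mm = tumor_radius_mm,
               heterogeneity = heterogeneity,
               n_branches = as.integer(n_branches),
               tortuosity = tortuosity,
               vessel_radius_mm = vessel_radius_mm,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  extent <- (spec$grid_shape - 1) * spec$spacing_mm
  lo <- spec$tumor_center_mm - spec$tumor_radius_mm
  hi <- spec$tumor_center_mm + spec$tumor_radius_mm
  if (any(lo < 0) || any(hi > extent))
    stop("bounds: tumor does not lie fully inside the grid")
  if (spec$vessel_radius_mm <= 0) stop("vessel_radius_mm must be > 0")
  if (spec$heterogeneity < 0) stop("heterogeneity must be >= 0")
  if (spec$tortuosity < 0) stop("tortuosity must be >= 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(spec)
}

# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample a (possibly helical) vessel branch centerline
#'
#' Returns points along a circular helix of amplitude `a` around the axis
#' `direction`, sampled at arc steps of at most 0.5 mm. A circular helix
#' with amplitude a and pitch b has constant curvature a/(a^2+b^2) and
#' torsion b/(a^2+b^2); `a = 0` gives a straight segment.
#'
#' @param start numeric(3), start point (mm).
#' @param direction numeric(3), helix axis direction (normalized
#'   internally).
#' @param length_mm positive arc length of the branch (mm).
#' @param helix_radius_mm helix amplitude a >= 0 (mm).
#' @param helix_pitch_mm helix pitch b (mm per radian); must be > 0 when
#'   a > 0.
#' @param phase starting phase angle (radians) of the helix.
#' @return an n-by-3 matrix of points (mm); the first row is `start`.
#' @examples
#' b <- generateVesselBranch(c(0, 0, 0), c(0, 0, 1), 20, 5, 2)
#' head(b)
#' @export
generateVesselBranch <- function(start, direction, length_mm,
                                 helix_radius_mm, helix_pitch_mm,
                                 phase = 0) {
  if (length_mm <= 0) stop("length_mm must be positive")
  a <- helix_radius_mm
  b <- helix_pitch_mm
  if (a < 0) stop("helix_radius_mm must be >= 0")
  if (a > 0 && b <= 0) stop("helix_pitch_mm must be > 0 when amplitude > 0")
  d <- direction / sqrt(sum(direction^2))
  if (a == 0) {
    n <- max(2L, ceiling(length_mm / 0.5) + 1L)
    s <- seq(0, length_mm, length.out = n)
    return(cbind(start[1] + s * d[1], start[2] + s * d[2],
                 start[3] + s * d[3]))
  }
  # orthonormal frame (u, v) perpendicular to the axis
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  c2 <- sqrt(a^2 + b^2)              # arc length per radian
  t_max <- length_mm / c2
  n <- max(5L, ceiling(length_mm / 0.5) + 1L)
  t <- seq(0, t_max, length.out = n)
  ct <- cos(t + phase) - cos(phase)
  st <- sin(t + phase) - sin(phase)
  pts <- outer(b * t, d) + outer(a * ct, u) + outer(a * st, v)
  sweep(pts, 2, start, `+`)
}

#' Generate a synthetic phantom volume with known ground truth
#'
#' Builds a CT-like volume containing a low-intensity lung ellipsoid, a
#' bright heterogeneous tumor ball, and a binary-branching peritumoral
#' vessel tree rasterized around analytic helical centerlines. The
#' analytic centerlines and their closed-form curvature/torsion are
#' returned as ground truth, so downstream geometry measurements can be
#' validated against exact values.
#'
#' @param spec a [phantomSpec()].
#' @return a list with elements `volume` ([ImageVolume-class]), `tumor`
#'   and `lung` ([RoiMask-class]), and `truth`, a list carrying
#'   `centerlines` (list of n-by-3 matrices), `curvature`, `torsion`
#'   (per-branch analytic values, 1/mm), `vessel_mask` (RoiMask) and the
#'   spec itself.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .validate_phantom_spec(spec)
  .with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  extent <- (d - 1) * sp
  cx <- (seq_len(d[1]) - 1) * sp[1]
  cy <- (seq_len(d[2]) - 1) * sp[2]
  cz <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  center <- extent / 2
  semi <- extent * 0.48
  lung <- ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
  tc <- spec$tumor_center_mm
  r2 <- (X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2
  tumor <- r2 <= spec$tumor_radius_mm^2

  vol <- array(0.3, d)        # body/background
  vol[lung] <- -0.7           # aerated lung

  # vessel tree: binary branching rooted just outside the tumor surface;
  # branches stay strictly inside the lung so the vasculature is fully
  # surrounded by aerated parenchyma
  tree <- .grow_vessel_tree(spec, tc, extent, center, semi)
  vessel_mask <- array(FALSE, d)
  for (br in tree$centerlines)
    vessel_mask <- .rasterize_tube(vessel_mask, br, spec$vessel_radius_mm,
                                   sp)
  vessel_mask <- vessel_mask & lung & !tumor
  vol[vessel_mask] <- 0.8

  tumor_mean <- 1.0
  if (spec$heterogeneity > 0) {
    tex <- array(rnorm(prod(d)), d)
    tex <- .gaussian_smooth(tex, sigma_mm = 2, spacing = sp)
    tex <- tex / sd(tex)
    vol[tumor] <- tumor_mean * (1 + spec$heterogeneity * tex[tumor])
  } else {
    vol[tumor] <- tumor_mean
  }
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(prod(d), sd = spec$noise_sd), d)

  list(volume = imageVolume(vol, spacing = sp),
       tumor = roiMask(tumor, spacing = sp),
       lung = roiMask(lung | tumor, spacing = sp),
       truth = list(centerlines = tree$centerlines,
                    curvature = tree$curvature,
                    torsion = tree$torsion,
                    vessel_mask = roiMask(vessel_mask, spacing = sp),
                    spec = spec))
}

# helix geometry of the tortuosity parameter t: amplitude saturates at
# 1 mm while the pitch shrinks as 3/t, so both the analytic curvature
# a/(a^2+b^2) and torsion b/(a^2+b^2) increase monotonically with t and
# the perturbation wavelength stays measurable at branch scale
.helix_params <- function(tortuosity) {
  if (tortuosity <= 0) return(list(a = 0, b = Inf))
  list(a = min(tortuosity, 1), b = 3 / tortuosity)
}

.grow_vessel_tree <- function(spec, tumor_center, extent, lung_center,
                              lung_semi) {
  hp <- .helix_params(spec$tortuosity)
  a <- hp$a
  b <- hp$b
  n_target <- spec$n_branches
  centerlines <- list()
  curvature <- numeric(0)
  torsion <- numeric(0)
  # frontier of (start, direction) pairs; roots on the tumor surface
  n_roots <- min(3L, n_target)
  frontier <- list()
  for (i in seq_len(n_roots)) {
    dir0 <- rnorm(3)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    start <- tumor_center + dir0 * (spec$tumor_radius_mm + 1.5)
    frontier[[length(frontier) + 1L]] <- list(start = start, dir = dir0)
  }
  while (length(centerlines) < n_target && length(frontier) > 0) {
    node <- frontier[[1]]
    frontier[[1]] <- NULL
    len <- runif(1, 12, 18)
    phase <- runif(1, 0, 2 * pi)
    pts <- if (a > 0)
      generateVesselBranch(node$start, node$dir, len, a, b, phase = phase)
    else
      generateVesselBranch(node$start, node$dir, len, 0, 1)
    # truncate where the centerline leaves the grid margin or the lung
    margin <- spec$vessel_radius_mm + 0.5
    semi_in <- pmax(lung_semi - (spec$vessel_radius_mm + 1.5), 1)
    ell <- sweep(sweep(pts, 2, lung_center), 2, semi_in, `/`)
    inside <- pts[, 1] >= margin & pts[, 1] <= extent[1] - margin &
      pts[, 2] >= margin & pts[, 2] <= extent[2] - margin &
      pts[, 3] >= margin & pts[, 3] <= extent[3] - margin &
      rowSums(ell^2) <= 1
    cut <- which(!inside)
    if (length(cut) && cut[1] <= 4) next   # too little room, drop
    if (length(cut)) pts <- pts[seq_len(cut[1] - 1L), , drop = FALSE]
    centerlines[[length(centerlines) + 1L]] <- pts
    if (a > 0) {
      curvature <- c(curvature, a / (a^2 + b^2))
      torsion <- c(torsion, b / (a^2 + b^2))
    } else {
      curvature <- c(curvature, 0)
      torsion <- c(torsion, 0)
    }
    # spawn two children at the branch end
    endp <- pts[nrow(pts), ]
    tangent <- pts[nrow(pts), ] - pts[max(1, nrow(pts) - 2), ]
    tangent <- tangent / sqrt(sum(tangent^2))
    for (k in 1:2) {
      perp <- rnorm(3)
      perp <- perp - sum(perp * tangent) * tangent
      perp <- perp / sqrt(sum(perp^2))
      ang <- runif(1, 0.4, 0.8)
      child_dir <- cos(ang) * tangent + sin(ang) * perp
      frontier[[length(frontier) + 1L]] <-
        list(start = endp, dir = child_dir)
    }
  }
  if (length(centerlines) == 0)
    stop("bounds: no vessel branch fits inside the grid")
  list(centerlines = centerlines, curvature = curvature, torsion = torsion)
}

.rasterize_tube <- function(mask, pts, radius_mm, spacing) {
  d <- dim(mask)
  rvox <- ceiling(radius_mm / spacing)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ctr <- p / spacing            # 0-based fractional voxel coords
    lo <- pmax(floor(ctr - rvox), 0)
    hi <- pmin(ceiling(ctr + rvox), d - 1)
    if (any(lo > hi)) next
    ix <- seq(lo[1], hi[1]); iy <- seq(lo[2], hi[2]); iz <- seq(lo[3], hi[3])
    dx2 <- (ix * spacing[1] - p[1])^2
    dy2 <- (iy * spacing[2] - p[2])^2
    dz2 <- (iz * spacing[3] - p[3])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
    block <- mask[ix + 1, iy + 1, iz + 1, drop = FALSE]
    mask[ix + 1, iy + 1, iz + 1] <- block | sub
  }
  mask
}

# separable Gaussian smoothing with edge replication
.gaussian_smooth <- function(arr, sigma_mm, spacing) {
  for (axis in 1:3) {
    sig_vox <- sigma_mm / spacing[axis]
    if (sig_vox < 1e-8) next
    r <- max(1L, ceiling(3 * sig_vox))
    k <- dnorm(seq(-r, r), sd = sig_vox)
    k <- k / sum(k)
    arr <- .conv_axis(arr, k, axis)
  }
  arr
}

# 1D convolution along an axis with edge-clamped boundary
.conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    k <- j - r - 1L
    out <- out + kernel[j] * .shift_axis_clamped(arr, axis, k)
  }
  out
}

.shift_axis_clamped <- function(arr, axis, k) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  n <- d[axis]
  idx[[axis]] <- pmin(pmax(seq_len(n) + k, 1L), n)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}
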