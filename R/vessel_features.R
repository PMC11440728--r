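#' The 91 peritumoral-vasculature features
#'
#' Computes the morphology block (five summary statistics -- mean, SD,
#' skewness, kurtosis, median -- over branches of 12 per-branch geometric
#' quantities from [branchGeometry()], plus the total vessel volume;
#' 12 x 5 + 1 = 61) and the organization block (branch/junction/tip
#' counts and densities plus the same five statistics over five
#' inter-branch arrangement quantities; 5 + 5 x 5 = 30). Names and order
#' follow [vesselManifest()]. Branches too short for torsion are skipped
#' from the torsion statistics and counted in attribute
#' `skipped_branches`. An empty tree yields all-zero features with
#' attribute `empty`.
#'
#' @param tree a [VesselTree-class].
#' @param cube_volume_mm3 physical volume of the peritumoral cube (mm^3),
#'   used for the per-cm^3 densities.
#' @param tumor_center numeric(3) (mm) for orientation angles; NULL
#'   disables (angles 0).
#' @param tumor_surface_points optional k-by-3 matrix of tumor surface
#'   coordinates (mm) for branch-to-tumor distances; NULL disables.
#' @param smoothing_mm passed to [branchGeometry()].
#' @return named numeric vector of length 91.
#' @export
extractVesselFeatures <- function(tree, cube_volume_mm3,
                                  tumor_center = NULL,
                                  tumor_surface_points = NULL,
                                  smoothing_mm = 1.5) {
  stopifnot(is(tree, "VesselTree"))
  manifest <- vesselManifest()
  if (length(tree@branches) == 0) {
    out <- setNames(numeric(91), manifest$name)
    attr(out, "empty") <- TRUE
    attr(out, "skipped_branches") <- 0L
    return(out)
  }
  geoms <- list()
  skipped <- 0L
  for (b in seq_along(tree@branches)) {
    pts <- tree@branches[[b]]
    g <- tryCatch(branchGeometry(pts, smoothing_mm = smoothing_mm),
                  error = function(e) NULL)
    if (is.null(g)) { skipped <- skipped + 1L; next }
    g$mean_radius <- mean(tree@radii[[b]])
    g$points <- pts
    g$radii <- tree@radii[[b]]
    geoms[[length(geoms) + 1L]] <- g
  }
  if (!length(geoms)) {
    out <- setNames(numeric(91), manifest$name)
    attr(out, "empty") <- TRUE
    attr(out, "skipped_branches") <- skipped
    return(out)
  }
  quant_names <- c("mean_curvature", "max_curvature", "mean_torsion",
                   "max_torsion", "length", "mean_radius", "straightness",
                   "curvature_skewness", "torsion_skewness",
                   "inflection_count", "total_curvature", "total_torsion")
  morph <- numeric(0)
  for (qn in quant_names) {
    vals <- vapply(geoms, function(g) g[[qn]], numeric(1))
    vals <- vals[!is.na(vals)]
    morph <- c(morph, .summary5(vals))
  }
  total_vol <- sum(vapply(geoms, function(g) {
    seg <- sqrt(rowSums(diff(g$points)^2))
    mid_r <- (g$radii[-1] + g$radii[-length(g$radii)]) / 2
    sum(pi * mid_r^2 * seg)
  }, numeric(1)))
  morph <- c(morph, total_vol)

  n_br <- length(geoms)
  n_j <- nrow(tree@junctions)
  cube_cm3 <- cube_volume_mm3 / 1000
  # tips: branch endpoints not within one voxel-ish (1.8 mm) of a junction
  ends <- do.call(rbind, lapply(geoms, function(g)
    g$points[c(1, nrow(g$points)), , drop = FALSE]))
  if (n_j > 0) {
    dmin <- apply(ends, 1, function(p)
      min(sqrt(colSums((t(tree@junctions) - p)^2))))
    n_tips <- sum(dmin > 1.8)
  } else n_tips <- nrow(ends)

  centroids <- t(vapply(geoms, function(g) colMeans(g$points), numeric(3)))
  nearest_d <- .nearest_branch_distances(geoms)
  angle <- vapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    chord <- g$points[nrow(g$points), ] - g$points[1, ]
    nc <- sqrt(sum(chord^2))
    if (is.null(tumor_center) || nc == 0) return(0)
    ray <- centroids[i, ] - tumor_center
    nr <- sqrt(sum(ray^2))
    if (nr == 0) return(0)
    acos(pmin(pmax(abs(sum(chord * ray)) / (nc * nr), 0), 1))
  }, numeric(1))
  dispersion <- vapply(geoms, function(g) {
    tang <- diff(g$points)
    nt <- sqrt(rowSums(tang^2))
    tang <- tang[nt > 0, , drop = FALSE] / nt[nt > 0]
    if (nrow(tang) == 0) return(0)
    1 - sqrt(sum(colMeans(tang)^2))
  }, numeric(1))
  tumor_dist <- vapply(seq_along(geoms), function(i) {
    if (is.null(tumor_surface_points)) return(0)
    p <- centroids[i, ]
    min(sqrt(colSums((t(tumor_surface_points) - p)^2)))
  }, numeric(1))
  local_spacing <- .local_spacing(geoms)

  org <- c(branch_count = n_br, junction_count = n_j,
           branch_density_cm3 = n_br / cube_cm3,
           junction_density_cm3 = n_j / cube_cm3,
           tip_count = n_tips,
           .summary5(nearest_d), .summary5(angle), .summary5(dispersion),
           .summary5(tumor_dist), .summary5(local_spacing))
  out <- c(morph, org)
  names(out) <- manifest$name
  attr(out, "empty") <- FALSE
  attr(out, "skipped_branches") <- skipped
  out
}

# per branch: minimum centerline-to-centerline distance to any other
# branch (0 when there is a single branch)
.nearest_branch_distances <- function(geoms) {
  n <- length(geoms)
  if (n == 1) return(0)
  pts <- lapply(geoms, function(g) g$points)
  vapply(seq_len(n), function(i) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      a <- pts[[i]]; b <- pts[[j]]
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
      best <- min(best, min(d2))
    }
    sqrt(max(best, 0))
  }, numeric(1))
}

# per branch: median nearest-point distance from its points to the
# other branches' points
.local_spacing <- function(geoms) {
  n <- length(geoms)
  if (n == 1) return(0)
  pts <- lapply(geoms, function(g) g$points)
  vapply(seq_len(n), function(i) {
    a <- pts[[i]]
    other <- do.call(rbind, pts[-i])
    d2 <- outer(rowSums(a^2), rowSums(other^2), `+`) - 2 * a %*% t(other)
    median(sqrt(pmax(apply(d2, 1, min), 0)))
  }, numeric(1))
}

#' End-to-end peritumoral-vasculature radiomics
#'
#' Convenience wrapper: segments the peritumoral vessels
#' ([segmentVessels()]), extracts centerlines ([extractCenterlines()])
#' and computes the 91 vasculature features
#' ([extractVesselFeatures()]).
#'
#' @inheritParams segmentVessels
#' @param ... passed to [segmentVessels()].
#' @return named numeric vector of length 91 (attributes `empty`,
#'   `skipped_branches`), with the intermediate `tree` attached as
#'   attribute `tree`.
#' @export
extractVesselRadiomics <- function(volume, tumor_mask, lung_mask = NULL,
                                   ...) {
  seg <- segmentVessels(volume, tumor_mask, lung_mask, ...)
  lo <- seg$cube$lo; hi <- seg$cube$hi
  sp <- volume@spacing
  cube_vol <- prod((hi - lo + 1) * sp)
  cube_vals <- seg$vessel_mask@values[lo[1]:hi[1], lo[2]:hi[2],
                                      lo[3]:hi[3], drop = FALSE]
  cube_mask <- roiMask(cube_vals, spacing = sp,
                       origin = (lo - 1) * sp)
  tree <- extractCenterlines(cube_mask)
  # shift branch coordinates back to volume frame
  offset <- (lo - 1) * sp
  tree@branches <- lapply(tree@branches, function(b)
    sweep(b, 2, offset, `+`))
  if (nrow(tree@junctions) > 0)
    tree@junctions <- sweep(tree@junctions, 2, offset, `+`)
  tidx <- which(.surface_voxels(tumor_mask@values), arr.ind = TRUE)
  tsurf <- sweep(tidx - 1, 2, sp, `*`)
  tcenter <- colMeans(sweep(which(tumor_mask@values, arr.ind = TRUE) - 1,
                            2, sp, `*`))
  fv <- extractVesselFeatures(tree, cube_vol, tumor_center = tcenter,
                              tumor_surface_points = tsurf)
  attr(fv, "tree") <- tree
  fv
}

#' Outlier-based feature filtering
#'
#' For every feature, the mean and SD are computed on the reference rows
#' (normally the training split); the outlier fraction -- values more
#' than `z_threshold` reference-SDs from the reference mean -- is counted
#' over ALL rows, and features whose fraction strictly exceeds
#' `max_fraction` are removed. Features with zero reference SD are
#' removed and reported. Reference statistics must come from a subset:
#' a fraction above 20% outside three SDs of the same sample's own
#' moments is impossible (Chebyshev bounds it near 11%).
#'
#' @param feature_table data.frame or matrix of numeric features.
#' @param reference_rows integer indices of the reference (training)
#'   rows.
#' @param z_threshold SD multiple defining an outlier (default 3).
#' @param max_fraction removal threshold on the outlier fraction,
#'   exclusive (default 0.20).
#' @return a list: `filtered` (table restricted to kept columns),
#'   `report` (data.frame feature/fraction/reason for every removal),
#'   `kept` (character vector).
#' @export
outlierFilter <- function(feature_table, reference_rows,
                          z_threshold = 3, max_fraction = 0.20) {
  X <- as.data.frame(feature_table)
  num_cols <- names(X)[vapply(X, is.numeric, logical(1))]
  if (length(reference_rows) == 0) stop("reference_rows must be nonempty")
  removed <- character(0)
  fractions <- numeric(0)
  reasons <- character(0)
  for (nm in num_cols) {
    x <- X[[nm]]
    mu <- mean(x[reference_rows])
    s <- sd(x[reference_rows])
    if (!is.finite(s) || s == 0) {
      removed <- c(removed, nm); fractions <- c(fractions, NA_real_)
      reasons <- c(reasons, "zero reference SD")
      next
    }
    frac <- mean(abs(x - mu) > z_threshold * s)
    if (frac > max_fraction) {
      removed <- c(removed, nm); fractions <- c(fractions, frac)
      reasons <- c(reasons, "outlier fraction")
    }
  }
  kept <- setdiff(names(X), removed)
  list(filtered = X[, kept, drop = FALSE],
       report = data.frame(feature = removed, fraction = fractions,
                           reason = reasons),
       kept = kept)
}
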