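#' Extract vessel centerlines and branches from a binary mask
#'
#' Computes a one-voxel-wide curve skeleton by distance-ordered homotopic
#' thinning: voxels are removed in order of increasing distance to the
#' vessel surface, only when removal preserves local topology (simple
#' points) and the voxel is not a curve endpoint, so the result is
#' maximally distant from the surface. Spur branches shorter than the
#' local vessel radius (medial-surface remnants of the thinning) are
#' pruned iteratively, with branches re-partitioned after every pass.
#' The skeleton graph is split into branches at junction voxels (3 or
#' more skeleton neighbors); the per-point radius is the Euclidean
#' distance to the vessel surface, and each centerline point is refined
#' to the centroid of its local vessel cross-section for sub-voxel
#' accuracy.
#'
#' @param vessel_mask a [RoiMask-class].
#' @param min_branch_points branches with fewer centerline points are
#'   dropped (default 3).
#' @param prune_mm minimum arc length (mm) of a junction-attached twig;
#'   the effective threshold per twig is
#'   `max(prune_mm, 1.5 * median twig radius)` (default 2 mm).
#' @param recenter refine each centerline point to the centroid of its
#'   local vessel cross-section (default TRUE).
#' @return a [VesselTree-class]; an empty mask (or one thinner than one
#'   voxel everywhere) yields an empty tree with attribute `empty`.
#' @export
extractCenterlines <- function(vessel_mask, min_branch_points = 3L,
                               prune_mm = 2, recenter = TRUE) {
  stopifnot(is(vessel_mask, "RoiMask"))
  m <- vessel_mask@values
  sp <- vessel_mask@spacing
  d <- dim(m)
  bounds <- rbind(c(0, 0, 0), (d - 1) * sp)
  empty_tree <- function() {
    tr <- new("VesselTree", branches = list(), radii = list(),
              junctions = matrix(numeric(0), 0, 3), bounds = bounds)
    attr(tr, "empty") <- TRUE
    tr
  }
  if (!any(m)) return(empty_tree())
  d2 <- .edt_sq(m, sp)
  skel <- array(cpp_thin(as.logical(m), as.integer(d), as.numeric(d2)), d)
  if (!any(skel)) return(empty_tree())
  radii_arr <- sqrt(d2)

  # iterative twig pruning: partition, drop short junction-attached
  # spurs, re-partition (junction voxels may turn into ordinary path
  # voxels once their spurs are gone)
  for (pass in 1:6) {
    part <- .partition_skeleton(skel, sp)
    if (is.null(part)) return(empty_tree())
    twig <- logical(length(part$paths))
    for (i in seq_along(part$paths)) {
      p <- part$paths[[i]]
      anchored <- part$head_j[i] || part$tail_j[i]
      if (!anchored) next
      arc <- sum(sqrt(rowSums(diff(part$coords[p, , drop = FALSE])^2)))
      rad <- median(radii_arr[part$lin[p]])
      both_j <- part$head_j[i] && part$tail_j[i]
      tipped <- !both_j
      if (tipped && arc < max(prune_mm, 1.5 * rad)) twig[i] <- TRUE
      if (both_j && part$same_cluster[i] && part$n_interior[i] <= 2L)
        twig[i] <- TRUE
    }
    if (!any(twig)) break
    for (i in which(twig)) {
      interior <- part$interior[[i]]
      skel[part$lin[interior]] <- FALSE
    }
    if (!any(skel)) return(empty_tree())
  }
  part <- .partition_skeleton(skel, sp)
  if (is.null(part)) return(empty_tree())

  branch_list <- list()
  radii_list <- list()
  for (i in seq_along(part$paths)) {
    p <- part$paths[[i]]
    if (length(p) < max(2L, min_branch_points)) next
    branch_list[[length(branch_list) + 1L]] <-
      part$coords[p, , drop = FALSE]
    radii_list[[length(radii_list) + 1L]] <- radii_arr[part$lin[p]]
  }
  if (!length(branch_list)) return(empty_tree())
  if (recenter) {
    mask_coords <- sweep(which(m, arr.ind = TRUE) - 1, 2, sp, `*`)
    branch_list <- lapply(seq_along(branch_list), function(bi)
      .recenter_branch(branch_list[[bi]], mask_coords,
                       mean(radii_list[[bi]]), max(sp)))
  }
  tr <- new("VesselTree", branches = branch_list, radii = radii_list,
            junctions = part$junction_centroids, bounds = bounds)
  attr(tr, "empty") <- FALSE
  tr
}

# Partition skeleton voxels into branch paths. Returns NULL when the
# skeleton is empty; otherwise a list with per-voxel data (coords in mm,
# linear indices) and per-branch data: ordered voxel-id paths (junction
# anchors included), whether each end is junction-anchored, whether both
# anchors fall in the same junction cluster, the interior (non-junction)
# ids, and the junction-cluster centroids.
.partition_skeleton <- function(skel, sp) {
  d <- dim(skel)
  vox <- which(skel, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0) return(NULL)
  lin <- which(as.vector(skel))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edge_src <- integer(0); edge_tgt <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] +
      nb[ok, 1]
    j <- match(nb_lin, lin)
    present <- !is.na(j)
    edge_src <- c(edge_src, which(ok)[present])
    edge_tgt <- c(edge_tgt, j[present])
  }
  nbr <- rep(list(integer(0)), n)
  if (length(edge_src)) {
    sp_edges <- split(edge_tgt, edge_src)
    nbr[as.integer(names(sp_edges))] <- sp_edges
  }
  deg <- lengths(nbr)
  is_junction <- deg >= 3L
  coords <- sweep(vox - 1, 2, sp, `*`)

  jset <- rep(NA_integer_, n)
  jc <- matrix(numeric(0), 0, 3)
  if (any(is_junction)) {
    cl <- 0L
    for (j in which(is_junction)) {
      if (!is.na(jset[j])) next
      cl <- cl + 1L
      stack <- j
      while (length(stack)) {
        cur <- stack[[1]]; stack <- stack[-1]
        if (!is.na(jset[cur])) next
        jset[cur] <- cl
        nxt <- nbr[[cur]]
        stack <- c(stack, nxt[is_junction[nxt] & is.na(jset[nxt])])
      }
    }
    jc <- do.call(rbind, lapply(seq_len(cl), function(k)
      colMeans(coords[which(jset == k), , drop = FALSE])))
  }

  visited <- rep(FALSE, n)
  paths <- list(); head_j <- logical(0); tail_j <- logical(0)
  same_cluster <- logical(0); interior <- list(); n_interior <- integer(0)
  for (start in seq_len(n)) {
    if (visited[start] || is_junction[start]) next
    seg <- integer(0)
    stack <- start
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      if (visited[cur] || is_junction[cur]) next
      visited[cur] <- TRUE
      seg <- c(seg, cur)
      nxt <- nbr[[cur]]
      stack <- c(stack, nxt[!visited[nxt] & !is_junction[nxt]])
    }
    ends <- seg[vapply(seg, function(i)
      sum(nbr[[i]] %in% seg) <= 1L, logical(1))]
    first <- if (length(ends)) ends[1] else seg[1]
    path <- integer(0)
    cur <- first; prev <- -1L
    repeat {
      path <- c(path, cur)
      cand <- nbr[[cur]]
      cand <- cand[cand %in% seg & cand != prev & !(cand %in% path)]
      if (!length(cand)) break
      prev <- cur
      cur <- cand[1]
    }
    hj <- nbr[[path[1]]][is_junction[nbr[[path[1]]]]]
    tj <- nbr[[path[length(path)]]][
      is_junction[nbr[[path[length(path)]]]]]
    full <- c(if (length(hj)) hj[1], path, if (length(tj)) tj[1])
    paths[[length(paths) + 1L]] <- full
    head_j <- c(head_j, length(hj) > 0)
    tail_j <- c(tail_j, length(tj) > 0)
    same_cluster <- c(same_cluster,
                      length(hj) > 0 && length(tj) > 0 &&
                        identical(jset[hj[1]], jset[tj[1]]))
    interior[[length(interior) + 1L]] <- path
    n_interior <- c(n_interior, length(path))
  }
  if (!length(paths)) return(NULL)
  list(coords = coords, lin = lin, paths = paths, head_j = head_j,
       tail_j = tail_j, same_cluster = same_cluster,
       interior = interior, n_interior = n_interior,
       junction_centroids = jc)
}

# sub-voxel refinement: move each skeleton point to the centroid of the
# vessel voxels in a thin slab perpendicular to the local tangent,
# projected back onto the normal plane so arc positions are preserved
.recenter_branch <- function(b, mask_coords, radius_guess, voxel_mm) {
  n <- nrow(b)
  out <- b
  rmax2 <- (max(radius_guess, voxel_mm) * 1.6)^2
  for (i in seq_len(n)) {
    i0 <- max(1L, i - 2L); i1 <- min(n, i + 2L)
    tg <- b[i1, ] - b[i0, ]
    ntg <- sqrt(sum(tg^2))
    if (ntg == 0) next
    tg <- tg / ntg
    rel <- sweep(mask_coords, 2, b[i, ])
    sel <- rowSums(rel^2) <= rmax2
    if (sum(sel) < 3) next
    rels <- rel[sel, , drop = FALSE]
    proj <- as.numeric(rels %*% tg)
    slab <- abs(proj) <= 0.71 * voxel_mm
    if (sum(slab) < 3) next
    cen <- colMeans(rels[slab, , drop = FALSE])
    cen <- cen - sum(cen * tg) * tg
    nc <- sqrt(sum(cen^2))
    cap <- 0.6 * voxel_mm       # raster jitter never exceeds a voxel
    if (nc > cap) cen <- cen * cap / nc
    out[i, ] <- b[i, ] + cen
  }
  # keep the <= 2 mm consecutive-step guarantee: back the refinement off
  # if it ever stretched a step too far
  for (k in 1:4) {
    if (all(sqrt(rowSums(diff(out)^2)) <= 2 - 1e-9)) break
    out <- b + (out - b) / 2
  }
  if (any(sqrt(rowSums(diff(out)^2)) > 2 - 1e-9)) out <- b
  out
}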