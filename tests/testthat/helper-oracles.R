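# Independent brute-force oracles used across the suite. Each one is a
# direct, unoptimized implementation of the defining formula, kept free
# of any code path it is used to check.

# O(n^2) concordance by explicit double loop over ordered pairs
oracle_cindex <- function(time, event, risk) {
  conc <- 0; eval_n <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      eval_n <- eval_n + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / eval_n
}

# Mann-Whitney AUC between case scores and control scores
oracle_mann_whitney <- function(cases, controls) {
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# exhaustive pair counting for the symmetric GLCM over given offsets
oracle_glcm <- function(q, n_bins, dirs) {
  d <- dim(q)
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      a <- q[x, y, z]
      if (is.na(a)) next
      xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      b <- q[xx, yy, zz]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# direct run scanning along one direction for the GLRLM
oracle_glrlm <- function(q, dir, n_bins) {
  d <- dim(q)
  runs <- list()
  visited <- array(FALSE, d)
  step_back <- function(p) p - dir
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    g <- q[x, y, z]
    if (is.na(g)) next
    # start of a run: predecessor out of bounds, off-mask, or different
    pb <- step_back(p)
    if (inb(pb) && !is.na(q[pb[1], pb[2], pb[3]]) &&
        q[pb[1], pb[2], pb[3]] == g) next
    len <- 0
    while (inb(p) && !is.na(q[p[1], p[2], p[3]]) &&
           q[p[1], p[2], p[3]] == g) {
      len <- len + 1
      p <- p + dir
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  m <- do.call(rbind, runs)
  max_len <- max(m[, 2])
  out <- matrix(0, n_bins, max_len)
  for (r in seq_len(nrow(m))) out[m[r, 1], m[r, 2]] <-
      out[m[r, 1], m[r, 2]] + 1
  out
}

# per-voxel 26-neighbor greater-than count, straight enumeration
oracle_lbp_counts <- function(v, mask) {
  d <- dim(v)
  res <- c()
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    if (!mask[x, y, z]) next
    cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (v[x + dx, y + dy, z + dz] > v[x, y, z]) cnt <- cnt + 1
    }
    res <- c(res, cnt)
  }
  res
}

# Breslow partial log-likelihood of a single-covariate Cox model,
# written out directly for grid-search maximization
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# curvature/torsion by independent finite differences on raw points
# (no resampling or smoothing)
oracle_frenet <- function(pts) {
  n <- nrow(pts)
  i <- 2:(n - 1)
  h <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  d1 <- (pts[i + 1, ] - pts[i - 1, ]) / (2 * h)
  d2 <- (pts[i + 1, ] - 2 * pts[i, ] + pts[i - 1, ]) / h^2
  j <- 3:(n - 2)
  d3 <- (pts[j + 2, ] - 2 * pts[j + 1, ] + 2 * pts[j - 1, ] -
           pts[j - 2, ]) / (2 * h^3)
  d1j <- d1[j - 1, ]; d2j <- d2[j - 1, ]
  cr <- cbind(d1j[, 2] * d2j[, 3] - d1j[, 3] * d2j[, 2],
              d1j[, 3] * d2j[, 1] - d1j[, 1] * d2j[, 3],
              d1j[, 1] * d2j[, 2] - d1j[, 2] * d2j[, 1])
  kappa <- sqrt(rowSums(cr^2)) / rowSums(d1j^2)^1.5
  tau <- rowSums(cr * d3) / rowSums(cr^2)
  list(kappa = kappa, tau = tau)
}

# small random survival dataset
random_outcome <- function(n, seed, cens = 0.3) {
  set.seed(seed)
  data.frame(time = round(rexp(n, 0.2), 3) + 0.01,
             event = rbinom(n, 1, 1 - cens))
}
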