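# Independent brute-force oracles. These deliberately use naive loops and
# different algorithms from the package implementation so that agreement is
# meaningful.

# symmetric co-occurrence counts by looping over every voxel pair
oracle_glcm <- function(g, n_levels, dir) {
  d <- dim(g)
  M <- matrix(0, n_levels, n_levels)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- g[i, j, k]
    if (a == 0) next
    ii <- i + dir[1]; jj <- j + dir[2]; kk <- k + dir[3]
    if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
      next
    b <- g[ii, jj, kk]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# run-length counts by explicitly scanning every lattice line
oracle_glrlm <- function(g, n_levels, dir) {
  d <- dim(g)
  runs <- list()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    # line start: predecessor along -dir is outside the grid
    pi <- i - dir[1]; pj <- j - dir[2]; pk <- k - dir[3]
    if (pi >= 1 && pj >= 1 && pk >= 1 && pi <= d[1] && pj <= d[2] &&
        pk <= d[3]) next
    # walk the whole line, emitting maximal constant nonzero runs
    ci <- i; cj <- j; ck <- k
    cur <- 0L; len <- 0L
    while (ci >= 1 && cj >= 1 && ck >= 1 && ci <= d[1] && cj <= d[2] &&
           ck <= d[3]) {
      v <- g[ci, cj, ck]
      if (v == cur) {
        len <- len + 1L
      } else {
        if (cur > 0) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v
        len <- 1L
      }
      ci <- ci + dir[1]; cj <- cj + dir[2]; ck <- ck + dir[3]
    }
    if (cur > 0) runs[[length(runs) + 1]] <- c(cur, len)
  }
  max_len <- max(c(1, vapply(runs, `[`, numeric(1), 2)))
  M <- matrix(0, n_levels, max_len)
  for (r in runs) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# zones by breadth-first flood fill over the 26-neighbourhood
oracle_zones <- function(g) {
  d <- dim(g)
  seen <- array(FALSE, dim = d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(g > 0)) {
    if (seen[start]) next
    lev <- g[start]
    queue <- start
    seen[start] <- TRUE
    members <- c()
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      members <- c(members, p)
      pc <- arrayInd(p, d)
      for (r in seq_len(nrow(offs))) {
        q <- pc + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (!seen[qi] && g[qi] == lev) {
          seen[qi] <- TRUE
          queue <- c(queue, qi)
        }
      }
    }
    zones[[length(zones) + 1]] <- list(level = lev, size = length(members))
  }
  zones
}

# per-voxel neighbour averages by direct looping (for NGTDM)
oracle_ngtdm_si <- function(g, n_levels) {
  d <- dim(g)
  si <- rep(0, n_levels)
  ni <- rep(0L, n_levels)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- g[i, j, k]
    if (v == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
          kk > d[3]) next
      w <- g[ii, jj, kk]
      if (w > 0) nb <- c(nb, w)
    }
    if (length(nb) == 0) next
    ni[v] <- ni[v] + 1L
    si[v] <- si[v] + abs(v - mean(nb))
  }
  list(ni = ni, si = si)
}

# NGLDM dependence-count matrix by direct looping (alpha = 0, distance 1)
oracle_ngldm <- function(g, n_levels) {
  d <- dim(g)
  recs <- list()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- g[i, j, k]
    if (v == 0) next
    dep <- 0L
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
          kk > d[3]) next
      if (g[ii, jj, kk] == v) dep <- dep + 1L
    }
    recs[[length(recs) + 1]] <- c(v, dep + 1L)
  }
  max_dep <- max(vapply(recs, `[`, numeric(1), 2))
  M <- matrix(0, n_levels, max_dep)
  for (r in recs) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# one-way ANOVA ICC via stats::aov, an independent code path
oracle_icc_aov <- function(panel) {
  df <- data.frame(y = as.vector(panel),
                   subject = factor(rep(seq_len(nrow(panel)),
                                        times = ncol(panel))))
  tab <- summary(stats::aov(y ~ subject, data = df))[[1]]
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(panel)
  (msb - msw) / (msb + (k - 1) * msw)
}
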