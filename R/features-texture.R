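# Texture-matrix feature families on the discretised ROI: GLCM (25), GLRLM
# (16), GLSZM (16), GLDZM (16), NGTDM (5) and NGLDM (17). Matrices are
# built in 3D; GLCM and GLRLM are computed per direction (13 unique lattice
# directions at Chebyshev distance 1) and their features averaged, the
# zone/distance/dependence families use a single matrix per ROI.

# the 13 unique (up to sign) 26-neighbourhood directions
TEXTURE_DIRECTIONS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

glcm_feature_names <- c(
  "joint_max", "joint_avg", "joint_var", "joint_entropy", "diff_avg",
  "diff_var", "diff_entropy", "sum_avg", "sum_var", "sum_entropy",
  "angular_second_moment", "contrast", "dissimilarity", "inv_diff",
  "inv_diff_norm", "inv_diff_mom", "inv_diff_mom_norm", "inv_var",
  "correlation", "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "info_corr_1", "info_corr_2")

glrlm_feature_names <- c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_pct", "gl_var", "rl_var",
  "run_entropy")

glszm_feature_names <- c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "glnu_norm", "zsnu", "zsnu_norm", "zone_pct", "gl_var", "zs_var",
  "zs_entropy")

gldzm_feature_names <- c(
  "sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge", "ldhge",
  "glnu", "glnu_norm", "zdnu", "zdnu_norm", "zone_pct", "gl_var", "zd_var",
  "zd_entropy")

ngtdm_feature_names <- c("coarseness", "contrast", "busyness", "complexity",
                         "strength")

ngldm_feature_names <- c(
  "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
  "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_pct", "gl_var", "dc_var",
  "dc_entropy", "dc_energy")

# Discretised ROI as an integer array: grey levels 1..Ng inside the
# intensity mask, 0 elsewhere.
level_grid <- function(image, int_mask, method, value, config) {
  g <- array(0L, dim = dim(image$voxels))
  lv <- discretise(image$voxels[int_mask$labels], method = method,
                   value = value, config = config)
  g[int_mask$labels] <- lv
  attr(g, "n_levels") <- attr(lv, "n_levels")
  g
}

# ---- GLCM -----------------------------------------------------------------

# Symmetric co-occurrence matrix for one direction (voxel pairs at Chebyshev
# distance 1 along `dir`, both inside the ROI).
glcm_matrix <- function(grid, n_levels, dir) {
  d <- dim(grid)
  sx <- shift_range(d[1], dir[1]); sy <- shift_range(d[2], dir[2])
  sz <- shift_range(d[3], dir[3])
  a <- grid[sx$dst, sy$dst, sz$dst]
  b <- grid[sx$src, sy$src, sz$src]
  keep <- a > 0 & b > 0
  a <- a[keep]; b <- b[keep]
  M <- matrix(0, n_levels, n_levels)
  if (length(a) > 0) {
    tab <- table(factor(a, levels = seq_len(n_levels)),
                 factor(b, levels = seq_len(n_levels)))
    M <- unclass(tab) + t(unclass(tab))
    dimnames(M) <- NULL
    M <- matrix(as.numeric(M), n_levels, n_levels)
  }
  M
}

glcm_features_one <- function(M) {
  out <- stats::setNames(rep(NA_real_, length(glcm_feature_names)),
                         glcm_feature_names)
  s <- sum(M)
  if (s == 0) return(out)
  P <- M / s
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu <- sum(i * P)
  out["joint_max"] <- max(P)
  out["joint_avg"] <- mu
  out["joint_var"] <- sum((i - mu)^2 * P)
  pp <- P[P > 0]
  out["joint_entropy"] <- -sum(pp * log2(pp))
  # diagonal (difference) and cross-diagonal (sum) probabilities
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  out["diff_avg"] <- da
  out["diff_var"] <- sum((k_diff - da)^2 * p_diff)
  pd <- p_diff[p_diff > 0]
  out["diff_entropy"] <- -sum(pd * log2(pd))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  sa <- sum(k_sum * p_sum)
  out["sum_avg"] <- sa
  out["sum_var"] <- sum((k_sum - sa)^2 * p_sum)
  ps <- p_sum[p_sum > 0]
  out["sum_entropy"] <- -sum(ps * log2(ps))
  out["angular_second_moment"] <- sum(P^2)
  out["contrast"] <- sum((i - j)^2 * P)
  out["dissimilarity"] <- sum(abs(i - j) * P)
  out["inv_diff"] <- sum(P / (1 + abs(i - j)))
  out["inv_diff_norm"] <- sum(P / (1 + abs(i - j) / ng))
  out["inv_diff_mom"] <- sum(P / (1 + (i - j)^2))
  out["inv_diff_mom_norm"] <- sum(P / (1 + (i - j)^2 / ng^2))
  off <- i != j
  out["inv_var"] <- sum(P[off] / (i[off] - j[off])^2)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  out["correlation"] <- if (sdx * sdy > 0) {
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  } else 1  # degenerate one-level limit
  out["autocorrelation"] <- sum(i * j * P)
  ct <- (i + j - mux - muy)
  out["cluster_tendency"] <- sum(ct^2 * P)
  out["cluster_shade"] <- sum(ct^3 * P)
  out["cluster_prominence"] <- sum(ct^4 * P)
  # information correlations
  hxy <- out["joint_entropy"]
  pxi <- px[i]; pyj <- py[j]
  valid <- P > 0 & pxi > 0 & pyj > 0
  hxy1 <- -sum(P[valid] * log2((pxi * pyj)[valid]))
  pij <- outer(px, py)
  hxy2 <- -sum(pij[pij > 0] * log2(pij[pij > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  out["info_corr_1"] <- if (hx > 0) (hxy - hxy1) / hx else 1
  out["info_corr_2"] <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy)))
                        else 0
  out
}

glcm_features <- function(grid, n_levels) {
  per_dir <- apply(TEXTURE_DIRECTIONS, 1, function(dir) {
    glcm_features_one(glcm_matrix(grid, n_levels, dir))
  })
  rowMeans(per_dir, na.rm = TRUE)
}

# ---- generic grey level / size style matrix features ----------------------

# Shared feature set for GLRLM / GLSZM / GLDZM / NGLDM: `mat` is a count
# matrix with grey level in rows and the size-like quantity (run length,
# zone size, zone distance, dependence count) in columns; `nv` the number of
# ROI voxels. `extra` enables the NGLDM energy feature.
size_matrix_features <- function(mat, nv, names_out, extra_energy = FALSE) {
  out <- stats::setNames(rep(NA_real_, length(names_out)), names_out)
  ns <- sum(mat)
  if (ns == 0 || nv == 0) return(out)
  ng <- nrow(mat); nl <- ncol(mat)
  i <- row(mat); j <- col(mat)
  ri <- rowSums(mat)  # per grey level
  rj <- colSums(mat)  # per size
  p <- mat / ns
  out[1] <- sum(mat / j^2) / ns           # small/short emphasis
  out[2] <- sum(mat * j^2) / ns           # large/long emphasis
  out[3] <- sum(mat / i^2) / ns           # low grey level
  out[4] <- sum(mat * i^2) / ns           # high grey level
  out[5] <- sum(mat / (i^2 * j^2)) / ns
  out[6] <- sum(mat * i^2 / j^2) / ns
  out[7] <- sum(mat * j^2 / i^2) / ns
  out[8] <- sum(mat * i^2 * j^2) / ns
  out[9] <- sum(ri^2) / ns                # grey level non-uniformity
  out[10] <- sum(ri^2) / ns^2
  out[11] <- sum(rj^2) / ns               # size non-uniformity
  out[12] <- sum(rj^2) / ns^2
  out[13] <- ns / nv                      # percentage
  mu_i <- sum(i * p)
  out[14] <- sum((i - mu_i)^2 * p)        # grey level variance
  mu_j <- sum(j * p)
  out[15] <- sum((j - mu_j)^2 * p)        # size variance
  pp <- p[p > 0]
  out[16] <- -sum(pp * log2(pp))          # entropy
  if (extra_energy) out[17] <- sum(p^2)
  out
}

# ---- GLRLM ----------------------------------------------------------------

glrlm_matrix <- function(grid, n_levels, dir) {
  runs <- cpp_runs(as.vector(grid), as.integer(dim(grid)), as.integer(dir))
  max_len <- max(c(1L, runs[, 2]))
  M <- matrix(0, n_levels, max_len)
  if (nrow(runs) > 0) {
    for (r in seq_len(nrow(runs))) {
      M[runs[r, 1], runs[r, 2]] <- M[runs[r, 1], runs[r, 2]] + 1
    }
  }
  M
}

glrlm_features <- function(grid, n_levels) {
  nv <- sum(grid > 0)
  per_dir <- apply(TEXTURE_DIRECTIONS, 1, function(dir) {
    size_matrix_features(glrlm_matrix(grid, n_levels, dir), nv,
                         glrlm_feature_names)
  })
  rowMeans(per_dir, na.rm = TRUE)
}

# ---- GLSZM ----------------------------------------------------------------

# zones: 26-connected components of constant grey level
zone_table <- function(grid, n_levels) {
  lab <- cpp_label_zones(as.vector(grid), as.integer(dim(grid)), TRUE)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab)
  greys <- integer(max(lab))
  greys[lab[lab > 0]] <- as.vector(grid)[lab > 0]
  list(grey = greys, size = sizes, label = lab)
}

glszm_features <- function(grid, n_levels) {
  zt <- zone_table(grid, n_levels)
  nv <- sum(grid > 0)
  if (is.null(zt)) {
    return(stats::setNames(rep(NA_real_, length(glszm_feature_names)),
                           glszm_feature_names))
  }
  M <- matrix(0, n_levels, max(zt$size))
  for (z in seq_along(zt$size)) {
    M[zt$grey[z], zt$size[z]] <- M[zt$grey[z], zt$size[z]] + 1
  }
  size_matrix_features(M, nv, glszm_feature_names)
}

# ---- GLDZM ----------------------------------------------------------------

# City-block distance of each morphological-mask voxel to the mask edge
# (edge voxels have distance 1); computed by iterative 6-neighbour
# propagation.
zone_distance_map <- function(morph_mask) {
  lab <- morph_mask$labels
  d <- dim(lab)
  dist <- array(Inf, dim = d)
  # voxels with a 6-neighbour outside the mask (or outside the grid)
  inner <- array(TRUE, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    lo <- index_axis(lab, c(1L, seq_len(n - 1L)), ax)
    hi <- index_axis(lab, c(seq_len(n - 1L) + 1L, n), ax)
    edge <- array(FALSE, dim = d)
    if (ax == 1) edge[c(1, n), , ] <- TRUE
    if (ax == 2) edge[, c(1, n), ] <- TRUE
    if (ax == 3) edge[, , c(1, n)] <- TRUE
    inner <- inner & lo & hi & !edge
  }
  dist[lab & !inner] <- 1
  repeat {
    nb <- array(Inf, dim = d)
    for (ax in 1:3) {
      n <- d[ax]
      lo <- index_axis(dist, c(1L, seq_len(n - 1L)), ax)
      hi <- index_axis(dist, c(seq_len(n - 1L) + 1L, n), ax)
      nb <- pmin(nb, lo, hi)
    }
    new_dist <- dist
    cand <- lab & is.infinite(dist)
    new_dist[cand] <- nb[cand] + 1
    if (all(is.infinite(new_dist) == is.infinite(dist))) break
    dist <- new_dist
  }
  dist[!lab] <- NA
  dist
}

gldzm_features <- function(grid, n_levels, morph_mask) {
  zt <- zone_table(grid, n_levels)
  nv <- sum(grid > 0)
  if (is.null(zt)) {
    return(stats::setNames(rep(NA_real_, length(gldzm_feature_names)),
                           gldzm_feature_names))
  }
  dmap <- zone_distance_map(morph_mask)
  nz <- length(zt$size)
  zone_dist <- rep(NA_real_, nz)
  dv <- as.vector(dmap)
  lv <- zt$label
  sel <- lv > 0 & is.finite(dv)
  agg <- tapply(dv[sel], lv[sel], min)
  zone_dist[as.integer(names(agg))] <- agg
  zone_dist[!is.finite(zone_dist)] <- 1
  M <- matrix(0, n_levels, max(zone_dist))
  for (z in seq_len(nz)) {
    M[zt$grey[z], zone_dist[z]] <- M[zt$grey[z], zone_dist[z]] + 1
  }
  size_matrix_features(M, nv, gldzm_feature_names)
}

# ---- NGTDM ----------------------------------------------------------------

# mean intensity of valid 26-neighbours for every ROI voxel
neighbour_average <- function(grid) {
  d <- dim(grid)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  inroi <- grid > 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- shift_range(d[1], dx); sy <- shift_range(d[2], dy)
    sz <- shift_range(d[3], dz)
    src_vals <- grid[sx$src, sy$src, sz$src]
    src_in <- inroi[sx$src, sy$src, sz$src]
    acc[sx$dst, sy$dst, sz$dst] <- acc[sx$dst, sy$dst, sz$dst] +
      src_vals * src_in
    cnt[sx$dst, sy$dst, sz$dst] <- cnt[sx$dst, sy$dst, sz$dst] + src_in
  }
  list(avg = ifelse(cnt > 0, acc / cnt, NA), count = cnt)
}

ngtdm_features <- function(grid, n_levels) {
  out <- stats::setNames(rep(NA_real_, length(ngtdm_feature_names)),
                         ngtdm_feature_names)
  inroi <- grid > 0
  nv <- sum(inroi)
  if (nv == 0) return(out)
  nb <- neighbour_average(grid)
  valid <- inroi & nb$count > 0
  nvc <- sum(valid)
  if (nvc == 0) return(out)
  g <- grid[valid]
  a <- nb$avg[valid]
  ni <- tabulate(g, nbins = n_levels)
  si <- rep(0, n_levels)
  agg <- tapply(abs(g - a), g, sum)
  si[as.integer(names(agg))] <- agg
  pi_ <- ni / nvc
  present <- which(pi_ > 0)
  ngp <- length(present)
  denom <- sum(pi_ * si)
  out["coarseness"] <- if (denom > 0) 1 / denom else 1e6
  if (ngp > 1) {
    pij_d2 <- 0
    busy_den <- 0
    strength_num <- 0
    complexity <- 0
    for (ii in present) for (jj in present) {
      pij_d2 <- pij_d2 + pi_[ii] * pi_[jj] * (ii - jj)^2
      busy_den <- busy_den + abs(ii * pi_[ii] - jj * pi_[jj])
      strength_num <- strength_num + (pi_[ii] + pi_[jj]) * (ii - jj)^2
      complexity <- complexity + abs(ii - jj) *
        (pi_[ii] * si[ii] + pi_[jj] * si[jj]) / (pi_[ii] + pi_[jj])
    }
    out["contrast"] <- pij_d2 / (ngp * (ngp - 1)) * sum(si) / nvc
    out["busyness"] <- if (busy_den > 0) denom / busy_den else 0
    out["complexity"] <- complexity / nvc
    out["strength"] <- if (sum(si) > 0) strength_num / sum(si) else 0
  } else {
    out["contrast"] <- 0
    out["busyness"] <- 0
    out["complexity"] <- 0
    out["strength"] <- 0
  }
  out
}

# ---- NGLDM ----------------------------------------------------------------

# dependence count: number of 26-neighbours inside the ROI with the same
# grey level (coarseness parameter alpha = 0); matrix column = count + 1
ngldm_features <- function(grid, n_levels) {
  d <- dim(grid)
  inroi <- grid > 0
  nv <- sum(inroi)
  if (nv == 0) {
    return(stats::setNames(rep(NA_real_, length(ngldm_feature_names)),
                           ngldm_feature_names))
  }
  dep <- array(0L, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- shift_range(d[1], dx); sy <- shift_range(d[2], dy)
    sz <- shift_range(d[3], dz)
    same <- (grid[sx$dst, sy$dst, sz$dst] == grid[sx$src, sy$src, sz$src]) &
      inroi[sx$src, sy$src, sz$src]
    dep[sx$dst, sy$dst, sz$dst] <- dep[sx$dst, sy$dst, sz$dst] + same
  }
  g <- grid[inroi]
  k <- dep[inroi] + 1L
  M <- matrix(0, n_levels, max(k))
  for (r in seq_along(g)) M[g[r], k[r]] <- M[g[r], k[r]] + 1
  size_matrix_features(M, nv, ngldm_feature_names, extra_energy = TRUE)
}
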