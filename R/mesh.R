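# Surface mesh construction and 3D convex-hull utilities backing the
# morphological feature family. The mask surface is extracted by marching
# tetrahedra at the 0.5 iso-level of a lightly smoothed occupancy field:
# smoothing regularises the voxel staircase so that surface area estimates
# converge to the smooth-shape limit, while vertex placement by linear
# interpolation keeps the surface at the (sub-voxel) 0.5 crossing. Enclosed
# volume comes from the divergence theorem over the consistently
# outward-oriented triangles.

# Six tetrahedra sharing the main diagonal c0-c7 of each cube. Cube corners
# are numbered by binary (bx, by, bz) offsets: c0=(0,0,0) ... c7=(1,1,1).
TET_DECOMP <- list(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
                   c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))

corner_offset_bits <- function(corner) {
  c(bitwAnd(corner, 1L), bitwAnd(corner %/% 2L, 1L), bitwAnd(corner %/% 4L, 1L))
}

# Mesh-derived surface statistics of a binary mask: total triangle area,
# enclosed volume and the bounding box of the mesh vertices.
# `smooth_sigma` is the Gaussian smoothing of the occupancy field in voxel
# units applied before iso-extraction (0 meshes the raw binary field).
mesh_surface_stats <- function(mask, smooth_sigma = 0.7, iso = 0.5) {
  d <- dim(mask$labels)
  sp <- mask$spacing
  pad <- as.integer(max(2, ceiling(3 * smooth_sigma) + 1))
  P <- array(0, dim = d + 2L * pad)
  P[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$labels
  if (smooth_sigma > 0) {
    P <- gaussian_blur(P, rep(smooth_sigma, 3))
  }
  dp <- dim(P)
  nc <- dp - 1L
  o_pad <- mask$origin - pad * sp  # origin of the padded grid

  ii <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  jj <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  kk <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  base <- ii + dp[1] * (jj - 1L) + dp[1] * dp[2] * (kk - 1L)

  # restrict to cubes whose 8 corners straddle the iso-level
  c000 <- P[base]
  c111 <- P[base + 1L + dp[1] + dp[1] * dp[2]]
  cmin <- pmin(c000, c111)
  cmax <- pmax(c000, c111)
  for (corner in 1:6) {
    b <- corner_offset_bits(corner)
    v <- P[base + b[1] + dp[1] * b[2] + dp[1] * dp[2] * b[3]]
    cmin <- pmin(cmin, v)
    cmax <- pmax(cmax, v)
  }
  act <- which(cmin < iso & cmax >= iso)
  if (length(act) == 0) {
    # tiny masks can be smoothed entirely below the iso-level; fall back to
    # meshing the raw binary field
    if (smooth_sigma > 0) {
      return(mesh_surface_stats(mask, smooth_sigma = 0, iso = iso))
    }
    return(list(area = 0, volume = 0, bb_min = rep(NA_real_, 3),
                bb_max = rep(NA_real_, 3)))
  }
  ii <- ii[act]; jj <- jj[act]; kk <- kk[act]; base <- base[act]

  corner_val <- function(corner) {
    b <- corner_offset_bits(corner)
    P[base + b[1] + dp[1] * b[2] + dp[1] * dp[2] * b[3]]
  }
  corner_xyz <- function(sel, corner) {
    b <- corner_offset_bits(corner)
    cbind(o_pad[1] + (ii[sel] - 1 + b[1]) * sp[1],
          o_pad[2] + (jj[sel] - 1 + b[2]) * sp[2],
          o_pad[3] + (kk[sel] - 1 + b[3]) * sp[3])
  }
  # iso crossing between corner coordinates/values (A inside-or-outside mix)
  cut_point <- function(A, fa, B, fb) {
    t <- (iso - fa) / (fb - fa)
    A + (B - A) * t
  }
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }

  area <- 0
  volume <- 0
  bb_min <- rep(Inf, 3)
  bb_max <- rep(-Inf, 3)

  # accumulate one oriented triangle set; `ref` = direction the outward
  # normal must follow
  add_tris <- function(p1, p2, p3, ref) {
    n <- cross3(p2 - p1, p3 - p1)
    area <<- area + sum(sqrt(rowSums(n^2))) / 2
    flip <- rowSums(n * ref) < 0
    detv <- rowSums(p1 * cross3(p2, p3))
    detv[flip] <- -detv[flip]
    volume <<- volume + sum(detv) / 6
    pts <- rbind(p1, p2, p3)
    bb_min <<- pmin(bb_min, apply(pts, 2, min))
    bb_max <<- pmax(bb_max, apply(pts, 2, max))
  }

  for (tet in TET_DECOMP) {
    f <- cbind(corner_val(tet[1]), corner_val(tet[2]),
               corner_val(tet[3]), corner_val(tet[4]))
    vin <- f >= iso
    cnt <- rowSums(vin)
    active <- which(cnt > 0 & cnt < 4)
    if (length(active) == 0) next
    va <- vin[active, , drop = FALSE]
    ca <- cnt[active]
    # single-corner cases (corner `pos` is the lone inside or outside one)
    for (pos in 1:4) {
      lone_in <- ca == 1 & va[, pos]
      lone_out <- ca == 3 & !va[, pos]
      sel <- active[lone_in | lone_out]
      if (length(sel) == 0) next
      is_in <- (lone_in | lone_out)[lone_in | lone_out]
      is_in <- lone_in[lone_in | lone_out]  # TRUE if the lone corner is inside
      others <- setdiff(1:4, pos)
      rowsel <- match(sel, active)
      A <- corner_xyz(sel, tet[pos]);   fa <- f[sel, pos]
      B <- corner_xyz(sel, tet[others[1]]); fb <- f[sel, others[1]]
      C <- corner_xyz(sel, tet[others[2]]); fc <- f[sel, others[2]]
      D <- corner_xyz(sel, tet[others[3]]); fd <- f[sel, others[3]]
      p1 <- cut_point(A, fa, B, fb)
      p2 <- cut_point(A, fa, C, fc)
      p3 <- cut_point(A, fa, D, fd)
      ctr <- (p1 + p2 + p3) / 3
      # outward points away from the lone inside corner / toward the lone
      # outside corner
      ref <- ctr - A
      ref[!is_in, ] <- -ref[!is_in, , drop = FALSE]
      add_tris(p1, p2, p3, ref)
    }
    # two-in / two-out cases: quad split into two triangles
    pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pr in pairs) {
      selmask <- ca == 2 & va[, pr[1]] & va[, pr[2]]
      sel <- active[selmask]
      if (length(sel) == 0) next
      outs <- setdiff(1:4, pr)
      A <- corner_xyz(sel, tet[pr[1]]);  fa <- f[sel, pr[1]]
      B <- corner_xyz(sel, tet[pr[2]]);  fb <- f[sel, pr[2]]
      C <- corner_xyz(sel, tet[outs[1]]); fc <- f[sel, outs[1]]
      D <- corner_xyz(sel, tet[outs[2]]); fd <- f[sel, outs[2]]
      q1 <- cut_point(A, fa, C, fc)
      q2 <- cut_point(A, fa, D, fd)
      q3 <- cut_point(B, fb, D, fd)
      q4 <- cut_point(B, fb, C, fc)
      ref <- (C + D) / 2 - (A + B) / 2  # outward: toward the outside pair
      add_tris(q1, q2, q3, ref)
      add_tris(q1, q3, q4, ref)
    }
  }
  list(area = area, volume = abs(volume), bb_min = bb_min, bb_max = bb_max)
}

# Centres of mask voxels that touch the background via a face (the digital
# surface); used as the point cloud for hull-based descriptors.
surface_voxel_centres <- function(mask) {
  lab <- mask$labels
  d <- dim(lab)
  shifted_all <- array(TRUE, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    lo <- index_axis(lab, c(1L, seq_len(n - 1L)), ax)
    hi <- index_axis(lab, c(seq_len(n - 1L) + 1L, n), ax)
    # border voxels face the outside of the grid
    edge <- array(FALSE, dim = d)
    if (ax == 1) edge[c(1, n), , ] <- TRUE
    if (ax == 2) edge[, c(1, n), ] <- TRUE
    if (ax == 3) edge[, , c(1, n)] <- TRUE
    shifted_all <- shifted_all & lo & hi & !edge
  }
  surf <- lab & !shifted_all
  idx <- which(surf, arr.ind = TRUE)
  cbind(mask$origin[1] + (idx[, 1] - 1) * mask$spacing[1],
        mask$origin[2] + (idx[, 2] - 1) * mask$spacing[2],
        mask$origin[3] + (idx[, 3] - 1) * mask$spacing[3])
}

# Incremental 3D convex hull (beneath-beyond). Returns NULL for degenerate
# (coplanar) input. Faces are index triples oriented outward.
convex_hull_3d <- function(pts, tol = NULL) {
  pts <- unique(round(pts, 9))
  n <- nrow(pts)
  if (n < 4) return(NULL)
  scale <- max(apply(pts, 2, function(c) diff(range(c))))
  if (scale == 0) return(NULL)
  if (is.null(tol)) tol <- 1e-9 * scale

  # initial non-degenerate tetrahedron
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < tol^2) return(NULL)
  e1 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossn <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  a2 <- apply(rel, 1, function(r) sum(crossn(e1, r)^2))
  i3 <- which.max(a2)
  if (a2[i3] < tol^2) return(NULL)
  nrm <- crossn(e1, pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < tol) return(NULL)

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  face_normal <- function(f) {
    nn <- crossn(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (interior - pts[f[1], ])) > 0) nn <- -nn
    nn
  }
  normals <- t(apply(faces, 1, face_normal))

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    dists <- rowSums(normals * (matrix(pts[p, ], nrow(faces), 3,
                                       byrow = TRUE) - pts[faces[, 1], ]))
    nrm_len <- sqrt(rowSums(normals^2))
    visible <- dists > tol * nrm_len
    if (!any(visible)) next
    vis_faces <- faces[visible, , drop = FALSE]
    # horizon: undirected edges of visible faces seen exactly once
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                   vis_faces[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!visible, , drop = FALSE]
    normals <- normals[!visible, , drop = FALSE]
    if (nrow(horizon) == 0) next
    new_faces <- cbind(horizon, p)
    new_normals <- t(apply(new_faces, 1, face_normal))
    faces <- rbind(faces, new_faces)
    normals <- rbind(normals, new_normals)
  }

  verts <- sort(unique(as.vector(faces)))
  # area and volume (divergence theorem from the interior point)
  area <- 0
  volume <- 0
  for (r in seq_len(nrow(faces))) {
    a <- pts[faces[r, 1], ] - interior
    b <- pts[faces[r, 2], ] - interior
    cc <- pts[faces[r, 3], ] - interior
    cr <- crossn(b - a, cc - a)
    area <- area + sqrt(sum(cr^2)) / 2
    volume <- volume + abs(sum(a * crossn(b, cc))) / 6
  }
  list(vertices = pts[verts, , drop = FALSE], faces = faces,
       area = area, volume = volume)
}

# Minimum-volume enclosing ellipsoid (Khachiyan's algorithm) of a point
# cloud; returns the semi-axis lengths. Usually run on convex-hull vertices.
mvee_semiaxes <- function(P, tol = 1e-3, max_iter = 200) {
  n <- nrow(P)
  d <- 3
  if (n <= d) return(NULL)
  P <- sweep(P, 2, colMeans(P))  # centre for numerical conditioning
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) return(NULL)
    M <- rowSums((t(Q) %*% Xi) * t(Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    if (!is.finite(step) || step < tol / n) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- colSums(u * P)
  A <- tryCatch(
    solve(t(P) %*% (u * P) - tcrossprod(ctr)) / d,
    error = function(e) NULL)
  if (is.null(A)) return(NULL)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(NULL)
  sort(1 / sqrt(ev), decreasing = TRUE)
}

# Knud Thomsen's approximation of the surface area of an ellipsoid with
# semi-axes a >= b >= c (relative error < 1.1%).
ellipsoid_area <- function(axes) {
  p <- 1.6075
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}
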