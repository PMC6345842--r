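#' Volumetric image
#'
#' A 3D scalar image on a regular, possibly anisotropic grid. Array axis 1
#' maps to x, axis 2 to y and axis 3 to z (slices). The centre of voxel
#' `(i, j, k)` (1-based array indices) lies at
#' `origin + (i - 1, j - 1, k - 1) * spacing` in physical millimetres, so all
#' geometric parameters elsewhere in the package are expressed in mm or
#' degrees, never in raw indices.
#'
#' @param voxels 3D numeric array of intensities (Hounsfield units for CT).
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, physical coordinate of the first voxel
#'   centre in mm.
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("voxel grid is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(voxels))) {
    stop("image intensities must be finite (no NaN/Inf)", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  cat(sprintf("<vol_image> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A binary mask on the same grid as its parent [vol_image()]. `kind`
#' distinguishes the original segmentation from the morphological and
#' intensity masks created during processing: the intensity mask is the
#' re-segmented subset of the morphological mask and feeds intensity and
#' texture features, while the morphological mask feeds shape features.
#'
#' @param labels 3D logical (or 0/1 numeric) array.
#' @param spacing,origin Grid geometry, as in [vol_image()].
#' @param kind One of `"original"`, `"morphological"`, `"intensity"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     kind = c("original", "morphological", "intensity")) {
  kind <- match.arg(kind)
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (is.numeric(labels)) {
    storage <- array(labels != 0, dim = dim(labels))
  } else {
    storage <- array(as.logical(labels), dim = dim(labels))
  }
  if (any(is.na(storage))) stop("mask labels must not be NA", call. = FALSE)
  structure(list(labels = storage, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask:%s> %s voxels, %d foreground (%.1f mm^3)\n",
              x$kind, paste(dim(x$labels), collapse = "x"),
              sum(x$labels), sum(x$labels) * prod(x$spacing)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask A [roi_mask()].
#' @return Integer count.
#' @export
mask_volume <- function(mask) {
  sum(mask$labels)
}

# check mask and image share a grid
check_same_grid <- function(image, mask) {
  if (!identical(dim(image$voxels), dim(mask$labels)) ||
      max(abs(image$spacing - mask$spacing)) > 1e-9 ||
      max(abs(image$origin - mask$origin)) > 1e-9) {
    stop("image and mask are not on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}

# physical coordinates of all voxel centres along one axis
axis_coords <- function(n, spacing, origin) {
  origin + (seq_len(n) - 1) * spacing
}

#' Read a volumetric image from file
#'
#' NIfTI-1 is the supported interchange format; spacing is taken from
#' `pixdim` and the origin from the stored transform. DICOM series input is
#' not provided by this package; convert series to NIfTI with standard tools
#' (e.g. dcm2niix) first.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param format Only `"nifti"` is supported.
#' @return A [vol_image()].
#' @export
read_image <- function(path, format = c("nifti", "dicom-series")) {
  format <- match.arg(format)
  if (format == "dicom-series") {
    stop("DICOM series reading is not supported; convert to NIfTI first",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("could not parse NIfTI file: ", conditionMessage(e),
                         call. = FALSE)
                  })
  vox <- array(as.numeric(nii), dim = dim(nii)[1:3])
  if (any(!is.finite(vox))) {
    stop("image contains non-finite intensities", call. = FALSE)
  }
  spc <- RNifti::pixdim(nii)[1:3]
  xf <- RNifti::xform(nii)
  # image written by this package uses a diagonal RAS transform
  origin <- as.numeric(xf[1:3, 4])
  vol_image(vox, spacing = spc, origin = origin)
}

#' Read a mask from a NIfTI file
#'
#' @param path File path.
#' @param kind Mask kind, see [roi_mask()].
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, kind = "original") {
  img <- read_image(path)
  roi_mask(img$voxels != 0, spacing = img$spacing, origin = img$origin,
           kind = kind)
}

#' Write an image or mask to NIfTI-1
#'
#' Voxels are stored as float64 so that write/read round-trips are
#' bit-exact; the grid transform is a diagonal matrix carrying spacing and
#' origin.
#'
#' @param x A [vol_image()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    vox <- array(as.numeric(x$labels), dim = dim(x$labels))
  } else {
    vox <- x$voxels
  }
  xf <- diag(4)
  xf[1, 1] <- x$spacing[1]
  xf[2, 2] <- x$spacing[2]
  xf[3, 3] <- x$spacing[3]
  xf[1:3, 4] <- x$origin
  attr(vox, "pixdim") <- x$spacing
  nii <- RNifti::asNifti(vox, datatype = "double")
  RNifti::qform(nii) <- structure(xf, code = 2L)
  RNifti::sform(nii) <- structure(xf, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Rasterise per-slice closed polygons into a mask
#'
#' Converts RTSTRUCT-style planar contours (closed polygons in physical mm,
#' each lying in a constant-z plane) into a voxel mask on the grid of
#' `grid`. A voxel becomes foreground when its centre lies inside the
#' polygon by the even-odd (ray crossing) rule. Polygons are snapped to the
#' nearest grid slice; a polygon further than half a slice spacing from any
#' slice is an error. Multiple polygons on one slice combine by even-odd
#' parity, so holes are supported. Self-intersecting polygons are reported
#' with a warning and rasterised with the same even-odd rule.
#'
#' @param polygons List of numeric matrices, each `n x 3` (x, y, z in mm)
#'   with constant z; the polygon closes implicitly (last vertex joins the
#'   first).
#' @param grid A [vol_image()] supplying the target geometry.
#' @return A [roi_mask()] of kind `"original"`.
#' @export
rasterise_contours <- function(polygons, grid) {
  if (length(polygons) == 0) stop("empty polygon set", call. = FALSE)
  dims <- dim(grid$voxels)
  parity <- array(0L, dim = dims)
  xs <- axis_coords(dims[1], grid$spacing[1], grid$origin[1])
  ys <- axis_coords(dims[2], grid$spacing[2], grid$origin[2])
  zs <- axis_coords(dims[3], grid$spacing[3], grid$origin[3])
  for (pg in polygons) {
    pg <- as.matrix(pg)
    if (ncol(pg) != 3 || nrow(pg) < 3) {
      stop("each polygon needs >= 3 vertices with (x, y, z) columns",
           call. = FALSE)
    }
    if (max(pg[, 3]) - min(pg[, 3]) > 1e-6) {
      stop("polygon does not lie in a constant-z plane", call. = FALSE)
    }
    z <- pg[1, 3]
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > grid$spacing[3] / 2 + 1e-9) {
      stop(sprintf("polygon plane z = %.3f mm matches no grid slice", z),
           call. = FALSE)
    }
    if (polygon_self_intersects(pg[, 1:2, drop = FALSE])) {
      warning("self-intersecting polygon; even-odd rule applied")
    }
    inside <- points_in_polygon_eo(xs, ys, pg[, 1:2, drop = FALSE])
    parity[, , k] <- parity[, , k] + inside
  }
  labels <- (parity %% 2L) == 1L
  if (!any(labels)) {
    stop("rasterisation produced an empty mask", call. = FALSE)
  }
  roi_mask(labels, spacing = grid$spacing, origin = grid$origin,
           kind = "original")
}

# Even-odd point-in-polygon over the tensor grid xs x ys; returns an
# integer matrix (length(xs) x length(ys)) of 0/1. Vectorised ray crossing:
# for each polygon edge, accumulate crossings of the horizontal ray through
# each grid y at each grid x.
points_in_polygon_eo <- function(xs, ys, poly) {
  nv <- nrow(poly)
  px <- poly[, 1]
  py <- poly[, 2]
  nxg <- length(xs)
  nyg <- length(ys)
  crossings <- matrix(0L, nxg, nyg)
  jprev <- nv
  for (j in seq_len(nv)) {
    x1 <- px[jprev]; y1 <- py[jprev]
    x2 <- px[j]; y2 <- py[j]
    jprev <- j
    if (y1 == y2) next
    # edge straddles the ray at grid y iff min(y) <= y < max(y)
    ylo <- min(y1, y2); yhi <- max(y1, y2)
    sel <- which(ys >= ylo & ys < yhi)
    if (length(sel) == 0) next
    xint <- x1 + (ys[sel] - y1) / (y2 - y1) * (x2 - x1)
    # crossing where voxel-centre x is strictly left of the intersection
    for (ii in seq_along(sel)) {
      hit <- xs < xint[ii]
      crossings[hit, sel[ii]] <- crossings[hit, sel[ii]] + 1L
    }
  }
  crossings %% 2L
}

# crude O(n^2) segment-pair self-intersection check (non-adjacent edges)
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  ccw <- function(ax, ay, bx, by, cx, cy) {
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}
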