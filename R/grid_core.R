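#' @useDynLib oarseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile setNames
#' @importFrom utils write.csv read.csv
NULL

# ---- volume grid ------------------------------------------------------------

#' 3D scalar volume on a regular axis-aligned grid
#'
#' A `volume_grid` holds a 3D array of scalar intensities (HU-like) together
#' with voxel spacing and world origin. World coordinates follow the LPS
#' convention (+x left, +y posterior, +z superior); the world position of voxel
#' index `(i,j,k)` (0-based) is `origin + (i*sx, j*sy, k*sz)`, i.e. `origin` is
#' the center of voxel `(0,0,0)`.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing positive numeric triple, mm per voxel along each axis.
#' @param origin numeric triple, world mm of the center of voxel (0,0,0).
#' @return An object of class `volume_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a strictly positive triple")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite triple")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary structure mask on a volume grid
#'
#' @param occupancy logical 3D array (TRUE = inside the structure).
#' @param spacing,origin grid metadata as in [volume_grid()].
#' @param structure_name label for the structure (e.g. `"heart"`).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, spacing, origin = c(0, 0, 0),
                           structure_name = "structure") {
  if (length(dim(occupancy)) != 3L) stop("occupancy must be a 3D array")
  storage.mode(occupancy) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be a positive triple")
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin), structure_name = structure_name),
            class = "structure_mask")
}

#' Integer label map on a volume grid
#'
#' Label 0 is background; nonzero labels are mutually exclusive structures
#' named by `legend` (a character vector whose i-th element names label i).
#'
#' @param labels integer 3D array of labels (0 = background).
#' @param spacing,origin grid metadata as in [volume_grid()].
#' @param legend character vector naming labels `1..length(legend)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing, origin = c(0, 0, 0), legend = character()) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  mx <- suppressWarnings(max(labels))
  if (mx > length(legend)) stop("every nonzero label must appear in the legend")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), legend = legend),
            class = "label_map")
}

#' Axis-aligned world-space region of interest
#'
#' Half-open box `[lower, upper)` in world mm; a voxel belongs to the box iff
#' its center does.
#'
#' @param lower,upper numeric world-mm triples with `lower < upper` per axis.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(!(lower < upper)))
    stop("roi_box requires lower < upper on every axis")
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

grid_dims <- function(x) {
  d <- dim(if (!is.null(x$values)) x$values else if (!is.null(x$occupancy)) x$occupancy else x$labels)
  as.integer(d)
}

#' Grid metadata (dims, spacing, origin) of a volume, mask or label map
#' @param x a `volume_grid`, `structure_mask` or `label_map`.
#' @return list with `dims`, `spacing`, `origin`.
#' @export
grid_meta <- function(x) list(dims = grid_dims(x), spacing = x$spacing, origin = x$origin)

same_grid <- function(a, b, tol = 1e-6) {
  ma <- grid_meta(a); mb <- grid_meta(b)
  identical(ma$dims, mb$dims) &&
    all(abs(ma$spacing - mb$spacing) < tol) &&
    all(abs(ma$origin - mb$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grid mismatch: objects are not defined on the same grid")
}

#' Voxel index to world coordinates
#' @param index integer matrix (n x 3) of 0-based voxel indices (or a triple).
#' @param meta grid metadata from [grid_meta()] (or any gridded object).
#' @return n x 3 matrix of world mm positions of the voxel centers.
#' @export
index_to_world <- function(index, meta) {
  if (!is.null(meta$values) || !is.null(meta$occupancy) || !is.null(meta$labels))
    meta <- grid_meta(meta)
  idx <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(idx, 2, meta$spacing, `*`), 2, meta$origin, `+`)
}

#' World coordinates to (fractional) voxel index
#' @param world numeric matrix (n x 3) of world mm positions (or a triple).
#' @param meta grid metadata (or any gridded object).
#' @return n x 3 matrix of 0-based fractional voxel indices.
#' @export
world_to_index <- function(world, meta) {
  if (!is.null(meta$values) || !is.null(meta$occupancy) || !is.null(meta$labels))
    meta <- grid_meta(meta)
  w <- matrix(as.numeric(world), ncol = 3)
  sweep(sweep(w, 2, meta$origin, `-`), 2, meta$spacing, `/`)
}

# trilinear/nearest sampling of an array at fractional 0-based indices;
# indices are assumed pre-validated or clamping is requested by the caller
sample_at_index <- function(values, idx, mode = c("trilinear", "nearest"),
                            clamp = FALSE, fill = NULL) {
  mode <- match.arg(mode)
  d <- dim(values)
  outside <- idx[, 1] < 0 | idx[, 1] > d[1] - 1 |
             idx[, 2] < 0 | idx[, 2] > d[2] - 1 |
             idx[, 3] < 0 | idx[, 3] > d[3] - 1
  if (any(outside) && !clamp && is.null(fill))
    stop("sample point outside the voxel-center bounds of the grid")
  if (clamp) {
    for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), d[a] - 1)
  }
  if (mode == "nearest") {
    i <- floor(idx + 0.5)
    for (a in 1:3) i[, a] <- pmin(pmax(i[, a], 0), d[a] - 1)
    out <- values[cbind(i[, 1] + 1, i[, 2] + 1, i[, 3] + 1)]
  } else {
    i0 <- floor(idx)
    for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 0), max(d[a] - 2, 0))
    f <- pmin(pmax(idx - i0, 0), 1)
    out <- 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- (if (cx) f[, 1] else 1 - f[, 1]) *
           (if (cy) f[, 2] else 1 - f[, 2]) *
           (if (cz) f[, 3] else 1 - f[, 3])
      v <- values[cbind(pmin(i0[, 1] + cx, d[1] - 1) + 1,
                        pmin(i0[, 2] + cy, d[2] - 1) + 1,
                        pmin(i0[, 3] + cz, d[3] - 1) + 1)]
      out <- out + w * v
    }
  }
  if (!clamp && !is.null(fill) && any(outside)) out[outside] <- fill
  out
}

# ---- operations -------------------------------------------------------------

#' Sample a volume with trilinear interpolation at world positions
#'
#' Interpolates the 8 surrounding voxel-center values; queries exactly at a
#' voxel center return the stored value. Points outside the voxel-center convex
#' hull raise an error — there is no silent clamping.
#'
#' @param volume a [volume_grid()].
#' @param point numeric triple or n x 3 matrix of world mm positions.
#' @return numeric vector of interpolated values.
#' @export
sample_trilinear <- function(volume, point) {
  idx <- world_to_index(point, volume)
  sample_at_index(volume$values, idx, "trilinear")
}

#' Resample a volume to isotropic spacing
#'
#' The output grid has spacing `(t,t,t)`, voxel `(0,0,0)` centered at the input
#' origin, and `dims = ceiling(extent / t)` where `extent = dims_in * spacing_in`,
#' so the physical extent is conserved within one output voxel per axis.
#' Sample positions beyond the input voxel-center hull (possible within the
#' trailing half-voxel margin) are clamped to the hull edge.
#'
#' @param volume a [volume_grid()] (or a [structure_mask()]/[label_map()] with
#'   `mode = "nearest"`).
#' @param target_spacing positive scalar, mm.
#' @param mode `"trilinear"` for images, `"nearest"` (required) for masks and
#'   label maps.
#' @return object of the same class as `volume` on the new grid.
#' @export
resample_isotropic <- function(volume, target_spacing, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("target_spacing must be a positive scalar")
  is_mask <- inherits(volume, "structure_mask")
  is_lab <- inherits(volume, "label_map")
  if ((is_mask || is_lab) && mode != "nearest")
    stop("masks and label maps must be resampled with mode = \"nearest\"")
  values <- if (is_mask) volume$occupancy else if (is_lab) volume$labels else volume$values
  d <- dim(values)
  extent <- d * volume$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / t - 1e-9)))
  # t/spacing is computed once per axis so that resampling to the native
  # spacing lands exactly on integer indices (bitwise identity)
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * (t / volume$spacing[a]))
  idx <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  vals <- if (is_mask || is_lab) as.numeric(values) else values
  storage.mode(vals) <- "double"
  dim(vals) <- d
  out <- sample_at_index(vals, idx, mode, clamp = TRUE)
  dim(out) <- nd
  if (is_mask) {
    structure_mask(out > 0.5, rep(t, 3), volume$origin, volume$structure_name)
  } else if (is_lab) {
    label_map(array(as.integer(round(out)), nd), rep(t, 3), volume$origin, volume$legend)
  } else {
    volume_grid(out, rep(t, 3), volume$origin)
  }
}

#' Crop a volume to a world-space ROI box
#'
#' Retains all voxels whose centers fall inside the half-open box, clipped to
#' the volume; the output origin is the world position of the first retained
#' voxel.
#'
#' @param volume a [volume_grid()], [structure_mask()] or [label_map()].
#' @param box an [roi_box()].
#' @return cropped object of the same class.
#' @export
crop_to_roi <- function(volume, box) {
  if (!inherits(box, "roi_box")) stop("box must be an roi_box")
  meta <- grid_meta(volume)
  keep <- lapply(1:3, function(a) {
    centers <- meta$origin[a] + (seq_len(meta$dims[a]) - 1) * meta$spacing[a]
    which(centers >= box$lower[a] & centers < box$upper[a])
  })
  if (any(vapply(keep, length, 1L) == 0L))
    stop("empty ROI: the box does not contain any voxel center of the volume")
  new_origin <- meta$origin + (vapply(keep, min, 1L) - 1) * meta$spacing
  sub <- function(arr) arr[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  if (inherits(volume, "structure_mask")) {
    structure_mask(sub(volume$occupancy), meta$spacing, new_origin, volume$structure_name)
  } else if (inherits(volume, "label_map")) {
    label_map(sub(volume$labels), meta$spacing, new_origin, volume$legend)
  } else {
    volume_grid(sub(volume$values), meta$spacing, new_origin)
  }
}

#' Resample a binary mask onto a target grid (nearest neighbor)
#'
#' Each target voxel takes the occupancy of the nearest source voxel center in
#' world space; target voxels outside the source physical bounds are
#' background. Output is always binary.
#'
#' @param mask a [structure_mask()].
#' @param target grid metadata ([grid_meta()]) or any gridded object.
#' @return a [structure_mask()] on the target grid.
#' @export
resample_mask_to_grid <- function(mask, target) {
  tm <- if (!is.null(target$dims)) target else grid_meta(target)
  ax <- lapply(1:3, function(a) tm$origin[a] + (seq_len(tm$dims[a]) - 1) * tm$spacing[a])
  w <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  idx <- world_to_index(w, mask)
  vals <- array(as.double(mask$occupancy), dim(mask$occupancy))
  # outside the source half-voxel bounds -> background
  occ <- sample_at_index(vals, idx, "nearest", clamp = TRUE)
  d <- dim(mask$occupancy)
  for (a in 1:3) {
    bad <- idx[, a] < -0.5 | idx[, a] > d[a] - 0.5
    if (any(bad)) occ[bad] <- 0
  }
  dim(occ) <- tm$dims
  structure_mask(occ > 0.5, tm$spacing, tm$origin, mask$structure_name)
}

#' Aggregate per-organ masks into a single multi-organ label map
#'
#' Every voxel is claimed by exactly one structure; where masks overlap, the
#' earliest structure in `priority` wins. Label i (1-based in priority order)
#' maps to the i-th structure name in the legend.
#'
#' @param masks list of [structure_mask()] objects on one shared grid.
#' @param priority character vector of structure names, earliest wins; default
#'   is the order of `masks`.
#' @return a [label_map()].
#' @export
aggregate_masks <- function(masks, priority = NULL) {
  nms <- vapply(masks, function(m) m$structure_name, "")
  if (is.null(priority)) priority <- nms
  if (!setequal(priority, nms) || anyDuplicated(priority))
    stop("priority must be a permutation of the mask structure names")
  if (length(masks) == 0L)
    stop("aggregate_masks needs a reference grid; pass at least one mask")
  ref <- masks[[1]]
  for (m in masks[-1]) stop_if_grid_mismatch(ref, m)
  lab <- array(0L, dim(ref$occupancy))
  for (i in rev(seq_along(priority))) {
    m <- masks[[match(priority[i], nms)]]
    lab[m$occupancy] <- i
  }
  label_map(lab, ref$spacing, ref$origin, priority)
}

#' All-background label map on a grid
#' @param meta grid metadata or gridded object.
#' @return a [label_map()] with every voxel 0.
#' @export
empty_label_map <- function(meta) {
  tm <- if (!is.null(meta$dims)) meta else grid_meta(meta)
  label_map(array(0L, tm$dims), tm$spacing, tm$origin, character())
}

# ---- NIfTI / JSON interfaces ------------------------------------------------

lps_affine_from_meta <- function(meta) {
  # our LPS world -> NIfTI RAS: x,y flip sign
  aff <- diag(4)
  aff[1, 1] <- -meta$spacing[1]
  aff[2, 2] <- -meta$spacing[2]
  aff[3, 3] <- meta$spacing[3]
  aff[1:3, 4] <- c(-meta$origin[1], -meta$origin[2], meta$origin[3])
  aff
}

meta_from_nifti <- function(img) {
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  offdiag <- lin; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-3 * max(abs(lin))))
    stop("oblique NIfTI affine: only axis-aligned grids are supported")
  sgn <- sign(diag(lin))
  if (!(all(sgn == c(-1, -1, 1)) || all(sgn == c(1, 1, 1))))
    stop("unsupported NIfTI axis orientation: expected RAS (-,-,+ diagonal) or LPS-aligned affine")
  spacing <- abs(diag(lin))
  trans <- aff[1:3, 4]
  if (all(sgn == c(-1, -1, 1))) {
    origin <- c(-trans[1], -trans[2], trans[3]) # RAS -> LPS
  } else {
    origin <- trans
  }
  list(spacing = spacing, origin = origin)
}

#' Read / write volumes and masks as NIfTI-1
#'
#' Only axis-aligned, positive-scale grids are supported; oblique affines are
#' rejected. NIfTI's RAS world axes are converted to the package's LPS frame.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume_grid()]; `read_mask` a
#'   [structure_mask()] named from the file name unless overridden.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- meta_from_nifti(img)
  volume_grid(array(as.numeric(img), dim(img)[1:3]), m$spacing, m$origin)
}

#' @rdname read_volume
#' @param structure_name structure label for the mask; default from file name.
#' @export
read_mask <- function(path, structure_name = NULL) {
  img <- RNifti::readNifti(path)
  m <- meta_from_nifti(img)
  if (is.null(structure_name))
    structure_name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
                 m$spacing, m$origin, structure_name)
}

#' @rdname read_volume
#' @param x a [volume_grid()], [structure_mask()] or [label_map()].
#' @export
write_nifti <- function(x, path) {
  meta <- grid_meta(x)
  arr <- if (inherits(x, "structure_mask")) array(as.integer(x$occupancy), meta$dims)
         else if (inherits(x, "label_map")) x$labels
         else x$values
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, meta$spacing)
  img <- RNifti::`sform<-`(img, structure(lps_affine_from_meta(meta), code = 2L))
  img <- RNifti::`qform<-`(img, structure(lps_affine_from_meta(meta), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write ROI boxes as JSON sidecars
#'
#' Sidecar format: a JSON array of objects
#' `{structure, lower_mm: [x,y,z], upper_mm: [x,y,z]}`.
#'
#' @param path JSON file path.
#' @return named list of [roi_box()] objects.
#' @export
read_roi_json <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  boxes <- lapply(rec, function(r) roi_box(unlist(r$lower_mm), unlist(r$upper_mm)))
  names(boxes) <- vapply(rec, function(r) r$structure, "")
  boxes
}

#' @rdname read_roi_json
#' @param boxes named list of [roi_box()] objects.
#' @export
write_roi_json <- function(boxes, path) {
  rec <- lapply(names(boxes), function(nm) {
    list(structure = nm, lower_mm = boxes[[nm]]$lower, upper_mm = boxes[[nm]]$upper)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
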