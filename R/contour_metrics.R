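# Geometric comparison of an automatic (AUTO) contour against a manual (MAN)
# reference: volume, overlap and surface-distance measures. Set sizes are voxel
# counts on the shared grid; surfaces are mask voxels with a 6-connected
# outside neighbor (grid-boundary voxels count as surface); distances are
# Euclidean mm between voxel centers, anisotropic-aware. Undefined metrics
# (empty masks) become NA, never silent zeros.

#' Mask volume in millilitres
#' @param mask a [structure_mask()].
#' @return voxel count times voxel volume (mm^3) / 1000.
#' @export
volume_ml <- function(mask) {
  sum(mask$occupancy) * prod(mask$spacing) / 1000
}

#' Overlap indices between AUTO and MAN
#'
#' Computes Sensitivity = |AUTO∩MAN|/|MAN|, Specificity =
#' |outside-AUTO ∩ outside-MAN| / |outside-MAN| (over the full shared grid),
#' Jaccard = |AUTO∩MAN|/|AUTO∪MAN|, Dice = 2|AUTO∩MAN|/(|AUTO|+|MAN|),
#' Discordance = 1 − |MAN∩AUTO|/|AUTO| (fraction of AUTO outside MAN) and
#' GMI = |MAN \ AUTO|/|MAN| (fraction of MAN missed by AUTO).
#'
#' Metrics whose defining denominator is empty raise an error when requested
#' directly; [evaluate_pair()] records them as missing instead.
#'
#' @param auto,man [structure_mask()] objects on one shared grid.
#' @return named list with `sensitivity`, `specificity`, `jaccard`, `dice`,
#'   `discordance`, `gmi`.
#' @export
overlap_metrics <- function(auto, man) {
  stop_if_grid_mismatch(auto, man)
  a <- auto$occupancy; m <- man$occupancy
  n_a <- sum(a); n_m <- sum(m)
  if (n_a == 0L && n_m == 0L)
    stop("both masks are empty: all overlap metrics are undefined")
  n_int <- sum(a & m)
  n_uni <- n_a + n_m - n_int
  n_tot <- length(a)
  sens <- if (n_m > 0L) n_int / n_m else
    stop("empty MAN mask: sensitivity/GMI undefined")
  disc <- if (n_a > 0L) 1 - n_int / n_a else
    stop("empty AUTO mask: discordance undefined")
  list(sensitivity = sens,
       specificity = (n_tot - n_uni) / (n_tot - n_m),
       jaccard = n_int / n_uni,
       dice = 2 * n_int / (n_a + n_m),
       discordance = disc,
       gmi = 1 - sens)
}

#' Surface voxels of a mask
#'
#' A mask voxel belongs to the surface iff at least one of its 6 face
#' neighbors is outside the mask or beyond the grid boundary.
#'
#' @param mask a [structure_mask()].
#' @return An object of class `surface_points`: list with `points` (n x 3
#'   world-mm matrix of surface voxel centers), `voxels` (logical array
#'   marking surface voxels), `structure_name`, and grid metadata `meta`.
#' @export
surface_voxels <- function(mask) {
  occ <- mask$occupancy
  interior <- occ
  for (a in 1:3) for (s in c(-1L, 1L)) {
    sh <- integer(3); sh[a] <- s
    interior <- interior & shift_array(occ, sh)
  }
  surf <- occ & !interior
  idx <- which(surf, arr.ind = TRUE) - 1
  pts <- if (nrow(idx)) index_to_world(idx, mask) else matrix(numeric(), 0, 3)
  structure(list(points = pts, voxels = surf,
                 structure_name = mask$structure_name, meta = grid_meta(mask)),
            class = "surface_points")
}

#' Directed nearest-surface distances
#'
#' For every point of `src`, the minimum Euclidean mm distance to any point of
#' `dst`. When both surfaces live on the same grid the distances come from an
#' exact anisotropic Euclidean distance transform; otherwise from exhaustive
#' point-pair search. Both routes are exact.
#'
#' @param src,dst `surface_points` objects (see [surface_voxels()]).
#' @return numeric vector of length `nrow(src$points)`.
#' @export
directed_distances <- function(src, dst) {
  if (nrow(dst$points) == 0L) stop("empty destination surface: distances undefined")
  if (nrow(src$points) == 0L) return(numeric())
  same <- !is.null(src$voxels) && !is.null(dst$voxels) &&
    length(src$meta$dims) == 3L && identical(src$meta$dims, dst$meta$dims) &&
    all(abs(src$meta$spacing - dst$meta$spacing) < 1e-9) &&
    all(abs(src$meta$origin - dst$meta$origin) < 1e-9)
  if (same) {
    dmap <- cpp_edt(as.logical(dst$voxels), dst$meta$dims, dst$meta$spacing)
    dim(dmap) <- dst$meta$dims
    dmap[src$voxels]
  } else {
    cpp_min_dists(src$points, dst$points)
  }
}

#' Symmetric surface-distance summary
#'
#' Mean surface distance pools both directed distance lists:
#' `msd = (sum d(p,S') + sum d(p',S)) / (n_s + n_s')`; the residual (RMS)
#' variant takes the root of the pooled mean of squares. The Hausdorff
#' distance is the larger of the two directed maxima; the percentile variant
#' (`hd_p`) is the larger of the two directions' linearly interpolated
#' percentiles (rank `1 + q(n-1)`).
#'
#' @param s,s_prime `surface_points` objects.
#' @param percentile percentile in `[0,100]` for `hd_p` (95 for HD95).
#' @return named list `msd_mm`, `rmsd_mm`, `hd_mm`, `hd_p_mm`.
#' @export
surface_distance_summary <- function(s, s_prime, percentile = 95) {
  if (nrow(s$points) == 0L || nrow(s_prime$points) == 0L)
    stop("empty surface: surface distances undefined")
  d1 <- directed_distances(s, s_prime)
  d2 <- directed_distances(s_prime, s)
  n <- length(d1) + length(d2)
  q <- percentile / 100
  list(msd_mm = (sum(d1) + sum(d2)) / n,
       rmsd_mm = sqrt((sum(d1^2) + sum(d2^2)) / n),
       hd_mm = max(max(d1), max(d2)),
       hd_p_mm = max(quantile(d1, q, names = FALSE, type = 7),
                     quantile(d2, q, names = FALSE, type = 7)))
}

#' Distance between mask centroids (center-of-volume distance)
#' @param auto,man nonempty [structure_mask()] objects.
#' @return Euclidean mm distance between the world-space occupied-voxel means.
#' @export
centroid_distance <- function(auto, man) {
  sqrt(sum((mask_centroid_world(auto) - mask_centroid_world(man))^2))
}

#' Signed directional boundary differences
#'
#' For each anatomical direction under LPS (+x left, +y posterior, +z
#' superior), the difference between the extreme world coordinate of the
#' furthest-reaching AUTO voxel and that of MAN at the same side, reported in
#' mm along the axis: positive values mean the AUTO boundary is displaced
#' toward +axis (left / posterior / superior) relative to MAN.
#'
#' @param auto,man nonempty [structure_mask()] objects on one grid.
#' @return named numeric: `right`, `left`, `anterior`, `posterior`,
#'   `inferior`, `superior`.
#' @export
boundary_differences <- function(auto, man) {
  stop_if_grid_mismatch(auto, man)
  ext <- function(mask) {
    idx <- which(mask$occupancy, arr.ind = TRUE) - 1
    if (nrow(idx) == 0L) stop("empty mask: boundary differences undefined")
    w <- index_to_world(idx, mask)
    c(min_x = min(w[, 1]), max_x = max(w[, 1]),
      min_y = min(w[, 2]), max_y = max(w[, 2]),
      min_z = min(w[, 3]), max_z = max(w[, 3]))
  }
  ea <- ext(auto); em <- ext(man)
  c(right = ea[["min_x"]] - em[["min_x"]],
    left = ea[["max_x"]] - em[["max_x"]],
    anterior = ea[["min_y"]] - em[["min_y"]],
    posterior = ea[["max_y"]] - em[["max_y"]],
    inferior = ea[["min_z"]] - em[["min_z"]],
    superior = ea[["max_z"]] - em[["max_z"]])
}

pair_metric_names <- function() {
  c("volume_man_ml", "volume_auto_ml", "volume_diff_ml", "volume_ratio",
    "sensitivity", "specificity", "jaccard", "dice", "discordance", "gmi",
    "centroid_distance_mm", "msd_mm", "rmsd_mm", "hd95_mm", "hd_mm",
    paste0("boundary_", c("right", "left", "anterior", "posterior",
                          "inferior", "superior"), "_mm"))
}

#' Evaluate an AUTO/MAN contour pair
#'
#' Populates the full per-case metric set: volumes (MAN, AUTO, MAN−AUTO
#' difference, MAN/AUTO ratio), overlap indices, centroid distance, symmetric
#' surface distances (MSD, RMSD, HD, HD95) and the six signed boundary
#' differences. Metrics that are undefined for the pair (e.g. any distance
#' when a mask is empty) are recorded as `NA` rather than aborting.
#'
#' @param auto,man [structure_mask()] objects on one shared grid.
#' @return named numeric vector with the fields of [pair_metric_names()].
#' @export
evaluate_pair <- function(auto, man) {
  stop_if_grid_mismatch(auto, man)
  out <- setNames(rep(NA_real_, length(pair_metric_names())), pair_metric_names())
  n_a <- sum(auto$occupancy); n_m <- sum(man$occupancy)
  out["volume_man_ml"] <- volume_ml(man)
  out["volume_auto_ml"] <- volume_ml(auto)
  out["volume_diff_ml"] <- out["volume_man_ml"] - out["volume_auto_ml"]
  if (n_a > 0L) out["volume_ratio"] <- out["volume_man_ml"] / out["volume_auto_ml"]
  if (n_a > 0L || n_m > 0L) {
    n_int <- sum(auto$occupancy & man$occupancy)
    n_uni <- n_a + n_m - n_int
    n_tot <- length(auto$occupancy)
    if (n_m > 0L) {
      out["sensitivity"] <- n_int / n_m
      out["gmi"] <- 1 - n_int / n_m
    }
    if (n_a > 0L) out["discordance"] <- 1 - n_int / n_a
    out["specificity"] <- (n_tot - n_uni) / (n_tot - n_m)
    out["jaccard"] <- n_int / n_uni
    out["dice"] <- 2 * n_int / (n_a + n_m)
  }
  if (n_a > 0L && n_m > 0L) {
    out["centroid_distance_mm"] <- centroid_distance(auto, man)
    sa <- surface_voxels(auto); sm <- surface_voxels(man)
    sd <- surface_distance_summary(sa, sm, percentile = 95)
    out["msd_mm"] <- sd$msd_mm
    out["rmsd_mm"] <- sd$rmsd_mm
    out["hd95_mm"] <- sd$hd_p_mm
    out["hd_mm"] <- sd$hd_mm
    bd <- boundary_differences(auto, man)
    out[paste0("boundary_", names(bd), "_mm")] <- bd
  }
  out
}
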