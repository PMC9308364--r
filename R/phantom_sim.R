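# Synthetic planning-CT-like phantoms with known ground truth. Organs are
# smooth parametric solids (ellipsoids; a bent tube for the rectum) inside a
# body outline, with per-tissue HU-like intensities plus Gaussian noise.
# Analytic shapes give closed-form volume/centroid oracles for the tests.

# Organ volume targets (ml) at full adult scale; the phantom scales these by
# size_factor^3 to fit its desk-scale field of view.
ADULT_VOLUMES_ML <- c(bladder = 331, rectum = 89, heart = 569,
                      lung_left = 1897, lung_right = 2220)

thorax_organs <- function(sf) {
  # semi-axes chosen so 4/3*pi*abc matches the scaled volume target and the
  # shapes stay disjoint inside the body outline under +/-20% semi-axis jitter
  list(
    heart = list(type = "ellipsoid", center = c(72, 80, 70) ,
                 semi = sf / 0.4 * c(23, 21, 18), intensity = c(90, 12)),
    lung_left = list(type = "ellipsoid", center = c(116, 72, 105),
                     semi = sf / 0.4 * c(17, 30, 57), intensity = c(-750, 25)),
    lung_right = list(type = "ellipsoid", center = c(28, 72, 105),
                      semi = sf / 0.4 * c(18, 32, 59), intensity = c(-750, 25))
  )
}

pelvis_organs <- function(sf) {
  list(
    bladder = list(type = "ellipsoid", center = c(72, 60, 100),
                   semi = sf / 0.4 * c(16, 15, 21), intensity = c(60, 10)),
    rectum = list(type = "tube", center = c(72, 92), zrange = c(75, 125),
                  radius = sf / 0.4 * 6, bend = sf / 0.4 * 8,
                  intensity = c(-350, 30))
  )
}

#' Parametric description of a synthetic planning-CT phantom
#'
#' Defines the grid, the organ set for the anatomical region (thorax:
#' left/right lung and heart; pelvis: bladder and rectum), per-tissue
#' intensities and the noise model. Organ volumes are the adult-scale targets
#' (bladder 331, rectum 89, heart 569, left lung 1897, right lung 2220 ml)
#' scaled by `size_factor^3` so that the anatomy fits the desk-scale field of
#' view; the default grid (96 x 96 x 64 at 1.5 x 1.5 x 3 mm) mirrors
#' planning-CT anisotropy with 3 mm slice thickness.
#'
#' @param region `"thorax"` or `"pelvis"`.
#' @param dims integer triple, voxels per axis.
#' @param spacing mm triple.
#' @param size_factor linear scale applied to all organ dimensions.
#' @param body_intensity mean/SD (HU-like) of soft tissue inside the body outline.
#' @param air_intensity intensity outside the body.
#' @param noise_sd additive Gaussian noise SD applied to the whole image.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @param organs optional list overriding the per-region organ definitions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(region = c("thorax", "pelvis"), dims = c(96, 96, 64),
                         spacing = c(1.5, 1.5, 3), size_factor = 0.4,
                         body_intensity = c(20, 12), air_intensity = -1000,
                         noise_sd = 10, seed = 1, organs = NULL) {
  region <- match.arg(region)
  if (is.null(organs))
    organs <- switch(region, thorax = thorax_organs(size_factor),
                     pelvis = pelvis_organs(size_factor))
  lung_means <- vapply(organs[grepl("^lung", names(organs))],
                       function(o) o$intensity[1], 0)
  if (length(lung_means) && any(lung_means >= body_intensity[1]))
    stop("lung intensity mean must lie below the soft-tissue mean")
  structure(list(region = region, dims = as.integer(dims),
                 spacing = as.numeric(spacing), size_factor = size_factor,
                 body_intensity = body_intensity, air_intensity = air_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed), organs = organs),
            class = "phantom_spec")
}

#' Controlled contour-error model
#'
#' Describes how a ground-truth mask is degraded into an "AUTO-like" mask:
#' a world-mm translation (rounded to whole voxels), then 6-connected
#' dilation/erosion steps, then a smooth boundary displacement field.
#'
#' @param translation mm triple.
#' @param dilation_voxels integer; negative values erode.
#' @param boundary_noise_sd mm SD of the smooth surface-displacement field.
#' @param seed integer seed.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(translation = c(0, 0, 0), dilation_voxels = 0L,
                              boundary_noise_sd = 0, seed = 1) {
  structure(list(translation = as.numeric(translation),
                 dilation_voxels = as.integer(dilation_voxels),
                 boundary_noise_sd = boundary_noise_sd, seed = as.integer(seed)),
            class = "perturbation_spec")
}

organ_mask_array <- function(org, ax) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  if (org$type == "ellipsoid") {
    ex <- ((ax[[1]] - org$center[1]) / org$semi[1])^2
    ey <- ((ax[[2]] - org$center[2]) / org$semi[2])^2
    ez <- ((ax[[3]] - org$center[3]) / org$semi[3])^2
    q <- outer(outer(ex, ey, `+`), ez, `+`)
    q <= 1
  } else if (org$type == "tube") {
    occ <- array(FALSE, c(nx, ny, nz))
    zin <- ax[[3]] >= org$zrange[1] & ax[[3]] <= org$zrange[2]
    L <- diff(org$zrange)
    for (k in which(zin)) {
      cy <- org$center[2] + org$bend * sin(pi * (ax[[3]][k] - org$zrange[1]) / L)
      d2 <- outer((ax[[1]] - org$center[1])^2, (ax[[2]] - cy)^2, `+`)
      occ[, , k] <- d2 <= org$radius^2
    }
    occ
  } else stop("unknown organ type: ", org$type)
}

organ_bounds <- function(org) {
  if (org$type == "ellipsoid") {
    list(lower = org$center - org$semi, upper = org$center + org$semi)
  } else {
    list(lower = c(org$center[1] - org$radius,
                   org$center[2] - org$radius - abs(org$bend),
                   org$zrange[1]),
         upper = c(org$center[1] + org$radius,
                   org$center[2] + org$radius + abs(org$bend),
                   org$zrange[2]))
  }
}

mask_centroid_world <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE) - 1
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  colMeans(index_to_world(idx, mask))
}

mask_landmarks <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE) - 1
  w <- index_to_world(idx, mask)
  extreme <- function(col, fun) {
    v <- w[, col]
    target <- fun(v)
    colMeans(w[v == target, , drop = FALSE])
  }
  list(centroid = colMeans(w),
       right = extreme(1, min), left = extreme(1, max),
       anterior = extreme(2, min), posterior = extreme(2, max),
       inferior = extreme(3, min), superior = extreme(3, max))
}

#' Generate a synthetic phantom case
#'
#' Builds the CT-like volume, one binary ground-truth mask per organ (each a
#' single 6-connected component, pairwise disjoint), and named landmarks
#' (per-organ centroid and the six axis-extreme points). Deterministic for a
#' fixed spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([volume_grid()]), `masks` (named list
#'   of [structure_mask()]), `landmarks` (named list of world-mm triples,
#'   names like `"heart.centroid"`, `"heart.superior"`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$dims; s <- spec$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * s[a])
  fov_upper <- (d - 1) * s
  for (nm in names(spec$organs)) {
    b <- organ_bounds(spec$organs[[nm]])
    if (any(b$lower < 0) || any(b$upper > fov_upper))
      stop("organ '", nm, "' exceeds the grid bounds")
  }
  set.seed(spec$seed)
  # body outline: elliptical cylinder spanning the full z range
  bc <- c(72, 76) * s[1:2] * d[1:2] / (c(96, 96) * c(1.5, 1.5)) # scale with FOV
  br <- c(66, 60) * s[1:2] * d[1:2] / (c(96, 96) * c(1.5, 1.5))
  body2d <- outer(((ax[[1]] - bc[1]) / br[1])^2, ((ax[[2]] - bc[2]) / br[2])^2, `+`) <= 1
  body <- array(body2d, d)

  img <- array(spec$air_intensity, d)
  nb <- sum(body)
  img[body] <- spec$body_intensity[1] + rnorm(nb, sd = spec$body_intensity[2])

  masks <- list()
  for (nm in names(spec$organs)) {
    org <- spec$organs[[nm]]
    occ <- organ_mask_array(org, ax)
    if (!any(occ)) stop("organ '", nm, "' voxelizes to an empty mask")
    img[occ] <- org$intensity[1] + rnorm(sum(occ), sd = org$intensity[2])
    masks[[nm]] <- structure_mask(occ, s, c(0, 0, 0), nm)
  }
  # ground-truth masks must be pairwise disjoint
  if (length(masks) > 1L) {
    tot <- Reduce(`+`, lapply(masks, function(m) m$occupancy))
    if (any(tot > 1L)) stop("organ shapes overlap; adjust the phantom spec")
  }
  img <- img + rnorm(length(img), sd = spec$noise_sd)
  dim(img) <- d

  landmarks <- list()
  for (nm in names(masks)) {
    lm <- mask_landmarks(masks[[nm]])
    for (k in names(lm)) landmarks[[paste0(nm, ".", k)]] <- unname(lm[[k]])
  }
  list(volume = volume_grid(img, s), masks = masks, landmarks = landmarks,
       spec = spec)
}

shift_array <- function(occ, sh) {
  d <- dim(occ)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    n <- d[a] - abs(sh[a])
    if (n <= 0L) return(out)
    if (sh[a] >= 0) {
      src[[a]] <- seq_len(n)
      dst[[a]] <- src[[a]] + sh[a]
    } else {
      src[[a]] <- seq_len(n) - sh[a]
      dst[[a]] <- seq_len(n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(occ) {
  out <- occ
  for (a in 1:3) for (s in c(-1L, 1L)) {
    sh <- integer(3); sh[a] <- s
    out <- out | shift_array(occ, sh)
  }
  out
}

# 6-connected erosion; beyond-grid neighbors count as background, so voxels on
# the grid boundary are eroded (mirrors the surface-voxel convention)
erode6 <- function(occ) {
  out <- occ
  for (a in 1:3) for (s in c(-1L, 1L)) {
    sh <- integer(3); sh[a] <- s
    out <- out & shift_array(occ, sh)
  }
  out
}

smooth_field <- function(dims, lattice = 8, sd_mm = 1) {
  cd <- pmax(2L, as.integer(ceiling(dims / lattice)) + 1L)
  coarse <- array(rnorm(prod(cd)), cd)
  idx <- as.matrix(expand.grid((seq_len(dims[1]) - 1) / lattice,
                               (seq_len(dims[2]) - 1) / lattice,
                               (seq_len(dims[3]) - 1) / lattice,
                               KEEP.OUT.ATTRS = FALSE))
  f <- sample_at_index(coarse, idx, "trilinear", clamp = TRUE)
  f <- f - mean(f)
  f <- f * (sd_mm / max(sd(f), 1e-12))
  dim(f) <- dims
  f
}

signed_distance_mm <- function(occ, spacing) {
  d_to_in <- cpp_edt(as.logical(occ), dim(occ), spacing)
  d_to_out <- cpp_edt(!as.logical(occ), dim(occ), spacing)
  out <- ifelse(as.logical(occ), -d_to_out, d_to_in)
  dim(out) <- dim(occ)
  out
}

#' Perturb a mask with a controlled contour-error model
#'
#' Applies, in order: world-mm translation rounded to the nearest whole voxel,
#' `dilation_voxels` steps of 6-connected dilation (negative = erosion), and a
#' smooth boundary displacement by a random field of the stated SD (generated
#' on a coarse lattice and trilinearly upsampled so the perturbed surface stays
#' smooth). Deterministic given the spec seed.
#'
#' @param mask a [structure_mask()].
#' @param pert a [perturbation_spec()].
#' @return the perturbed [structure_mask()].
#' @export
perturb_mask <- function(mask, pert) {
  if (!inherits(pert, "perturbation_spec")) stop("pert must be a perturbation_spec")
  occ <- mask$occupancy
  sh <- as.integer(round(pert$translation / mask$spacing))
  if (any(sh != 0L)) occ <- shift_array(occ, sh)
  k <- pert$dilation_voxels
  if (k > 0L) for (i in seq_len(k)) occ <- dilate6(occ)
  if (k < 0L) for (i in seq_len(-k)) occ <- erode6(occ)
  if (!any(occ)) stop("perturbation emptied the mask")
  if (pert$boundary_noise_sd > 0) {
    set.seed(pert$seed)
    f <- smooth_field(dim(occ), lattice = 8, sd_mm = pert$boundary_noise_sd)
    sdist <- signed_distance_mm(occ, mask$spacing)
    occ <- sdist <= f
    if (!any(occ)) stop("perturbation emptied the mask")
  }
  structure_mask(occ, mask$spacing, mask$origin, mask$structure_name)
}

#' Generate a cohort of phantom cases
#'
#' Each case gets independently jittered organ dimensions (semi-axes and tube
#' radii multiplied by uniform factors in `1 +/- jitter`) and a per-case seed
#' derived deterministically from the master seed.
#'
#' @param n number of cases (>= 1).
#' @param template a [phantom_spec()] used as the base for every case.
#' @param jitter relative jitter of organ dimensions (0 disables it).
#' @param seed master seed.
#' @return list of cases as returned by [generate_phantom()], each with an
#'   added `id` element.
#' @export
make_cohort <- function(n, template = phantom_spec(), jitter = 0.1, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  case_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2)
  lapply(seq_len(n), function(i) {
    spec <- template
    if (jitter > 0) {
      set.seed(case_seeds[i, 1])
      for (nm in names(spec$organs)) {
        org <- spec$organs[[nm]]
        if (org$type == "ellipsoid") {
          org$semi <- org$semi * runif(3, 1 - jitter, 1 + jitter)
        } else {
          org$radius <- org$radius * runif(1, 1 - jitter, 1 + jitter)
          org$bend <- org$bend * runif(1, 1 - jitter, 1 + jitter)
        }
        spec$organs[[nm]] <- org
      }
    }
    spec$seed <- case_seeds[i, 2]
    case <- generate_phantom(spec)
    case$id <- sprintf("case_%03d", i)
    case
  })
}

#' Write a phantom case (NIfTI volume, per-organ masks, landmark JSON)
#' @param case a case from [generate_phantom()] or [make_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- case$id %||% "case"
  paths <- c(file.path(dir, paste0(id, "_ct.nii.gz")))
  write_nifti(case$volume, paths[1])
  for (nm in names(case$masks)) {
    p <- file.path(dir, paste0(id, "_", nm, ".nii.gz"))
    write_nifti(case$masks[[nm]], p)
    paths <- c(paths, p)
  }
  lm_path <- file.path(dir, paste0(id, "_landmarks.json"))
  jsonlite::write_json(case$landmarks, lm_path, auto_unbox = FALSE, digits = NA)
  invisible(c(paths, lm_path))
}

#' Cohort manifest (case id, seed, per-organ volumes in ml)
#' @param cohort list of cases from [make_cohort()].
#' @return data.frame, one row per case.
#' @export
cohort_manifest <- function(cohort) {
  organ_names <- names(cohort[[1]]$masks)
  rows <- lapply(cohort, function(case) {
    vols <- vapply(case$masks, volume_ml, 0)
    df <- data.frame(case_id = case$id %||% NA_character_,
                     seed = case$spec$seed)
    for (nm in organ_names) df[[paste0("volume_", nm, "_ml")]] <- vols[[nm]]
    df
  })
  do.call(rbind, rows)
}
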