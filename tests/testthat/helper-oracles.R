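# Pure-R brute-force oracles, kept independent of the package's accelerated
# implementations, plus small fixture builders.

# random blob mask: thresholded smoothed noise, possibly empty
random_mask <- function(dims, spacing, p_fill = 0.3, structure_name = "m") {
  occ <- array(runif(prod(dims)) < p_fill, dims)
  structure_mask(occ, spacing, c(0, 0, 0), structure_name)
}

cube_mask <- function(dims, spacing, lo, hi, origin = c(0, 0, 0), name = "cube") {
  occ <- array(FALSE, dims)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  structure_mask(occ, spacing, origin, name)
}

# all-pairs directed distances between two world-mm point matrices
oracle_directed <- function(src, dst) {
  apply(src, 1, function(p) sqrt(min(colSums((t(dst) - p)^2))))
}

# surface voxel centers by explicit 6-neighborhood enumeration
oracle_surface_points <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  idx <- which(occ, arr.ind = TRUE)
  keep <- apply(idx, 1, function(v) {
    for (a in 1:3) for (s in c(-1, 1)) {
      n <- v
      n[a] <- n[a] + s
      if (any(n < 1) || any(n > d)) return(TRUE)
      if (!occ[n[1], n[2], n[3]]) return(TRUE)
    }
    FALSE
  })
  idx0 <- idx[keep, , drop = FALSE] - 1
  sweep(sweep(idx0, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# full metric set computed the slow way (voxel counting + all-pairs distances)
oracle_pair_metrics <- function(auto, man, percentile = 95) {
  a <- auto$occupancy
  m <- man$occupancy
  n_a <- sum(a); n_m <- sum(m); n_int <- sum(a & m); n_tot <- length(a)
  sa <- oracle_surface_points(auto)
  sm <- oracle_surface_points(man)
  d1 <- oracle_directed(sa, sm)
  d2 <- oracle_directed(sm, sa)
  q <- percentile / 100
  list(sensitivity = n_int / n_m,
       specificity = (n_tot - (n_a + n_m - n_int)) / (n_tot - n_m),
       jaccard = n_int / (n_a + n_m - n_int),
       dice = 2 * n_int / (n_a + n_m),
       discordance = 1 - n_int / n_a,
       gmi = 1 - n_int / n_m,
       msd = (sum(d1) + sum(d2)) / (length(d1) + length(d2)),
       rmsd = sqrt((sum(d1^2) + sum(d2^2)) / (length(d1) + length(d2))),
       hd = max(d1, d2),
       hd_p = max(quantile(d1, q, names = FALSE), quantile(d2, q, names = FALSE)))
}

# nonempty random mask pair on a shared anisotropic grid
random_mask_pair <- function(max_dim = 20) {
  dims <- sample(4:max_dim, 3, replace = TRUE)
  spacing <- c(runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 1, 4))
  repeat {
    a <- random_mask(dims, spacing, p_fill = runif(1, 0.1, 0.5), "auto")
    m <- random_mask(dims, spacing, p_fill = runif(1, 0.1, 0.5), "man")
    if (any(a$occupancy) && any(m$occupancy)) return(list(auto = a, man = m))
  }
}

# tiny thorax-like phantom spec for fast end-to-end tests
small_thorax_spec <- function(seed = 1)
  phantom_spec(region = "thorax", seed = seed)
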