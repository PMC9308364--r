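# Multi-scale landmark-walking agent. An action scorer (small MLP on a fixed
# patch centered at the current voxel) is trained by supervised classification
# against the distance-minimizing step; at detection time the agent greedily
# follows the top action coarse-to-fine until it revisits a position.

# rows: -x, +x, -y, +y, -z, +z (fixed tie-break order)
ACTION_TABLE <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                       ncol = 3, byrow = TRUE)

#' The distance-minimizing unit step towards a target voxel
#'
#' Among the six axis-aligned unit steps (weighted by voxel spacing, i.e.
#' measured in world mm), returns the one that maximally reduces the Euclidean
#' distance to the target. Ties break in the fixed order -x, +x, -y, +y, -z,
#' +z (axis order x, y, z; negative before positive).
#'
#' @param position,target 0-based voxel index triples (must differ).
#' @param spacing mm triple of the grid the agent walks on.
#' @return integer action index 1..6 into the action table, with attribute
#'   `step` (the index offset triple).
#' @export
optimal_action <- function(position, target, spacing = c(1, 1, 1)) {
  position <- as.numeric(position); target <- as.numeric(target)
  if (all(position == target))
    stop("position equals target: no action is defined")
  cand <- sweep(ACTION_TABLE, 2, spacing, `*`)
  delta <- sweep(-cand, 2, (target - position) * spacing, `+`)
  d2 <- rowSums(delta^2)
  a <- which.min(d2) # first minimum = stated tie order
  structure(as.integer(a), step = ACTION_TABLE[a, ])
}

#' Configuration of the landmark agent
#'
#' @param scales coarse-to-fine resampling factors (grid spacing multipliers);
#'   the agent walks one voxel of the scaled grid per step, so a factor-4
#'   stage takes effectively 4x larger steps.
#' @param patch odd patch edge length in voxels (per scale).
#' @param hidden hidden units of the action-scorer MLP.
#' @param samples_per_case training positions sampled per case and scale.
#' @param epochs,lr MLP training schedule.
#' @param window HU-like intensity window for patch normalization.
#' @param max_steps step budget per scale during detection.
#' @return list of class `agent_config`.
#' @export
agent_config <- function(scales = c(4, 2, 1), patch = 15, hidden = 64,
                         samples_per_case = 300, epochs = 120, lr = 2e-3,
                         window = c(-1000, 300), max_steps = 120) {
  if (patch %% 2 == 0) stop("patch size must be odd")
  structure(list(scales = sort(scales, decreasing = TRUE), patch = as.integer(patch),
                 hidden = as.integer(hidden),
                 samples_per_case = as.integer(samples_per_case),
                 epochs = as.integer(epochs), lr = lr, window = window,
                 max_steps = as.integer(max_steps)),
            class = "agent_config")
}

# resample a volume by an integer factor (spacing multiplied, trilinear)
resample_by_factor <- function(volume, f) {
  if (f == 1) return(volume)
  d <- dim(volume$values)
  nd <- pmax(1L, as.integer(ceiling(d / f)))
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * f)
  idx <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  out <- sample_at_index(volume$values, idx, "trilinear", clamp = TRUE)
  dim(out) <- nd
  volume_grid(out, volume$spacing * f, volume$origin)
}

# patch matrix (p^3 x n) for 0-based centers; outside-grid voxels filled
patch_matrix <- function(values, centers0, p, fill = -1000) {
  d <- dim(values)
  h <- (p - 1) / 2
  off <- as.matrix(expand.grid(-h:h, -h:h, -h:h, KEEP.OUT.ATTRS = FALSE))
  n <- nrow(centers0)
  out <- matrix(fill, p^3, n)
  for (j in seq_len(n)) {
    ij <- sweep(off, 2, as.numeric(centers0[j, ]), `+`)
    ok <- ij[, 1] >= 0 & ij[, 1] < d[1] & ij[, 2] >= 0 & ij[, 2] < d[2] &
      ij[, 3] >= 0 & ij[, 3] < d[3]
    lin <- ij[ok, 1] + d[1] * (ij[ok, 2] + d[2] * ij[ok, 3]) + 1
    out[ok, j] <- values[lin]
  }
  out
}

normalize_window <- function(x, window) {
  (pmin(pmax(x, window[1]), window[2]) - window[1]) / (window[2] - window[1])
}

#' Train a multi-scale landmark agent
#'
#' For each scale (coarse to fine) the case volumes are resampled by the scale
#' factor and an action scorer is trained on (patch, optimal action) pairs at
#' positions sampled across the volume (coarsest scale) or in a neighborhood
#' of the landmark sized to the previous stage's step size (finer scales,
#' mirroring where each stage starts at detection time).
#'
#' @param cohort list of phantom cases (each with `volume` and `landmarks`).
#' @param landmark_name name of the ground-truth landmark (e.g.
#'   `"heart.centroid"`).
#' @param config an [agent_config()].
#' @param seed integer seed for sampling and MLP initialization.
#' @return An object of class `agent_policy`.
#' @export
train_landmark_agent <- function(cohort, landmark_name, config = agent_config(),
                                 seed = 1) {
  for (case in cohort)
    if (is.null(case$landmarks[[landmark_name]]))
      stop("case is missing ground-truth landmark '", landmark_name, "'")
  scales <- config$scales
  models <- vector("list", length(scales))
  accuracy <- numeric(length(scales))
  for (si in seq_along(scales)) {
    f <- scales[si]
    set.seed(seed + si)
    X_list <- list(); y_list <- list()
    for (case in cohort) {
      vol <- resample_by_factor(case$volume, f)
      d <- dim(vol$values)
      tgt <- round(world_to_index(case$landmarks[[landmark_name]], vol))
      tgt <- pmin(pmax(as.numeric(tgt), 0), d - 1)
      m <- config$samples_per_case
      near_positions <- function(n, r) sapply(1:3, function(a)
        pmin(pmax(tgt[a] + sample.int(2 * r + 1, n, TRUE) - r - 1, 0), d[a] - 1))
      if (si == 1L) {
        # coarsest stage: mostly uniform starts, plus a near-target share so
        # the oscillation basin around the landmark is well trained
        m_near <- m %/% 4
        pos <- rbind(cbind(sample.int(d[1], m - m_near, TRUE),
                           sample.int(d[2], m - m_near, TRUE),
                           sample.int(d[3], m - m_near, TRUE)) - 1,
                     near_positions(m_near, 6))
      } else {
        # finer stages start where the previous stage hands off; a dense share
        # right at the target trains the final-approach behavior
        r <- ceiling(3 * scales[si - 1L] / f) + 2
        m_dense <- (2L * m) %/% 5L
        pos <- rbind(near_positions(m - m_dense, r), near_positions(m_dense, 3))
      }
      keep <- rowSums(sweep(pos, 2, tgt, `!=`)) > 0
      pos <- pos[keep, , drop = FALSE]
      labs <- apply(pos, 1, function(p0) as.integer(optimal_action(p0, tgt, vol$spacing)))
      X_list[[length(X_list) + 1L]] <-
        normalize_window(patch_matrix(vol$values, pos, config$patch), config$window)
      y_list[[length(y_list) + 1L]] <- labs
    }
    X <- do.call(cbind, X_list)
    y <- unlist(y_list)
    par <- mlp_init(nrow(X), config$hidden, 6L)
    fit <- mlp_train(par, X, y, epochs = config$epochs, lr = config$lr)
    z <- mlp_forward(fit$par, X)
    accuracy[si] <- mean(max.col(t(z), ties.method = "first") == y)
    models[[si]] <- fit$par
  }
  structure(list(landmark = landmark_name, scales = scales,
                 patch = config$patch, window = config$window,
                 max_steps = config$max_steps, models = models,
                 train_accuracy = accuracy),
            class = "agent_policy")
}

action_entropy <- function(z) {
  p <- exp(z - max(z)); p <- p / sum(p)
  -sum(p * log(pmax(p, 1e-12)))
}

#' Walk an agent to its landmark
#'
#' Runs the multi-stage search coarse to fine. At each scale the agent
#' greedily follows the top-scoring in-bounds action one voxel at a time until
#' a position repeats (the action estimation has converged and the walk
#' oscillates) or the step budget is exhausted; on oscillation the
#' more-converged position of the cycle (higher action-score entropy) is kept
#' and seeds the next finer scale.
#'
#' @param policy an `agent_policy` from [train_landmark_agent()].
#' @param volume the [volume_grid()] to search.
#' @param start 0-based voxel index to start from; default volume center.
#' @param max_steps per-scale step budget; default from the policy.
#' @return list with `position` (world mm triple of the fine-scale stop),
#'   `index` (0-based fine-scale voxel index) and `converged` (FALSE iff the
#'   finest scale exhausted its budget without oscillating).
#' @export
detect_landmark <- function(policy, volume, start = NULL, max_steps = NULL) {
  if (is.null(max_steps)) max_steps <- policy$max_steps
  d0 <- dim(volume$values)
  if (is.null(start)) start <- floor(d0 / 2)
  start <- as.numeric(start)
  if (any(start < 0 | start > d0 - 1)) stop("start position outside the volume")
  world <- as.numeric(index_to_world(start, volume))
  converged <- TRUE
  for (si in seq_along(policy$scales)) {
    f <- policy$scales[si]
    vol <- resample_by_factor(volume, f)
    d <- dim(vol$values)
    pos <- pmin(pmax(round(as.numeric(world_to_index(world, vol))), 0), d - 1)
    visited <- new.env(hash = TRUE)
    assign(paste(pos, collapse = ","), TRUE, envir = visited)
    steps <- 0L
    osc <- FALSE
    prev_a <- 0L
    while (steps < max_steps) {
      patch <- normalize_window(patch_matrix(vol$values, matrix(pos, 1), policy$patch),
                                policy$window)
      z <- as.numeric(mlp_forward(policy$models[[si]], patch))
      feasible <- vapply(1:6, function(a) {
        np <- pos + ACTION_TABLE[a, ]
        all(np >= 0) && all(np <= d - 1)
      }, TRUE)
      z_masked <- ifelse(feasible, z, -Inf)
      if (prev_a > 0L && sum(is.finite(z_masked)) > 1L) {
        # do not immediately undo the previous step: walks slide along scorer
        # decision boundaries instead of freezing there; any longer cycle is
        # still caught by the visited-position rule below
        inv <- prev_a + if (prev_a %% 2 == 1L) 1L else -1L
        z_masked[inv] <- -Inf
      }
      a <- which.max(z_masked)
      np <- pos + ACTION_TABLE[a, ]
      key <- paste(np, collapse = ",")
      if (!is.null(visited[[key]])) {
        patch2 <- normalize_window(patch_matrix(vol$values, matrix(np, 1), policy$patch),
                                   policy$window)
        z2 <- as.numeric(mlp_forward(policy$models[[si]], patch2))
        if (action_entropy(z2) > action_entropy(z)) pos <- np
        osc <- TRUE
        break
      }
      assign(key, TRUE, envir = visited)
      pos <- np
      prev_a <- a
      steps <- steps + 1L
    }
    if (!osc && si == length(policy$scales)) converged <- FALSE
    world <- as.numeric(index_to_world(pos, vol))
  }
  fine_index <- round(as.numeric(world_to_index(world, volume)))
  list(position = world, index = fine_index, converged = converged)
}

#' Fit ROI statistics from a training cohort
#'
#' For each named structure (an organ, or a group given as a character vector
#' of organ names whose union bounding box is used), computes the mean offset
#' of the structure's bounding-box center from its anchor landmark and the
#' per-axis maximum bounding-box extent over the cohort plus `2 * margin_mm`.
#'
#' @param cohort list of phantom cases with `masks` and `landmarks`.
#' @param structures named list mapping a structure name to the organ names it
#'   covers; default: each organ of the first case by itself.
#' @param anchors named character vector mapping structure name to the anchor
#'   landmark name; default `"<first organ>.superior"` (boundary points are
#'   better localized by local appearance than interior points, so the
#'   superior pole is the default anchor the detection agent walks to).
#' @param margin_mm non-negative safety margin added on every side.
#' @return An object of class `roi_stats`: per structure, `offset` (mm triple),
#'   `size` (mm triple) and the margin used.
#' @export
fit_roi_stats <- function(cohort, structures = NULL, anchors = NULL, margin_mm = 5) {
  if (length(cohort) == 0L) stop("empty cohort")
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (is.null(structures)) {
    organ_names <- names(cohort[[1]]$masks)
    structures <- setNames(as.list(organ_names), organ_names)
  }
  if (is.null(anchors))
    anchors <- setNames(vapply(structures, function(o) paste0(o[1], ".superior"), ""),
                        names(structures))
  stats <- list()
  for (nm in names(structures)) {
    offs <- matrix(NA_real_, length(cohort), 3)
    exts <- matrix(NA_real_, length(cohort), 3)
    for (ci in seq_along(cohort)) {
      case <- cohort[[ci]]
      lowers <- uppers <- NULL
      for (org in structures[[nm]]) {
        m <- case$masks[[org]]
        if (is.null(m)) stop("cohort case lacks mask '", org, "'")
        idx <- which(m$occupancy, arr.ind = TRUE) - 1
        w <- index_to_world(idx, m)
        lo <- apply(w, 2, min) - m$spacing / 2
        up <- apply(w, 2, max) + m$spacing / 2
        lowers <- if (is.null(lowers)) lo else pmin(lowers, lo)
        uppers <- if (is.null(uppers)) up else pmax(uppers, up)
      }
      anchor <- case$landmarks[[anchors[[nm]]]]
      if (is.null(anchor)) stop("cohort case lacks landmark '", anchors[[nm]], "'")
      offs[ci, ] <- (lowers + uppers) / 2 - anchor
      exts[ci, ] <- uppers - lowers
    }
    stats[[nm]] <- list(offset = colMeans(offs),
                        size = apply(exts, 2, max) + 2 * margin_mm,
                        margin_mm = margin_mm, anchor = unname(anchors[[nm]]))
  }
  structure(stats, class = "roi_stats")
}

#' Derive a world-space ROI box from a detected landmark
#'
#' The box is centered at `landmark + offset` with the fitted size, half-open.
#'
#' @param landmark world mm triple (detected or ground-truth anchor position).
#' @param organ structure name present in `stats`.
#' @param stats an `roi_stats` object from [fit_roi_stats()].
#' @return an [roi_box()].
#' @export
derive_roi <- function(landmark, organ, stats) {
  st <- stats[[organ]]
  if (is.null(st)) stop("no ROI statistics for structure '", organ, "'")
  center <- as.numeric(landmark) + st$offset
  roi_box(center - st$size / 2, center + st$size / 2)
}

#' Save / load an agent policy as a JSON-headed archive
#'
#' The checkpoint is a plain RDS-free, text-based file: a JSON header (landmark
#' name, scales, patch size, window) followed by base64-free numeric payload in
#' JSON. Suitable for small desk-scale policies.
#'
#' @param policy an `agent_policy`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_policy <- function(policy, path) {
  payload <- list(landmark = policy$landmark, scales = policy$scales,
                  patch = policy$patch, window = policy$window,
                  max_steps = policy$max_steps,
                  train_accuracy = policy$train_accuracy,
                  models = lapply(policy$models, function(m)
                    lapply(m, function(x) list(dim = dim(x) %||% length(x),
                                               data = as.numeric(x)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  models <- lapply(p$models, function(m) {
    out <- lapply(m, function(x) {
      v <- as.numeric(x$data)
      if (length(x$dim) == 2L) dim(v) <- x$dim
      v
    })
    out
  })
  structure(list(landmark = p$landmark, scales = p$scales, patch = p$patch,
                 window = p$window, max_steps = p$max_steps,
                 train_accuracy = p$train_accuracy, models = models),
            class = "agent_policy")
}
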