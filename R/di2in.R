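# Deep image-to-image segmentation network: convolutional encoder-decoder with
# stride-2 convolutions for downsampling (no max pooling), trilinear
# upsampling in the decoder, multi-level feature concatenation, Conv+BN+ReLU
# blocks, softmax cross-entropy training with Adam. Feature maps are C x Nvox
# matrices (voxel linear index x-fastest); the heavy convolution kernels live
# in compiled code.

#' Segmentation model configuration
#'
#' @param input_size voxel triple; must be divisible by `2^(levels-1)`.
#' @param levels number of resolution levels (encoder depth).
#' @param channels feature channels per level, length `levels`.
#' @param n_out output channels: 1 for single-organ, `1 + number of organs`
#'   for multi-organ segmentation.
#' @param organ_names names of the foreground channels (length `n_out - 1`
#'   for multi-organ, 1 for single-organ).
#' @param lr learning rate of the Adam optimizer.
#' @param epochs default training epochs.
#' @param batch_size cases per parameter update.
#' @param seed seed for parameter initialization.
#' @param window HU-like intensity window; inputs are clipped to it and scaled
#'   to [0,1] before entering the network.
#' @param skip_connections if `FALSE`, the encoder-to-decoder concatenation
#'   links are removed (ablation switch).
#' @return list of class `seg_model_config`.
#' @export
seg_model_config <- function(input_size = c(48, 48, 48), levels = 3,
                             channels = c(8, 16, 32), n_out = 2,
                             organ_names = NULL, lr = 0.001, epochs = 50,
                             batch_size = 1, seed = 1, window = c(-1000, 300),
                             skip_connections = TRUE) {
  input_size <- as.integer(input_size)
  if (length(channels) != levels) stop("channels must have one entry per level")
  if (any(input_size %% 2^(levels - 1) != 0))
    stop("input size must be divisible by 2^(levels-1) on every axis")
  if (n_out < 1) stop("n_out must be >= 1")
  if (is.null(organ_names))
    organ_names <- if (n_out == 1) "structure" else paste0("organ_", seq_len(n_out - 1))
  structure(list(input_size = input_size, levels = as.integer(levels),
                 channels = as.integer(channels), n_out = as.integer(n_out),
                 organ_names = organ_names, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 window = window, skip_connections = isTRUE(skip_connections)),
            class = "seg_model_config")
}

conv_init <- function(c_out, c_in) {
  fan_in <- 27 * c_in
  list(W = matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in),
       b = numeric(c_out), gamma = rep(1, c_out), beta = numeric(c_out))
}

#' Build a segmentation network
#'
#' The encoder halves the spatial size per level with stride-2 3x3x3
#' convolutions; the decoder upsamples with trilinear interpolation and, at
#' each level, concatenates the matching encoder features before a 3x3x3
#' convolution. All convolutions are followed by batch normalization and
#' rectified-linear activation; a final 1x1x1 convolution produces the
#' per-channel scores. Parameter initialization is seeded.
#'
#' @param config a [seg_model_config()].
#' @return An object of class `seg_model`.
#' @export
build_di2in <- function(config) {
  if (!inherits(config, "seg_model_config")) stop("config must be a seg_model_config")
  set.seed(config$seed)
  L <- config$levels
  ch <- config$channels
  params <- list(enc1 = conv_init(ch[1], 1))
  if (L > 1)
    for (l in 2:L) params[[paste0("down", l)]] <- conv_init(ch[l], ch[l - 1])
  if (L > 1)
    for (l in (L - 1):1) {
      c_in <- ch[l + 1] + if (config$skip_connections) ch[l] else 0L
      params[[paste0("dec", l)]] <- conv_init(ch[l], c_in)
    }
  params$head <- list(W = matrix(rnorm(config$n_out * ch[1], sd = sqrt(2 / ch[1])),
                                 config$n_out, ch[1]),
                      b = numeric(config$n_out))
  structure(list(config = config, params = params), class = "seg_model")
}

#' Number of trainable parameters of a segmentation model
#' @param model a `seg_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(bl) sum(vapply(bl, length, 0L)), 0L))
}

bn_relu_fwd <- function(y, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(y)
  xc <- y - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  out <- gamma * xhat + beta
  mask <- out > 0
  list(out = out * mask, xhat = xhat, invstd = invstd, mask = mask)
}

bn_relu_bwd <- function(dout, cache, gamma) {
  dy <- dout * cache$mask
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  N <- ncol(dy)
  dx <- (cache$invstd / N) *
    (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# forward pass; x is a 1 x Nvox matrix of window-normalized intensities
di2in_forward <- function(model, x, dims) {
  cfg <- model$config
  L <- cfg$levels
  p <- model$params
  cache <- list(dims = vector("list", L), enc = vector("list", L),
                bn = list(), convin = list())
  cache$dims[[1]] <- dims
  cur <- x
  for (l in 1:L) {
    nm <- if (l == 1) "enc1" else paste0("down", l)
    stride <- if (l == 1) 1L else 2L
    indims <- cache$dims[[if (l == 1) 1 else l - 1]]
    cache$convin[[nm]] <- cur
    y <- cpp_conv3d_fwd(cur, indims, stride, p[[nm]]$W, p[[nm]]$b)
    if (l > 1) cache$dims[[l]] <- indims %/% 2L
    bn <- bn_relu_fwd(y, p[[nm]]$gamma, p[[nm]]$beta)
    cache$bn[[nm]] <- bn[c("xhat", "invstd", "mask")]
    cur <- bn$out
    cache$enc[[l]] <- cur
  }
  if (L > 1) {
    for (l in (L - 1):1) {
      nm <- paste0("dec", l)
      up <- cpp_upsample2(cur, cache$dims[[l + 1]])
      cat_in <- if (cfg$skip_connections) rbind(up, cache$enc[[l]]) else up
      cache$convin[[nm]] <- cat_in
      y <- cpp_conv3d_fwd(cat_in, cache$dims[[l]], 1L, p[[nm]]$W, p[[nm]]$b)
      bn <- bn_relu_fwd(y, p[[nm]]$gamma, p[[nm]]$beta)
      cache$bn[[nm]] <- bn[c("xhat", "invstd", "mask")]
      cur <- bn$out
    }
  }
  cache$feat <- cur
  scores <- p$head$W %*% cur + p$head$b
  list(scores = scores, cache = cache)
}

# backward pass; dscores is n_out x Nvox; returns grads named like params
di2in_backward <- function(model, cache, dscores) {
  cfg <- model$config
  L <- cfg$levels
  p <- model$params
  grads <- list()
  grads$head <- list(W = dscores %*% t(cache$feat), b = rowSums(dscores))
  dcur <- t(p$head$W) %*% dscores
  # skip-gradient accumulators for encoder outputs
  dskip <- vector("list", L)
  if (L > 1) {
    for (l in 1:(L - 1)) {
      nm <- paste0("dec", l)
      bb <- bn_relu_bwd(dcur, cache$bn[[nm]], p[[nm]]$gamma)
      wb <- cpp_conv3d_bwd_w(cache$convin[[nm]], cache$dims[[l]], 1L, bb$dx)
      grads[[nm]] <- list(W = wb$dW, b = as.numeric(wb$db),
                          gamma = bb$dgamma, beta = bb$dbeta)
      c_in <- nrow(cache$convin[[nm]])
      dcat <- cpp_conv3d_bwd_x(bb$dx, cache$dims[[l]], 1L, p[[nm]]$W, c_in)
      c_up <- cfg$channels[l + 1]
      dup <- dcat[seq_len(c_up), , drop = FALSE]
      if (cfg$skip_connections)
        dskip[[l]] <- dcat[(c_up + 1):c_in, , drop = FALSE]
      dcur <- cpp_upsample2_adj(dup, cache$dims[[l + 1]])
    }
  }
  # dcur now carries the gradient flowing into encoder level L
  for (l in L:1) {
    nm <- if (l == 1) "enc1" else paste0("down", l)
    stride <- if (l == 1) 1L else 2L
    indims <- cache$dims[[if (l == 1) 1 else l - 1]]
    if (!is.null(dskip[[l]])) dcur <- dcur + dskip[[l]]
    bb <- bn_relu_bwd(dcur, cache$bn[[nm]], p[[nm]]$gamma)
    wb <- cpp_conv3d_bwd_w(cache$convin[[nm]], indims, stride, bb$dx)
    grads[[nm]] <- list(W = wb$dW, b = as.numeric(wb$db),
                        gamma = bb$dgamma, beta = bb$dbeta)
    if (l > 1) {
      c_in <- nrow(cache$convin[[nm]])
      dcur <- cpp_conv3d_bwd_x(bb$dx, indims, stride, p[[nm]]$W, c_in)
    }
  }
  grads
}

flatten_params <- function(params) {
  out <- list()
  for (bl in names(params)) for (k in names(params[[bl]]))
    out[[paste0(bl, ".", k)]] <- params[[bl]][[k]]
  out
}

unflatten_params <- function(flat, template) {
  for (bl in names(template)) for (k in names(template[[bl]]))
    template[[bl]][[k]] <- flat[[paste0(bl, ".", k)]]
  template
}

normalize_input <- function(volume, window) {
  v <- if (inherits(volume, "volume_grid")) volume$values else volume
  matrix(normalize_window(as.numeric(v), window), nrow = 1)
}

case_labels_vector <- function(labels) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  as.integer(lab) + 1L # 1-based channel index, background = channel 1
}

#' Train a segmentation model
#'
#' Per-voxel cross-entropy over softmax-normalized channel scores, optimized
#' with Adam at the configured learning rate (default 0.001). Cases are
#' visited in a fixed order; the loss history records the mean per-voxel loss
#' of each epoch. Deterministic given the model seed.
#'
#' For a single-channel model (`n_out = 1`) the loss is the per-voxel
#' binary (sigmoid) cross-entropy against the 0/1 labels.
#'
#' @param model a `seg_model` from [build_di2in()].
#' @param cases list of cases, each a list with `volume` (a [volume_grid()] or
#'   raw array at the model input size) and `labels` (a [label_map()] or
#'   integer array with labels `< n_out` for multi-organ, 0/1 for `n_out = 1`).
#' @param epochs,lr optional overrides of the config values.
#' @return list with the trained `model` and `loss` (one entry per epoch).
#' @export
train_segmentation <- function(model, cases, epochs = NULL, lr = NULL) {
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(lr)) lr <- cfg$lr
  dims <- cfg$input_size
  prepared <- lapply(cases, function(case) {
    x <- normalize_input(case$volume, cfg$window)
    if (ncol(x) != prod(dims)) stop("case volume does not match the model input size")
    y <- case_labels_vector(case$labels)
    if (length(y) != prod(dims)) stop("case labels do not match the model input size")
    if (cfg$n_out > 1 && max(y) > cfg$n_out)
      stop("label >= n_out: case contains labels the model has no channel for")
    if (cfg$n_out == 1 && max(y) > 2L)
      stop("single-organ model requires binary labels")
    list(x = x, y = y)
  })
  flat <- flatten_params(model$params)
  st <- adam_init(flat)
  history <- numeric(epochs)
  nvox <- prod(dims)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (case in prepared) {
      fw <- di2in_forward(model, case$x, dims)
      if (cfg$n_out == 1) {
        z <- fw$scores
        pr <- 1 / (1 + exp(-z))
        t01 <- matrix(as.numeric(case$y == 2L), 1)
        tot <- tot + mean(-(t01 * log(pmax(pr, 1e-12)) +
                              (1 - t01) * log(pmax(1 - pr, 1e-12))))
        dsc <- (pr - t01) / nvox
      } else {
        pmat <- softmax_cols(fw$scores)
        sel <- cbind(case$y, seq_len(nvox))
        tot <- tot - mean(log(pmax(pmat[sel], 1e-12)))
        dsc <- pmat
        dsc[sel] <- dsc[sel] - 1
        dsc <- dsc / nvox
      }
      grads <- di2in_backward(model, fw$cache, dsc)
      upd <- adam_step(flat, flatten_params(grads)[names(flat)], st, lr = lr)
      flat <- upd$params
      st <- upd$state
      model$params <- unflatten_params(flat, model$params)
    }
    history[ep] <- tot / length(prepared)
  }
  list(model = model, loss = history)
}

#' Per-voxel channel probabilities
#' @param model a `seg_model`.
#' @param volume a [volume_grid()] (or raw array) at the model input size.
#' @return `n_out` x Nvox matrix; columns sum to 1 for multi-organ models
#'   (sigmoid probabilities for `n_out = 1`).
#' @export
predict_probs <- function(model, volume) {
  cfg <- model$config
  x <- normalize_input(volume, cfg$window)
  if (ncol(x) != prod(cfg$input_size))
    stop("volume does not match the model input size")
  sc <- di2in_forward(model, x, cfg$input_size)$scores
  if (cfg$n_out == 1) 1 / (1 + exp(-sc)) else softmax_cols(sc)
}

#' Predict a label map
#'
#' Softmax across channels per voxel; the label is the argmax channel with
#' ties broken toward the lower (background-first) index. Single-channel
#' models threshold the sigmoid score at 0.5.
#'
#' @param model a `seg_model`.
#' @param volume a [volume_grid()] at the model input size.
#' @return a [label_map()] on the volume's grid.
#' @export
predict_labels <- function(model, volume) {
  cfg <- model$config
  meta <- if (inherits(volume, "volume_grid")) grid_meta(volume)
          else list(dims = cfg$input_size, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  if (!identical(as.integer(meta$dims), cfg$input_size))
    stop("volume does not match the model input size")
  pr <- predict_probs(model, volume)
  if (cfg$n_out == 1) {
    lab <- array(as.integer(pr >= 0.5), meta$dims)
    return(label_map(lab, meta$spacing, meta$origin, cfg$organ_names[1]))
  }
  best <- pr[1, ]
  lab <- integer(ncol(pr)) # channel 0 = background
  if (cfg$n_out > 1) for (k in 2:cfg$n_out) {
    better <- pr[k, ] > best # strict: ties stay with the lower index
    lab[better] <- k - 1L
    best[better] <- pr[k, better]
  }
  label_map(array(lab, meta$dims), meta$spacing, meta$origin, cfg$organ_names)
}

# resample a volume onto explicit grid metadata (trilinear, fill outside)
resample_to_grid <- function(volume, meta, fill = -1000) {
  tm <- if (!is.null(meta$dims)) meta else grid_meta(meta)
  ax <- lapply(1:3, function(a) tm$origin[a] + (seq_len(tm$dims[a]) - 1) * tm$spacing[a])
  w <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  idx <- world_to_index(w, volume)
  d <- dim(volume$values)
  outside <- idx[, 1] < 0 | idx[, 1] > d[1] - 1 | idx[, 2] < 0 |
    idx[, 2] > d[2] - 1 | idx[, 3] < 0 | idx[, 3] > d[3] - 1
  out <- sample_at_index(volume$values, idx, "trilinear", clamp = TRUE)
  out[outside] <- fill
  dim(out) <- tm$dims
  volume_grid(out, tm$spacing, tm$origin)
}

#' Segment a case end to end
#'
#' Executes the full flow: detect the anchor landmark of every route, derive
#' its ROI, resample the ROI to the working grid, run the route's model,
#' resample each organ mask back to the original grid (nearest neighbor) and
#' aggregate everything into one multi-organ label map. A route whose landmark
#' does not converge is recorded as failed while the other routes proceed; an
#' empty predicted organ is kept (with a warning entry).
#'
#' @param volume the [volume_grid()] to segment.
#' @param policies named list of `agent_policy` objects.
#' @param stats an `roi_stats` object.
#' @param models named list of `seg_model` objects.
#' @param routes named list; each route is
#'   `list(organs = <character>, policy = , stats = , model = )` with the
#'   lookup names defaulting to the route name. The i-th organ of a route maps
#'   to label i of its model.
#' @param working_spacing mm (scalar or triple) of the working grid; `NULL`
#'   fits the ROI extent to the model input size per axis.
#' @param priority aggregation priority (earliest wins); default: organs in
#'   route order.
#' @param landmarks optional named list of known anchor positions (world mm)
#'   per route; routes present here skip agent detection (useful for oracle
#'   experiments and for replaying stored detections).
#' @return a [label_map()] on the input grid, with attributes `failures` and
#'   `warnings` (character vectors).
#' @export
segment_case <- function(volume, policies, stats, models, routes,
                         working_spacing = NULL, priority = NULL,
                         landmarks = NULL) {
  organ_masks <- list()
  failures <- character()
  warns <- character()
  for (rt in names(routes)) {
    route <- routes[[rt]]
    mdl <- models[[route$model %||% rt]]
    stat_name <- route$stats %||% rt
    if (is.null(mdl) || is.null(stats[[stat_name]]))
      stop("route '", rt, "' lacks a policy/ROI/model")
    if (!is.null(landmarks[[rt]])) {
      anchor_pos <- as.numeric(landmarks[[rt]])
    } else {
      pol <- policies[[route$policy %||% rt]]
      if (is.null(pol)) stop("route '", rt, "' lacks a policy/ROI/model")
      det <- detect_landmark(pol, volume)
      if (!det$converged) {
        failures <- c(failures, paste0(rt, ": landmark search did not converge"))
        next
      }
      anchor_pos <- det$position
    }
    roi <- derive_roi(anchor_pos, stat_name, stats)
    dims <- mdl$config$input_size
    sp <- if (is.null(working_spacing)) (roi$upper - roi$lower) / dims
          else rep(as.numeric(working_spacing), length.out = 3)
    center <- (roi$lower + roi$upper) / 2
    wmeta <- list(dims = dims, spacing = sp,
                  origin = center - (dims - 1) / 2 * sp)
    wvol <- resample_to_grid(volume, wmeta, fill = -1000)
    lab <- predict_labels(mdl, wvol)
    for (i in seq_along(route$organs)) {
      organ <- route$organs[i]
      occ_w <- array(lab$labels == i, dim(lab$labels))
      mw <- structure_mask(occ_w, lab$spacing, lab$origin, organ)
      mo <- resample_mask_to_grid(mw, grid_meta(volume))
      if (!any(mo$occupancy))
        warns <- c(warns, paste0(organ, ": empty predicted mask"))
      organ_masks[[organ]] <- mo
    }
  }
  if (length(organ_masks) == 0L) {
    out <- empty_label_map(volume)
  } else {
    if (is.null(priority)) priority <- names(organ_masks)
    out <- aggregate_masks(organ_masks, priority)
  }
  attr(out, "failures") <- failures
  attr(out, "warnings") <- warns
  out
}

#' Save / load a segmentation model as a JSON checkpoint
#' @param model a `seg_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_seg_model <- function(model, path) {
  cfg <- unclass(model$config)
  payload <- list(config = cfg,
                  params = lapply(model$params, function(bl)
                    lapply(bl, function(x) list(dim = dim(x) %||% length(x),
                                                data = as.numeric(x)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  cfg <- do.call(seg_model_config, p$config[setdiff(names(p$config), character())])
  params <- lapply(p$params, function(bl) {
    lapply(bl, function(x) {
      v <- as.numeric(x$data)
      if (length(x$dim) == 2L) dim(v) <- x$dim
      v
    })
  })
  structure(list(config = cfg, params = params), class = "seg_model")
}
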