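# End-to-end orchestration: simulate a phantom cohort, train landmark agents
# and segmentation models, segment held-out cases, evaluate AUTO against the
# ground truth, and aggregate per-structure summaries. Everything is driven by
# a single config with named seeds, so a run is reproducible byte for byte.

#' Aggregate per-case metrics into a cohort summary
#'
#' Per structure and metric: mean and sample standard deviation (n-1
#' denominator) over the defined (non-missing) values, plus `n_usable`, the
#' count of pairs where the metric was defined. The SD is reported only when
#' `n_usable >= 2`.
#'
#' @param per_case data.frame with columns `case_id`, `structure` and one
#'   column per metric (as produced by [run_pipeline()] /
#'   [evaluate_pair()] rows).
#' @return data.frame with columns `structure`, `metric`, `mean`, `sd`,
#'   `n_usable`.
#' @export
aggregate_cohort <- function(per_case) {
  if (nrow(per_case) == 0L) stop("empty per-case metric list")
  metric_cols <- setdiff(names(per_case), c("case_id", "structure"))
  rows <- list()
  for (structure in unique(per_case$structure)) {
    sub <- per_case[per_case$structure == structure, , drop = FALSE]
    for (metric in metric_cols) {
      v <- sub[[metric]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = structure, metric = metric,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2L) sd(v) else NA_real_,
        n_usable = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Default end-to-end run configuration
#'
#' @param region `"thorax"` or `"pelvis"`.
#' @param n_train,n_eval training and evaluation cohort sizes.
#' @param seed master seed; all stage seeds derive from it.
#' @param auto_source `"model"` runs the full landmark + network pipeline;
#'   `"perturbation"` manufactures AUTO masks by perturbing the ground truth
#'   (evaluation path standalone).
#' @param seg_epochs segmentation training epochs over the training cohort.
#' @param seg_lr learning rate for the desk-scale training schedule (a few
#'   hundred optimizer steps; larger than the production-recipe default of
#'   0.001 which assumes a much longer schedule).
#' @param input_size,channels network size (desk scale).
#' @param jitter cohort shape jitter.
#' @param margin_mm ROI safety margin.
#' @param agent an [agent_config()].
#' @param perturbation a [perturbation_spec()] used when
#'   `auto_source = "perturbation"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(region = "thorax", n_train = 10, n_eval = 20, seed = 1,
                       auto_source = c("model", "perturbation"),
                       seg_epochs = 30, seg_lr = 0.01, input_size = c(48, 48, 48),
                       channels = c(4, 8, 16), jitter = 0.1, margin_mm = 10,
                       agent = agent_config(),
                       perturbation = perturbation_spec(translation = c(3, 4, 0),
                                                        dilation_voxels = 1)) {
  structure(list(region = region, n_train = n_train, n_eval = n_eval,
                 seed = as.integer(seed), auto_source = match.arg(auto_source),
                 seg_epochs = seg_epochs, seg_lr = seg_lr,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels), jitter = jitter,
                 margin_mm = margin_mm, agent = agent,
                 perturbation = perturbation),
            class = "run_config")
}

#' Read a run configuration from YAML/JSON
#' @param path YAML or JSON config file; fields override [run_config()]
#'   defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  args <- raw[intersect(names(raw), setdiff(names(formals(run_config)),
                                            c("agent", "perturbation")))]
  cfg <- do.call(run_config, args)
  if (!is.null(raw$agent)) cfg$agent <- do.call(agent_config, raw$agent)
  if (!is.null(raw$perturbation))
    cfg$perturbation <- do.call(perturbation_spec, raw$perturbation)
  cfg
}

region_routes <- function(region) {
  if (region == "thorax") {
    list(thorax = list(organs = c("lung_right", "lung_left", "heart"),
                       anchor = "lung_left.superior"))
  } else {
    list(pelvis = list(organs = c("bladder", "rectum"),
                       anchor = "rectum.superior"))
  }
}

#' Run the full pipeline
#'
#' Simulates a training and an evaluation cohort, trains (or skips, for the
#' perturbation-only mode) the landmark agent and the segmentation model,
#' segments every evaluation case, evaluates AUTO against the ground-truth
#' MAN masks, and writes per-case metrics, the cohort summary and a run log.
#' Per-case failures are logged and excluded from aggregation per metric.
#'
#' @param config a [run_config()] (or path readable by [read_run_config()]).
#' @param out_dir output directory for CSV reports and the run log; `NULL`
#'   skips writing.
#' @return list with `per_case` (data.frame), `summary` (data.frame),
#'   `failures` (character), and the trained `artifacts`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed
  template <- phantom_spec(region = config$region)
  train_cohort <- make_cohort(config$n_train, template, jitter = config$jitter,
                              seed = seed)
  eval_cohort <- make_cohort(config$n_eval, template, jitter = config$jitter,
                             seed = seed + 1000L)
  routes <- region_routes(config$region)
  organ_names <- routes[[1]]$organs
  failures <- character()
  artifacts <- list()

  if (config$auto_source == "model") {
    group <- names(routes)[1]
    structures <- setNames(list(organ_names), group)
    anchors <- setNames(routes[[1]]$anchor, group)
    stats <- fit_roi_stats(train_cohort, structures, anchors,
                           margin_mm = config$margin_mm)
    policy <- train_landmark_agent(train_cohort, routes[[1]]$anchor,
                                   config$agent, seed = seed + 2000L)
    seg_cfg <- seg_model_config(input_size = config$input_size,
                                levels = length(config$channels),
                                channels = config$channels,
                                n_out = 1L + length(organ_names),
                                organ_names = organ_names,
                                epochs = config$seg_epochs,
                                seed = seed + 3000L)
    model <- build_di2in(seg_cfg)
    train_cases <- lapply(train_cohort, function(case)
      make_training_crop(case, organ_names, stats[[group]], seg_cfg))
    trained <- train_segmentation(model, train_cases, lr = config$seg_lr)
    model <- trained$model
    artifacts <- list(policy = policy, stats = stats, model = model,
                      loss = trained$loss)
    seg_routes <- setNames(list(list(organs = organ_names)), group)
    policies <- setNames(list(policy), group)
    models <- setNames(list(model), group)
  }

  rows <- list()
  for (case in eval_cohort) {
    if (config$auto_source == "model") {
      lab <- segment_case(case$volume, policies, artifacts$stats, models,
                          seg_routes)
      failures <- c(failures, paste0(case$id, ": ", attr(lab, "failures")))
      auto_masks <- lapply(seq_along(organ_names), function(i)
        structure_mask(array(lab$labels == i, dim(lab$labels)), lab$spacing,
                       lab$origin, organ_names[i]))
      names(auto_masks) <- organ_names
    } else {
      pert <- config$perturbation
      auto_masks <- lapply(case$masks, function(m) {
        p <- pert
        p$seed <- (p$seed + case$spec$seed) %% .Machine$integer.max
        perturb_mask(m, p)
      })
    }
    for (organ in names(case$masks)) {
      metrics <- evaluate_pair(auto_masks[[organ]], case$masks[[organ]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(case_id = case$id, structure = organ),
        as.data.frame(as.list(metrics)))
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- aggregate_cohort(per_case)
  failures <- failures[nzchar(failures) & !endsWith(failures, ": ")]

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_case, file.path(out_dir, "per_case_metrics.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    log_lines <- c("run log", paste0("package_version: ",
                                     as.character(utils::packageVersion("oarseg"))),
                   paste0("r_version: ", R.version.string),
                   yaml::as.yaml(serialize_config(config)),
                   paste0("failures: ", length(failures)), failures)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(per_case = per_case, summary = summary, failures = failures,
       artifacts = artifacts, config = config)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$agent <- unclass(cfg$agent)
  cfg$perturbation <- unclass(cfg$perturbation)
  cfg
}

# crop a training case to the model input grid using ground-truth landmarks
make_training_crop <- function(case, organ_names, stat, seg_cfg) {
  anchor <- case$landmarks[[stat$anchor]]
  center <- anchor + stat$offset
  dims <- seg_cfg$input_size
  sp <- stat$size / dims
  wmeta <- list(dims = dims, spacing = sp, origin = center - (dims - 1) / 2 * sp)
  wvol <- resample_to_grid(case$volume, wmeta, fill = -1000)
  masks_w <- lapply(organ_names, function(nm)
    resample_mask_to_grid(case$masks[[nm]], wmeta))
  lab <- aggregate_masks(masks_w, organ_names)
  list(volume = wvol, labels = lab)
}
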