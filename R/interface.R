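#' Command-line entry point
#'
#' Thin shell-facing driver binding the pipeline stages:
#' `synth` (generate a synthetic field plus ground-truth tracks),
#' `classify` (tracks to labeled behaviour steps), `fit` (tune and fit the
#' two behaviour models), `simulate` (run a cohort) and `evaluate`
#' (compare cohorts). Installed as the `smoltsim` executable script; every
#' run writes a JSON run log carrying the inputs, seed, package version,
#' a config hash and the wall time, so any artefact can be traced to the
#' configuration that produced it.
#'
#' Options may come from a JSON config file (`--config path`) with
#' command-line flags taking precedence. Unknown keys are rejected.
#'
#' @param argv character vector of arguments, e.g.
#'   `c("synth", "--out-prefix", "run1", "--seed", "7")`.
#' @return integer exit status, invisibly: 0 on success, 2 on validation
#'   failure, 3 on runtime failure.
#' @export
run_cli <- function(argv) {
  if (length(argv) < 1L) {
    message("usage: smoltsim <synth|classify|fit|simulate|evaluate> [options]")
    return(invisible(2L))
  }
  sub <- argv[[1L]]
  handlers <- list(synth = cli_synth, classify = cli_classify, fit = cli_fit,
                   simulate = cli_simulate, evaluate = cli_evaluate)
  if (!sub %in% names(handlers)) {
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  opts <- tryCatch(parse_cli_options(argv[-1L], cli_known_keys[[sub]]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message("invalid arguments: ", conditionMessage(opts))
    return(invisible(2L))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(handlers[[sub]](opts), error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    status <- if (inherits(res, "smoltsim_validation_error")) 2L else 3L
    return(invisible(status))
  }
  write_run_log(sub, opts, res, proc.time()[["elapsed"]] - t0)
  invisible(0L)
}

cli_known_keys <- list(
  synth = c("config", "out-prefix", "n-rows", "n-cols", "base-speed",
            "cross-flow-amplitude", "intake-attraction", "tke-scale",
            "n-fish", "max-steps", "tolerance", "seed"),
  classify = c("config", "field", "meta", "tracks", "out", "tolerance",
               "max-displacement"),
  fit = c("config", "steps", "out-prefix", "seed", "k", "lr-grid",
          "depth-grid", "max-trees", "patience"),
  simulate = c("config", "field", "meta", "follow-model", "direction-model",
               "mode", "starts", "replicates", "max-steps", "tolerance",
               "seed", "out-prefix"),
  evaluate = c("config", "field", "meta", "behaviour-tracks", "drift-tracks",
               "observed-tracks", "out-prefix")
)

parse_cli_options <- function(args, known) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("expected --option, got '", a, "'")
    key <- substring(a, 3L)
    if (!key %in% known)
      stop("unknown option --", key)
    if (i == length(args)) stop("option --", key, " needs a value")
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  if (!is.null(opts$config)) {
    file_opts <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    bad <- setdiff(names(file_opts), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (k in setdiff(names(file_opts), names(opts)))
      opts[[k]] <- file_opts[[k]]
  }
  opts
}

validation_error <- function(...) {
  stop(structure(class = c("smoltsim_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

opt_num <- function(opts, key, default, lower = -Inf, upper = Inf) {
  v <- opts[[key]]
  if (is.null(v)) return(default)
  v <- suppressWarnings(as.numeric(v))
  if (is.na(v) || v < lower || v > upper)
    validation_error("option --", key, " out of range [", lower, ", ",
                     upper, "]")
  v
}

opt_path <- function(opts, key, must_exist = TRUE) {
  v <- opts[[key]]
  if (is.null(v)) validation_error("option --", key, " is required")
  if (must_exist && !file.exists(v))
    validation_error("file not found: ", v)
  v
}

write_run_log <- function(sub, opts, artefacts, elapsed) {
  prefix <- opts[["out-prefix"]] %||% opts[["out"]] %||% sub
  cfg_json <- jsonlite::toJSON(opts[order(names(opts))], auto_unbox = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  log <- list(subcommand = sub, options = opts,
              config_hash = unname(tools::md5sum(tf)),
              seed = opts[["seed"]] %||% NA,
              artefacts = artefacts,
              package_version = as.character(utils::packageVersion("smoltsim")),
              elapsed_s = round(elapsed, 3))
  unlink(tf)
  jsonlite::write_json(log, paste0(prefix, "_runlog.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
}

cli_synth <- function(opts) {
  tol <- opt_num(opts, "tolerance", 20, 0, 179.999)
  spec <- synthetic_field_spec(
    n_rows = opt_num(opts, "n-rows", 40, 5),
    n_cols = opt_num(opts, "n-cols", 60, 5),
    base_speed = opt_num(opts, "base-speed", 0.8, 1e-9),
    cross_flow_amplitude = opt_num(opts, "cross-flow-amplitude", 0),
    intake_attraction = opt_num(opts, "intake-attraction", 0.4),
    tke_scale = opt_num(opts, "tke-scale", 0.05, 0),
    seed = opt_num(opts, "seed", 1))
  scenario <- make_channel_field(spec)
  truth <- truth_params(tolerance = tol)
  gen <- generate_truth_tracks(
    scenario, truth,
    n_fish = opt_num(opts, "n-fish", 20, 1),
    max_steps = opt_num(opts, "max-steps", 200, 1),
    seed = opt_num(opts, "seed", 1))
  p <- opts[["out-prefix"]] %||% "synth"
  write_scenario(scenario, paste0(p, "_field.csv"), paste0(p, "_meta.json"))
  utils::write.csv(gen$points, paste0(p, "_tracks.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(gen$steps, paste0(p, "_truth_steps.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(follow_coefficients = as.list(truth$follow_coefficients),
         random_coefficients = as.list(truth$random_coefficients),
         tolerance = truth$tolerance,
         labels_path = paste0(p, "_truth_steps.csv")),
    paste0(p, "_truth.json"), auto_unbox = TRUE, digits = NA)
  paste0(p, c("_field.csv", "_meta.json", "_tracks.csv", "_truth_steps.csv",
              "_truth.json"))
}

cli_classify <- function(opts) {
  tol <- opt_num(opts, "tolerance", 20, 0, 179.999)
  scenario <- load_scenario(opt_path(opts, "field"), opt_path(opts, "meta"))
  points <- read_tracks(opt_path(opts, "tracks"))
  steps <- cellize_track(points, scenario,
                         max_displacement = opt_num(opts, "max-displacement",
                                                    5, 0))
  labeled <- label_steps(steps, tolerance = tol)
  out <- opts[["out"]] %||% "labeled_steps.csv"
  write_labeled_steps(labeled, out)
  out
}

cli_fit <- function(opts) {
  labeled <- utils::read.csv(opt_path(opts, "steps"))
  if (!"behaviour" %in% names(labeled))
    validation_error("steps file lacks a behaviour column; run classify first")
  seed <- opt_num(opts, "seed", 1)
  lr_grid <- if (is.null(opts[["lr-grid"]])) default_lr_grid else
    as.numeric(strsplit(opts[["lr-grid"]], ",")[[1]])
  depth_grid <- if (is.null(opts[["depth-grid"]])) default_depth_grid else
    as.integer(strsplit(opts[["depth-grid"]], ",")[[1]])
  if (anyNA(lr_grid) || anyNA(depth_grid))
    validation_error("could not parse hyperparameter grids")
  k <- opt_num(opts, "k", 10, 2)
  max_trees <- opt_num(opts, "max-trees", 10000, 1)
  patience <- opt_num(opts, "patience", 50, 1)
  ds <- build_datasets(labeled)
  p <- opts[["out-prefix"]] %||% "models"
  metrics <- list(); outs <- character()
  for (kind in c("follow", "direction")) {
    tab <- if (kind == "follow") ds$follow_table else ds$direction_table
    cv <- tune_brt(tab, lr_grid, depth_grid, k = k, seed = seed,
                   max_trees = max_trees, patience = patience)
    model <- fit_brt(tab, cv$best, seed = seed)
    base <- paste0(p, "_", kind)
    save_model(model, base)
    outs <- c(outs, paste0(base, c(".ubj", ".json")))
    metrics[[kind]] <- model_metrics(model, tab, cv)
  }
  utils::write.csv(do.call(rbind, metrics), paste0(p, "_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  c(outs, paste0(p, "_metrics.csv"))
}

parse_starts <- function(txt, scenario) {
  if (file.exists(txt)) {
    tab <- utils::read.csv(txt)
    return(lapply(seq_len(nrow(tab)), function(i)
      c(tab$row[i], tab$col[i])))
  }
  lapply(strsplit(txt, ";")[[1]], function(s) {
    rc <- suppressWarnings(as.integer(strsplit(s, ",")[[1]]))
    if (length(rc) != 2L || anyNA(rc))
      validation_error("could not parse start cell '", s, "'")
    rc
  })
}

cli_simulate <- function(opts) {
  scenario <- load_scenario(opt_path(opts, "field"), opt_path(opts, "meta"))
  mode <- opts[["mode"]] %||% "behaviour"
  if (!mode %in% c("behaviour", "drift_only"))
    validation_error("mode must be behaviour or drift_only")
  follow <- direction <- NULL
  if (mode == "behaviour") {
    follow <- load_model(opt_path(opts, "follow-model", must_exist = FALSE))
    direction <- load_model(opt_path(opts, "direction-model",
                                     must_exist = FALSE))
  }
  if (is.null(opts$starts)) validation_error("option --starts is required")
  cfg <- sim_config(
    start_cells = parse_starts(opts$starts, scenario),
    replicates_per_start = opt_num(opts, "replicates", 5, 1),
    max_steps = opt_num(opts, "max-steps", 1000, 1),
    tolerance = opt_num(opts, "tolerance", 20, 0, 179.999),
    seed = opt_num(opts, "seed", 1),
    mode = mode)
  cohort <- simulate_cohort(scenario, follow, direction, cfg)
  p <- opts[["out-prefix"]] %||% "sim"
  utils::write.csv(cohort_tracks_df(cohort), paste0(p, "_tracks.csv"),
                   row.names = FALSE, quote = FALSE)
  fates <- data.frame(fate = names(cohort$fate_counts),
                      n = as.integer(cohort$fate_counts))
  utils::write.csv(fates, paste0(p, "_fates.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(cfg), paste0(p, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  paste0(p, c("_tracks.csv", "_fates.csv", "_config.json"))
}

tracks_csv_to_cells <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$track_id), function(d) {
    d <- d[order(d$step), ]
    cbind(row = d$row, col = d$col)
  })
}

cli_evaluate <- function(opts) {
  scenario <- load_scenario(opt_path(opts, "field"), opt_path(opts, "meta"))
  cohorts <- list(
    behaviour = tracks_csv_to_cells(opt_path(opts, "behaviour-tracks")),
    drift_only = tracks_csv_to_cells(opt_path(opts, "drift-tracks")))
  if (!is.null(opts[["observed-tracks"]])) {
    pts <- read_tracks(opt_path(opts, "observed-tracks"))
    cohorts$observed <- lapply(split(pts, pts$fish_id), function(d) {
      cells <- xy_to_cell(scenario, d$x, d$y)
      keep <- c(TRUE, cells[-1, "row"] != cells[-nrow(cells), "row"] |
                      cells[-1, "col"] != cells[-nrow(cells), "col"])
      cells[keep, , drop = FALSE]
    })
  }
  cmp <- compare_cohorts(cohorts, scenario)
  p <- opts[["out-prefix"]] %||% "eval"
  utils::write.csv(cmp$fate_table, paste0(p, "_fates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cmp$metric_summary, paste0(p, "_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fate_table = cmp$fate_table,
                            metric_summary = cmp$metric_summary),
                       paste0(p, "_summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  paste0(p, c("_fates.csv", "_metrics.csv", "_summary.json"))
}
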