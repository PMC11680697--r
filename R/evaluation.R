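#' Complexity metrics of one track
#'
#' Quantifies the shape of a cell-sequence track: total path length, net
#' displacement, sinuosity (path length over net displacement; 1 for a
#' straight track, undefined for a closed one), mean absolute per-step
#' heading change, and the fraction of visited cells visited more than
#' once. These are the diagnostics for "searching" behaviour (back-and-
#' forth movement, revisited areas).
#'
#' @param cells matrix of `(row, col)` positions (at least 2 rows), or a
#'   `smolt_track`.
#' @param cell_size cell edge length in metres.
#' @return data.frame with `n_steps`, `path_length`, `net_displacement`,
#'   `sinuosity` (`NA` when net displacement is zero), `heading_change_rate`
#'   and `revisit_fraction`.
#' @export
track_metrics <- function(cells, cell_size = 0.5) {
  if (inherits(cells, "smolt_track")) cells <- cells$cells
  if (is.null(dim(cells)) || nrow(cells) < 2L)
    stop("track must visit at least two cells", call. = FALSE)
  x <- cells[, 2] * cell_size
  y <- cells[, 1] * cell_size
  dx <- diff(x); dy <- diff(y)
  seg <- sqrt(dx^2 + dy^2)
  path_length <- sum(seg)
  net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  hd <- bearing_deg(dx, dy)
  hcr <- if (length(hd) > 1L)
    mean(circular_difference(hd[-1], hd[-length(hd)])) else 0
  key <- paste(cells[, 1], cells[, 2])
  tab <- table(key)
  data.frame(n_steps = nrow(cells) - 1L,
             path_length = path_length,
             net_displacement = net,
             sinuosity = if (net > 0) path_length / net else NA_real_,
             heading_change_rate = hcr,
             revisit_fraction = sum(tab > 1L) / length(tab))
}

cohort_metrics <- function(cohort, cell_size) {
  do.call(rbind, lapply(cohort$tracks, track_metrics, cell_size = cell_size))
}

#' Compare simulated (and observed) cohorts
#'
#' Produces the fate table (counts and proportions of intake / bypass /
#' undetermined outcomes per cohort) and per-cohort mean and standard
#' deviation of every track metric. The canonical use is behaviour mode
#' against the drift-only baseline, optionally alongside cellised observed
#' tracks.
#'
#' @param cohorts named list; each element either a `smolt_cohort` or a
#'   list of cell matrices (observed tracks, whose fates are counted as
#'   `undetermined` unless they end in a region of `scenario`).
#' @param scenario the [flow_scenario()] the cohorts ran on.
#' @return list of class `fate_comparison` with `fate_table` (one row per
#'   cohort and fate: `cohort, fate, n, proportion`) and `metric_summary`
#'   (one row per cohort and metric: `cohort, metric, mean, sd`).
#' @export
compare_cohorts <- function(cohorts, scenario) {
  stopifnot(length(cohorts) >= 2L, !is.null(names(cohorts)))
  fate_rows <- list(); met_rows <- list()
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    if (inherits(ch, "smolt_cohort")) {
      if (length(ch$tracks) == 0L) stop("cohort '", nm, "' is empty",
                                        call. = FALSE)
      fates <- ch$fate_counts
      mets <- cohort_metrics(ch, scenario$cell_size)
    } else {
      if (length(ch) == 0L) stop("cohort '", nm, "' is empty", call. = FALSE)
      tr <- lapply(ch, function(cells)
        structure(list(cells = cells), class = "smolt_track"))
      f <- vapply(tr, classify_fate, "", scenario = scenario)
      fates <- table(factor(f, levels = c("intake", "bypass",
                                          "undetermined")))
      mets <- do.call(rbind, lapply(ch, track_metrics,
                                    cell_size = scenario$cell_size))
    }
    fate_rows[[nm]] <- data.frame(cohort = nm, fate = names(fates),
                                  n = as.integer(fates),
                                  proportion = as.integer(fates) / sum(fates))
    met_rows[[nm]] <- data.frame(
      cohort = nm, metric = names(mets),
      mean = vapply(mets, mean, 0, na.rm = TRUE),
      sd = vapply(mets, stats::sd, 0, na.rm = TRUE))
  }
  out <- list(fate_table = do.call(rbind, c(fate_rows, make.row.names = FALSE)),
              metric_summary = do.call(rbind, c(met_rows,
                                                make.row.names = FALSE)))
  class(out) <- "fate_comparison"
  out
}

#' @export
print.fate_comparison <- function(x, ...) {
  cat("<fate_comparison>\n")
  print(x$fate_table, row.names = FALSE)
  invisible(x)
}

#' Replicate an observed track under matched initial conditions
#'
#' Simulates `n_replicates` smolts from the observed track's starting cell,
#' each allowed exactly as many steps as the observed track, and reports
#' the track metrics side by side. This is the per-individual evaluation:
#' does the simulator reproduce the complexity of a specific observed
#' trajectory under matching conditions?
#'
#' @param observed data.frame of track points (`fish_id, t, x, y`) for one
#'   fish, or a cell matrix.
#' @param scenario the [flow_scenario()].
#' @param follow_model,direction_model fitted behaviour models.
#' @param n_replicates simulated replicates (default 3).
#' @param seed master seed.
#' @param tolerance angular tolerance, degrees.
#' @return list with `observed_metrics`, `replicate_metrics` (one row per
#'   replicate), `tracks` (the simulated `smolt_track`s) and `start`.
#' @export
matched_simulation <- function(observed, scenario, follow_model,
                               direction_model, n_replicates = 3L, seed = 1L,
                               tolerance = 20) {
  if (is.data.frame(observed)) {
    cells <- xy_to_cell(scenario, observed$x, observed$y)
    keep <- c(TRUE, cells[-1, "row"] != cells[-nrow(cells), "row"] |
                    cells[-1, "col"] != cells[-nrow(cells), "col"])
    cells <- cells[keep, , drop = FALSE]
  } else {
    cells <- observed
  }
  if (nrow(cells) < 2L)
    stop("observed track must span at least two cells", call. = FALSE)
  start <- as.integer(cells[1L, ])
  if (!cell_active(scenario, start[1], start[2]))
    stop("observed start cell is not active in this scenario", call. = FALSE)
  n_steps <- nrow(cells) - 1L
  cfg <- sim_config(start_cells = list(start), replicates_per_start = 1L,
                    max_steps = n_steps, tolerance = tolerance, seed = seed)
  grids <- model_grids(scenario, follow_model, direction_model, "behaviour")
  tracks <- lapply(seq_len(n_replicates), function(i) {
    set.seed(track_seed(seed, start[1], start[2], i))
    run_track(scenario, start, grids, cfg)
  })
  list(observed_metrics = track_metrics(cells, scenario$cell_size),
       replicate_metrics = do.call(rbind, lapply(tracks, track_metrics,
                                                 cell_size = scenario$cell_size)),
       tracks = tracks, start = start)
}
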