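#' Simulation configuration
#'
#' Bundles the knobs of a cohort simulation. Defaults mirror the study
#' design: four release points with five replicates each, at most 1000 steps
#' per smolt, and a 20 degree angular tolerance.
#'
#' @param start_cells list (or 2-column matrix) of `(row, col)` start cells.
#' @param replicates_per_start simulated smolts per start cell (default 5).
#' @param max_steps maximum cell transitions per smolt (default 1000).
#' @param tolerance angular tolerance in degrees (default 20).
#' @param seed master RNG seed; per-track substreams are derived from it.
#' @param mode `"behaviour"` (both fitted models drive decisions) or
#'   `"drift_only"` (every step follows the flow within the tolerance).
#' @param first_random `"per_bout"` (default): after every return to
#'   following the flow, the next non-follow step draws a fresh random
#'   heading; `"per_fish"`: only the very first non-follow step of a smolt
#'   is forced random.
#' @param drift_jitter in drift mode, jitter the heading uniformly within
#'   the tolerance of the flow heading (default) rather than following the
#'   exact resultant.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(start_cells, replicates_per_start = 5L,
                       max_steps = 1000L, tolerance = 20, seed = 1L,
                       mode = c("behaviour", "drift_only"),
                       first_random = c("per_bout", "per_fish"),
                       drift_jitter = TRUE) {
  mode <- match.arg(mode)
  first_random <- match.arg(first_random)
  if (is.matrix(start_cells))
    start_cells <- lapply(seq_len(nrow(start_cells)),
                          function(i) as.integer(start_cells[i, ]))
  stopifnot(length(start_cells) >= 1L, replicates_per_start >= 1L,
            max_steps >= 1L)
  if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 180)
    stop("tolerance must be in [0, 180)", call. = FALSE)
  structure(list(start_cells = start_cells,
                 replicates_per_start = as.integer(replicates_per_start),
                 max_steps = as.integer(max_steps), tolerance = tolerance,
                 seed = as.integer(seed), mode = mode,
                 first_random = first_random, drift_jitter = drift_jitter),
            class = "sim_config")
}

#' Draw a random heading away from the flow
#'
#' Uniform over `[0, 360)` minus the closed arc `flow_heading` plus/minus
#' `tolerance`; the returned heading always differs from the flow heading by
#' more than the tolerance. This is the "searching" heading draw.
#'
#' @param flow_heading local flow heading, degrees.
#' @param tolerance excluded half-arc, degrees (must be < 180).
#' @return heading in `[0, 360)`.
#' @export
draw_random_heading <- function(flow_heading, tolerance) {
  stopifnot(tolerance < 180)
  repeat {
    h <- norm_heading(flow_heading + tolerance +
                        stats::runif(1, 0, 360 - 2 * tolerance))
    if (circular_difference(h, flow_heading) > tolerance) return(h)
  }
}

#' One behaviour decision of the movement loop
#'
#' Implements the per-cell decision: a Bernoulli draw at the
#' follow-the-flow probability decides whether the smolt follows the flow
#' (heading = flow heading jittered uniformly within the tolerance, and any
#' non-follow bout ends). Otherwise, on the first step of a non-follow bout
#' a random heading away from the flow is always drawn; within a bout a
#' second Bernoulli draw at the swim-direction probability chooses between
#' a fresh random heading (searching) and keeping the stored heading
#' (directional burst).
#'
#' Consumes the current R RNG stream; callers control reproducibility via
#' `set.seed()` (the cohort driver seeds a substream per track).
#'
#' @param state list with at least `heading` (degrees or `NA`) and
#'   `in_bout` (logical).
#' @param hydraulics named vector `u, v, w, tke` of the occupied cell.
#' @param flow_heading flow heading of the occupied cell, degrees.
#' @param follow_model,direction_model behaviour models for
#'   [predict_prob()].
#' @param tolerance angular tolerance, degrees.
#' @return list with `decision` (`"FOLLOW"`, `"DIRECTIONAL"` or
#'   `"NONDIRECTIONAL"`), `heading` and updated `in_bout`.
#' @export
decide_step <- function(state, hydraulics, flow_heading, follow_model,
                        direction_model, tolerance = 20) {
  p_follow <- predict_prob(follow_model, hydraulics)
  decide_step_p(state, flow_heading, p_follow,
                function() predict_prob(direction_model, hydraulics),
                tolerance)
}

# decision core shared by decide_step and the raster-driven cohort loop;
# p_random_fn is called only when a within-bout draw is actually needed
decide_step_p <- function(state, flow_heading, p_follow, p_random_fn,
                          tolerance) {
  if (stats::runif(1) < p_follow) {
    heading <- norm_heading(flow_heading +
                              stats::runif(1, -tolerance, tolerance))
    return(list(decision = "FOLLOW", heading = heading, in_bout = FALSE))
  }
  if (!isTRUE(state$in_bout) || is.na(state$heading)) {
    heading <- draw_random_heading(flow_heading, tolerance)
    return(list(decision = "NONDIRECTIONAL", heading = heading,
                in_bout = TRUE))
  }
  if (stats::runif(1) < p_random_fn()) {
    heading <- draw_random_heading(flow_heading, tolerance)
    list(decision = "NONDIRECTIONAL", heading = heading, in_bout = TRUE)
  } else {
    list(decision = "DIRECTIONAL", heading = state$heading, in_bout = TRUE)
  }
}

# 8-neighbour offsets and their centre-to-centre bearings (dy = drow,
# dx = dcol under the package geometry)
neighbour_offsets <- local({
  off <- expand.grid(drow = -1:1, dcol = -1:1)
  off <- off[!(off$drow == 0 & off$dcol == 0), ]
  off$bearing <- bearing_deg(off$dcol, off$drow)
  off
})

#' Move one cell along a heading
#'
#' Among the eight neighbouring cells, selects the active one whose
#' centre-to-centre bearing is closest (circularly) to the heading; ties are
#' broken clockwise-first. Dry or out-of-grid neighbours are skipped in
#' favour of the next-best active neighbour, so a smolt never enters
#' non-navigable water. When no active neighbour exists the function returns
#' `NULL` and the track terminates.
#'
#' @param scenario a [flow_scenario()].
#' @param cell current `(row, col)`.
#' @param heading desired heading, degrees.
#' @return integer `(row, col)` of the next cell, or `NULL`.
#' @export
move_step <- function(scenario, cell, heading) {
  off <- neighbour_offsets
  rows <- cell[[1]] + off$drow
  cols <- cell[[2]] + off$dcol
  ok <- cell_active(scenario, rows, cols)
  if (!any(ok)) return(NULL)
  diffs <- circular_difference(off$bearing, heading)
  clockwise <- (heading - off$bearing) %% 360
  ord <- order(!ok, diffs, clockwise)  # active first, nearest bearing first
  i <- ord[1L]
  c(rows[i], cols[i])
}

#' Simulate one smolt trajectory
#'
#' Runs the decision loop from a start cell: at each occupied cell a
#' behaviour decision assigns a heading ([decide_step()]; in drift-only mode
#' the flow is always followed), the smolt moves to the nearest-bearing
#' active neighbour ([move_step()]), and the loop ends when an intake or
#' exit-boundary cell is entered, when `max_steps` transitions have been
#' taken, or when the smolt has no active neighbour.
#'
#' @param scenario a [flow_scenario()] with `intake` and `exit_boundary`
#'   regions.
#' @param start integer `(row, col)` start cell (must be active).
#' @param follow_model,direction_model behaviour models (ignored in
#'   drift-only mode).
#' @param config a [sim_config()]; its `start_cells` are ignored here.
#' @return object of class `smolt_track`: list with `cells` (matrix of
#'   visited cells, one row per position), `decisions`, `headings`,
#'   `termination` (`"exited"`, `"max_steps_reached"` or `"stuck"`) and
#'   `fate` (`"intake"`, `"bypass"` or `"undetermined"`).
#' @export
simulate_smolt <- function(scenario, start, follow_model = NULL,
                           direction_model = NULL, config = sim_config(list(start))) {
  start <- as.integer(c(start[[1]], start[[2]]))
  if (!cell_active(scenario, start[1], start[2]))
    stop("start cell (", start[1], ", ", start[2], ") is not active",
         call. = FALSE)
  grids <- model_grids(scenario, follow_model, direction_model, config$mode,
                       config$drift_jitter)
  run_track(scenario, start, grids, config)
}

# probability rasters for the cohort loop; drift-only mode is the same loop
# with a constant follow probability of 1
model_grids <- function(scenario, follow_model, direction_model, mode,
                        drift_jitter = TRUE) {
  if (mode == "drift_only") {
    follow_model <- constant_model(1, "drift_only")
    direction_model <- constant_model(0, "drift_only")
  }
  if (is.null(follow_model) || is.null(direction_model))
    stop("behaviour mode requires both fitted models", call. = FALSE)
  act <- which(scenario$active)
  hyd <- data.frame(u = scenario$u[act], v = scenario$v[act],
                    w = scenario$w[act], tke = scenario$tke[act])
  pf <- matrix(NA_real_, nrow(scenario$u), ncol(scenario$u))
  pr <- pf
  pf[act] <- predict_prob(follow_model, hyd)
  pr[act] <- predict_prob(direction_model, hyd)
  list(p_follow = pf, p_random = pr,
       exact_flow = (mode == "drift_only") && !drift_jitter)
}

run_track <- function(scenario, start, grids, config) {
  max_steps <- config$max_steps
  tol <- config$tolerance
  per_fish <- config$first_random == "per_fish"
  cells <- matrix(NA_integer_, max_steps + 1L, 2L)
  decisions <- character(max_steps)
  headings <- numeric(max_steps)
  cells[1L, ] <- start
  state <- list(heading = NA_real_, in_bout = FALSE)
  cur <- start
  termination <- "max_steps_reached"
  n <- 0L
  intake <- scenario$regions$intake
  exitb <- scenario$regions$exit_boundary
  for (k in seq_len(max_steps)) {
    fh <- scenario$heading[cur[1], cur[2]]
    if (grids$exact_flow) {
      d <- list(decision = "FOLLOW", heading = fh, in_bout = FALSE)
    } else {
      d <- decide_step_p(state, fh, grids$p_follow[cur[1], cur[2]],
                         function() grids$p_random[cur[1], cur[2]], tol)
    }
    if (per_fish && d$decision == "FOLLOW") d$in_bout <- state$in_bout
    state <- list(heading = d$heading, in_bout = d$in_bout)
    nxt <- move_step(scenario, cur, d$heading)
    if (is.null(nxt)) { termination <- "stuck"; break }
    n <- k
    cells[k + 1L, ] <- nxt
    decisions[k] <- d$decision
    headings[k] <- d$heading
    cur <- nxt
    if ((!is.null(intake) && intake[cur[1], cur[2]]) ||
        (!is.null(exitb) && exitb[cur[1], cur[2]])) {
      termination <- "exited"
      break
    }
  }
  track <- structure(list(
    start = start,
    cells = cells[seq_len(n + 1L), , drop = FALSE],
    decisions = decisions[seq_len(n)],
    headings = headings[seq_len(n)],
    termination = termination,
    fate = NA_character_
  ), class = "smolt_track")
  track$fate <- classify_fate(track, scenario)
  track
}

#' Final fate of a simulated track
#'
#' @param track a `smolt_track`.
#' @param scenario the [flow_scenario()] it was simulated on.
#' @return `"intake"` (entered the turbine intake), `"bypass"` (passed the
#'   exit boundary / weir) or `"undetermined"`.
#' @export
classify_fate <- function(track, scenario) {
  last <- track$cells[nrow(track$cells), ]
  intake <- scenario$regions$intake
  exitb <- scenario$regions$exit_boundary
  if (!is.null(intake) && intake[last[1], last[2]]) return("intake")
  if (!is.null(exitb) && exitb[last[1], last[2]]) return("bypass")
  "undetermined"
}

# deterministic 32-bit substream seed from master seed + start cell +
# replicate, independent of start-cell ordering
track_seed <- function(seed, row, col, rep) {
  x <- (as.double(seed) * 48271 + row * 100003 + col * 10007 + rep * 7919)
  as.integer(x %% 2147483647)
}

#' Simulate a cohort of smolts
#'
#' Releases `replicates_per_start` smolts from every start cell in the
#' configuration. Each track runs on its own RNG substream derived from the
#' master seed and the (start cell, replicate) pair, so a cohort is
#' reproducible and independent of the ordering of start cells.
#'
#' @param scenario a [flow_scenario()].
#' @param follow_model,direction_model behaviour models (ignored in
#'   drift-only mode).
#' @param config a [sim_config()].
#' @return object of class `smolt_cohort`: list with `tracks` (list of
#'   `smolt_track`), `fate_counts` (named integer vector over intake /
#'   bypass / undetermined, summing to the number of tracks), `mode` and
#'   `config`.
#' @export
simulate_cohort <- function(scenario, follow_model = NULL,
                            direction_model = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  for (sc in config$start_cells) {
    if (!cell_active(scenario, sc[[1]], sc[[2]]))
      stop("start cell (", sc[[1]], ", ", sc[[2]], ") is not active",
           call. = FALSE)
  }
  grids <- model_grids(scenario, follow_model, direction_model, config$mode,
                       config$drift_jitter)
  tracks <- list()
  for (sc in config$start_cells) {
    for (rep_i in seq_len(config$replicates_per_start)) {
      set.seed(track_seed(config$seed, sc[[1]], sc[[2]], rep_i))
      tracks[[length(tracks) + 1L]] <-
        run_track(scenario, as.integer(c(sc[[1]], sc[[2]])), grids, config)
    }
  }
  fates <- factor(vapply(tracks, `[[`, "", "fate"),
                  levels = c("intake", "bypass", "undetermined"))
  structure(list(tracks = tracks,
                 fate_counts = table(fates),
                 mode = config$mode, config = config),
            class = "smolt_cohort")
}

#' @export
print.smolt_cohort <- function(x, ...) {
  cat(sprintf("<smolt_cohort> %d tracks (%s mode)\n", length(x$tracks),
              x$mode))
  print(x$fate_counts)
  invisible(x)
}

#' Tracks of a cohort as one data.frame
#'
#' @param cohort a `smolt_cohort`.
#' @return data.frame `track_id, step, row, col, decision, heading` (the
#'   start position has step 0 and no decision).
#' @export
cohort_tracks_df <- function(cohort) {
  dfs <- lapply(seq_along(cohort$tracks), function(i) {
    tr <- cohort$tracks[[i]]
    n <- nrow(tr$cells)
    data.frame(track_id = i, step = seq_len(n) - 1L,
               row = tr$cells[, 1], col = tr$cells[, 2],
               decision = c(NA_character_, tr$decisions),
               heading = c(NA_real_, tr$headings))
  })
  do.call(rbind, dfs)
}
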