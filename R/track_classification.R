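#' Convert positional tracks into cell-to-cell movement steps
#'
#' Maps each position onto the scenario grid, collapses consecutive positions
#' that fall in the same cell, and emits one movement step per transition
#' between distinct cells. Step headings are computed from cell centre to
#' cell centre. Positions falling outside the grid (or on dry cells), and
#' displacements larger than `max_displacement` between consecutive pings
#' (a coarse outlier filter for positioning noise), split the track into
#' independent segments: no step is formed across a gap, and the first step
#' of each segment has no previous heading.
#'
#' @param points data.frame with columns `fish_id`, `t` (seconds), `x`, `y`
#'   (metres); timestamps must be strictly increasing within a fish.
#' @param scenario a [flow_scenario()].
#' @param max_displacement largest plausible displacement (metres) between
#'   consecutive positions; larger jumps break the segment. `Inf` disables
#'   the filter. Default 5.
#' @return data.frame of steps with columns `fish_id`, `segment`,
#'   `from_row`, `from_col`, `to_row`, `to_col`, `step_heading`,
#'   `flow_heading`, `prev_step_heading` (`NA` for the first step of a
#'   segment), and the departure-cell hydraulics `u`, `v`, `w`, `tke`.
#' @export
cellize_track <- function(points, scenario, max_displacement = 5) {
  stopifnot(inherits(scenario, "flow_scenario"))
  need <- c("fish_id", "t", "x", "y")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("coordinates must be finite", call. = FALSE)

  out <- list()
  for (id in unique(points$fish_id)) {
    p <- points[points$fish_id == id, , drop = FALSE]
    p <- p[order(p$t), , drop = FALSE]
    if (any(diff(p$t) <= 0))
      stop("timestamps must be strictly increasing within fish '", id, "'",
           call. = FALSE)
    cells <- xy_to_cell(scenario, p$x, p$y)
    ok <- cell_active(scenario, cells[, "row"], cells[, "col"])
    jump <- c(FALSE, sqrt(diff(p$x)^2 + diff(p$y)^2) > max_displacement)
    # segment id increments at every inactive position or oversized jump
    seg <- cumsum(!ok | jump)
    seg[!ok] <- NA_integer_
    out[[length(out) + 1L]] <- segment_steps(id, cells, seg, scenario)
  }
  steps <- do.call(rbind, out)
  if (is.null(steps) || nrow(steps) == 0L) {
    warning("no usable steps: track(s) entirely outside the active grid")
    steps <- empty_steps()
  }
  rownames(steps) <- NULL
  steps
}

empty_steps <- function() {
  data.frame(fish_id = character(), segment = integer(),
             from_row = integer(), from_col = integer(),
             to_row = integer(), to_col = integer(),
             step_heading = numeric(), flow_heading = numeric(),
             prev_step_heading = numeric(),
             u = numeric(), v = numeric(), w = numeric(), tke = numeric())
}

# build steps for one fish given per-position cells and segment ids
segment_steps <- function(id, cells, seg, scenario) {
  res <- empty_steps()
  for (s in unique(seg[!is.na(seg)])) {
    i <- which(!is.na(seg) & seg == s)
    cc <- cells[i, , drop = FALSE]
    # collapse consecutive duplicates
    keep <- c(TRUE, cc[-1, "row"] != cc[-nrow(cc), "row"] |
                    cc[-1, "col"] != cc[-nrow(cc), "col"])
    cc <- cc[keep, , drop = FALSE]
    if (nrow(cc) < 2L) next
    fr <- cc[-nrow(cc), , drop = FALSE]
    to <- cc[-1, , drop = FALSE]
    ctr_f <- cell_center(scenario, fr[, "row"], fr[, "col"])
    ctr_t <- cell_center(scenario, to[, "row"], to[, "col"])
    hd <- bearing_deg(ctr_t[, "x"] - ctr_f[, "x"], ctr_t[, "y"] - ctr_f[, "y"])
    res <- rbind(res, data.frame(
      fish_id = id, segment = s,
      from_row = fr[, "row"], from_col = fr[, "col"],
      to_row = to[, "row"], to_col = to[, "col"],
      step_heading = hd,
      flow_heading = scenario$heading[fr],
      prev_step_heading = c(NA_real_, hd[-length(hd)]),
      u = scenario$u[fr], v = scenario$v[fr],
      w = scenario$w[fr], tke = scenario$tke[fr]
    ))
  }
  res
}

#' Label movement steps with their behaviour class
#'
#' A step is `FOLLOW` when its heading lies within `tolerance` degrees of the
#' local flow heading (flow-aligned swimming or drift). A non-follow step is
#' `DIRECTIONAL` when it maintains the previous step's heading within the
#' same tolerance (a deterministic burst away from the flow), otherwise
#' `NONDIRECTIONAL` (searching). The first step of a fish or segment has no
#' previous heading and can therefore never be `DIRECTIONAL`.
#'
#' The 20 degree default reflects the combined uncertainty of hydraulic
#' modelling and telemetry positioning; observed step-to-flow angular
#' differences concentrate below roughly that value.
#'
#' @param steps data.frame from [cellize_track()].
#' @param tolerance half-width of the angular acceptance band, degrees.
#' @return `steps` with an added `behaviour` factor
#'   (`FOLLOW`/`DIRECTIONAL`/`NONDIRECTIONAL`).
#' @export
label_steps <- function(steps, tolerance = 20) {
  if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 180)
    stop("tolerance must be in [0, 180)", call. = FALSE)
  dflow <- circular_difference(steps$step_heading, steps$flow_heading)
  dprev <- circular_difference(steps$step_heading, steps$prev_step_heading)
  beh <- ifelse(dflow <= tolerance, "FOLLOW",
         ifelse(!is.na(dprev) & dprev <= tolerance, "DIRECTIONAL",
                "NONDIRECTIONAL"))
  steps$behaviour <- factor(beh, levels = c("FOLLOW", "DIRECTIONAL",
                                            "NONDIRECTIONAL"))
  steps
}

#' Build the two binary training tables
#'
#' The follow-the-flow table has one row per labeled step with outcome
#' `y_follow` (1 = followed the flow). The swim-direction table is restricted
#' to non-follow steps that have a defined previous heading, with outcome
#' `y_random` (1 = fresh heading / searching, 0 = kept the previous
#' heading). Predictors are the departure-cell hydraulics.
#'
#' @param labeled data.frame from [label_steps()].
#' @return list with data.frames `follow_table` (`u,v,w,tke,y_follow`) and
#'   `direction_table` (`u,v,w,tke,y_random`; may have zero rows).
#' @export
build_datasets <- function(labeled) {
  stopifnot("behaviour" %in% names(labeled))
  pred <- c("u", "v", "w", "tke")
  follow_table <- cbind(labeled[, pred, drop = FALSE],
                        y_follow = as.integer(labeled$behaviour == "FOLLOW"))
  nf <- labeled$behaviour != "FOLLOW" & !is.na(labeled$prev_step_heading)
  direction_table <- cbind(labeled[nf, pred, drop = FALSE],
                           y_random = as.integer(
                             labeled$behaviour[nf] == "NONDIRECTIONAL"))
  rownames(follow_table) <- rownames(direction_table) <- NULL
  list(follow_table = follow_table, direction_table = direction_table)
}

#' Read a track CSV
#'
#' @param path CSV with header `fish_id,t,x,y` (metres, seconds).
#' @return data.frame of track points.
#' @export
read_tracks <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("fish_id", "t", "x", "y")
  if (!all(need %in% names(tab)))
    stop("track CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Write labeled steps to CSV
#'
#' @param labeled data.frame from [label_steps()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_labeled_steps <- function(labeled, path) {
  utils::write.csv(labeled, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
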