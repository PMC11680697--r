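# Shared fixtures: small scenarios and independent oracles, all built in code.

# uniform rectangular channel flowing +u (heading 0); banks dry, exit at the
# last column, optional intake block in the interior
uniform_scenario <- function(n_rows = 10, n_cols = 20, u = 0.5, v = 0,
                             w = 0, tke = 0.01, intake_rows = NULL,
                             intake_col = NULL, cell_size = 0.5) {
  mk <- function(val) matrix(val, n_rows, n_cols)
  um <- mk(u); vm <- mk(v); wm <- mk(w); tm <- mk(tke)
  um[c(1, n_rows), ] <- vm[c(1, n_rows), ] <- wm[c(1, n_rows), ] <-
    tm[c(1, n_rows), ] <- NA
  exitb <- matrix(FALSE, n_rows, n_cols)
  exitb[2:(n_rows - 1), n_cols] <- TRUE
  regions <- list(exit_boundary = exitb)
  if (!is.null(intake_rows)) {
    intake <- matrix(FALSE, n_rows, n_cols)
    intake[intake_rows, intake_col] <- TRUE
    regions$intake <- intake
  }
  flow_scenario(um, vm, wm, tm, cell_size = cell_size, regions = regions)
}

# independent oracle: mean Bernoulli deviance by explicit term-by-term sum
oracle_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  total <- 0
  for (i in seq_along(y)) {
    total <- total + if (y[i] == 1) log(p[i]) else log(1 - p[i])
  }
  -2 * total / length(y)
}

# independent oracle: AUC by exhaustive pair enumeration, ties counted 1/2
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# independent oracle: track metrics by explicit stepwise recomputation
oracle_track_metrics <- function(cells, cell_size) {
  pts <- cells * cell_size
  path <- 0; headings <- c()
  for (i in 2:nrow(pts)) {
    d <- pts[i, ] - pts[i - 1, ]
    path <- path + sqrt(sum(d^2))
    headings <- c(headings, (atan2(d[1], d[2]) * 180 / pi) %% 360)
  }
  net <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  hc <- 0
  if (length(headings) > 1) {
    for (i in 2:length(headings)) {
      dd <- abs(headings[i] - headings[i - 1]) %% 360
      hc <- hc + min(dd, 360 - dd)
    }
    hc <- hc / (length(headings) - 1)
  }
  visits <- table(apply(cells, 1, paste, collapse = "_"))
  list(path_length = path, net_displacement = net,
       sinuosity = if (net > 0) path / net else NA_real_,
       heading_change_rate = hc,
       revisit_fraction = sum(visits > 1) / length(visits))
}

# a small labeled-step table with known behaviour counts, hydraulics attached
labeled_fixture <- function(n_follow = 10, n_dir = 4, n_nondir = 6) {
  n <- n_follow + n_dir + n_nondir
  data.frame(
    fish_id = "f1", segment = 0L,
    from_row = 2L, from_col = seq_len(n), to_row = 2L, to_col = seq_len(n) + 1L,
    step_heading = c(rep(0, n_follow), rep(90, n_dir), rep(200, n_nondir)),
    flow_heading = 0,
    prev_step_heading = c(NA, rep(0, n_follow - 1), rep(90, n_dir),
                          rep(100, n_nondir)),
    u = stats::runif(n), v = stats::runif(n, -0.2, 0.2),
    w = stats::runif(n, -0.05, 0.05), tke = stats::runif(n, 0, 0.1),
    behaviour = factor(rep(c("FOLLOW", "DIRECTIONAL", "NONDIRECTIONAL"),
                           c(n_follow, n_dir, n_nondir)),
                       levels = c("FOLLOW", "DIRECTIONAL", "NONDIRECTIONAL"))
  )
}

# binary training table with a strong signal in one predictor
signal_table <- function(n = 400, slope = 4, predictor = "v", seed = 1,
                         outcome = "y_follow") {
  set.seed(seed)
  tab <- data.frame(u = runif(n, 0, 1), v = runif(n, -0.5, 0.5),
                    w = rnorm(n, 0, 0.05), tke = runif(n, 0, 0.2))
  eta <- slope * tab[[predictor]]
  tab[[outcome]] <- rbinom(n, 1, stats::plogis(eta))
  tab
}
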