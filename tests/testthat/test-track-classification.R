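test_that("circular difference wraps correctly", {
  expect_equal(circular_difference(350, 10), 20)
  expect_equal(circular_difference(0, 180), 180)
  expect_equal(circular_difference(90, 70), 20)
  expect_equal(circular_difference(-10, 10), 20)
  set.seed(1)
  a <- runif(100, -720, 720); b <- runif(100, -720, 720)
  d <- circular_difference(a, b)
  expect_true(all(d >= 0 & d <= 180))
  expect_equal(d, circular_difference(b, a))
})

test_that("cellizing collapses within-cell pings and emits distinct-cell steps", {
  sc <- uniform_scenario(n_rows = 6, n_cols = 8)
  # along +x through three cells of row 3 (y in cell row 3: 1.0..1.5)
  pts <- data.frame(fish_id = "a", t = 1:3,
                    x = c(0.25, 0.75, 1.25), y = 1.2)
  st <- cellize_track(pts, sc)
  expect_equal(nrow(st), 2)
  expect_true(all(st$step_heading == 0))
  expect_true(all(st$flow_heading == 0))
  expect_true(is.na(st$prev_step_heading[1]))
  expect_equal(st$prev_step_heading[2], 0)
  # five pings, middle three in the same cell -> two steps
  pts2 <- data.frame(fish_id = "a", t = 1:5,
                     x = c(0.25, 0.6, 0.65, 0.7, 1.3), y = 1.2)
  expect_equal(nrow(cellize_track(pts2, sc)), 2)
})

test_that("positions off the grid split a track into independent segments", {
  sc <- uniform_scenario(n_rows = 6, n_cols = 8)
  # middle ping on the dry bank (row 1): segments of 2 cells each side
  pts <- data.frame(fish_id = "a", t = 1:5,
                    x = c(0.25, 0.75, 0.75, 1.25, 1.75),
                    y = c(1.2, 1.2, 0.2, 1.2, 1.2))
  st <- cellize_track(pts, sc)
  expect_equal(nrow(st), 2)
  expect_equal(length(unique(st$segment)), 2)
  expect_true(all(is.na(st$prev_step_heading)))  # each segment restarts
  # oversized displacement breaks the segment too
  pts2 <- data.frame(fish_id = "a", t = 1:4,
                     x = c(0.25, 0.75, 3.9, 3.4), y = 1.2)
  st2 <- cellize_track(pts2, sc, max_displacement = 2)
  expect_equal(length(unique(st2$segment)), 2)
  # entirely outside the active grid: empty with a warning
  pts3 <- data.frame(fish_id = "a", t = 1:2, x = c(0.2, 0.7), y = 0.2)
  expect_warning(st3 <- cellize_track(pts3, sc), "outside")
  expect_equal(nrow(st3), 0)
})

test_that("behaviour labels follow the flow/previous-heading tolerance rules", {
  base <- data.frame(fish_id = "a", segment = 0L, from_row = 2L,
                     from_col = 2L, to_row = 2L, to_col = 3L,
                     u = 0.5, v = 0, w = 0, tke = 0.01)
  steps <- rbind(
    cbind(base, step_heading = 100, flow_heading = 90, prev_step_heading = NA),
    cbind(base, step_heading = 150, flow_heading = 90, prev_step_heading = 145),
    cbind(base, step_heading = 150, flow_heading = 90, prev_step_heading = 300))
  lab <- label_steps(steps, tolerance = 20)
  expect_equal(as.character(lab$behaviour),
               c("FOLLOW", "DIRECTIONAL", "NONDIRECTIONAL"))
  # first step of a segment can never be DIRECTIONAL
  first <- cbind(base, step_heading = 150, flow_heading = 90,
                 prev_step_heading = NA)
  expect_equal(as.character(label_steps(first)$behaviour), "NONDIRECTIONAL")
  # wrap-around: flow 350, step 10 is within 20 degrees
  wrap <- cbind(base, step_heading = 10, flow_heading = 350,
                prev_step_heading = NA)
  expect_equal(as.character(label_steps(wrap)$behaviour), "FOLLOW")
  expect_error(label_steps(steps, tolerance = -5), "tolerance")
})

test_that("every step gets exactly one label and FOLLOW grows with tolerance", {
  set.seed(7)
  n <- 300
  steps <- data.frame(fish_id = "a", segment = 0L, from_row = 2L,
                      from_col = seq_len(n), to_row = 2L,
                      to_col = seq_len(n) + 1L,
                      step_heading = runif(n, 0, 360),
                      flow_heading = runif(n, 0, 360),
                      prev_step_heading = c(NA, runif(n - 1, 0, 360)),
                      u = 0.5, v = 0, w = 0, tke = 0.01)
  tols <- c(0, 5, 10, 20, 45, 90, 179)
  follows <- vapply(tols, function(tol) {
    lab <- label_steps(steps, tolerance = tol)
    expect_false(anyNA(lab$behaviour))
    sum(lab$behaviour == "FOLLOW")
  }, 0L)
  expect_true(all(diff(follows) >= 0))
})

test_that("training tables mirror the label bookkeeping", {
  lab <- labeled_fixture(n_follow = 10, n_dir = 4, n_nondir = 6)
  ds <- build_datasets(lab)
  expect_equal(nrow(ds$follow_table), 20)
  expect_equal(sum(ds$follow_table$y_follow), 10)
  expect_equal(nrow(ds$direction_table), 10)
  expect_equal(sum(ds$direction_table$y_random), 6)
  # all-FOLLOW input leaves the direction table empty
  allf <- labeled_fixture(10, 0, 0)
  expect_equal(nrow(build_datasets(allf)$direction_table), 0)
})

test_that("classifying generated tracks recovers the generator bookkeeping", {
  sc <- make_channel_field(synthetic_field_spec(n_rows = 20, n_cols = 30,
                                                seed = 3))
  gen <- generate_truth_tracks(sc, truth_params(), n_fish = 8,
                               max_steps = 80, seed = 5)
  st <- cellize_track(gen$points, sc, max_displacement = Inf)
  # one step per generated cell transition
  expect_equal(nrow(st), nrow(gen$points) - length(unique(gen$points$fish_id)))
  lab <- label_steps(st)
  ds <- build_datasets(lab)
  expect_equal(nrow(ds$follow_table), nrow(st))
})

test_that("angular differences on follow-dominated tracks are left-skewed", {
  sc <- uniform_scenario(n_rows = 12, n_cols = 40)
  follow <- constant_model(0.9)
  random <- constant_model(0.5)
  cfg <- sim_config(list(c(6, 2)), replicates_per_start = 30, max_steps = 60,
                    seed = 9)
  coh <- simulate_cohort(sc, follow, random, cfg)
  pts <- do.call(rbind, lapply(seq_along(coh$tracks), function(i) {
    tr <- coh$tracks[[i]]
    data.frame(fish_id = i, t = seq_len(nrow(tr$cells)),
               x = (tr$cells[, 2] - 0.5) * 0.5,
               y = (tr$cells[, 1] - 0.5) * 0.5)
  }))
  st <- cellize_track(pts, sc, max_displacement = Inf)
  d <- circular_difference(st$step_heading, st$flow_heading)
  expect_gt(mean(d <= 20), 0.6)    # mass concentrated within the tolerance
  expect_lt(median(d), 20)         # left-skewed towards alignment
})

test_that("labeled steps round-trip through CSV", {
  lab <- labeled_fixture()
  td <- withr::local_tempdir()
  p <- file.path(td, "lab.csv")
  write_labeled_steps(lab, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(lab))
  expect_equal(back$behaviour, as.character(lab$behaviour))
})
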