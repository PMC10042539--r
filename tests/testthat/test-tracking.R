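# helper: label maps for moving discs; `paths` is a list per cell of a
# data.frame(frame, row, col, mass); absent frames mean the cell is gone.
frames_from_paths <- function(paths, n_frames, shape = c(96, 96), radius = 8) {
  lapply(seq_len(n_frames), function(f) {
    rows <- do.call(rbind, lapply(paths, function(p) p[p$frame == f, ]))
    if (is.null(rows) || !nrow(rows))
      return(label_map(matrix(0L, shape[1], shape[2]),
                       matrix(0, shape[1], shape[2])))
    make_disc_labels(shape, as.matrix(rows[, c("row", "col")]), radius,
                     rows$mass)
  })
}

test_that("a stationary cell yields one full-length track", {
  paths <- list(data.frame(frame = 1:10, row = 48, col = 48, mass = 100 + 1:10))
  lms <- frames_from_paths(paths, 10)
  tr <- track_cells(lms, times = (0:9) * 0.25)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$data), 10L)
  expect_equal(tr[[1]]$fate, "censored_at_end")
  expect_equal(tr[[1]]$data$mass_pg, 100 + 1:10, tolerance = 1e-12)
})

test_that("two moving cells keep their identities", {
  pa <- data.frame(frame = 1:8, row = 20 + (1:8), col = 20, mass = 100)
  pb <- data.frame(frame = 1:8, row = 70 - (1:8), col = 70, mass = 200)
  lms <- frames_from_paths(list(pa, pb), 8, shape = c(96, 96))
  tr <- track_cells(lms, times = (0:7) * 0.25)
  expect_length(tr, 2L)
  masses <- sort(vapply(tr, function(t) mean(t$data$mass_pg), numeric(1)))
  expect_equal(masses, c(100, 200), tolerance = 1e-9)
  for (t in tr) expect_equal(nrow(t$data), 8L)
  # displacement per frame (0.6 um/px * 1 px) is far below the default limit
})

test_that("a cell leaving near the border is marked left_frame", {
  pa <- data.frame(frame = 1:6, row = 10 - (1:6), col = 48, mass = 100)
  pb <- data.frame(frame = 1:10, row = 48, col = 48, mass = 150)
  lms <- frames_from_paths(list(pa, pb), 10, shape = c(96, 96), radius = 4)
  tr <- track_cells(lms, times = (0:9) * 0.25, max_displacement = 5)
  fates <- vapply(tr, `[[`, character(1), "fate")
  lens <- vapply(tr, function(t) nrow(t$data), integer(1))
  expect_equal(sort(lens), c(6L, 10L))
  expect_equal(fates[lens == 6L], "left_frame")
  expect_equal(fates[lens == 10L], "censored_at_end")
})

test_that("division is detected and daughters linked to the parent", {
  par <- data.frame(frame = 1:5, row = 48, col = 48, mass = 200)
  d1 <- data.frame(frame = 6:10, row = 38, col = 48, mass = 100)
  d2 <- data.frame(frame = 6:10, row = 58, col = 48, mass = 100)
  lms <- frames_from_paths(list(par, d1, d2), 10, radius = 6)
  tr <- track_cells(lms, times = (0:9) * 0.25)
  expect_length(tr, 3L)
  expect_equal(tr[[1]]$fate, "divided")
  expect_equal(tr[[1]]$division_time, 5 * 0.25)
  expect_setequal(tr[[1]]$daughter_ids, c(2L, 3L))
  lin <- lineages(tr)
  expect_length(lin, 1L)
  norm <- normalize_daughter_masses(lin[[1]])
  expect_equal(norm[[1]]$normalized_mass[1], 1)
  expect_equal(norm[[2]]$normalized_mass[1], 1)
})

test_that("links implying implausible mass jumps are refused", {
  # the cell's region suddenly doubles (e.g. merged with a neighbor)
  pa <- data.frame(frame = 1:10, row = 48, col = 48,
                   mass = c(rep(100, 5), rep(210, 5)))
  lms <- frames_from_paths(list(pa), 10)
  tr <- track_cells(lms, times = (0:9) * 0.25, max_mass_jump = 0.3)
  lens <- sort(vapply(tr, function(t) nrow(t$data), integer(1)))
  expect_equal(lens, c(5L, 5L))   # track ends at the jump; a new one starts
  tr2 <- track_cells(lms, times = (0:9) * 0.25, max_mass_jump = Inf)
  expect_length(tr2, 1L)
})

test_that("specific growth rate equals slope over mean mass", {
  # linear series: slope 2 pg/h, mean mass 110 pg
  t <- seq(0, 10, by = 0.25)
  tr <- make_track(t, 100 + 2 * t)
  expect_equal(specific_growth_rate(tr), 2 / 110, tolerance = 1e-12)
  # constant mass: zero rate
  expect_equal(specific_growth_rate(make_track(t, rep(80, length(t)))), 0)
  # exponential at k = 0.02/h over 10 h: recovered within 2%
  expect_equal(specific_growth_rate(make_track(t, 120 * exp(0.02 * t))), 0.02,
               tolerance = 0.02)
  expect_error(specific_growth_rate(make_track(c(0, 1), c(1, 2))),
               "at least 3 frames")
})

test_that("cytokinesis fraction applies the observation and doubling rules", {
  divider <- make_track(seq(0, 20, 0.5), rep(100, 41), fate = "divided",
                        division_time = 20)
  watcher <- make_track(seq(0, 35, 0.5), rep(100, 71))
  early_exit <- make_track(seq(0, 25, 0.5), rep(100, 51), fate = "left_frame")
  expect_equal(cytokinesis_fraction(list(divider, watcher)), 50)
  # a cell leaving at 25 h is excluded from the denominator entirely
  expect_equal(cytokinesis_fraction(list(divider, watcher, early_exit)), 50)
  expect_equal(cytokinesis_fraction(list(divider, divider)), 100)
  # a division later than the 40 h ceiling does not count in the numerator
  slow <- make_track(seq(0, 45, 0.5), rep(100, 91), fate = "divided",
                     division_time = 45)
  expect_equal(cytokinesis_fraction(list(divider, slow)), 50)
  expect_error(cytokinesis_fraction(list(early_exit)), "undefined")
})
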