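test_that("rendered cells integrate to the requested mass", {
  oc <- optical_constants()
  canvas <- matrix(0, 96, 96)
  expect_equal(render_cell_phase(canvas, 0, c(48, 48), 8, oc), canvas)
  for (M in c(50, 180, 400)) {
    out <- render_cell_phase(canvas, M, c(47.5, 47.5), 8, oc)
    expect_equal(sum(phase_to_mass(out, oc)), M, tolerance = 1e-9)
  }
  # linearity: doubling the mass doubles the integrated phase
  a <- render_cell_phase(canvas, 100, c(47.5, 47.5), 8, oc)
  b <- render_cell_phase(canvas, 200, c(47.5, 47.5), 8, oc)
  expect_equal(b, 2 * a, tolerance = 1e-12)
  expect_error(render_cell_phase(canvas, 100, c(2, 48), 8, oc),
               "beyond the canvas")
})

test_that("the generator is reproducible and its truth table consistent", {
  p <- synth_params("fast", n_cells = 12, duration = 6, seed = 9)
  mv1 <- generate_timelapse(p)
  mv2 <- generate_timelapse(p)
  expect_identical(mv1$phase, mv2$phase)
  expect_identical(mv1$donor, mv2$donor)
  expect_identical(mv1$truth, mv2$truth)
  founders <- mv1$truth$cells[is.na(mv1$truth$cells$parent_id), ]
  expect_equal(nrow(founders), 12L)
  expect_equal(sum(founders$recipient), 1L)   # round(0.05 * 12) floored to >= 1
  expect_equal(length(mv1$phase), 25L)        # 6 h at 15-min frames
})

test_that("true masses follow the exponential law with the recipient multiplier", {
  p <- synth_params("fast", n_cells = 8, duration = 8, seed = 2)
  mv <- generate_timelapse(p)
  cells <- mv$truth$cells
  st <- mv$truth$states
  for (cid in cells$cell_id) {
    s <- st[st$cell_id == cid, ]
    if (nrow(s) < 2) next
    k_true <- cells$k[cells$cell_id == cid]
    expected <- cells$birth_mass_pg[cells$cell_id == cid] *
      exp(k_true * (s$time_h - cells$birth_time_h[cells$cell_id == cid]))
    expect_equal(s$mass_pg, expected, tolerance = 1e-12)
  }
  # recipients carry k0 * r, others k0
  expect_setequal(unique(round(cells$k / p$k0, 6)), c(1, p$r))
  expect_equal(cells$k[cells$recipient] / p$k0, rep(p$r, sum(cells$recipient)))
})

test_that("division halves mass exactly and passes punctae to one daughter", {
  p <- synth_params("fast", n_cells = 10, duration = 12, seed = 6)
  mv <- generate_timelapse(p)
  cells <- mv$truth$cells
  div <- cells[!is.na(cells$division_time_h), ]
  expect_gt(nrow(div), 0)
  for (i in seq_len(nrow(div))) {
    ds <- cells[cells$cell_id %in% c(div$daughter1[i], div$daughter2[i]), ]
    expect_equal(nrow(ds), 2L)
    expect_equal(ds$birth_mass_pg[1], ds$birth_mass_pg[2])
    expect_equal(ds$birth_time_h, rep(div$division_time_h[i], 2))
    if (div$recipient[i]) expect_equal(sum(ds$recipient), 1L)
    else expect_equal(sum(ds$recipient), 0L)
  }
})

test_that("recipient count tracks the requested fraction", {
  founders_rec <- function(frac, n) {
    p <- synth_params("fast", n_cells = n, duration = 1,
                      recipient_fraction = frac, seed = 3)
    f <- generate_timelapse(p)$truth$cells
    sum(f$recipient[is.na(f$parent_id)])
  }
  expect_equal(founders_rec(0, 10), 0L)
  expect_equal(founders_rec(0.2, 10), 2L)
  expect_equal(founders_rec(0.5, 12), 6L)
})
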