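test_that("phase-to-mass conversion matches the per-pixel summation oracle", {
  oc <- optical_constants()
  # single pixel at phi = 1 with the default constants
  expect_equal(phase_to_mass(matrix(1), oc)[1, 1], 0.623 * 0.36 / 0.185)
  # all-zero image carries no mass
  expect_equal(sum(phase_to_mass(matrix(0, 8, 8), oc)), 0)
  # random image vs brute-force double loop
  set.seed(1)
  ph <- matrix(runif(15 * 11, -0.1, 1), 15, 11)
  expect_equal(sum(phase_to_mass(ph, oc)), oracle_mass_sum(ph, oc),
               tolerance = 1e-12)
  # linearity: doubling phase doubles every pixel mass
  expect_equal(phase_to_mass(2 * ph, oc), 2 * phase_to_mass(ph, oc))
  # constants enter as lambda * A / alpha
  oc2 <- optical_constants(wavelength = 0.532, alpha = 0.2, pixel_area = 0.25)
  expect_equal(phase_to_mass(matrix(1), oc2)[1, 1], 0.532 * 0.25 / 0.2)
})

test_that("optical constants are validated and pixel size derived", {
  expect_error(optical_constants(alpha = 0), "positive")
  expect_equal(pixel_size(optical_constants(pixel_area = 0.36)), 0.6)
})

test_that("background correction removes an exact polynomial surface", {
  n <- 96
  x <- seq(-1, 1, length.out = n)
  surf <- outer(x, x, function(y, x)
    0.2 + 0.5 * x - 0.3 * y + 0.2 * x^2 * y - 0.1 * y^3 + 0.05 * x^4 * y^2)
  corr <- correct_background(surf)
  expect_lt(max(abs(corr)), 1e-6 * diff(range(surf)))
  # all-zero input stays zero
  expect_equal(correct_background(matrix(0, 40, 40)), matrix(0, 40, 40))
  # too-small image: more polynomial terms than pixels
  expect_error(correct_background(matrix(0, 5, 5)), "degenerate fit")
})

test_that("cell mass survives background correction (ground-truth check)", {
  n <- 160
  oc <- optical_constants()
  x <- seq(-1, 1, length.out = n)
  bg <- outer(x, x, function(y, x) 0.3 + 0.4 * x - 0.25 * y + 0.15 * x * y)
  truth_mass <- 200
  cellimg <- render_cell_phase(matrix(0, n, n), truth_mass, c(79.5, 79.5),
                               radius = 8, optical = oc)
  set.seed(4)
  noisy <- cellimg + bg + matrix(rnorm(n * n, 0, 0.01), n, n)
  corr <- correct_background(noisy)
  # integrate corrected phase over the true footprint
  mask <- cellimg > 0
  est <- sum(phase_to_mass(corr, oc)[mask])
  expect_equal(est, truth_mass, tolerance = 0.05)
  # background median ~ 0 after correction
  expect_lt(abs(median(corr[!mask])), 0.005)
})
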