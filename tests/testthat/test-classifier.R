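test_that("resizing preserves shape, constants, and punctae positions", {
  m <- matrix(runif(100), 10, 10)
  expect_identical(resize_to_match(m, c(10, 10)), m)
  up <- resize_to_match(matrix(3.5, 10, 10), c(20, 20))
  expect_equal(dim(up), c(20L, 20L))
  expect_equal(range(up), c(3.5, 3.5))
  expect_error(resize_to_match(m, c(0, 10)), "positive")
  # a bright spot downsampled 2x and resized back stays within 1 px
  big <- matrix(0, 64, 64); big[40:42, 20:22] <- 100
  small <- resize_to_match(big, c(32, 32))
  back <- resize_to_match(small, c(64, 64))
  pk <- which(back == max(back), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(41, 21))), 1)
})

test_that("per-cell intensity is the area-normalized integral", {
  lab <- matrix(0L, 10, 10)
  lab[2:5, 2:5] <- 1L          # 16 px
  lab[7:9, 7:9] <- 2L          # 9 px
  fl <- matrix(0, 10, 10)
  fl[2:5, 2:5] <- 7
  fl[7:9, 7:9] <- rep(c(10, 0, 10), 3)  # half-ish bright
  lm_ <- label_map(lab, matrix(0, 10, 10))
  v <- per_cell_intensity(fl, lm_)
  expect_equal(as.numeric(v["1"]), 7)
  expect_equal(as.numeric(v["2"]), mean(rep(c(10, 0, 10), 3)))
  expect_equal(as.numeric(per_cell_intensity(matrix(0, 10, 10), lm_)),
               c(0, 0))
  expect_error(per_cell_intensity(matrix(0, 5, 5), lm_), "shapes differ")
})

test_that("rolling-ball opening matches the brute-force oracle", {
  set.seed(5)
  img <- matrix(runif(26 * 24, 0, 10), 26, 24)
  img[13, 12] <- 60
  for (diam in c(4, 7)) {
    expect_equal(rolling_ball(img, diam), oracle_opening(img, diam),
                 tolerance = 1e-12)
  }
  expect_error(rolling_ball(img, 0.5), "below one pixel")
})

test_that("punctae are recovered while broad network signal is suppressed", {
  px <- 0.6
  n <- 96
  gates <- gate_params()           # 6 um ball
  # constant image: residual ~ 0
  out <- extract_punctae(matrix(50, n, n), gates, px)
  expect_equal(max(out$punctae), 0)
  # flat background + one 1.5 um disc of amplitude 100
  img <- matrix(20, n, n)
  rr <- row(img); cc <- col(img)
  disc <- (rr - 48)^2 + (cc - 48)^2 < (1.5 / px / 2)^2
  img[disc] <- 120
  out <- extract_punctae(img, gates, px)
  expect_gte(max(out$punctae[disc]), 90)
  expect_true(any(out$detected[disc]))
  # broad 20 um Gaussian blob: residual stays below 10% of its amplitude
  blob <- 20 + 100 * exp(-((rr - 48)^2 + (cc - 48)^2) / (2 * (20 / px / 2.355)^2))
  outb <- extract_punctae(blob, gates, px)
  expect_lt(max(outb$punctae), 10)
  # decomposition: the opening never exceeds the input
  expect_true(all(out$background <= img + 1e-12))
  # idempotence: re-filtering the punctae image changes it by < 1%
  again <- extract_punctae(out$punctae, gates, px)
  expect_lt(max(abs(again$punctae - out$punctae)), 0.01 * max(out$punctae))
})

test_that("intensity gates classify cancer, macrophage, and recipient cells", {
  bgs <- c(recipient_marker = 100, donor_mito = 100)
  res <- classify_population(
    recipient_intensity = c(140, 160, 90, 160, 160),
    donor_intensity = c(30, 30, 250, 30, 250),
    punctae_present = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    backgrounds = bgs)
  # 140 < 1.5 x 100: fails the cancer gate
  expect_equal(res$class, c("other", "recipient_cancer", "macrophage",
                            "cancer", "other"))
  # the last cell passes both whole-cell gates -> excluded as a fusion
  expect_error(classify_population(1, 1, TRUE, c(recipient_marker = 0,
                                                 donor_mito = 1)),
               "positive")
})

test_that("raising intensities never demotes a cell (gate monotonicity)", {
  bgs <- c(recipient_marker = 100, donor_mito = 50)
  set.seed(8)
  for (i in 1:40) {
    rec <- runif(1, 50, 400)
    don <- runif(1, 10, 60)       # below the macrophage gate
    pun <- runif(1) < 0.5
    c0 <- classify_population(rec, don, pun, bgs)$class
    c1 <- classify_population(rec * runif(1, 1, 3), don, pun, bgs)$class
    if (c0 %in% c("cancer", "recipient_cancer"))
      expect_true(c1 %in% c("cancer", "recipient_cancer"))
    # punctae turning on can only promote cancer -> recipient
    c2 <- classify_population(rec, don, TRUE, bgs)$class
    if (c0 == "recipient_cancer") expect_equal(c2, "recipient_cancer")
  }
})
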