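# Independent brute-force oracles used across tests.

# per-pixel dry-mass summation oracle (double loop, no vectorization)
oracle_mass_sum <- function(phase, oc, mask = NULL) {
  total <- 0
  for (i in seq_len(nrow(phase)))
    for (j in seq_len(ncol(phase)))
      if (is.null(mask) || mask[i, j])
        total <- total + phase[i, j] * oc$wavelength * oc$pixel_area / oc$alpha
  total
}

# brute-force grayscale opening with a disc (min filter then max filter)
oracle_opening <- function(img, diameter_px) {
  sz <- 2L * floor(diameter_px / 2) + 1L
  if (sz < 3L) sz <- 3L
  r <- (sz - 1L) / 2L
  offs <- expand.grid(di = -r:r, dj = -r:r)
  # EBImage's disc brush of size sz: offsets with distance <= r (matches
  # makeBrush for odd sizes)
  br <- EBImage::imageData(EBImage::makeBrush(sz, "disc")) > 0
  keep <- mapply(function(di, dj) br[di + r + 1L, dj + r + 1L],
                 offs$di, offs$dj)
  offs <- offs[keep, ]
  # replicate-edge boundary handling, same convention as the implementation
  filt <- function(m, fun) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
      for (j in seq_len(ncol(m))) {
        vals <- numeric(0)
        for (k in seq_len(nrow(offs))) {
          ii <- min(max(i + offs$di[k], 1L), nrow(m))
          jj <- min(max(j + offs$dj[k], 1L), ncol(m))
          vals <- c(vals, m[ii, jj])
        }
        out[i, j] <- fun(vals)
      }
    out
  }
  filt(filt(img, min), max)
}

# build a one-frame label map from circles: centers (row, col, 0-based), radius px
make_disc_labels <- function(shape, centers, radius, masses) {
  lab <- matrix(0L, shape[1], shape[2])
  mass <- matrix(0, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(shape[1]))
      for (j in seq_len(shape[2])) {
        if ((i - 1 - centers[k, 1])^2 + (j - 1 - centers[k, 2])^2 < radius^2) {
          lab[i, j] <- k
        }
      }
  }
  for (k in seq_len(nrow(centers))) {
    npx <- sum(lab == k)
    mass[lab == k] <- masses[k] / npx
  }
  label_map(lab, mass)
}

# minimal hand-built track object (enough for growth/cytokinesis functions)
make_track <- function(times, masses, fate = "censored_at_end",
                       division_time = NA_real_, track_id = 1L) {
  structure(list(track_id = track_id, parent_id = NA_integer_,
                 daughter_ids = integer(), fate = fate,
                 division_time = division_time,
                 data = data.frame(frame = seq_along(times), time_h = times,
                                   label = 1L, row_px = 0, col_px = 0,
                                   mass_pg = masses)),
            class = "cell_track")
}
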