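#' Parameters for the synthetic QPI movie generator
#'
#' Describes a synthetic co-culture time lapse with exact ground truth:
#' exponentially growing cells imaged as smooth phase profiles on a low-order
#' polynomial background with additive Gaussian noise, a recipient
#' subpopulation growing `r` times faster and carrying small donor-channel
#' punctae that pass to exactly one daughter at division, plus a uniform
#' recipient-marker channel over every cell footprint.
#'
#' The `"paper"` preset mirrors the study's imaging regime: ~40 h doubling
#' time, frames every 15 min for 48 h, 5% recipients growing 15% faster. The
#' `"fast"` preset is a scaled-down variant for quick checks.
#'
#' @param preset `"paper"` or `"fast"`, setting defaults below.
#' @param n_cells Number of founder cells.
#' @param doubling_time Baseline mass doubling time (h); `k0 =
#'   log(2)/doubling_time`.
#' @param r Growth multiplier of recipient cells.
#' @param recipient_fraction Fraction of founders that are recipients. The
#'   realized count is `round(recipient_fraction * n_cells)` (at least 1 when
#'   the fraction is positive) so that small fields still contain both
#'   classes.
#' @param frame_interval Time between frames (h).
#' @param duration Movie duration (h).
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param optical An [optical_constants()] object.
#' @param m0 Birth mass (pg) of a founder; founders start at a random point
#'   of their mass cycle in `[m0, 2 m0)`.
#' @param cell_radius Cell footprint radius (micrometers).
#' @param background_poly Data frame with columns `i`, `j`, `coef`: the phase
#'   background surface `sum coef * x^i * y^j` on coordinates normalized to
#'   `[-1, 1]` (total degree at most 6). `NULL` for no background.
#' @param noise_sigma Additive Gaussian phase noise sd; `NULL` for 2% of the
#'   peak phase of a cell of mass `1.5 * m0`.
#' @param punctae_per_recipient Number of donor punctae per recipient cell.
#' @param punctae_diameter Punctae diameter (micrometers).
#' @param rfp_background,rfp_level Recipient-marker channel background and
#'   in-cell intensity (a.u.).
#' @param donor_background,punctae_amplitude Donor channel background and
#'   punctae peak amplitude above background (a.u.).
#' @param fluor_noise_frac Gaussian noise sd on both fluorescence channels,
#'   as a fraction of the channel background.
#' @param motility_sigma Random-walk step sd of cell centroids
#'   (micrometers/frame).
#' @param seed RNG seed.
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(preset = c("paper", "fast"),
                         n_cells = NULL, doubling_time = 40, r = 1.15,
                         recipient_fraction = 0.05,
                         frame_interval = 0.25, duration = NULL,
                         image_shape = NULL,
                         optical = optical_constants(),
                         m0 = 150, cell_radius = 8,
                         background_poly = default_background_poly(),
                         noise_sigma = NULL,
                         punctae_per_recipient = 2L, punctae_diameter = 1.5,
                         rfp_background = 100, rfp_level = 300,
                         donor_background = 20, punctae_amplitude = 200,
                         fluor_noise_frac = 0.05,
                         motility_sigma = 0.3, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n_cells)) n_cells <- if (preset == "paper") 30L else 6L
  if (is.null(duration)) duration <- if (preset == "paper") 48 else 10
  if (is.null(image_shape))
    image_shape <- if (preset == "paper") c(384L, 384L) else c(192L, 192L)
  if (recipient_fraction < 0 || recipient_fraction > 1)
    stop("'recipient_fraction' must lie in [0, 1]", call. = FALSE)
  if (frame_interval <= 0) stop("'frame_interval' must be positive", call. = FALSE)
  if (duration < frame_interval) stop("'duration' must cover at least one frame interval", call. = FALSE)
  if (m0 <= 0 || cell_radius <= 0) stop("'m0' and 'cell_radius' must be positive", call. = FALSE)
  if (punctae_diameter <= 0) stop("'punctae_diameter' must be positive", call. = FALSE)
  structure(list(preset = preset, n_cells = as.integer(n_cells),
                 doubling_time = doubling_time, k0 = log(2) / doubling_time,
                 r = r, recipient_fraction = recipient_fraction,
                 frame_interval = frame_interval, duration = duration,
                 image_shape = as.integer(image_shape), optical = optical,
                 m0 = m0, cell_radius = cell_radius,
                 background_poly = background_poly, noise_sigma = noise_sigma,
                 punctae_per_recipient = as.integer(punctae_per_recipient),
                 punctae_diameter = punctae_diameter,
                 rfp_background = rfp_background, rfp_level = rfp_level,
                 donor_background = donor_background,
                 punctae_amplitude = punctae_amplitude,
                 fluor_noise_frac = fluor_noise_frac,
                 motility_sigma = motility_sigma, seed = as.integer(seed)),
            class = "synth_params")
}

#' Default synthetic phase background surface
#'
#' A fixed smooth polynomial surface (total degree 3) of amplitude comparable
#' to the cell signal, used to exercise the background correction.
#'
#' @return Data frame with columns `i`, `j`, `coef`.
#' @export
default_background_poly <- function() {
  data.frame(i = c(0, 1, 0, 2, 1, 0, 3, 0),
             j = c(0, 0, 1, 0, 1, 2, 0, 3),
             coef = c(0.10, 0.15, -0.10, 0.08, 0.05, -0.06, 0.04, 0.03))
}

# Evaluate a background polynomial (i, j, coef rows) on an image grid.
render_background <- function(background_poly, shape) {
  if (is.null(background_poly)) return(matrix(0, shape[1L], shape[2L]))
  x <- if (shape[2L] > 1) 2 * (seq_len(shape[2L]) - 1) / (shape[2L] - 1) - 1 else 0
  y <- if (shape[1L] > 1) 2 * (seq_len(shape[1L]) - 1) / (shape[1L] - 1) - 1 else 0
  out <- matrix(0, shape[1L], shape[2L])
  for (k in seq_len(nrow(background_poly)))
    out <- out + background_poly$coef[k] *
      outer(y^background_poly$j[k], x^background_poly$i[k])
  out
}

#' Render one cell's phase profile onto a canvas
#'
#' Adds a smooth truncated-Gaussian phase footprint centered at `centroid`
#' whose integrated dry mass (via the phase-to-mass conversion) equals the
#' requested mass up to floating-point error.
#'
#' @param canvas Numeric matrix to add onto.
#' @param mass Dry mass to deposit (pg); 0 leaves the canvas unchanged.
#' @param centroid Numeric `c(row, col)`, 0-based pixel coordinates.
#' @param radius Cell footprint radius (micrometers); the Gaussian sd is
#'   `radius/2.5` and the profile is truncated (continuously) at `radius`.
#' @param optical An [optical_constants()] object.
#' @return The canvas with the cell's phase added.
#' @export
render_cell_phase <- function(canvas, mass, centroid, radius,
                              optical = optical_constants()) {
  stopifnot(is.matrix(canvas), length(centroid) == 2L)
  if (mass < 0) stop("'mass' must be non-negative", call. = FALSE)
  if (mass == 0) return(canvas)
  r_px <- radius / pixel_size(optical)
  r0 <- centroid[1L]; c0 <- centroid[2L]
  lo_r <- floor(r0 - r_px); hi_r <- ceiling(r0 + r_px)
  lo_c <- floor(c0 - r_px); hi_c <- ceiling(c0 + r_px)
  if (lo_r < 0 || lo_c < 0 || hi_r > nrow(canvas) - 1 || hi_c > ncol(canvas) - 1)
    stop("cell footprint extends beyond the canvas", call. = FALSE)
  rows <- (lo_r:hi_r) + 1L; cols <- (lo_c:hi_c) + 1L
  sig <- r_px / 2.5
  d2 <- outer(((lo_r:hi_r) - r0)^2, ((lo_c:hi_c) - c0)^2, `+`)
  prof <- exp(-d2 / (2 * sig^2)) - exp(-r_px^2 / (2 * sig^2))
  prof[d2 >= r_px^2] <- 0
  phase_total <- mass * optical$alpha / (optical$wavelength * optical$pixel_area)
  canvas[rows, cols] <- canvas[rows, cols] + prof * (phase_total / sum(prof))
  canvas
}

# footprint mask (logical) of a cell, used for the recipient-marker channel
cell_footprint <- function(shape, centroid, r_px) {
  lo_r <- max(0L, floor(centroid[1L] - r_px)); hi_r <- min(shape[1L] - 1L, ceiling(centroid[1L] + r_px))
  lo_c <- max(0L, floor(centroid[2L] - r_px)); hi_c <- min(shape[2L] - 1L, ceiling(centroid[2L] + r_px))
  d2 <- outer(((lo_r:hi_r) - centroid[1L])^2, ((lo_c:hi_c) - centroid[2L])^2, `+`)
  list(rows = (lo_r:hi_r) + 1L, cols = (lo_c:hi_c) + 1L, inside = d2 < r_px^2)
}

#' Generate a ground-truthed synthetic QPI time lapse
#'
#' Simulates founder cells placed on a jittered grid, growing exponentially
#' (`m(t) = m_birth * exp(k t)` exactly between divisions, `k = k0` for
#' non-recipients and `k0 * r` for recipients), moving by a Gaussian random
#' walk, and dividing into two half-mass daughters once mass reaches twice
#' the birth mass; donor punctae (and the growth advantage) pass to exactly
#' one daughter. Renders, per frame, the phase channel (cells + polynomial
#' background + noise), the recipient-marker channel (uniform level over
#' every cell footprint), and the donor-mitochondria channel (punctae on a
#' flat background). Fully reproducible for a fixed seed.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `"synth_movie"` with elements `phase`, `rfp`,
#'   `donor` (lists of matrices, one per frame), `times` (h), `truth` (list
#'   of data frames `cells` and `states`; see Details), and `params`.
#'
#' @details `truth$cells` has one row per cell: `cell_id`, `parent_id`,
#'   `recipient` (carries punctae), `k` (1/h), `birth_time_h`,
#'   `birth_mass_pg`, `division_time_h`, `daughter1`, `daughter2`.
#'   `truth$states` has one row per cell per frame in which it is alive:
#'   `cell_id`, `frame`, `time_h`, `mass_pg`, `row_px`, `col_px` (0-based).
#' @export
generate_timelapse <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  shp <- params$image_shape
  pxs <- pixel_size(params$optical)
  r_px <- params$cell_radius / pxs
  margin <- r_px + 2
  n_frames <- floor(params$duration / params$frame_interval) + 1L
  times <- (seq_len(n_frames) - 1L) * params$frame_interval

  # jittered-grid founder placement
  n <- params$n_cells
  n_side <- ceiling(sqrt(n))
  spacing_r <- (shp[1L] - 2 * margin) / n_side
  spacing_c <- (shp[2L] - 2 * margin) / n_side
  if (min(spacing_r, spacing_c) < 2.2 * r_px)
    stop("overcrowded canvas: too many cells for the image size", call. = FALSE)
  sites <- expand.grid(gr = seq_len(n_side), gc = seq_len(n_side))
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  jit <- 0.1 * min(spacing_r, spacing_c)
  pos_r <- margin + (sites$gr - 0.5) * spacing_r + runif(n, -jit, jit)
  pos_c <- margin + (sites$gc - 0.5) * spacing_c + runif(n, -jit, jit)

  n_rec <- if (params$recipient_fraction > 0)
    max(1L, as.integer(round(params$recipient_fraction * n))) else 0L
  recipient <- logical(n)
  recipient[sample.int(n, n_rec)] <- TRUE

  cells <- data.frame(
    cell_id = seq_len(n), parent_id = NA_integer_, recipient = recipient,
    k = ifelse(recipient, params$k0 * params$r, params$k0),
    birth_time_h = NA_real_, birth_mass_pg = params$m0,
    division_time_h = NA_real_, daughter1 = NA_integer_, daughter2 = NA_integer_)
  # founders start mid-cycle: mass in [m0, 2 m0); equivalent birth time < 0
  start_mass <- params$m0 * 2^runif(n)
  cells$birth_time_h <- -log(start_mass / params$m0) / cells$k

  # live state
  live <- data.frame(cell_id = seq_len(n), row = pos_r, col = pos_c)
  punctae_offsets <- vector("list", n)   # row/col offsets (px) per carrier
  for (i in which(recipient)) {
    ang <- runif(params$punctae_per_recipient, 0, 2 * pi)
    rad <- runif(params$punctae_per_recipient, 0, 0.5 * r_px)
    punctae_offsets[[i]] <- cbind(rad * cos(ang), rad * sin(ang))
  }

  noise_sigma <- params$noise_sigma
  if (is.null(noise_sigma)) {
    probe <- render_cell_phase(matrix(0, shp[1L], shp[2L]), 1.5 * params$m0,
                               c(shp[1L] / 2, shp[2L] / 2), params$cell_radius,
                               params$optical)
    noise_sigma <- 0.02 * max(probe)
  }
  bg_surface <- render_background(params$background_poly, shp)
  p_px <- params$punctae_diameter / pxs / 2   # punctae radius, px
  step_px <- params$motility_sigma / pxs

  phase_stack <- rfp_stack <- donor_stack <- vector("list", n_frames)
  states <- vector("list", n_frames)

  for (f in seq_len(n_frames)) {
    t <- times[f]
    if (f > 1L && step_px > 0) {
      live$row <- pmin(pmax(live$row + rnorm(nrow(live), 0, step_px), margin), shp[1L] - 1 - margin)
      live$col <- pmin(pmax(live$col + rnorm(nrow(live), 0, step_px), margin), shp[2L] - 1 - margin)
    }
    # division check (before rendering, so daughters appear at this frame)
    mass_now <- cells$birth_mass_pg[live$cell_id] *
      exp(cells$k[live$cell_id] * (t - cells$birth_time_h[live$cell_id]))
    divided <- integer()
    for (li in which(mass_now >= 2 * cells$birth_mass_pg[live$cell_id])) {
      cid <- live$cell_id[li]
      m_div <- mass_now[li]
      cells$division_time_h[cid] <- t
      ang <- runif(1, 0, 2 * pi)
      off <- 1.2 * r_px
      d_ids <- nrow(cells) + 1:2
      inherit_first <- runif(1) < 0.5
      for (d in 1:2) {
        drow <- min(max(live$row[li] + (if (d == 1) off else -off) * sin(ang), margin), shp[1L] - 1 - margin)
        dcol <- min(max(live$col[li] + (if (d == 1) off else -off) * cos(ang), margin), shp[2L] - 1 - margin)
        inherits_punctae <- cells$recipient[cid] && (d == 1) == inherit_first
        cells <- rbind(cells, data.frame(
          cell_id = d_ids[d], parent_id = cid, recipient = inherits_punctae,
          k = if (inherits_punctae) params$k0 * params$r else params$k0,
          birth_time_h = t, birth_mass_pg = m_div / 2,
          division_time_h = NA_real_, daughter1 = NA_integer_, daughter2 = NA_integer_))
        live <- rbind(live, data.frame(cell_id = d_ids[d], row = drow, col = dcol))
        if (inherits_punctae) {
          punctae_offsets[[d_ids[d]]] <- punctae_offsets[[cid]]
        } else punctae_offsets[d_ids[d]] <- list(NULL)
      }
      cells$daughter1[cid] <- d_ids[1L]; cells$daughter2[cid] <- d_ids[2L]
      divided <- c(divided, cid)
    }
    if (length(divided))
      live <- live[!(live$cell_id %in% divided), , drop = FALSE]
    mass_now <- cells$birth_mass_pg[live$cell_id] *
      exp(cells$k[live$cell_id] * (t - cells$birth_time_h[live$cell_id]))

    phase <- matrix(0, shp[1L], shp[2L])
    rfp <- matrix(params$rfp_background, shp[1L], shp[2L])
    donor <- matrix(params$donor_background, shp[1L], shp[2L])
    for (li in seq_len(nrow(live))) {
      cen <- c(live$row[li], live$col[li])
      phase <- render_cell_phase(phase, mass_now[li], cen, params$cell_radius,
                                 params$optical)
      fp <- cell_footprint(shp, cen, r_px)
      rfp[fp$rows, fp$cols][fp$inside] <- params$rfp_level
      po <- punctae_offsets[[live$cell_id[li]]]
      if (!is.null(po)) {
        for (pk in seq_len(nrow(po))) {
          pp <- cell_footprint(shp, cen + po[pk, ], p_px)
          donor[pp$rows, pp$cols][pp$inside] <-
            params$donor_background + params$punctae_amplitude
        }
      }
    }
    phase <- phase + bg_surface
    if (noise_sigma > 0)
      phase <- phase + matrix(rnorm(length(phase), 0, noise_sigma), shp[1L], shp[2L])
    fns <- params$fluor_noise_frac
    if (fns > 0) {
      rfp <- rfp + matrix(rnorm(length(rfp), 0, fns * params$rfp_background), shp[1L], shp[2L])
      donor <- donor + matrix(rnorm(length(donor), 0, fns * params$donor_background), shp[1L], shp[2L])
    }
    phase_stack[[f]] <- frame_image(phase, t)
    rfp_stack[[f]] <- frame_image(pmax(rfp, 0), t)
    donor_stack[[f]] <- frame_image(pmax(donor, 0), t)
    states[[f]] <- data.frame(cell_id = live$cell_id, frame = f, time_h = t,
                              mass_pg = mass_now, row_px = live$row,
                              col_px = live$col)
  }

  structure(list(phase = phase_stack, rfp = rfp_stack, donor = donor_stack,
                 times = times,
                 truth = list(cells = cells, states = do.call(rbind, states)),
                 params = params),
            class = "synth_movie")
}

#' @export
print.synth_movie <- function(x, ...) {
  cat(sprintf("<synth_movie> %d frames (%g h at %g h), %dx%d px, %d cells (%d recipients)\n",
              length(x$phase), x$params$duration, x$params$frame_interval,
              x$params$image_shape[1L], x$params$image_shape[2L],
              nrow(x$truth$cells), sum(x$truth$cells$recipient)))
  invisible(x)
}
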