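#' Write an image stack as a multi-frame TIFF
#'
#' Stores a list of numeric matrices as one multi-frame 32-bit TIFF. Since
#' TIFF integer samples span `[0, 1]`, each stack is affinely rescaled to
#' that range and the offset/gain are recorded in a JSON sidecar file
#' (`<path>.json`), so [read_stack()] restores the original values
#' (round-trip exact to about `range * 2^-32`).
#'
#' @param frames List of numeric matrices (or a single matrix), all the same
#'   shape.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop("no frames to write", call. = FALSE)
  shp <- dim(frames[[1L]])
  for (f in frames)
    if (!is.matrix(f) || !all(dim(f) == shp))
      stop("all frames must be numeric matrices of identical shape", call. = FALSE)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  gain <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(f) {
    m <- (f - lo) / gain
    attributes(m) <- list(dim = dim(m))
    m
  })
  ok <- tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  if (!all(ok > 0)) stop(sprintf("failed to write TIFF '%s'", path), call. = FALSE)
  jsonlite::write_json(list(offset = lo, gain = gain),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF stack
#'
#' Reads an image stack written by [write_stack()] (or any grayscale TIFF),
#' undoing the offset/gain rescaling recorded in the `<path>.json` sidecar
#' when present, and attaches frame times.
#'
#' @param path TIFF file path.
#' @param frame_interval Time between frames (h), used to assign frame times
#'   `0, dt, 2 dt, ...`; `NULL` leaves times `NA`.
#' @return List of numeric matrices with attribute `"frame_time"`.
#' @export
read_stack <- function(path, frame_interval = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read image stack: no such file '%s'", path), call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(meta) && !all(c("offset", "gain") %in% names(meta)))
      meta <- NULL
  }
  out <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (length(dim(f)) == 3L && dim(f)[3L] == 1L) f <- f[, , 1L]
    if (length(dim(f)) != 2L)
      stop(sprintf("frame %d of '%s' is not a single-channel 2-D image", i, path),
           call. = FALSE)
    vals <- matrix(as.numeric(f), nrow(f), ncol(f))
    if (!is.null(meta)) vals <- vals * meta$gain + meta$offset
    t_i <- if (is.null(frame_interval)) NA_real_ else (i - 1L) * frame_interval
    frame_image(vals, t_i)
  })
  out
}

# full-precision numeric formatting so CSV round-trips are lossless
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write cell tracks (and classes) to CSV
#'
#' One row per (track, frame) with position, mass, fate and -- when a
#' classification table is supplied -- the cell class and punctae flag.
#' Numeric fields are written with 17 significant digits so that reading the
#' file back reproduces them exactly.
#'
#' @param tracks A `"cell_tracks"` object.
#' @param path Output CSV path.
#' @param classes Optional data frame keyed by `id` (track id), as returned
#'   by [classify_population()].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, classes = NULL) {
  df <- if (length(tracks)) as.data.frame(tracks) else
    data.frame(track_id = integer(), frame = integer(), time_h = numeric(),
               label = integer(), row_px = numeric(), col_px = numeric(),
               mass_pg = numeric(), fate = character(),
               parent_id = integer(), division_time = numeric())
  if (!is.null(classes)) {
    i <- match(df$track_id, classes$id)
    df$class <- classes$class[i]
    df$punctae_present <- classes$punctae_present[i]
  }
  out <- df
  for (cn in c("time_h", "row_px", "col_px", "mass_pg", "division_time"))
    if (cn %in% names(out)) out[[cn]] <- fmt_num(df[[cn]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}

#' Read a tracks CSV written by [write_tracks()]
#'
#' @param path CSV path.
#' @return Data frame, numeric columns restored at full precision.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read tracks: no such file '%s'", path), call. = FALSE)
  read.csv(path, na.strings = "")
}

# --- configuration -----------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter: the optical constants, frame
#' interval, segmentation / tracking / gating blocks, the agent-based-model
#' block, and the synthetic-movie preset. Defaults follow the study system:
#' 0.623 um light, alpha 0.185 um^3/pg, 0.36 um^2 pixels, 15-min frames, 40 h
#' doubling time, 1.5x/2x fluorescence gates, 6 um rolling ball, transfer
#' fraction 5% and growth multiplier 1.15.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    frame_interval = 0.25,
    optical = list(wavelength = 0.623, alpha = 0.185, pixel_area = 0.36),
    segmentation = list(min_area = 200L, closing_radius = 3L, dilate_radius = 2L),
    tracking = list(max_displacement = 20, division_mass_tol = 0.2,
                    max_mass_jump = 0.3),
    gates = list(rfp_factor = 1.5, donor_factor = 2.0, ball_diameter = 6.0,
                 punctae_min_intensity = 5),
    growth = list(min_track_frames = 32L),
    abm = list(n0 = 1000L, m0 = 250, f = 0.05, r = 1.15, Td = 40,
               dt_frac = 0.01, d_target = 20),
    synth = list(preset = "paper")
  )
}

validate_range <- function(cfg) {
  chk <- function(cond, key, msg)
    if (!cond) stop(sprintf("config key '%s' %s", key, msg), call. = FALSE)
  chk(cfg$frame_interval > 0, "frame_interval", "must be positive")
  with(cfg$optical, {
    chk(wavelength > 0, "optical.wavelength", "must be positive")
    chk(alpha > 0, "optical.alpha", "must be positive")
    chk(pixel_area > 0, "optical.pixel_area", "must be positive")
  })
  chk(cfg$segmentation$min_area >= 0, "segmentation.min_area", "must be non-negative")
  chk(cfg$tracking$max_displacement > 0, "tracking.max_displacement", "must be positive")
  chk(cfg$gates$rfp_factor > 1, "gates.rfp_factor", "must exceed 1")
  chk(cfg$gates$donor_factor > 1, "gates.donor_factor", "must exceed 1")
  chk(cfg$gates$ball_diameter > 0, "gates.ball_diameter", "must be positive")
  chk(cfg$abm$f >= 0 && cfg$abm$f <= 1, "abm.f", "must lie in [0, 1]")
  chk(cfg$abm$r >= 1, "abm.r", "must be >= 1")
  chk(cfg$abm$Td > 0, "abm.Td", "must be positive")
  chk(cfg$abm$dt_frac > 0 && cfg$abm$dt_frac <= 0.05, "abm.dt_frac",
      "must lie in (0, 0.05]")
  invisible(cfg)
}

merge_config <- function(defaults, user, prefix = "") {
  if (!is.list(user))
    stop(sprintf("config block '%s' must be an object", prefix), call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(prefix, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load a JSON pipeline configuration
#'
#' Reads a JSON file of overrides, fills every absent key from
#' [default_config()], rejects unknown keys, and validates ranges.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$gates$rfp_factor  # 1.5
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("cannot read config: no such file '%s'", path), call. = FALSE)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  cfg$seed <- as.integer(cfg$seed)
  validate_range(cfg)
  cfg
}

#' Save a configuration to JSON
#'
#' @param config Configuration list (as from [load_config()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
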