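#' Intensity-gating parameters for cell classification
#'
#' Thresholds used to classify segmented cells from the two fluorescence
#' channels: cells whose recipient-marker (RFP-like) intensity is at least
#' `rfp_factor` times the channel background are cancer cells; cells whose
#' whole-cell donor-mitochondria (mEmerald-like) intensity is at least
#' `donor_factor` times background are macrophages; cancer cells carrying
#' detected donor punctae are recipients.
#'
#' @param rfp_factor Recipient-marker gate, as a multiple of channel
#'   background (> 1).
#' @param donor_factor Donor-channel whole-cell gate, as a multiple of
#'   channel background (> 1).
#' @param ball_diameter Rolling-ball diameter (micrometers) for punctae /
#'   network separation; sensible range about 4.8-9 (just above the size of
#'   mitochondrial punctae).
#' @param punctae_min_intensity Punctae detection threshold, in multiples of
#'   the residual standard deviation after background removal.
#' @return An object of class `"gate_params"`.
#' @export
gate_params <- function(rfp_factor = 1.5, donor_factor = 2.0,
                        ball_diameter = 6.0, punctae_min_intensity = 5) {
  if (rfp_factor <= 1 || donor_factor <= 1)
    stop("gate factors must exceed 1", call. = FALSE)
  if (ball_diameter <= 0) stop("'ball_diameter' must be positive", call. = FALSE)
  if (punctae_min_intensity <= 0)
    stop("'punctae_min_intensity' must be positive", call. = FALSE)
  structure(list(rfp_factor = rfp_factor, donor_factor = donor_factor,
                 ball_diameter = ball_diameter,
                 punctae_min_intensity = punctae_min_intensity),
            class = "gate_params")
}

#' Resize a fluorescence image to match another grid
#'
#' Bilinear resampling of a fluorescence frame onto a target grid shape
#' (typically the QPI grid). Constant images are preserved exactly.
#'
#' @param fluor Numeric matrix of fluorescence intensities.
#' @param target_shape Integer vector `c(rows, cols)`.
#' @return Resampled numeric matrix of shape `target_shape`.
#' @export
resize_to_match <- function(fluor, target_shape) {
  stopifnot(is.matrix(fluor), is.numeric(fluor))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2L || any(target_shape < 1L))
    stop("'target_shape' must be two positive integers", call. = FALSE)
  if (all(dim(fluor) == target_shape)) return(fluor)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(fluor),
                                            w = target_shape[1L],
                                            h = target_shape[2L]))
  matrix(out, target_shape[1L], target_shape[2L])
}

#' Area-normalized per-cell fluorescence intensity
#'
#' For each labeled region, the integrated fluorescence intensity divided by
#' the region area (mean intensity per pixel).
#'
#' @param fluor Numeric matrix of fluorescence intensities.
#' @param labels A [label_map()] object (or integer label matrix) of the same
#'   shape.
#' @return Named numeric vector of normalized intensities, one per region
#'   label.
#' @export
per_cell_intensity <- function(fluor, labels) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (!all(dim(fluor) == dim(lab)))
    stop("fluorescence image and label map shapes differ", call. = FALSE)
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(setNames(numeric(0), character(0)))
  px <- which(lab > 0L)
  sums <- tapply(fluor[px], lab[px], sum)
  areas <- tapply(rep(1L, length(px)), lab[px], sum)
  setNames(as.numeric(sums / areas), names(sums))
}

#' Background level of a fluorescence channel
#'
#' Median intensity over non-cell pixels (label-map background), robust to
#' bright punctae.
#'
#' @inheritParams per_cell_intensity
#' @return Scalar background level.
#' @export
channel_background <- function(fluor, labels) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (!all(dim(fluor) == dim(lab)))
    stop("fluorescence image and label map shapes differ", call. = FALSE)
  median(fluor[lab == 0L])
}

#' Grayscale opening with a disc (rolling-ball background)
#'
#' Morphological grayscale opening (erosion then dilation) with a flat disc
#' structuring element of the given diameter. The opening removes bright
#' features smaller than the disc while following the larger-scale intensity
#' landscape, and never exceeds the input anywhere.
#'
#' @param img Numeric matrix.
#' @param diameter_px Disc diameter in pixels (>= 1).
#' @return Numeric matrix, the opened (background) image.
#' @export
rolling_ball <- function(img, diameter_px) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (diameter_px < 1) stop("rolling-ball diameter is below one pixel", call. = FALSE)
  sz <- 2L * floor(diameter_px / 2) + 1L   # odd brush size >= diameter
  if (sz < 3L) sz <- 3L
  r <- (sz - 1L) %/% 2L
  # EBImage grayscale morphology operates on [0, 1] intensities and pads with
  # zeros; opening is invariant under increasing affine maps, so rescale, and
  # replicate the borders per operation so padding cannot bite into the image
  lo <- min(img); hi <- max(img)
  gain <- if (hi > lo) hi - lo else 1
  brush <- EBImage::makeBrush(sz, "disc")
  with_pad <- function(m, op) {
    ri <- pmin(pmax(seq_len(nrow(m) + 2L * r) - r, 1L), nrow(m))
    ci <- pmin(pmax(seq_len(ncol(m) + 2L * r) - r, 1L), ncol(m))
    out <- EBImage::imageData(op(EBImage::Image(m[ri, ci, drop = FALSE]), brush))
    out[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
  }
  core <- with_pad(with_pad((img - lo) / gain, EBImage::erode), EBImage::dilate)
  matrix(core * gain + lo, nrow(img), ncol(img))
}

#' Separate mitochondrial punctae from bulk network fluorescence
#'
#' Estimates the low-spatial-frequency component of a donor-mitochondria
#' fluorescence image by a rolling-ball (grayscale opening) filter whose ball
#' is just larger than typical punctae, and returns the residual punctae
#' image together with a detection mask. Punctae are detected where the
#' residual exceeds `punctae_min_intensity` times the residual standard
#' deviation.
#'
#' @param fluor Numeric matrix of donor-channel fluorescence.
#' @param gates A [gate_params()] object (ball diameter in micrometers).
#' @param px_size Pixel edge length (micrometers).
#' @return A list with `punctae` (residual image, clipped at 0),
#'   `background` (the opening), `detected` (logical mask), and
#'   `sigma_residual`.
#' @details The opening of a noisy image sits systematically below its local
#'   mean (it tracks local minima), so the residual carries a positive
#'   offset under noise. Detection therefore thresholds the residual
#'   relative to its own median, with a robust (MAD) spread estimate that
#'   the sparse bright punctae cannot inflate.
#' @export
extract_punctae <- function(fluor, gates = gate_params(), px_size = 0.6) {
  diameter_px <- gates$ball_diameter / px_size
  if (diameter_px < 1)
    stop("rolling ball smaller than one pixel; increase ball_diameter", call. = FALSE)
  bg <- rolling_ball(fluor, diameter_px)
  punctae <- pmax(fluor - bg, 0)
  sigma <- mad(punctae)
  detected <- (punctae - median(punctae)) > gates$punctae_min_intensity * sigma &
    punctae > 0
  list(punctae = punctae, background = bg, detected = detected,
       sigma_residual = sigma)
}

#' Classify cells from gated fluorescence intensities
#'
#' Applies the intensity gates: a cell is a cancer cell if its
#' recipient-marker intensity is at least `rfp_factor` times the channel
#' background; a macrophage if its whole-cell donor intensity is at least
#' `donor_factor` times background; a recipient cancer cell if it passes the
#' cancer gate, is not a macrophage, and carries detected donor punctae. A
#' cell passing both whole-cell gates is treated as a cancer/macrophage
#' fusion and excluded (class `"other"`).
#'
#' @param recipient_intensity Numeric vector of per-cell area-normalized
#'   recipient-marker intensities.
#' @param donor_intensity Numeric vector of per-cell area-normalized donor
#'   channel intensities.
#' @param punctae_present Logical vector: detected donor punctae per cell.
#' @param backgrounds Named list or vector with positive elements
#'   `recipient_marker` and `donor_mito`: channel background levels.
#' @param gates A [gate_params()] object.
#' @param ids Optional identifiers (labels or track ids) for the result.
#' @return A data frame with columns `id`, `class` (one of `"cancer"`,
#'   `"macrophage"`, `"recipient_cancer"`, `"other"`),
#'   `recipient_intensity`, `donor_intensity`, `punctae_present`.
#' @export
#' @examples
#' classify_population(c(140, 160, 90), c(30, 30, 260), c(FALSE, TRUE, FALSE),
#'                     backgrounds = c(recipient_marker = 100, donor_mito = 100))
classify_population <- function(recipient_intensity, donor_intensity,
                                punctae_present,
                                backgrounds, gates = gate_params(),
                                ids = seq_along(recipient_intensity)) {
  n <- length(recipient_intensity)
  if (length(donor_intensity) != n || length(punctae_present) != n)
    stop("per-cell intensity and punctae vectors must have equal length", call. = FALSE)
  bg_r <- backgrounds[["recipient_marker"]]
  bg_d <- backgrounds[["donor_mito"]]
  if (is.null(bg_r) || is.null(bg_d) || !is.finite(bg_r) || !is.finite(bg_d) ||
      bg_r <= 0 || bg_d <= 0)
    stop("'backgrounds' must supply positive 'recipient_marker' and 'donor_mito' levels",
         call. = FALSE)
  is_cancer <- recipient_intensity >= gates$rfp_factor * bg_r
  is_macro <- donor_intensity >= gates$donor_factor * bg_d
  cls <- rep("other", n)
  cls[is_macro & !is_cancer] <- "macrophage"
  cls[is_cancer & !is_macro] <- "cancer"
  cls[is_cancer & !is_macro & punctae_present] <- "recipient_cancer"
  # cells passing both whole-cell gates are likely fusions: excluded ("other")
  data.frame(id = ids, class = cls,
             recipient_intensity = recipient_intensity,
             donor_intensity = donor_intensity,
             punctae_present = as.logical(punctae_present))
}
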