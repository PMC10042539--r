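#' Optical constants of the QPI system
#'
#' Constants needed to convert a phase-shift image (in fractions of a
#' wavelength) into a dry-mass map: per-pixel mass is
#' `phi * wavelength * pixel_area / alpha`.
#'
#' @param wavelength Source-light wavelength (micrometers).
#' @param alpha Specific refractive increment (micrometers^3/pg), the
#'   proportionality between refractive index and biomolecular concentration.
#' @param pixel_area Area imaged by one pixel (micrometers^2/pixel).
#' @return An object of class `"optical_constants"`.
#' @export
#' @examples
#' oc <- optical_constants()
#' oc$wavelength * oc$pixel_area / oc$alpha  # pg of dry mass per unit phase, per pixel
optical_constants <- function(wavelength = 0.623, alpha = 0.185,
                              pixel_area = 0.36) {
  if (wavelength <= 0 || alpha <= 0 || pixel_area <= 0)
    stop("optical constants must all be strictly positive", call. = FALSE)
  structure(list(wavelength = wavelength, alpha = alpha,
                 pixel_area = pixel_area),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> lambda = %g um, alpha = %g um^3/pg, pixel area = %g um^2 (pixel size %.4g um)\n",
              x$wavelength, x$alpha, x$pixel_area, pixel_size(x)))
  invisible(x)
}

#' Linear pixel size from the pixel area
#'
#' @param constants An [optical_constants()] object.
#' @return Pixel edge length in micrometers.
#' @export
pixel_size <- function(constants) sqrt(constants$pixel_area)

#' Attach a frame time to an image matrix
#'
#' Images in this package are plain numeric matrices (rows = image rows,
#' 0-based `(row, col)` coordinates in the region tables); this helper tags a
#' matrix with its acquisition time.
#'
#' @param values Numeric matrix.
#' @param frame_time Acquisition time (h).
#' @return The matrix with attribute `"frame_time"`.
#' @export
frame_image <- function(values, frame_time = NA_real_) {
  stopifnot(is.matrix(values), is.numeric(values))
  attr(values, "frame_time") <- frame_time
  values
}

# Design matrix of a 2-D polynomial surface of total degree <= degree,
# on coordinates normalized to [-1, 1] (numerically well conditioned).
poly2d_design <- function(nr, nc, degree, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    idx <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    rows <- idx$r; cols <- idx$c
  }
  x <- if (nc > 1) 2 * (cols - 1) / (nc - 1) - 1 else rep(0, length(cols))
  y <- if (nr > 1) 2 * (rows - 1) / (nr - 1) - 1 else rep(0, length(rows))
  terms <- expand.grid(i = 0:degree, j = 0:degree)
  terms <- terms[terms$i + terms$j <= degree, , drop = FALSE]
  X <- matrix(NA_real_, length(x), nrow(terms))
  for (k in seq_len(nrow(terms)))
    X[, k] <- x^terms$i[k] * y^terms$j[k]
  X
}

#' Polynomial background correction of a phase image
#'
#' Fits a low-order (default sixth-order) 2-D polynomial surface to the
#' image background and subtracts it. Background pixels are found by an
#' iterative robust fit: fit to all (subsampled) pixels, drop pixels lying
#' more than `sigma_cut` residual standard deviations *above* the surface
#' (cells only add phase), and refit, `n_iter` times. After correction the
#' background is centered near zero.
#'
#' @param phase Numeric matrix of phase shifts (fractions of a wavelength).
#' @param degree Total polynomial degree of the background surface.
#' @param sigma_cut Robustness cut in residual standard deviations.
#' @param n_iter Number of refit iterations.
#' @param max_fit_pixels Upper bound on the number of pixels entering the
#'   least-squares fit; pixels are subsampled on a regular stride beyond it
#'   (keeps the fit fast and deterministic).
#' @return The corrected phase matrix (attributes preserved).
#' @export
#' @examples
#' ph <- matrix(0.02, 64, 64) + outer(seq(0, .01, length = 64), seq(0, .01, length = 64))
#' summary(as.vector(correct_background(ph)))
correct_background <- function(phase, degree = 6L, sigma_cut = 2,
                               n_iter = 3L, max_fit_pixels = 10000L) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!all(is.finite(phase))) stop("phase image contains non-finite values", call. = FALSE)
  nr <- nrow(phase); nc <- ncol(phase)
  n_terms <- (degree + 1) * (degree + 2) / 2
  npx <- nr * nc
  stride <- max(1L, floor(npx / max_fit_pixels))
  fit_idx <- seq(1L, npx, by = stride)
  if (length(fit_idx) < n_terms)
    stop(sprintf("degenerate fit: %d background pixels for %d polynomial terms",
                 length(fit_idx), n_terms), call. = FALSE)
  rows <- ((fit_idx - 1L) %% nr) + 1L
  cols <- ((fit_idx - 1L) %/% nr) + 1L
  X <- poly2d_design(nr, nc, degree, rows, cols)
  z <- phase[fit_idx]
  keep <- rep(TRUE, length(z))
  coefs <- NULL
  for (it in seq_len(n_iter)) {
    if (sum(keep) < n_terms)
      stop(sprintf("degenerate fit: %d background pixels for %d polynomial terms",
                   sum(keep), n_terms), call. = FALSE)
    fit <- lm.fit(X[keep, , drop = FALSE], z[keep])
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    resid <- z - drop(X %*% coefs)
    s <- sd(resid[keep])
    if (!is.finite(s) || s == 0) break
    keep <- resid < sigma_cut * s
  }
  out <- phase - eval_poly2d(coefs, nr, nc, degree)
  attributes(out) <- attributes(phase)
  out
}

# Evaluate the fitted surface on the full grid via separable matrix products
# (powers-of-y matrix %*% coefficient matrix %*% powers-of-x, much cheaper
# than a full design matrix on large images).
eval_poly2d <- function(coefs, nr, nc, degree) {
  terms <- expand.grid(i = 0:degree, j = 0:degree)
  terms <- terms[terms$i + terms$j <= degree, , drop = FALSE]
  M <- matrix(0, degree + 1L, degree + 1L)   # rows: power of y, cols: power of x
  M[cbind(terms$j + 1L, terms$i + 1L)] <- coefs
  x <- if (nc > 1) 2 * (seq_len(nc) - 1) / (nc - 1) - 1 else 0
  y <- if (nr > 1) 2 * (seq_len(nr) - 1) / (nr - 1) - 1 else 0
  Xp <- outer(x, 0:degree, `^`)
  Yp <- outer(y, 0:degree, `^`)
  Yp %*% M %*% t(Xp)
}

#' Convert a phase image to a dry-mass map
#'
#' Per-pixel dry mass is `phi * wavelength * pixel_area / alpha` (pg), the
#' discrete form of integrating phase shift over area with the specific
#' refractive increment. Total cell mass is the sum of pixel masses over the
#' cell's segmented region.
#'
#' @param phase Numeric matrix of phase shifts (fractions of a wavelength).
#' @param constants An [optical_constants()] object.
#' @return Numeric matrix of per-pixel dry mass (pg), attributes preserved.
#' @export
#' @examples
#' phase_to_mass(matrix(1), optical_constants())  # 0.623*0.36/0.185 ~ 1.2124 pg
phase_to_mass <- function(phase, constants = optical_constants()) {
  stopifnot(is.matrix(phase), is.numeric(phase),
            inherits(constants, "optical_constants"))
  out <- phase * (constants$wavelength * constants$pixel_area / constants$alpha)
  attributes(out) <- attributes(phase)
  out
}
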