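#' Sobel gradient magnitude
#'
#' Convolves the image with the pair of 3x3 Sobel kernels (replicated
#' borders) and returns the gradient magnitude.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix of gradient magnitudes, same shape.
#' @export
sobel_magnitude <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), t(kx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

#' Segment cells in a dry-mass map
#'
#' Edge-based segmentation: Sobel gradient magnitude, Otsu threshold on the
#' gradient, morphological closing, hole filling, connected-component
#' labeling, and removal of regions below `min_area`. Returns a label map
#' with a per-region table of area, centroid, and total dry mass.
#'
#' @param mass Numeric matrix of per-pixel dry mass (pg), from
#'   [phase_to_mass()].
#' @param min_area Minimum region area (pixels); smaller regions are dropped.
#' @param closing_radius Radius (pixels) of the disc used for morphological
#'   closing of the thresholded edge mask.
#' @param dilate_radius Radius (pixels) of a final mask dilation; edge-based
#'   masks sit at the steepest gradient and a small dilation recovers the
#'   faint outer tail of the cell's mass distribution.
#' @param threshold Optional fixed gradient threshold; by default Otsu's
#'   threshold on the gradient magnitude is used.
#' @param watershed Split touching cells by watershed on the distance
#'   transform of the mask (recommended for confluent fields).
#' @param watershed_tolerance Minimum distance-map depth (pixels) between two
#'   objects for the watershed to keep them separate.
#' @return An object of class `"label_map"`: list with `labels` (integer
#'   matrix, 0 = background, labels contiguous from 1) and `regions` (data
#'   frame with columns `label`, `area_px`, `row_px`, `col_px` -- 0-based
#'   centroid coordinates -- and `mass_pg`).
#' @export
#' @examples
#' m <- matrix(0, 64, 64)
#' segment_cells(m)$regions  # empty: no cells
segment_cells <- function(mass, min_area = 200L, closing_radius = 3L,
                          dilate_radius = 2L, threshold = NULL,
                          watershed = TRUE, watershed_tolerance = 1) {
  stopifnot(is.matrix(mass), is.numeric(mass))
  if (!all(is.finite(mass))) stop("mass map contains non-finite values", call. = FALSE)
  g <- sobel_magnitude(mass)
  gmax <- max(g)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(mass), ncol(mass)),
                   regions = data.frame(label = integer(), area_px = integer(),
                                        row_px = numeric(), col_px = numeric(),
                                        mass_pg = numeric())),
              class = "label_map")
  }
  if (gmax <= 0) return(empty())
  if (is.null(threshold)) {
    gn <- g / gmax
    threshold <- EBImage::otsu(EBImage::Image(gn)) * gmax
  }
  mask <- g > threshold
  if (!any(mask)) return(empty())
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, "disc")
  m <- EBImage::Image(mask * 1)
  m <- EBImage::closing(m, brush)
  m <- EBImage::fillHull(m)
  if (dilate_radius >= 1L)
    m <- EBImage::dilate(m, EBImage::makeBrush(2L * dilate_radius + 1L, "disc"))
  lab <- if (watershed) {
    EBImage::imageData(EBImage::watershed(EBImage::distmap(m),
                                          tolerance = watershed_tolerance))
  } else EBImage::imageData(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  label_map(lab, mass, min_area = min_area)
}

#' Build a label map with its region table
#'
#' Relabels regions to contiguous positive integers, drops regions smaller
#' than `min_area`, and tabulates per-region area, centroid (0-based pixel
#' coordinates), and total dry mass.
#'
#' @param labels Integer matrix of region labels (0 = background).
#' @param mass Numeric matrix of per-pixel dry mass, same shape.
#' @param min_area Minimum region area in pixels.
#' @return An object of class `"label_map"`; see [segment_cells()].
#' @export
label_map <- function(labels, mass, min_area = 0L) {
  stopifnot(is.matrix(labels), is.matrix(mass),
            all(dim(labels) == dim(mass)))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids)) {
    areas <- tabulate(labels, nbins = max(ids))[ids]
    keep <- ids[areas >= min_area]
    if (length(keep) < length(ids)) {
      labels[!(labels %in% c(0L, keep))] <- 0L
      ids <- keep
    }
    # relabel contiguously
    if (length(ids) && !identical(ids, seq_along(ids))) {
      remap <- integer(max(ids))
      remap[ids] <- seq_along(ids)
      pos <- labels > 0L
      labels[pos] <- remap[labels[pos]]
      ids <- seq_along(ids)
    }
  }
  if (!length(ids)) {
    regions <- data.frame(label = integer(), area_px = integer(),
                          row_px = numeric(), col_px = numeric(),
                          mass_pg = numeric())
  } else {
    px <- which(labels > 0L)
    lab_px <- labels[px]
    rows <- ((px - 1L) %% nrow(labels))        # 0-based
    cols <- ((px - 1L) %/% nrow(labels))
    area <- tabulate(lab_px, nbins = length(ids))
    regions <- data.frame(
      label = ids,
      area_px = area,
      row_px = as.numeric(tapply(rows, lab_px, mean)),
      col_px = as.numeric(tapply(cols, lab_px, mean)),
      mass_pg = as.numeric(tapply(mass[px], lab_px, sum)))
  }
  structure(list(labels = labels, regions = regions), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %dx%d, %d regions\n",
              nrow(x$labels), ncol(x$labels), nrow(x$regions)))
  if (nrow(x$regions)) print(head(x$regions, 10))
  invisible(x)
}
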