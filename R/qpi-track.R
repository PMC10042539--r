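#' Track segmented cells across frames
#'
#' Links regions across consecutive frames by greedy nearest-centroid
#' assignment in physical units, with explicit division detection: when two
#' regions in the next frame both lie closest to the same vanished parent
#' (within `max_displacement`) and their mass sum is within
#' `division_mass_tol` of the parent's mass, the parent track is closed with
#' fate `"divided"` and two daughter tracks are opened and linked to it.
#' Unmatched regions start new tracks; a track that ends before the last
#' frame is assigned fate `"left_frame"` if its last centroid lies within
#' `border_margin` of the image border, otherwise `"censored_at_end"` (as are
#' all tracks alive at the final frame).
#'
#' @param label_maps List of [label_map()] objects, one per frame, all with
#'   identical image shape.
#' @param times Numeric vector of frame times (h), strictly increasing, same
#'   length as `label_maps`.
#' @param px_size Pixel edge length (micrometers); converts pixel centroids
#'   to physical displacements.
#' @param max_displacement Maximum centroid displacement allowed between
#'   consecutive frames (micrometers).
#' @param division_mass_tol Relative tolerance on (daughter mass sum vs
#'   parent mass) for division detection; each daughter must also hold
#'   between 25% and 75% of the parent mass.
#' @param max_mass_jump Maximum relative mass change tolerated across one
#'   frame-to-frame link. Dry mass changes by well under 1% per 15-min
#'   frame, so a large jump signals a segmentation artifact (e.g. two
#'   touching cells merging into one region); such links are refused and the
#'   track ends rather than absorbing the corrupted mass.
#' @param border_margin Distance from the border (micrometers) below which a
#'   disappearing cell is deemed to have left the frame; defaults to
#'   `max_displacement`.
#' @return An object of class `"cell_tracks"`: a list of tracks, each a list
#'   with `track_id`, `parent_id`, `daughter_ids`, `fate`, `division_time`,
#'   and `data` (data frame: `frame`, `time_h`, `label`, `row_px`, `col_px`,
#'   `mass_pg`).
#' @seealso [specific_growth_rate()], [cytokinesis_fraction()], [lineages()]
#' @export
track_cells <- function(label_maps, times, px_size = 0.6,
                        max_displacement = 20, division_mass_tol = 0.2,
                        max_mass_jump = 0.3,
                        border_margin = max_displacement) {
  if (length(label_maps) < 2L) stop("need at least two frames to track", call. = FALSE)
  if (length(times) != length(label_maps))
    stop("'times' must have one entry per frame", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  shp <- dim(label_maps[[1L]]$labels)
  for (lm_ in label_maps)
    if (!all(dim(lm_$labels) == shp))
      stop("all frames must share the same image shape", call. = FALSE)

  tracks <- list()          # finished + active track records
  next_id <- 1L
  new_track <- function(region, frame, parent_id = NA_integer_) {
    id <- next_id; next_id <<- next_id + 1L
    tracks[[id]] <<- list(
      track_id = id, parent_id = parent_id, daughter_ids = integer(),
      fate = NA_character_, division_time = NA_real_,
      data = data.frame(frame = frame, time_h = times[frame],
                        label = region$label, row_px = region$row_px,
                        col_px = region$col_px, mass_pg = region$mass_pg))
    id
  }
  append_point <- function(id, region, frame) {
    tracks[[id]]$data <<- rbind(tracks[[id]]$data, data.frame(
      frame = frame, time_h = times[frame], label = region$label,
      row_px = region$row_px, col_px = region$col_px,
      mass_pg = region$mass_pg))
  }
  close_track <- function(id, frame_ended) {
    last <- tail(tracks[[id]]$data, 1L)
    near_border <- min(last$row_px, last$col_px,
                       (shp[1L] - 1) - last$row_px,
                       (shp[2L] - 1) - last$col_px) * px_size <= border_margin
    tracks[[id]]$fate <<- if (near_border) "left_frame" else "censored_at_end"
  }

  active <- vapply(seq_len(nrow(label_maps[[1L]]$regions)),
                   function(i) new_track(label_maps[[1L]]$regions[i, ], 1L),
                   integer(1))

  for (fr in seq_len(length(label_maps) - 1L)) {
    nxt <- label_maps[[fr + 1L]]$regions
    if (!length(active) && !nrow(nxt)) next
    prev_cent <- do.call(rbind, lapply(active, function(id) {
      last <- tail(tracks[[id]]$data, 1L)
      c(last$row_px, last$col_px, last$mass_pg)
    }))
    n_prev <- length(active); n_nxt <- nrow(nxt)
    # distance matrix in micrometers
    D <- matrix(Inf, n_prev, n_nxt)
    if (n_prev && n_nxt)
      for (i in seq_len(n_prev))
        D[i, ] <- sqrt((prev_cent[i, 1L] - nxt$row_px)^2 +
                       (prev_cent[i, 2L] - nxt$col_px)^2) * px_size
    matched_prev <- rep(FALSE, n_prev)
    matched_nxt <- rep(FALSE, max(n_nxt, 0L))

    # division detection: two next regions whose nearest parent is the same
    # track, with mass sum close to the parent's
    if (n_prev && n_nxt >= 2L) {
      nearest <- apply(D, 2L, which.min)
      nearest_d <- D[cbind(nearest, seq_len(n_nxt))]
      for (i in seq_len(n_prev)) {
        kids <- which(nearest == i & nearest_d <= max_displacement)
        if (length(kids) == 2L) {
          msum <- sum(nxt$mass_pg[kids])
          mp <- prev_cent[i, 3L]
          balanced <- all(nxt$mass_pg[kids] >= 0.25 * mp & nxt$mass_pg[kids] <= 0.75 * mp)
          if (abs(msum - mp) <= division_mass_tol * mp && balanced) {
            id <- active[i]
            tracks[[id]]$fate <- "divided"
            tracks[[id]]$division_time <- times[fr + 1L]
            d1 <- new_track(nxt[kids[1L], ], fr + 1L, parent_id = id)
            d2 <- new_track(nxt[kids[2L], ], fr + 1L, parent_id = id)
            tracks[[id]]$daughter_ids <- c(d1, d2)
            matched_prev[i] <- TRUE
            matched_nxt[kids] <- TRUE
            active <- c(active, d1, d2)   # appended; excluded from greedy below
          }
        }
      }
    }

    # greedy nearest-centroid one-to-one assignment of the remainder;
    # links implying an implausible mass change are refused
    if (n_prev && n_nxt) {
      Dw <- D
      if (is.finite(max_mass_jump))
        for (i in seq_len(n_prev)) {
          bad <- abs(nxt$mass_pg / prev_cent[i, 3L] - 1) > max_mass_jump
          Dw[i, bad] <- Inf
        }
      Dw[matched_prev, ] <- Inf
      Dw[, matched_nxt] <- Inf
      repeat {
        mn <- min(Dw)
        if (!is.finite(mn) || mn > max_displacement) break
        ij <- which(Dw == mn, arr.ind = TRUE)[1L, ]
        append_point(active[ij[1L]], nxt[ij[2L], ], fr + 1L)
        matched_prev[ij[1L]] <- TRUE
        matched_nxt[ij[2L]] <- TRUE
        Dw[ij[1L], ] <- Inf
        Dw[, ij[2L]] <- Inf
      }
    }

    # close unmatched previous tracks; open tracks for unmatched regions
    ended <- which(!matched_prev)
    for (i in ended) close_track(active[i], fr)
    keep <- active[seq_len(n_prev)][matched_prev]
    keep <- keep[vapply(keep, function(id) is.na(tracks[[id]]$fate), logical(1))]
    newly <- if (n_nxt) which(!matched_nxt) else integer()
    new_ids <- vapply(newly, function(j) new_track(nxt[j, ], fr + 1L), integer(1))
    daughters <- setdiff(active[-seq_len(n_prev)], integer())
    active <- c(keep, daughters, new_ids)
  }
  for (id in active)
    if (is.na(tracks[[id]]$fate)) tracks[[id]]$fate <- "censored_at_end"

  structure(lapply(tracks, function(tr) { class(tr) <- "cell_track"; tr }),
            class = "cell_tracks",
            px_size = px_size, image_shape = shp, times = times)
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track %d> %d frames (%.2f-%.2f h), fate %s%s\n",
              x$track_id, nrow(x$data), min(x$data$time_h), max(x$data$time_h),
              x$fate,
              if (!is.na(x$division_time))
                sprintf(" at %.2f h -> daughters %s", x$division_time,
                        paste(x$daughter_ids, collapse = ", ")) else ""))
  invisible(x)
}

#' @export
print.cell_tracks <- function(x, ...) {
  fates <- table(vapply(x, `[[`, character(1), "fate"))
  cat(sprintf("<cell_tracks> %d tracks (%s)\n", length(x),
              paste(names(fates), fates, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cell_tracks <- function(x, ...) {
  do.call(rbind, lapply(x, function(tr) {
    cbind(track_id = tr$track_id, tr$data,
          fate = tr$fate, parent_id = tr$parent_id,
          division_time = tr$division_time)
  }))
}

#' Specific growth rate of a tracked cell
#'
#' The slope of a linear least-squares fit to the cell's mass-versus-time
#' series, divided by the cell's mean mass over the track (units 1/h). For a
#' cell growing exponentially with constant `k` over a duration short
#' compared with `1/k`, this estimates `k`.
#'
#' @param track A `"cell_track"`, or any list with a `data` data frame
#'   containing `time_h` and `mass_pg`.
#' @return Specific growth rate (1/h).
#' @export
#' @examples
#' tr <- list(data = data.frame(time_h = 0:10, mass_pg = 100 + 2 * (0:10)))
#' specific_growth_rate(tr)  # 2 / mean mass
specific_growth_rate <- function(track) {
  d <- track$data
  if (is.null(d) || nrow(d) < 3L)
    stop("specific growth rate needs a track with at least 3 frames", call. = FALSE)
  t <- d$time_h; m <- d$mass_pg
  slope <- sum((t - mean(t)) * (m - mean(m))) / sum((t - mean(t))^2)
  slope / mean(m)
}

#' Fraction of observed cells completing cytokinesis
#'
#' Counts a track as a divider if it divides within `max_doubling` hours of
#' observation; tracks observed for less than `min_observation` hours without
#' dividing (e.g. cells leaving the frame early) are omitted from the
#' denominator.
#'
#' @param tracks A `"cell_tracks"` object (or list of tracks).
#' @param max_doubling Maximum expected doubling time (h).
#' @param min_observation Minimum observation span (h) for a non-divider to
#'   count in the denominator.
#' @return Percent of eligible tracks that divide within `max_doubling`.
#' @export
cytokinesis_fraction <- function(tracks, max_doubling = 40, min_observation = 30) {
  info <- lapply(tracks, function(tr) {
    t0 <- min(tr$data$time_h)
    divided <- identical(tr$fate, "divided")
    list(divided = divided,
         observed = max(tr$data$time_h) - t0,
         time_to_division = if (divided) tr$division_time - t0 else NA_real_)
  })
  eligible <- vapply(info, function(i) i$divided || i$observed >= min_observation,
                     logical(1))
  if (!any(eligible))
    stop("cytokinesis fraction undefined: no track observed long enough", call. = FALSE)
  dividing <- vapply(info, function(i) isTRUE(i$divided && i$time_to_division < max_doubling),
                     logical(1))
  100 * sum(dividing & eligible) / sum(eligible)
}

#' Parent-daughter lineage records
#'
#' Collects every divided track together with its two daughter tracks.
#'
#' @param tracks A `"cell_tracks"` object.
#' @return A list of `"lineage_record"` objects, each with elements `parent`,
#'   `daughters` (list of two tracks) and `inheritance` (logical flags,
#'   `NA` until assigned from punctae classification).
#' @export
lineages <- function(tracks) {
  recs <- list()
  for (tr in tracks) {
    if (identical(tr$fate, "divided") && length(tr$daughter_ids) == 2L) {
      rec <- list(parent = tr,
                  daughters = list(tracks[[tr$daughter_ids[1L]]],
                                   tracks[[tr$daughter_ids[2L]]]),
                  inheritance = c(NA, NA))
      class(rec) <- "lineage_record"
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}

#' @export
print.lineage_record <- function(x, ...) {
  cat(sprintf("<lineage_record> parent %d -> daughters %d, %d (inheritance: %s)\n",
              x$parent$track_id, x$daughters[[1L]]$track_id,
              x$daughters[[2L]]$track_id,
              paste(x$inheritance, collapse = ", ")))
  invisible(x)
}

#' Birth-normalized daughter mass series
#'
#' Divides each daughter's mass series by its mass at birth (first tracked
#' frame), so both series start at exactly 1; used to compare the growth of
#' the daughter that inherited transferred mitochondria with its sister.
#'
#' @param lineage A `"lineage_record"` from [lineages()].
#' @return A list of two data frames (`time_h`, `normalized_mass`).
#' @export
normalize_daughter_masses <- function(lineage) {
  lapply(lineage$daughters, function(d) {
    if (!nrow(d$data)) stop("daughter track is empty", call. = FALSE)
    m0 <- d$data$mass_pg[1L]
    if (!is.finite(m0) || m0 <= 0)
      stop("daughter birth mass must be positive", call. = FALSE)
    data.frame(time_h = d$data$time_h, normalized_mass = d$data$mass_pg / m0)
  })
}
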