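#' Run the full QPI analysis pipeline on a time lapse
#'
#' From phase and fluorescence stacks to classified single-cell growth
#' rates: per frame, the phase image is background-corrected
#' ([correct_background()]), converted to dry mass ([phase_to_mass()]) and
#' segmented ([segment_cells()]); cells are tracked across frames
#' ([track_cells()]); fluorescence channels are resized to the QPI grid and
#' summarized per cell ([per_cell_intensity()]); donor punctae are separated
#' by the rolling-ball filter ([extract_punctae()]); tracks are classified
#' by the intensity gates ([classify_population()]), with a track counted
#' punctae-positive only when punctae are detected in at least two
#' consecutive frames; and each sufficiently long track receives a specific
#' growth rate ([specific_growth_rate()]).
#'
#' @param phase List of phase matrices (fractions of a wavelength), one per
#'   frame.
#' @param times Frame times (h).
#' @param rfp Optional recipient-marker stack (same length; any shape --
#'   resized to the phase grid).
#' @param donor Optional donor-mitochondria stack.
#' @param config Configuration list from [load_config()].
#' @param verbose Print per-stage counts.
#' @return Object of class `"qpi_analysis"`: list with `label_maps`,
#'   `tracks`, `cells` (per-track table: class, punctae flag, specific
#'   growth rate, fate...), `lineages` (with punctae-inheritance flags),
#'   `backgrounds`, and `config`.
#' @export
analyze_timelapse <- function(phase, times, rfp = NULL, donor = NULL,
                              config = load_config(), verbose = FALSE) {
  if (length(phase) < 2L) stop("need at least two frames", call. = FALSE)
  if (length(times) != length(phase))
    stop("'times' must match the number of frames", call. = FALSE)
  oc <- do.call(optical_constants, config$optical)
  px <- pixel_size(oc)
  seg_cfg <- config$segmentation
  gates <- do.call(gate_params, config$gates)
  shp <- dim(phase[[1L]])

  n_frames <- length(phase)
  label_maps <- vector("list", n_frames)
  rfp_int <- donor_int <- punct_flags <- vector("list", n_frames)
  rfp_bg <- donor_bg <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    corr <- correct_background(phase[[f]])
    mass <- phase_to_mass(corr, oc)
    lm_ <- segment_cells(mass, min_area = seg_cfg$min_area,
                         closing_radius = seg_cfg$closing_radius,
                         dilate_radius = seg_cfg$dilate_radius)
    label_maps[[f]] <- lm_
    if (!is.null(rfp)) {
      ch <- resize_to_match(rfp[[f]], shp)
      rfp_int[[f]] <- per_cell_intensity(ch, lm_)
      rfp_bg[f] <- channel_background(ch, lm_)
    }
    if (!is.null(donor)) {
      ch <- resize_to_match(donor[[f]], shp)
      donor_int[[f]] <- per_cell_intensity(ch, lm_)
      donor_bg[f] <- channel_background(ch, lm_)
      pk <- extract_punctae(ch, gates, px)
      det <- pk$detected
      labs <- lm_$labels
      hit <- tapply(det[labs > 0L], labs[labs > 0L], any)
      punct_flags[[f]] <- setNames(as.logical(hit), names(hit))
    }
  }
  if (verbose)
    message(sprintf("segmented %d frames; %s regions/frame (median)",
                    n_frames,
                    median(vapply(label_maps, function(l) nrow(l$regions), numeric(1)))))

  tracks <- track_cells(label_maps, times, px_size = px,
                        max_displacement = config$tracking$max_displacement,
                        division_mass_tol = config$tracking$division_mass_tol,
                        max_mass_jump = config$tracking$max_mass_jump)
  if (verbose) print(tracks)

  # per-track fluorescence summaries
  pull <- function(per_frame, tr) {
    vapply(seq_len(nrow(tr$data)), function(i) {
      v <- per_frame[[tr$data$frame[i]]]
      if (is.null(v)) return(NA_real_)
      val <- v[as.character(tr$data$label[i])]
      if (length(val)) as.numeric(val) else NA_real_
    }, numeric(1))
  }
  has_run <- function(x, n = 2L) {
    r <- rle(x)
    any(r$values & r$lengths >= n, na.rm = TRUE)
  }
  n_tracks <- length(tracks)
  rec_i <- don_i <- rep(NA_real_, n_tracks)
  punct <- rep(FALSE, n_tracks)
  punct_first3 <- rep(FALSE, n_tracks)
  for (k in seq_len(n_tracks)) {
    tr <- tracks[[k]]
    if (!is.null(rfp)) rec_i[k] <- median(pull(rfp_int, tr), na.rm = TRUE)
    if (!is.null(donor)) {
      don_i[k] <- median(pull(donor_int, tr), na.rm = TRUE)
      flags <- vapply(seq_len(nrow(tr$data)), function(i) {
        v <- punct_flags[[tr$data$frame[i]]]
        isTRUE(v[as.character(tr$data$label[i])])
      }, logical(1))
      punct[k] <- has_run(flags, 2L)
      punct_first3[k] <- any(head(flags, 3L))
    }
  }
  backgrounds <- c(recipient_marker = median(rfp_bg, na.rm = TRUE),
                   donor_mito = median(donor_bg, na.rm = TRUE))

  classes <- if (!is.null(rfp) && !is.null(donor)) {
    classify_population(rec_i, don_i, punct, backgrounds, gates,
                        ids = vapply(tracks, `[[`, integer(1), "track_id"))
  } else NULL

  lin <- lineages(tracks)
  for (i in seq_along(lin)) {
    lin[[i]]$inheritance <- vapply(lin[[i]]$daughters, function(d)
      punct_first3[d$track_id], logical(1))
  }

  min_frames <- config$growth$min_track_frames
  cells <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id,
               n_frames = nrow(tr$data),
               t_start = min(tr$data$time_h), t_end = max(tr$data$time_h),
               mean_mass_pg = mean(tr$data$mass_pg),
               fate = tr$fate, parent_id = tr$parent_id,
               division_time = tr$division_time,
               sgr_per_h = if (nrow(tr$data) >= max(3L, min_frames))
                 specific_growth_rate(tr) else NA_real_)
  }))
  if (!is.null(classes)) {
    i <- match(cells$track_id, classes$id)
    cells$class <- classes$class[i]
    cells$punctae_present <- classes$punctae_present[i]
  }

  structure(list(label_maps = label_maps, tracks = tracks, cells = cells,
                 classes = classes, lineages = lin,
                 backgrounds = backgrounds, config = config),
            class = "qpi_analysis")
}

#' @export
print.qpi_analysis <- function(x, ...) {
  cat(sprintf("<qpi_analysis> %d frames, %d tracks, %d lineages\n",
              length(x$label_maps), length(x$tracks), length(x$lineages)))
  if (!is.null(x$classes)) {
    tab <- table(x$classes$class)
    cat("  classes:", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  s <- growth_rate_summary(x)
  if (!is.na(s$pct_difference))
    cat(sprintf("  mean specific growth rate: recipients %.5f/h vs non-recipients %.5f/h (+%.1f%%)\n",
                s$mean_sgr_recipient, s$mean_sgr_nonrecipient, s$pct_difference))
  invisible(x)
}

#' Recipient vs non-recipient growth-rate comparison
#'
#' Means of the per-track specific growth rates for recipient cancer cells
#' (donor punctae present) and non-recipient cancer cells, and the percent
#' difference between them.
#'
#' @param analysis A `"qpi_analysis"` object.
#' @return List with `mean_sgr_recipient`, `mean_sgr_nonrecipient`,
#'   `pct_difference`, and the per-group track counts.
#' @export
growth_rate_summary <- function(analysis) {
  cells <- analysis$cells
  if (is.null(cells$class))
    return(list(mean_sgr_recipient = NA_real_, mean_sgr_nonrecipient = NA_real_,
                pct_difference = NA_real_, n_recipient = 0L, n_nonrecipient = 0L))
  ok <- !is.na(cells$sgr_per_h)
  rec <- ok & cells$class == "recipient_cancer"
  non <- ok & cells$class == "cancer"
  m_rec <- mean(cells$sgr_per_h[rec])
  m_non <- mean(cells$sgr_per_h[non])
  list(mean_sgr_recipient = m_rec, mean_sgr_nonrecipient = m_non,
       pct_difference = 100 * (m_rec / m_non - 1),
       n_recipient = sum(rec), n_nonrecipient = sum(non))
}
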