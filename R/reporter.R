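#' Delta-delta-Ct from a qPCR cycle-threshold table
#'
#' Computes the Livak ddCT from a long-format table of CT values. Technical
#' replicates are averaged within each (sample, condition, gene) cell first;
#' per condition, `dCT = CT_target - CT_reference` is computed per sample and
#' averaged; `ddCT = dCT_treated - dCT_control`.
#'
#' @param table Data frame with columns `sample`, `condition`, `gene`, `ct`.
#' @param target,reference Gene names (target of the knockdown and the
#'   housekeeping reference).
#' @param control,treated Condition labels.
#' @return Scalar ddCT, with per-sample dCT values as attribute `"dct"`.
#' @export
delta_delta_ct <- function(table, target, reference,
                           control = "control", treated = "treated") {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("CT table needs columns sample, condition, gene, ct", call. = FALSE)
  if (!all(is.finite(table$ct)) || any(table$ct <= 0))
    stop("CT values must be finite and positive", call. = FALSE)
  dct_cond <- function(cond) {
    sub <- table[table$condition == cond, , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("condition '%s' missing from CT table", cond), call. = FALSE)
    per <- lapply(split(sub, sub$sample), function(s) {
      ct_t <- mean(s$ct[s$gene == target])
      ct_r <- mean(s$ct[s$gene == reference])
      if (!is.finite(ct_t) || !is.finite(ct_r))
        stop(sprintf("sample '%s' (%s) lacks target or reference CT values",
                     s$sample[1L], cond), call. = FALSE)
      ct_t - ct_r
    })
    unlist(per)
  }
  dct_c <- dct_cond(control)
  dct_t <- dct_cond(treated)
  structure(mean(dct_t) - mean(dct_c),
            dct = list(control = dct_c, treated = dct_t))
}

#' Percent knockdown from ddCT
#'
#' The relative-quantification percent knockdown, `(1 - 2^(-ddCT)) * 100`.
#' Accepts either a precomputed ddCT value or a CT table (forwarded to
#' [delta_delta_ct()]). Monotone increasing in ddCT, bounded above by 100;
#' a negative ddCT (up-regulation) yields a negative value, reported as-is.
#'
#' @param x Numeric ddCT value, or a CT table data frame.
#' @param ... Passed to [delta_delta_ct()] when `x` is a data frame.
#' @return Percent knockdown.
#' @export
#' @examples
#' percent_knockdown(1)  # 50
#' percent_knockdown(2)  # 75
percent_knockdown <- function(x, ...) {
  ddct <- if (is.data.frame(x)) delta_delta_ct(x, ...) else x
  as.numeric((1 - 2^(-ddct)) * 100)
}

#' Normalized cytoplasm-to-nucleus ratio series for a translocation reporter
#'
#' For a kinase translocation reporter, computes the cytoplasmic:nuclear mean
#' fluorescence intensity ratio at each time point, normalized so the first
#' time point equals exactly 1. Invariant to rescaling both channels by a
#' common positive constant.
#'
#' @param series Data frame with columns `time_min`, `nuc_mfi`, `cyto_mfi`.
#' @return Data frame with columns `time_min` and `ratio` (normalized).
#' @export
#' @examples
#' ktr_ratio_series(data.frame(time_min = c(0, 10), nuc_mfi = c(10, 10),
#'                             cyto_mfi = c(10, 20)))
ktr_ratio_series <- function(series) {
  need <- c("time_min", "nuc_mfi", "cyto_mfi")
  if (!all(need %in% names(series)))
    stop("KTR series needs columns time_min, nuc_mfi, cyto_mfi", call. = FALSE)
  if (!nrow(series)) stop("KTR series is empty", call. = FALSE)
  series <- series[order(series$time_min), , drop = FALSE]
  if (any(!is.finite(series$nuc_mfi)) || any(series$nuc_mfi <= 0))
    stop("nuclear intensity must be positive at every time point", call. = FALSE)
  ratio <- series$cyto_mfi / series$nuc_mfi
  data.frame(time_min = series$time_min, ratio = ratio / ratio[1L])
}
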