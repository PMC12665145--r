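#' Basal fluorescence intensity of one cell
#'
#' Mean trace value over frames outside detected signaling events.
#'
#' @param F Numeric trace vector.
#' @param event_indicator Logical vector of the same length, `TRUE` inside
#'   events ([event_frame_labels()]).
#' @return Scalar basal intensity.
#' @export
basal_intensity <- function(F, event_indicator) {
  stopifnot(is.numeric(F), is.logical(event_indicator),
            length(F) == length(event_indicator))
  if (all(event_indicator)) {
    stop("basal intensity undefined: every frame lies inside an event",
         call. = FALSE)
  }
  mean(F[!event_indicator])
}

#' Per-cell basal intensities for a trace set
#'
#' @param traces A `trace_set`.
#' @param events Combined event table (as from [detect_events_all()]).
#' @return Data frame with columns `cell_id`, `basal`.
#' @export
basal_summary <- function(traces, events) {
  stopifnot(inherits(traces, "trace_set"))
  Tn <- nrow(traces$F)
  basal <- vapply(seq_along(traces$cell_ids), function(j) {
    ev <- events[events$cell_id == traces$cell_ids[j], , drop = FALSE]
    basal_intensity(traces$F[, j], event_frame_labels(Tn, ev))
  }, numeric(1))
  data.frame(cell_id = traces$cell_ids, basal = basal)
}

#' Standard deviation of log-transformed values
#'
#' The spread of log-transformed basal intensities measures intrinsic
#' (scale-free) variability, so standard deviations of samples with
#' different mean brightness can be compared directly.  Natural log by
#' default; the base is recorded on the result.
#'
#' @param x Positive numeric values (per-cell basal intensities), `n >= 2`.
#' @param base Log base (default `exp(1)`).
#' @return Sample standard deviation (n-1 denominator) of `log(x, base)`,
#'   with attribute `log_base`.
#' @examples
#' log_sd(c(10, 100, 1000))
#' @export
log_sd <- function(x, base = exp(1)) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  bad <- which(x <= 0)
  if (length(bad)) {
    stop("non-positive value at position ", bad[1L],
         ": cannot log-transform", call. = FALSE)
  }
  s <- stats::sd(log(x, base = base))
  attr(s, "log_base") <- base
  s
}

#' Percent difference between two log-scale standard deviations
#'
#' `100 * (sigma_signal - sigma_control) / sigma_control`.  The exact value
#' is returned; report it to the nearest percent.
#'
#' @param sigma_signal,sigma_control Standard deviations of the log basal
#'   intensities of the biosensor and control samples.
#' @return Percent difference (signed).
#' @examples
#' round(percent_difference(1.792, 1.688))  # 6
#' @export
percent_difference <- function(sigma_signal, sigma_control) {
  if (sigma_control <= 0) stop("'sigma_control' must be > 0", call. = FALSE)
  100 * (sigma_signal - sigma_control) / sigma_control
}

#' Survival fractions of event durations
#'
#' For each threshold `d`, the fraction of events lasting at least `d`
#' seconds, plus the fraction of single-frame events (duration equal to the
#' frame interval).
#'
#' @param durations_s Event durations in seconds (or an event table with a
#'   `duration_s` column); must be non-empty.
#' @param thresholds_s Duration thresholds in seconds (default `c(20, 60)`).
#' @param frame_interval_s Frame interval in seconds, used for the
#'   single-frame fraction (default 5).
#' @return List with `fraction_at_least` (named numeric, one entry per
#'   threshold) and `single_frame_fraction`.
#' @examples
#' duration_fractions(c(5, 5, 10, 20, 25, 60), c(20, 60))
#' @export
duration_fractions <- function(durations_s, thresholds_s = c(20, 60),
                               frame_interval_s = 5) {
  if (is.data.frame(durations_s)) durations_s <- durations_s$duration_s
  if (length(durations_s) == 0L) {
    stop("duration fractions undefined for an empty event list", call. = FALSE)
  }
  fr <- vapply(thresholds_s, function(d) mean(durations_s >= d), numeric(1))
  names(fr) <- paste0("ge_", thresholds_s, "s")
  list(fraction_at_least = fr,
       single_frame_fraction = mean(durations_s == frame_interval_s))
}

#' Event and cell counts for FDR estimation
#'
#' @param n_control_events Events detected in the inert-fluorophore control
#'   sample (all false positives).
#' @param n_control_cells Cells analyzed in the control sample.
#' @param n_signal_events Events detected in the biosensor sample.
#' @param n_signal_cells Cells analyzed in the biosensor sample.
#' @return A validated `fdr_inputs` object.
#' @export
fdr_inputs <- function(n_control_events, n_control_cells,
                       n_signal_events, n_signal_cells) {
  x <- list(n_control_events = n_control_events,
            n_control_cells = n_control_cells,
            n_signal_events = n_signal_events,
            n_signal_cells = n_signal_cells)
  if (x$n_control_cells <= 0 || x$n_signal_cells <= 0) {
    stop("cell counts must be > 0", call. = FALSE)
  }
  if (x$n_control_events < 0 || x$n_signal_events < 0) {
    stop("event counts must be >= 0", call. = FALSE)
  }
  structure(x, class = "fdr_inputs")
}

#' Control-based false-discovery-rate estimate
#'
#' Events detected in an inert-fluorophore control are all imaging
#' artifacts, so the control's per-cell event rate divided by the biosensor
#' sample's per-cell event rate estimates the fraction of detected biosensor
#' events that are false positives.  The per-cell-rate ratio normalizes for
#' unequal cell counts; the raw event-count ratio is reported alongside as a
#' secondary statistic.
#'
#' @param inputs An [fdr_inputs()] object.
#' @return An object of class `fdr_estimate`: list with `fdr` (the
#'   per-cell-rate ratio, a fraction), `event_count_ratio`
#'   (control events / signal events), and the inputs.
#' @examples
#' estimate_fdr(fdr_inputs(40, 250, 812, 245))
#' @export
estimate_fdr <- function(inputs) {
  stopifnot(inherits(inputs, "fdr_inputs"))
  if (inputs$n_signal_events <= 0) {
    stop("FDR undefined: no events detected in the biosensor sample",
         call. = FALSE)
  }
  control_rate <- inputs$n_control_events / inputs$n_control_cells
  signal_rate <- inputs$n_signal_events / inputs$n_signal_cells
  structure(list(fdr = control_rate / signal_rate,
                 event_count_ratio =
                   inputs$n_control_events / inputs$n_signal_events,
                 inputs = inputs),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(paste0("fdr_estimate: %.2f%% (per-cell rate ratio; raw event ",
                     "ratio %.2f%%)\n  control: %g events / %g cells; ",
                     "signal: %g events / %g cells\n"),
              100 * x$fdr, 100 * x$event_count_ratio,
              x$inputs$n_control_events, x$inputs$n_control_cells,
              x$inputs$n_signal_events, x$inputs$n_signal_cells))
  invisible(x)
}

#' Match detected events to ground-truth events
#'
#' A detected event is a true positive when its frame interval overlaps a
#' same-cell truth interval, matched one-to-one greedily by descending
#' overlap length (ties: earlier truth start, then earlier detected start).
#' When a side is empty the corresponding rate is undefined and reported as
#' 1 with a flag.
#'
#' @param detected,truth Event tables with columns `cell_id`,
#'   `start_frame`, `end_frame` (0-based inclusive); intervals of one cell
#'   must be disjoint within each table.
#' @return List with `precision`, `recall`, `n_tp`, `n_detected`,
#'   `n_truth`, and flags `precision_undefined`, `recall_undefined`.
#' @export
match_events <- function(detected, truth) {
  n_det <- nrow(detected); n_tru <- nrow(truth)
  tp <- 0L
  if (n_det > 0L && n_tru > 0L) {
    for (cid in intersect(unique(detected$cell_id), unique(truth$cell_id))) {
      d <- detected[detected$cell_id == cid, , drop = FALSE]
      u <- truth[truth$cell_id == cid, , drop = FALSE]
      cand <- expand.grid(i = seq_len(nrow(d)), j = seq_len(nrow(u)))
      cand$ov <- pmin(d$end_frame[cand$i], u$end_frame[cand$j]) -
        pmax(d$start_frame[cand$i], u$start_frame[cand$j]) + 1L
      cand <- cand[cand$ov >= 1L, , drop = FALSE]
      cand <- cand[order(-cand$ov, u$start_frame[cand$j],
                         d$start_frame[cand$i]), , drop = FALSE]
      used_i <- logical(nrow(d)); used_j <- logical(nrow(u))
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(precision = if (n_det == 0L) 1 else tp / n_det,
       recall = if (n_tru == 0L) 1 else tp / n_tru,
       n_tp = tp, n_detected = n_det, n_truth = n_tru,
       precision_undefined = n_det == 0L,
       recall_undefined = n_tru == 0L)
}

#' Plot the distribution of event durations
#'
#' Histogram of detected event durations with bin edges at multiples of the
#' frame interval.  Extreme outliers (durations above `plot_max_s`, default
#' 125 s) are excluded from the plot but retained in all statistics.
#'
#' @param durations_s Event durations in seconds (or an event table).
#' @param frame_interval_s Frame interval in seconds.
#' @param plot_max_s Upper plotting limit in seconds (default 125).
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot_signal_durations <- function(durations_s, frame_interval_s = 5,
                                  plot_max_s = 125, ...) {
  if (is.data.frame(durations_s)) durations_s <- durations_s$duration_s
  keep <- durations_s <= plot_max_s
  d <- durations_s[keep]
  breaks <- seq(0, max(d) + frame_interval_s, by = frame_interval_s)
  h <- graphics::hist(d, breaks = breaks,
                      xlab = "Signal duration (s)", ylab = "Events",
                      main = "Distribution of signal durations", ...)
  invisible(h)
}

#' Plot basal intensity distributions on a log scale
#'
#' Strip-and-box rendering of per-cell basal intensities for one or more
#' samples, on a logarithmic axis, annotated with each sample's log-scale
#' standard deviation.
#'
#' @param basal_list Named list of positive numeric vectors (per-cell basal
#'   intensities per sample).
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the per-sample log-scale standard deviations.
#' @export
plot_basal_distribution <- function(basal_list, ...) {
  stopifnot(is.list(basal_list), length(basal_list) > 0L)
  sds <- vapply(basal_list, log_sd, numeric(1))
  nm <- sprintf("%s\nsigma = %.3f", names(basal_list), sds)
  graphics::boxplot(basal_list, log = "y", names = nm,
                    ylab = "Basal fluorescence (log scale)", ...)
  for (i in seq_along(basal_list)) {
    n <- length(basal_list[[i]])
    off <- seq(-0.15, 0.15, length.out = max(n, 2L))[seq_len(n)]
    graphics::points(i + off[order(order(basal_list[[i]]))],
                     basal_list[[i]], pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("steelblue", 0.5))
  }
  invisible(sds)
}
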