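#' Scoring window for a component
#'
#' Time-window mean amplitude scoring uses a half-open window
#' `[window_start_ms, window_end_ms)` on the sample grid at a named channel,
#' which avoids double-counting shared endpoints and keeps scores
#' bit-reproducible.
#'
#' @param component component name.
#' @param window_start_ms,window_end_ms window bounds in ms (start < end).
#' @param channel channel label.
#' @return List of class `"scoring_window"`.
#' @export
scoring_window <- function(component, window_start_ms, window_end_ms, channel) {
  if (window_start_ms >= window_end_ms) stopf("window start must precede end")
  structure(list(component = component, window_start_ms = window_start_ms,
                 window_end_ms = window_end_ms, channel = channel),
            class = "scoring_window")
}

#' Shipped per-component scoring windows
#'
#' Reads the packaged configuration of scoring windows and channels for the
#' six components (duration/frequency mismatch negativity at Fz, P3a at Cz,
#' P3b at Pz, error-related negativity and reward positivity at FCz).
#'
#' @param component optional component name; when given, returns its
#'   [scoring_window()], otherwise the full named list.
#' @export
default_scoring_windows <- function(component = NULL) {
  path <- system.file("extdata", "component_windows.yaml", package = "trialvar")
  cfg <- yaml::read_yaml(path)
  wins <- lapply(names(cfg), function(nm)
    scoring_window(nm, cfg[[nm]]$window_start_ms, cfg[[nm]]$window_end_ms,
                   cfg[[nm]]$channel))
  names(wins) <- names(cfg)
  if (is.null(component)) return(wins)
  if (!component %in% names(wins)) stopf("unknown component '%s'", component)
  wins[[component]]
}

#' Baseline-adjust epochs
#'
#' Subtracts, per trial, the mean of the first `baseline_ms` milliseconds of
#' the epoch from every sample. Idempotent: the baseline mean of the output
#' is zero.
#'
#' @param epochs an `"epoch_set"`.
#' @param baseline_ms baseline duration (default 200 ms; the epoch must
#'   contain at least this much pre-event time).
#' @return The adjusted `"epoch_set"`.
#' @export
baseline_adjust <- function(epochs, baseline_ms = 200) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- -epochs$epoch_start_ms
  if (pre < baseline_ms)
    stopf("epoch has only %g ms before the event; %g ms needed for baseline adjustment",
          pre, baseline_ms)
  sel <- epochs$times_ms < epochs$epoch_start_ms + baseline_ms
  if (!any(sel)) stopf("no samples in the baseline segment")
  epochs$epochs <- lapply(epochs$epochs, function(per_ev)
    lapply(per_ev, function(m) m - rowMeans(m[, sel, drop = FALSE])))
  epochs
}

#' Score time-window mean amplitudes into a trial table
#'
#' One row per trial: the arithmetic mean of the samples with time `t` in
#' `[window_start_ms, window_end_ms)`.
#'
#' @param epochs an `"epoch_set"` (typically after [baseline_adjust()]).
#' @param window a [scoring_window()]; its channel must match the epochs'.
#' @return A `trial_table` data frame.
#' @export
score_mean_amplitude <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(window, "scoring_window"))
  if (!identical(window$channel, epochs$channel))
    stopf("window channel '%s' does not match epoch channel '%s'",
          window$channel, epochs$channel)
  sel <- epochs$times_ms >= window$window_start_ms &
    epochs$times_ms < window$window_end_ms
  if (!any(sel)) stopf("scoring window [%g, %g) selects no samples",
                       window$window_start_ms, window$window_end_ms)
  rows <- list()
  for (pt in names(epochs$epochs)) {
    for (ev in names(epochs$epochs[[pt]])) {
      m <- epochs$epochs[[pt]][[ev]]
      rows[[paste(pt, ev)]] <- data.frame(
        participant_id = pt,
        group = unname(epochs$groups[pt]),
        event = ev,
        trial = as.integer(rownames(m)),
        amplitude = rowMeans(m[, sel, drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_trial_table(out)
}

#' Collapsed-localizer window selection
#'
#' Grand-averages the condition-difference waveform across all participants
#' (groups pooled, equal weight per participant), finds the extremum of the
#' requested polarity inside the search window, and returns a scoring window
#' of `+/- half_width_ms` around the extremum latency, snapped to the sample
#' grid. Ties are broken toward the earliest latency; if the extremum's sign
#' contradicts the requested polarity a warning is raised.
#'
#' @param epochs an `"epoch_set"` containing both events for every
#'   participant.
#' @param events length-2 character: the difference is `events[1] - events[2]`
#'   (e.g. deviant minus standard).
#' @param search_window length-2 numeric, ms range to search.
#' @param polarity `"negative"` or `"positive"`.
#' @param half_width_ms half-width of the returned window (default 25 ms;
#'   published mismatch-negativity windows are 50 ms wide).
#' @param component label for the returned window.
#' @return A [scoring_window()].
#' @export
collapsed_localizer <- function(epochs, events, search_window,
                                polarity = c("negative", "positive"),
                                half_width_ms = 25,
                                component = "localized") {
  polarity <- match.arg(polarity)
  stopifnot(inherits(epochs, "epoch_set"), length(events) == 2L)
  diffs <- lapply(epochs$epochs, function(per_ev) {
    if (!all(events %in% names(per_ev))) return(NULL)
    colMeans(per_ev[[events[1]]]) - colMeans(per_ev[[events[2]]])
  })
  diffs <- diffs[!vapply(diffs, is.null, TRUE)]
  if (!length(diffs)) stopf("no participant has both events %s and %s",
                            events[1], events[2])
  grand <- Reduce(`+`, diffs) / length(diffs)
  sel <- which(epochs$times_ms >= search_window[1] &
                 epochs$times_ms <= search_window[2])
  if (!length(sel)) stopf("search window outside the epoch")
  gs <- grand[sel]
  if (max(gs) - min(gs) < .Machine$double.eps^0.5)
    warnf("grand-average difference wave is flat in the search window; earliest-latency tie-break used")
  pick <- if (polarity == "negative") which(gs == min(gs)) else which(gs == max(gs))
  peak_i <- sel[min(pick)]  # earliest latency on ties
  peak_val <- grand[peak_i]
  if ((polarity == "negative" && peak_val > 0) ||
      (polarity == "positive" && peak_val < 0))
    warnf("extremum at %g ms has sign opposite to the requested %s polarity",
          epochs$times_ms[peak_i], polarity)
  lat <- epochs$times_ms[peak_i]
  snap <- function(t) {
    epochs$times_ms[which.min(abs(epochs$times_ms - t))]
  }
  scoring_window(component, snap(lat - half_width_ms), snap(lat + half_width_ms),
                 epochs$channel)
}

#' Apply the registered minimum-trials inclusion rule
#'
#' Removes entirely every participant with fewer than `min_trials` rows in
#' any event cell (participants missing an event count as zero trials for
#' it). A participant with exactly `min_trials` in each cell is retained.
#'
#' @param table a trial table.
#' @param min_trials inclusion threshold (default 5 trials per condition).
#' @return The filtered `trial_table`, with an `"exclusions"` attribute: a
#'   data frame of excluded participants and their per-event trial counts
#'   (see [exclusion_report()]).
#' @export
filter_min_trials <- function(table, min_trials = 5) {
  table <- validate_trial_table(table)
  evs <- unique(as.character(table$event))
  cnt <- table(table$participant_id, table$event)
  cnt <- as.data.frame.matrix(cnt)
  low <- apply(cnt, 1, function(x) any(x < min_trials))
  excl_ids <- rownames(cnt)[low]
  rep_df <- data.frame(participant_id = excl_ids,
                       cnt[low, , drop = FALSE],
                       row.names = NULL, check.names = FALSE)
  rep_df$min_count <- if (nrow(rep_df)) apply(cnt[low, , drop = FALSE], 1, min) else integer(0)
  out <- table[!(table$participant_id %in% excl_ids), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warnf("all participants excluded by the %d-trial rule", min_trials)
  structure(out, exclusions = rep_df, min_trials = min_trials,
            class = c("trial_table", "data.frame"))
}

#' Exclusion report from [filter_min_trials()]
#' @param table the filtered table returned by [filter_min_trials()].
#' @return Data frame of excluded participants with per-event trial counts.
#' @export
exclusion_report <- function(table) attr(table, "exclusions")
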