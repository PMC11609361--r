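#' Waveform settings for the toy epoch generator
#'
#' Each simulated trial waveform is a constant baseline level plus a
#' component bump scaled by the trial's generating amplitude plus white
#' noise. The bump is either Gaussian-shaped (`shape = "gaussian"`, SD
#' `bump_width_ms`) or a flat boxcar spanning
#' `bump_latency_ms +/- bump_width_ms` (`shape = "flat"`, which makes
#' time-window mean scoring exact).
#'
#' @param sampling_rate_hz sampling rate of the epoch grid.
#' @param epoch_start_ms,epoch_end_ms epoch bounds relative to the event
#'   (start must be negative: pre-event baseline).
#' @param bump_latency_ms bump centre latency.
#' @param bump_width_ms Gaussian SD or boxcar half-width, in ms.
#' @param shape `"gaussian"` or `"flat"`.
#' @param noise_sd white-noise SD (uV).
#' @param baseline_level constant offset added to every sample (uV).
#' @param channel channel label attached to the epochs.
#' @return List of class `"epoch_params"`.
#' @export
epoch_params <- function(sampling_rate_hz = 250, epoch_start_ms = -200,
                         epoch_end_ms = 500, bump_latency_ms = 290,
                         bump_width_ms = 25, shape = c("gaussian", "flat"),
                         noise_sd = 1, baseline_level = 0, channel = "Fz") {
  shape <- match.arg(shape)
  p <- list(sampling_rate_hz = sampling_rate_hz,
            epoch_start_ms = epoch_start_ms, epoch_end_ms = epoch_end_ms,
            bump_latency_ms = bump_latency_ms, bump_width_ms = bump_width_ms,
            shape = shape, noise_sd = noise_sd,
            baseline_level = baseline_level, channel = channel)
  if (p$epoch_start_ms >= 0 || p$epoch_end_ms <= 0)
    stopf("epoch must span the event: epoch_start_ms < 0 < epoch_end_ms")
  if (p$bump_latency_ms - p$bump_width_ms < p$epoch_start_ms ||
      p$bump_latency_ms + p$bump_width_ms > p$epoch_end_ms)
    stopf("epoch bounds (%g, %g) ms exclude the bump window around %g ms",
          p$epoch_start_ms, p$epoch_end_ms, p$bump_latency_ms)
  structure(p, class = "epoch_params")
}

epoch_times <- function(p) {
  dt <- 1000 / p$sampling_rate_hz
  seq(p$epoch_start_ms, p$epoch_end_ms - dt / 2, by = dt)
}

new_epoch_set <- function(epochs, groups, p) {
  structure(list(epochs = epochs, groups = groups,
                 times_ms = epoch_times(p),
                 sampling_rate_hz = p$sampling_rate_hz,
                 epoch_start_ms = p$epoch_start_ms,
                 epoch_end_ms = p$epoch_end_ms,
                 channel = p$channel),
            class = "epoch_set")
}

#' Simulate toy epoched waveforms from the trial-level generator
#'
#' Draws a trial table from `cfg` (or uses a supplied one) and expands each
#' trial into a waveform per [epoch_params()]. Scoring the bump window of the
#' noise-free output with [score_mean_amplitude()] recovers the generating
#' amplitudes (exactly for the flat bump, up to the window-average shape
#' factor for the Gaussian bump).
#'
#' @param cfg a [generator_config()].
#' @param waveform_params an [epoch_params()] list.
#' @param table optional trial table to expand (defaults to
#'   `simulate_trial_table(cfg)`).
#' @return An object of class `"epoch_set"`: per participant and event a
#'   trials x samples matrix (rownames = trial indices), plus the sampling
#'   grid, channel and participant-to-group mapping.
#' @export
simulate_epochs <- function(cfg, waveform_params = epoch_params(),
                            table = NULL) {
  p <- waveform_params
  if (!inherits(p, "epoch_params")) p <- do.call(epoch_params, p)
  if (is.null(table)) table <- simulate_trial_table(cfg)
  validate_trial_table(table)
  tt <- epoch_times(p)
  bump <- if (p$shape == "flat")
    as.numeric(abs(tt - p$bump_latency_ms) <= p$bump_width_ms)
  else exp(-0.5 * ((tt - p$bump_latency_ms) / p$bump_width_ms)^2)
  # keep the bump strictly post-event so the baseline segment stays clean
  bump[tt < 0] <- 0

  with_seed(derive_seed(cfg$seed, 7919), {
    parts <- unique(table$participant_id)
    epochs <- lapply(parts, function(pt) {
      sub <- table[table$participant_id == pt, , drop = FALSE]
      evs <- unique(sub$event)
      out <- lapply(evs, function(ev) {
        amp <- sub$amplitude[sub$event == ev]
        trl <- sub$trial[sub$event == ev]
        m <- outer(amp, bump) + p$baseline_level
        if (p$noise_sd > 0)
          m <- m + matrix(stats::rnorm(length(m), 0, p$noise_sd),
                          nrow(m), ncol(m))
        rownames(m) <- trl
        m
      })
      names(out) <- evs
      out
    })
    names(epochs) <- parts
    groups <- vapply(parts, function(pt)
      as.character(table$group[table$participant_id == pt][1]), character(1))
    new_epoch_set(epochs, groups, p)
  })
}

#' Write / read an epoch set as per-participant CSV matrices + JSON sidecar
#'
#' The directory holds one `<participant>_<event>.csv` numeric matrix per
#' cell (rows = trials, rownames in a leading `trial` column) and a
#' `metadata.json` sidecar with the sampling grid, channel and group map.
#' @param epochs an `"epoch_set"`.
#' @param dir directory to create/read.
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pt in names(epochs$epochs)) {
    for (ev in names(epochs$epochs[[pt]])) {
      m <- epochs$epochs[[pt]][[ev]]
      df <- data.frame(trial = as.integer(rownames(m)), m, check.names = FALSE)
      utils::write.csv(df, file.path(dir, paste0(pt, "_", ev, ".csv")),
                       row.names = FALSE)
    }
  }
  meta <- list(sampling_rate_hz = epochs$sampling_rate_hz,
               epoch_start_ms = epochs$epoch_start_ms,
               epoch_end_ms = epochs$epoch_end_ms,
               channel = epochs$channel,
               groups = as.list(epochs$groups))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- list.files(dir, pattern = "\\.csv$")
  epochs <- list()
  for (f in files) {
    stem <- sub("\\.csv$", "", f)
    us <- regexpr("_[^_]+$", stem)
    pt <- substr(stem, 1, us - 1)
    ev <- substr(stem, us + 1, nchar(stem))
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$trial
    dimnames(m)[[2]] <- NULL
    epochs[[pt]][[ev]] <- m
  }
  p <- list(sampling_rate_hz = meta$sampling_rate_hz,
            epoch_start_ms = meta$epoch_start_ms,
            epoch_end_ms = meta$epoch_end_ms, channel = meta$channel)
  structure(list(epochs = epochs, groups = unlist(meta$groups),
                 times_ms = seq(p$epoch_start_ms,
                                p$epoch_end_ms - 500 / p$sampling_rate_hz,
                                by = 1000 / p$sampling_rate_hz),
                 sampling_rate_hz = p$sampling_rate_hz,
                 epoch_start_ms = p$epoch_start_ms,
                 epoch_end_ms = p$epoch_end_ms,
                 channel = p$channel),
            class = "epoch_set")
}
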