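# Shared fixtures: small generator settings and memoized fits so that
# several test files can reuse the same MCMC run.

quick_cfg <- function(...) {
  args <- list(n_per_group = 12, trials_per_condition = 10, dropout_rate = 0,
               tau_loc = c(1.3, 0.8), tau_scale = c(0.25, 0.08), seed = 11)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) assign(key, force(expr), envir = .fit_cache)
  get(key, envir = .fit_cache)
}

# small default location-scale fit reused across tests
small_fit <- function() {
  cached_fit("small_fit", {
    tab <- simulate_trial_table(quick_cfg())
    suppressWarnings(melsm(amplitude ~ event * group, data = tab,
                           chains = 2, iter = 700, warmup = 350, seed = 5))
  })
}

# hand-built epoch set: one participant/event per matrix supplied
make_epochs <- function(mats, groups = NULL, sampling_rate_hz = 250,
                        epoch_start_ms = -200, epoch_end_ms = 500,
                        channel = "Fz") {
  dt <- 1000 / sampling_rate_hz
  times <- seq(epoch_start_ms, epoch_end_ms - dt / 2, by = dt)
  for (pt in names(mats)) for (ev in names(mats[[pt]])) {
    stopifnot(ncol(mats[[pt]][[ev]]) == length(times))
    if (is.null(rownames(mats[[pt]][[ev]])))
      rownames(mats[[pt]][[ev]]) <- seq_len(nrow(mats[[pt]][[ev]]))
  }
  if (is.null(groups)) groups <- stats::setNames(rep("NP", length(mats)), names(mats))
  structure(list(epochs = mats, groups = groups, times_ms = times,
                 sampling_rate_hz = sampling_rate_hz,
                 epoch_start_ms = epoch_start_ms, epoch_end_ms = epoch_end_ms,
                 channel = channel),
            class = "epoch_set")
}

# build a contrast_result table (scale portion) from three
# (median, low, high) triples: reference event, other event, difference
fake_scale_contrasts <- function(ref, oth, dif) {
  row <- function(nm, x) data.frame(
    name = nm, median = x[1], cri_low = x[2], cri_high = x[3],
    excludes_zero = x[2] > 0 | x[3] < 0,
    scale_percent_change = 100 * (exp(x[1]) - 1),
    portion = "scale")
  out <- rbind(row("ref", ref), row("other", oth), row("difference", dif))
  class(out) <- c("contrast_result", "data.frame")
  out
}
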