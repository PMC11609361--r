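ns <- 175  # samples on the default grid (-200..500 ms at 250 Hz)

test_that("baseline adjustment removes constants and is idempotent", {
  m <- matrix(3, 2, ns)
  ep <- make_epochs(list(P1 = list(standard = m)))
  adj <- baseline_adjust(ep)
  expect_equal(max(abs(adj$epochs$P1$standard)), 0)

  # baseline at 2 uV, post-event at 7 uV -> post-event becomes 5 uV
  times <- ep$times_ms
  m2 <- matrix(rep(ifelse(times < 0, 2, 7), each = 1), 1, ns)
  ep2 <- make_epochs(list(P1 = list(standard = m2)))
  adj2 <- baseline_adjust(ep2)
  expect_equal(unique(adj2$epochs$P1$standard[1, times >= 0]), 5)
  expect_equal(unique(adj2$epochs$P1$standard[1, times < 0]), 0)

  # idempotence on arbitrary data
  set.seed(1)
  m3 <- matrix(rnorm(3 * ns), 3, ns)
  ep3 <- make_epochs(list(P1 = list(standard = m3)))
  once <- baseline_adjust(ep3)
  twice <- baseline_adjust(once)
  expect_equal(twice$epochs$P1$standard, once$epochs$P1$standard)
  # direct recomputation oracle: subtracting the first-200-ms mean by hand
  sel <- ep3$times_ms < 0
  oracle <- m3 - rowMeans(m3[, sel, drop = FALSE])
  expect_equal(once$epochs$P1$standard, oracle, ignore_attr = TRUE)
})

test_that("baseline adjustment requires enough pre-event time", {
  m <- matrix(0, 1, 50)
  ep <- make_epochs(list(P1 = list(standard = m)), epoch_start_ms = -100,
                    epoch_end_ms = 100)
  expect_error(baseline_adjust(ep), "100 ms")
})

test_that("time-window mean scoring matches brute-force oracles", {
  ep <- make_epochs(list(P1 = list(standard = matrix(5, 1, ns))))
  w <- scoring_window("any", 100, 300, "Fz")
  tab <- score_mean_amplitude(ep, w)
  expect_equal(tab$amplitude, 5)

  # linear ramp 0 -> 10 across the window
  times <- ep$times_ms
  ramp <- ifelse(times < 100, 0, ifelse(times >= 300, 10, (times - 100) / 20))
  ep2 <- make_epochs(list(P1 = list(standard = matrix(ramp, 1, ns))))
  tab2 <- score_mean_amplitude(ep2, w)
  sel <- times >= 100 & times < 300
  expect_equal(tab2$amplitude, mean(ramp[sel]))        # exact oracle
  expect_equal(tab2$amplitude, 5, tolerance = 0.025)   # half-sample correction

  expect_error(score_mean_amplitude(ep, scoring_window("x", 100, 300, "Cz")),
               "channel")
  expect_error(score_mean_amplitude(ep, scoring_window("x", 600, 700, "Fz")),
               "no samples")
})

test_that("scoring is linear in the waveforms", {
  set.seed(2)
  x <- matrix(rnorm(2 * ns), 2, ns)
  y <- matrix(rnorm(2 * ns), 2, ns)
  w <- scoring_window("any", 0, 400, "Fz")
  s <- function(m) score_mean_amplitude(
    make_epochs(list(P1 = list(standard = m))), w)$amplitude
  expect_equal(s(2 * x + 3 * y), 2 * s(x) + 3 * s(y))
})

test_that("baseline adjustment commutes with scoring", {
  set.seed(3)
  m <- matrix(rnorm(4 * ns), 4, ns)
  ep <- make_epochs(list(P1 = list(standard = m)))
  w <- scoring_window("any", 100, 300, "Fz")
  a <- score_mean_amplitude(baseline_adjust(ep), w)$amplitude
  bl <- rowMeans(m[, ep$times_ms < 0, drop = FALSE])
  b <- score_mean_amplitude(ep, w)$amplitude - bl
  expect_equal(a, b)
})

test_that("simulated epochs round-trip through scoring", {
  cfg <- quick_cfg(n_per_group = 4, trials_per_condition = 6, seed = 31)
  # flat bump spanning the scoring window, no noise: exact recovery
  wp <- epoch_params(bump_latency_ms = 290, bump_width_ms = 40,
                     shape = "flat", noise_sd = 0, baseline_level = 0)
  tab0 <- simulate_trial_table(cfg)
  ep <- simulate_epochs(cfg, wp, table = tab0)
  scored <- score_mean_amplitude(baseline_adjust(ep),
                                 scoring_window("mmn_d", 265, 315, "Fz"))
  key <- function(t) paste(t$participant_id, t$event, t$trial)
  m <- match(key(tab0), key(scored))
  expect_equal(scored$amplitude[m], tab0$amplitude, tolerance = 1e-10)

  # nonzero baseline level leaves baseline-adjusted scores unchanged
  wp2 <- epoch_params(bump_latency_ms = 290, bump_width_ms = 40,
                      shape = "flat", noise_sd = 0, baseline_level = 2)
  ep2 <- simulate_epochs(cfg, wp2, table = tab0)
  scored2 <- score_mean_amplitude(baseline_adjust(ep2),
                                  scoring_window("mmn_d", 265, 315, "Fz"))
  expect_equal(scored2$amplitude, scored$amplitude, tolerance = 1e-10)

  # Gaussian bump with noise: high correlation with generating amplitudes
  wp3 <- epoch_params(bump_latency_ms = 290, bump_width_ms = 25,
                      shape = "gaussian", noise_sd = 0.1)
  ep3 <- simulate_epochs(cfg, wp3, table = tab0)
  scored3 <- score_mean_amplitude(baseline_adjust(ep3),
                                  scoring_window("mmn_d", 265, 315, "Fz"))
  m3 <- match(key(tab0), key(scored3))
  expect_gt(stats::cor(scored3$amplitude[m3], tab0$amplitude), 0.99)
})

test_that("epoch sets round-trip through the CSV directory format", {
  cfg <- quick_cfg(n_per_group = 2, trials_per_condition = 3, seed = 5)
  ep <- simulate_epochs(cfg, epoch_params(noise_sd = 0.5))
  d <- file.path(tempdir(), "epochs-test")
  write_epoch_set(ep, d)
  back <- read_epoch_set(d)
  expect_equal(back$epochs$P001$standard, ep$epochs$P001$standard,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$channel, ep$channel)
  expect_equal(back$groups[["P003"]], "patient")
  unlink(d, recursive = TRUE)
})

test_that("collapsed localizer finds the injected peak and honors tie-breaks", {
  # 1 kHz grid so the published 265-315 ms window is representable exactly
  ns2 <- 700
  mk1 <- function(v) matrix(v, 1, ns2, byrow = TRUE)
  times <- seq(-200, 499, by = 1)
  bump <- -3 * exp(-0.5 * ((times - 290) / 10)^2)  # negative peak at 290 ms
  mk <- function(extra) list(standard = mk1(numeric(ns2)), deviant = mk1(extra))
  ep <- make_epochs(list(P1 = mk(bump), P2 = mk(bump)),
                    sampling_rate_hz = 1000)
  w <- collapsed_localizer(ep, c("deviant", "standard"),
                           search_window = c(100, 400), polarity = "negative")
  expect_equal(w$window_start_ms, 265)  # the published MMN-D window
  expect_equal(w$window_end_ms, 315)

  # two equal extrema -> earliest chosen
  bump2 <- numeric(ns2)
  bump2[times %in% c(200, 300)] <- -5
  ep2 <- make_epochs(list(P1 = mk(bump2)), sampling_rate_hz = 1000)
  w2 <- collapsed_localizer(ep2, c("deviant", "standard"), c(100, 400),
                            polarity = "negative")
  expect_equal(mean(c(w2$window_start_ms, w2$window_end_ms)), 200)

  # positive-polarity search on a negative-only wave warns
  expect_warning(
    collapsed_localizer(ep, c("deviant", "standard"), c(100, 400),
                        polarity = "positive"), "opposite")
  # flat wave warns about the tie-break
  ep3 <- make_epochs(list(P1 = mk(numeric(ns2))), sampling_rate_hz = 1000)
  expect_warning(
    collapsed_localizer(ep3, c("deviant", "standard"), c(100, 400)), "flat")
})

test_that("the minimum-trials filter implements the registered rule", {
  mk_rows <- function(id, grp, ev, n) if (n == 0) NULL else
    data.frame(participant_id = id, group = grp, event = ev,
               trial = seq_len(n), amplitude = rnorm(n))
  set.seed(4)
  tab <- do.call(rbind, list(
    mk_rows("A", "NP", "standard", 4), mk_rows("A", "NP", "deviant", 50),
    mk_rows("B", "NP", "standard", 5), mk_rows("B", "NP", "deviant", 5),
    mk_rows("C", "patient", "standard", 12), mk_rows("C", "patient", "deviant", 3),
    mk_rows("D", "patient", "standard", 8), mk_rows("D", "patient", "deviant", 9)))
  out <- filter_min_trials(tab, 5)
  expect_setequal(unique(as.character(out$participant_id)), c("B", "D"))
  rep <- exclusion_report(out)
  expect_setequal(rep$participant_id, c("A", "C"))
  expect_equal(rep$min_count[rep$participant_id == "A"], 4)

  # participant with exactly 5 + 5 (10 total) is retained
  expect_true("B" %in% out$participant_id)

  # min_trials = 1 excludes nobody when all cells are nonempty
  out1 <- filter_min_trials(tab, 1)
  expect_equal(nrow(exclusion_report(out1)), 0)

  # idempotence and monotonicity in the threshold
  out2 <- filter_min_trials(out, 5)
  expect_equal(out2$amplitude, out$amplitude)
  expect_setequal(unique(as.character(out2$participant_id)),
                  unique(as.character(out$participant_id)))
  out9 <- suppressWarnings(filter_min_trials(tab, 9))
  expect_true(all(unique(out9$participant_id) %in% unique(out$participant_id)))
})

test_that("shipped component windows match the published scoring setup", {
  wins <- default_scoring_windows()
  expect_setequal(names(wins), c("mmn_d", "mmn_f", "p3a", "p3b", "ern", "rewp"))
  w <- default_scoring_windows("mmn_d")
  expect_equal(c(w$window_start_ms, w$window_end_ms), c(265, 315))
  expect_equal(w$channel, "Fz")
  expect_equal(default_scoring_windows("ern")$channel, "FCz")
  expect_error(default_scoring_windows("nope"), "unknown component")
})
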