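test_that("posterior summaries match brute-force percentile oracles", {
  r <- melsm_summarize(1:100, name = "x")
  expect_equal(r$median, 50.5)
  expect_equal(r$cri_low, unname(quantile(1:100, 0.025)))  # 3.475
  expect_equal(r$cri_high, unname(quantile(1:100, 0.975))) # 97.525
  expect_equal(r$cri_low, 3.475)
  expect_true(r$excludes_zero)

  cc <- melsm_summarize(rep(3.2, 50))
  expect_equal(cc$median, 3.2)
  expect_equal(cc$cri_low, 3.2)
  expect_equal(cc$cri_high, 3.2)
  expect_true(cc$excludes_zero)
  c0 <- melsm_summarize(rep(0, 50))
  expect_false(c0$excludes_zero)
})

test_that("percent change in within-person SD back-transforms log-SD effects", {
  expect_equal(percent_change_in_sd(-0.02), 100 * (exp(-0.02) - 1))
  expect_equal(percent_change_in_sd(-0.02), -1.9801, tolerance = 1e-4)
  expect_equal(percent_change_in_sd(0), 0)
  expect_equal(percent_change_in_sd(log(2)), 100)
  expect_error(percent_change_in_sd(NA_real_))
})

test_that("hypothesis decision rules reproduce the registered logic", {
  # interaction CrI excludes zero with LOWER patient variability -> opposite
  mmn_d <- fake_scale_contrasts(c(0.04, -0.02, 0.10),
                                c(0.02, -0.04, 0.08),
                                c(-0.02, -0.03, -0.004))
  expect_equal(decide_hypothesis(mmn_d, "greater")$verdict, "opposite-direction")

  # all scale CrIs contain zero: null prediction supported, directional not
  rewp <- fake_scale_contrasts(c(0.003, -0.07, 0.08),
                               c(-0.01, -0.08, 0.07),
                               c(-0.01, -0.07, 0.06))
  expect_equal(decide_hypothesis(rewp, "null")$verdict, "supported")
  expect_equal(decide_hypothesis(rewp, "greater")$verdict, "not supported")

  # group parameter excludes zero with patients higher -> supported
  up <- fake_scale_contrasts(c(0.2, 0.1, 0.3),
                             c(0.25, 0.12, 0.4),
                             c(0.05, -0.02, 0.12))
  expect_equal(decide_hypothesis(up, "greater")$verdict, "supported")
  expect_equal(decide_hypothesis(up, "null")$verdict, "not supported")

  # interaction route: one event up, the other comparable
  inter <- fake_scale_contrasts(c(0.02, -0.03, 0.07),
                                c(0.22, 0.10, 0.35),
                                c(0.20, 0.05, 0.36))
  expect_equal(decide_hypothesis(inter, "greater")$verdict, "supported")

  expect_error(decide_hypothesis(mmn_d[1:2, ], "greater"), "three")
})

test_that("degenerate inputs are rejected", {
  tab <- simulate_trial_table(quick_cfg(n_per_group = 4, seed = 2))
  expect_error(melsm(amplitude ~ event * group, data = tab, chains = 1),
               "2 chains")
  one <- tab[tab$participant_id %in% c("P001", "P005"), ]
  one <- droplevels(one)
  expect_error(suppressWarnings(
    melsm(amplitude ~ event * group, data = one, iter = 200, warmup = 100)),
    "fewer than 2 participants")
  bad <- tab
  bad$amplitude[3] <- NA
  expect_error(melsm(amplitude ~ event * group, data = bad), "finite")
})

test_that("fits are reproducible given the seed", {
  tab <- simulate_trial_table(quick_cfg(n_per_group = 5, trials_per_condition = 6))
  f1 <- suppressWarnings(melsm(amplitude ~ event * group, data = tab,
                               chains = 2, iter = 250, warmup = 120, seed = 42))
  f2 <- suppressWarnings(melsm(amplitude ~ event * group, data = tab,
                               chains = 2, iter = 250, warmup = 120, seed = 42))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(melsm(amplitude ~ event * group, data = tab,
                               chains = 2, iter = 250, warmup = 120, seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("without random effects the location posterior matches OLS", {
  cfg <- quick_cfg(n_per_group = 30, trials_per_condition = 20,
                   tau_loc = c(0, 0), tau_scale = c(0, 0),
                   eta = c(log(2), 0, 0, 0), seed = 14)
  tab <- simulate_trial_table(cfg)
  fit <- suppressWarnings(
    melsm(amplitude ~ event * group, data = tab, scale = ~ 1,
          random = NULL, scale_random = NULL,
          chains = 2, iter = 1000, warmup = 400, seed = 6))
  ols <- stats::lm(amplitude ~ event * group, data = tab)
  s <- summary(fit)
  loc <- s[startsWith(s$parameter, "loc_"), ]
  mcse <- loc$sd / sqrt(pmax(loc$ess_bulk, 10))
  expect_true(all(abs(loc$median - stats::coef(ols)) <
                    3 * mcse + 0.02 * abs(stats::coef(ols)) + 0.01))
  # residual-SD intercept agrees with the OLS residual scale
  expect_equal(s$median[s$parameter == "scl_(Intercept)"],
               log(summary(ols)$sigma), tolerance = 0.02)
})

test_that("homoscedastic location estimates agree with restricted maximum likelihood", {
  cfg <- quick_cfg(n_per_group = 25, trials_per_condition = 12,
                   tau_loc = c(1.2, 0.6), tau_scale = c(0, 0),
                   eta = c(log(3), 0, 0, 0), seed = 15)
  tab <- simulate_trial_table(cfg)
  fit <- suppressWarnings(
    melsm(amplitude ~ event * group, data = tab, scale = ~ 1,
          random = ~ event, scale_random = NULL,
          chains = 2, iter = 900, warmup = 400, seed = 7))
  ref <- lme4::lmer(amplitude ~ event * group + (event | participant_id),
                    data = tab, REML = TRUE,
                    control = lme4::lmerControl(optimizer = "bobyqa"))
  fx <- lme4::fixef(ref)
  s <- summary(fit)
  loc <- s[startsWith(s$parameter, "loc_"), ]
  expect_true(all(abs(loc$median - fx) < pmax(0.15, 3 * loc$sd / sqrt(pmax(loc$ess_bulk, 10)))))
  # random-effect SDs in the same ballpark as REML
  vc <- as.data.frame(lme4::VarCorr(ref))
  tau_ref <- sqrt(vc$vcov[1:2])
  tau_fit <- s$median[startsWith(s$parameter, "tau_loc_")]
  expect_equal(tau_fit, tau_ref, tolerance = 0.35)
})

test_that("posteriors agree with an independent Gibbs sampler on a small model", {
  skip_if_not_installed("rjags")
  cfg <- quick_cfg(n_per_group = 12, trials_per_condition = 10,
                   tau_loc = c(1.2, 0.7), tau_scale = c(0.25, 0.1),
                   eta = c(1.0, 0.1, 0.05, -0.05), seed = 16)
  tab <- simulate_trial_table(cfg)
  fit <- suppressWarnings(
    melsm(amplitude ~ event * group, data = tab, cor_re = FALSE,
          chains = 2, iter = 1500, warmup = 700, seed = 8))

  X <- stats::model.matrix(~ event * group, tab)
  e <- as.numeric(tab$event == levels(tab$event)[2])
  pid <- as.integer(factor(tab$participant_id))
  model_str <- "
  model {
    for (n in 1:N) {
      mu[n] <- inprod(X[n,], beta) + b[pid[n],1] + b[pid[n],2] * e[n]
      lsig[n] <- inprod(X[n,], eta) + v[pid[n],1] + v[pid[n],2] * e[n]
      y[n] ~ dnorm(mu[n], exp(-2 * lsig[n]))
    }
    for (j in 1:J) {
      b[j,1] ~ dnorm(0, 1/pow(tau[1],2)); b[j,2] ~ dnorm(0, 1/pow(tau[2],2))
      v[j,1] ~ dnorm(0, 1/pow(tau[3],2)); v[j,2] ~ dnorm(0, 1/pow(tau[4],2))
    }
    for (k in 1:4) {
      beta[k] ~ dnorm(0, 0.01)
      eta[k] ~ dnorm(0, 1)
      tau[k] ~ dt(0, 1/6.25, 3) T(0,)
    }
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = tab$amplitude, X = X, e = e,
                                      pid = pid, N = nrow(tab), J = max(pid)),
                          n.chains = 2, n.adapt = 500, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("beta", "eta", "tau"), n.iter = 3000,
                            progress.bar = "none")
  jd <- do.call(rbind, lapply(sm, as.matrix))
  jmed <- apply(jd, 2, stats::median)

  s <- summary(fit)
  ours <- s$median
  names(ours) <- s$parameter
  pick <- c("loc_(Intercept)", "loc_eventdeviant", "loc_grouppatient",
            "loc_eventdeviant:grouppatient",
            "scl_(Intercept)", "scl_eventdeviant", "scl_grouppatient",
            "scl_eventdeviant:grouppatient")
  theirs <- jmed[c("beta[1]", "beta[2]", "beta[3]", "beta[4]",
                   "eta[1]", "eta[2]", "eta[3]", "eta[4]")]
  sds <- s$sd[match(pick, s$parameter)]
  expect_true(all(abs(ours[pick] - theirs) < pmax(0.3 * sds + 0.05, 0.08)),
              info = paste(round(ours[pick] - theirs, 3), collapse = ", "))
})

test_that("location and scale separate under shifts and scalings", {
  cfg <- quick_cfg(n_per_group = 10, trials_per_condition = 8, seed = 17)
  tab <- simulate_trial_table(cfg)
  fit0 <- suppressWarnings(melsm(amplitude ~ event * group, data = tab,
                                 chains = 2, iter = 600, warmup = 300, seed = 9))
  shift <- tab; shift$amplitude <- shift$amplitude + 50
  fit1 <- suppressWarnings(melsm(amplitude ~ event * group, data = shift,
                                 chains = 2, iter = 600, warmup = 300, seed = 9))
  s0 <- summary(fit0); s1 <- summary(fit1)
  scl <- startsWith(s0$parameter, "scl_")
  expect_true(all(abs(s1$median[scl] - s0$median[scl]) < 0.08))
  i0 <- s0$median[s0$parameter == "loc_(Intercept)"]
  i1 <- s1$median[s1$parameter == "loc_(Intercept)"]
  expect_equal(i1 - i0, 50, tolerance = 0.05)

  dbl <- tab; dbl$amplitude <- dbl$amplitude * 3
  fit2 <- suppressWarnings(melsm(amplitude ~ event * group, data = dbl,
                                 chains = 2, iter = 600, warmup = 300, seed = 9))
  s2 <- summary(fit2)
  sc_int0 <- s0$median[s0$parameter == "scl_(Intercept)"]
  sc_int2 <- s2$median[s2$parameter == "scl_(Intercept)"]
  expect_equal(sc_int2 - sc_int0, log(3), tolerance = 0.06)
  # location effects scale by 3 up to Monte-Carlo error of both fits
  loc <- startsWith(s0$parameter, "loc_")
  mc <- 3 * (3 * s0$sd[loc] / sqrt(pmax(s0$ess_bulk[loc], 20)) +
               s2$sd[loc] / sqrt(pmax(s2$ess_bulk[loc], 20)))
  expect_true(all(abs(s2$median[loc] - 3 * s0$median[loc]) < mc + 0.1))
  # non-intercept scale coefficients unchanged by rescaling
  scl_dev <- s0$parameter == "scl_eventdeviant"
  expect_lt(abs(s2$median[scl_dev] - s0$median[scl_dev]), 0.06)
})

test_that("fit methods expose coherent quantities", {
  fit <- small_fit()
  tab <- fit$data
  expect_s3_class(fit, "melsm")
  expect_output(print(fit), "location-scale")
  co <- coef(fit)
  expect_named(co, c("location", "scale"))
  expect_length(co$location, 4)
  expect_equal(length(predict(fit)), nrow(tab))
  expect_true(all(predict(fit, type = "scale") > 0))
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.5)
  rp <- residuals(fit, type = "pearson")
  expect_lt(abs(stats::sd(rp) - 1), 0.25)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(tab), 3))
  expect_lt(abs(mean(sim) - mean(tab$amplitude)), 1.5)
  re <- melsm_ranef(fit)
  expect_equal(nrow(re), length(unique(tab$participant_id)))
  # group contrasts carry percent-change annotation on the scale rows
  ct <- group_contrasts(fit)
  expect_equal(nrow(ct), 6)
  expect_true(all(is.finite(ct$scale_percent_change[ct$portion == "scale"])))
  # drawwise identity: difference contrast equals difference of event contrasts
  dr <- melsm_draws(fit)
  dif <- melsm_summarize(fit, "scl_eventdeviant:grouppatient")
  byhand <- melsm_summarize(
    dr[, "scl_grouppatient"] + dr[, "scl_eventdeviant:grouppatient"] -
      dr[, "scl_grouppatient"])
  expect_equal(dif$median, byhand$median)
  expect_equal(dif$cri_low, byhand$cri_low)
})

test_that("prior draws propagate through the reduced model honestly", {
  # simulation-based-calibration smoke test on the no-random-effect model:
  # rank of the true parameter among posterior draws should look uniform
  set.seed(33)
  K <- 16
  ranks <- matrix(NA_real_, K, 2)
  for (k in seq_len(K)) {
    beta0 <- rnorm(1, 0, 2)       # narrowed prior slice for a cheap check
    eta0 <- rnorm(1, 0, 0.5)
    df <- data.frame(participant_id = rep(c("A", "B", "C", "D"), each = 8),
                     amplitude = rnorm(32, beta0, exp(eta0)))
    fit <- suppressWarnings(
      melsm(amplitude ~ 1, data = df, scale = ~ 1, random = NULL,
            scale_random = NULL,
            priors = melsm_priors(beta_sd = 2, eta_sd = 0.5),
            chains = 2, iter = 500, warmup = 250, seed = 100 + k))
    dr <- melsm_draws(fit)
    ranks[k, 1] <- mean(dr[, "loc_(Intercept)"] < beta0)
    ranks[k, 2] <- mean(dr[, "scl_(Intercept)"] < eta0)
  }
  # uniform ranks have mean 0.5 and SD sqrt(1/12); allow 3 SEs
  for (j in 1:2) {
    expect_lt(abs(mean(ranks[, j]) - 0.5), 3 * sqrt(1 / 12 / K))
    expect_gt(stats::sd(ranks[, j]), 0.1)
  }
})
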