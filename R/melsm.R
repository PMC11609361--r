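#' Prior settings for [melsm()]
#'
#' Weakly informative defaults: Normal(0, `beta_sd`^2) on location fixed
#' effects (microvolt scale), Normal(0, `eta_sd`^2) on scale fixed effects
#' (log-SD scale), half-Student-t(`tau_df`, `tau_scale`) on random-effect
#' SDs, and an LKJ(`lkj_eta`) prior on the random-effect correlation matrix
#' (uniform over correlation matrices at the default `lkj_eta = 1`).
#'
#' @param beta_sd,eta_sd prior SDs for the fixed effects (`eta_sd` may be a
#'   vector recycled over scale coefficients).
#' @param tau_df,tau_scale half-t degrees of freedom and scale for the
#'   random-effect SDs.
#' @param lkj_eta LKJ concentration for the random-effect correlations.
#' @return A list of class `"melsm_priors"`.
#' @export
melsm_priors <- function(beta_sd = 10, eta_sd = 1, tau_df = 3,
                         tau_scale = 2.5, lkj_eta = 1) {
  structure(list(beta_sd = beta_sd, eta_sd = eta_sd, tau_df = tau_df,
                 tau_scale = tau_scale, lkj_eta = lkj_eta),
            class = "melsm_priors")
}

#' Fit a Bayesian mixed-effects location-scale model to single-trial ERP scores
#'
#' Models each single-trial amplitude as Gaussian with a linear predictor for
#' the mean (location) and a log-linear predictor for the residual standard
#' deviation (scale), each carrying fixed effects and per-participant random
#' effects:
#' \deqn{y_{ij} \sim N(x_{ij}'\beta + z_{ij}'u_i,\ \exp(w_{ij}'\eta + z_{ij}'v_i)^2)}
#' with \eqn{(u_i, v_i)} jointly multivariate normal,
#' \eqn{\Sigma = \mathrm{diag}(\tau)\,\Omega\,\mathrm{diag}(\tau)}.
#' Positive scale coefficients mean more within-person variability; a scale
#' coefficient \eqn{\eta} maps to a `100 * (exp(eta) - 1)` percent change in
#' within-person SD (see [percent_change_in_sd()]).
#'
#' Posterior sampling uses an adaptive Markov chain Monte Carlo scheme with
#' conjugate Gibbs updates for all location parameters, adaptive
#' random-walk Metropolis updates for the scale parameters, and an
#' interweaved rescaling move for the random-effect SDs. Convergence is
#' checked with rank-normalized split R-hat and bulk effective sample size;
#' a warning is attached (and emitted) when any reported parameter has
#' R-hat > 1.01 or bulk ESS < 400.
#'
#' A location-only (homoscedastic) model is obtained with `scale = ~1` and
#' `scale_random = NULL`.
#'
#' @param formula model formula for the location portion, e.g.
#'   `amplitude ~ event * group`.
#' @param data a trial table (see [simulate_trial_table()]), or any data frame
#'   with the model variables and a participant identifier column.
#' @param scale one-sided formula for the scale (log residual SD) portion.
#' @param random one-sided formula for the per-participant random-effect
#'   design on the location portion (default intercept + event slope);
#'   `NULL` drops location random effects.
#' @param scale_random as `random`, for the scale portion; `NULL` drops scale
#'   random effects.
#' @param participant name of the participant identifier column.
#' @param chains number of chains (at least 2).
#' @param iter iterations per chain, including warmup.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; fits are reproducible given the seed.
#' @param priors a [melsm_priors()] object.
#' @param cor_re estimate correlations among the random effects
#'   (`TRUE`, the default) or fix them to zero.
#' @param loglik_draws number of (thinned, evenly spaced) posterior draws at
#'   which the pointwise log-likelihood matrix is stored for [psis_loo()].
#' @param re_store number of thinned random-effect draws stored for
#'   [simulate.melsm()] and [predict.melsm()].
#' @return An object of class `"melsm"`; see [summary.melsm()],
#'   [coef.melsm()], [melsm_summarize()], [group_contrasts()], [psis_loo()].
#' @references The model is the location-scale generalization of the
#'   multilevel model; the scale portion makes within-person residual
#'   variability a modelled quantity rather than a nuisance.
#' @export
#' @examples
#' cfg <- generator_config(n_per_group = 8, trials_per_condition = 10,
#'                         dropout_rate = 0, tau_scale = c(0.2, 0.05))
#' tab <- simulate_trial_table(cfg)
#' \donttest{
#' fit <- melsm(amplitude ~ event * group, data = tab,
#'              chains = 2, iter = 400, warmup = 200, seed = 1)
#' summary(fit)
#' }
melsm <- function(formula = amplitude ~ event * group,
                  data,
                  scale = ~ event * group,
                  random = ~ event,
                  scale_random = ~ event,
                  participant = "participant_id",
                  chains = 2L,
                  iter = 2000L,
                  warmup = floor(iter / 2),
                  seed = 1L,
                  priors = melsm_priors(),
                  cor_re = TRUE,
                  loglik_draws = 1000L,
                  re_store = 100L) {
  cl <- match.call()
  if (chains < 2L) stopf("at least 2 chains are required")
  if (warmup < 50L || warmup >= iter)
    stopf("warmup must be >= 50 and smaller than iter")
  if (!participant %in% names(data))
    stopf("participant column '%s' not found in data", participant)

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
    stopf("response must be finite numeric (non-finite amplitudes found)")
  X <- stats::model.matrix(formula, mf)
  W <- stats::model.matrix(scale, data)
  Zl <- if (!is.null(random)) stats::model.matrix(random, data) else NULL
  Zs <- if (!is.null(scale_random)) stats::model.matrix(scale_random, data) else NULL

  pid <- factor(data[[participant]])
  pidx <- as.integer(pid)
  J <- nlevels(pid)
  if (J < 2L) stopf("at least 2 participants are required")
  if ("group" %in% names(data)) {
    per_grp <- tapply(as.character(pid), as.character(data$group),
                      function(x) length(unique(x)))
    if (any(per_grp < 2L))
      stopf("fewer than 2 participants in group(s): %s",
            paste(names(per_grp)[per_grp < 2L], collapse = ", "))
  }

  kept <- iter - warmup
  loglik_keep <- unique(round(seq(1, kept,
                                  length.out = min(loglik_draws, kept))))
  re_keep <- unique(round(seq(1, kept, length.out = min(re_store, kept))))

  control <- list(iter = iter, warmup = warmup, cor_re = cor_re,
                  n_vc_reps = 2L,
                  trans_loc = if (!is.null(Zl))
                    find_translation_pairs(X, Zl, pidx, J) else list(),
                  trans_scl = if (!is.null(Zs))
                    find_translation_pairs(W, Zs, pidx, J) else list())
  runs <- lapply(seq_len(chains), function(ch)
    melsm_chain(y, X, W, Zl, Zs, pidx, J, priors, control,
                chain_seed = derive_seed(seed, ch),
                loglik_keep = loglik_keep, re_keep = re_keep))

  par_names <- colnames(runs[[1]]$draws)
  arr <- array(NA_real_, c(kept, chains, length(par_names)),
               dimnames = list(NULL, paste0("chain", seq_len(chains)), par_names))
  for (ch in seq_len(chains)) arr[, ch, ] <- runs[[ch]]$draws
  diag_df <- melsm_diagnostics(arr)

  conv_ok <- all(diag_df$rhat <= 1.01, na.rm = TRUE) &&
    all(diag_df$ess_bulk >= 400, na.rm = TRUE)
  conv_msg <- NULL
  if (!conv_ok) {
    bad <- diag_df[which(diag_df$rhat > 1.01 | diag_df$ess_bulk < 400), ]
    conv_msg <- sprintf(
      "convergence warning: %d parameter(s) with R-hat > 1.01 or bulk ESS < 400 (worst: %s, R-hat %.3f, ESS %.0f)",
      nrow(bad), bad$parameter[which.max(bad$rhat)],
      max(bad$rhat, na.rm = TRUE), min(bad$ess_bulk, na.rm = TRUE))
    warnf("%s", conv_msg)
  }

  q <- (if (is.null(Zl)) 0L else ncol(Zl)) + (if (is.null(Zs)) 0L else ncol(Zs))
  fit <- structure(list(
    call = cl,
    formula = formula, scale_formula = scale,
    random = random, scale_random = scale_random,
    participant = participant,
    participants = levels(pid),
    data = data, y = y, X = X, W = W, Zl = Zl, Zs = Zs, pidx = pidx,
    draws = arr,
    parameters = par_names,
    diagnostics = diag_df,
    convergence = list(ok = conv_ok, message = conv_msg),
    mu_mean = Reduce(`+`, lapply(runs, `[[`, "mu_mean")) / chains,
    lsig_mean = Reduce(`+`, lapply(runs, `[[`, "lsig_mean")) / chains,
    re_mean = if (q > 0)
      Reduce(`+`, lapply(runs, `[[`, "re_mean")) / chains else NULL,
    loglik = do.call(rbind, lapply(runs, `[[`, "loglik")),
    re_draws = if (q > 0)
      do.call(abind_first, lapply(runs, `[[`, "re_draws")) else NULL,
    accept = Reduce(`+`, lapply(runs, `[[`, "accept")) / chains,
    chains = chains, iter = iter, warmup = warmup, seed = seed,
    loglik_keep = loglik_keep, re_keep = re_keep,
    priors = priors, cor_re = cor_re
  ), class = "melsm")
  fit
}

# bind arrays along the first margin
abind_first <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0)), d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Pooled posterior draws of the reported parameters
#' @param fit a fitted [melsm()] model.
#' @return A (draws x parameters) matrix pooling post-warmup draws over chains.
#' @export
melsm_draws <- function(fit) {
  arr <- fit$draws
  d <- dim(arr)
  out <- matrix(aperm(arr, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(out) <- dimnames(arr)[[3]]
  out
}

#' @export
print.melsm <- function(x, ...) {
  cat("Bayesian mixed-effects location-scale model (melsm)\n")
  cat("  location:", deparse(x$formula), "\n")
  cat("  scale:   ", deparse(x$scale_formula),
      if (is.null(x$scale_random)) "(no scale random effects)" else "", "\n")
  cat(sprintf("  %d observations, %d participants; %d chains x %d iterations (%d warmup)\n",
              length(x$y), length(x$participants), x$chains, x$iter, x$warmup))
  if (x$convergence$ok) cat("  convergence: R-hat <= 1.01, bulk ESS >= 400 for all reported parameters\n")
  else cat(" ", x$convergence$message, "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior medians, SDs and 95% equal-tailed credible intervals for the
#' fixed effects, random-effect SDs and (when estimated) random-effect
#' correlations, mirroring the layout of location-scale model reports:
#' the location intercept is the mean score of the reference cell, later
#' location rows are deviations from it, and scale rows are on the log-SD
#' scale.
#'
#' @param object a fitted [melsm()] model.
#' @param prob interval mass (default 0.95, equal-tailed).
#' @param ... unused.
#' @return A data frame of class `"summary.melsm"`.
#' @export
summary.melsm <- function(object, prob = 0.95, ...) {
  dr <- melsm_draws(object)
  a <- (1 - prob) / 2
  tab <- data.frame(
    parameter = colnames(dr),
    median = apply(dr, 2, stats::median),
    sd = apply(dr, 2, stats::sd),
    cri_low = apply(dr, 2, stats::quantile, probs = a),
    cri_high = apply(dr, 2, stats::quantile, probs = 1 - a),
    row.names = NULL
  )
  tab <- merge(tab, object$diagnostics, by = "parameter", sort = FALSE)
  structure(tab, class = c("summary.melsm", "data.frame"), prob = prob)
}

#' @export
print.summary.melsm <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (medians and %g%% equal-tailed CrIs)\n",
              100 * attr(x, "prob")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior-median fixed effects
#' @param object a fitted [melsm()] model.
#' @param ... unused.
#' @return Named list with `location` and `scale` coefficient vectors.
#' @export
coef.melsm <- function(object, ...) {
  dr <- melsm_draws(object)
  med <- apply(dr, 2, stats::median)
  loc <- med[startsWith(names(med), "loc_")]
  scl <- med[startsWith(names(med), "scl_")]
  names(loc) <- sub("^loc_", "", names(loc))
  names(scl) <- sub("^scl_", "", names(scl))
  list(location = loc, scale = scl)
}

#' Fitted means and residual SDs
#'
#' @param object a fitted [melsm()] model.
#' @param type `"location"` for posterior-mean fitted means (uV) or
#'   `"scale"` for posterior-mean residual SDs (uV, `exp` of the mean
#'   log-SD draws).
#' @param ... unused.
#' @export
predict.melsm <- function(object, type = c("location", "scale"), ...) {
  type <- match.arg(type)
  if (type == "location") object$mu_mean else exp(object$lsig_mean)
}

#' @export
fitted.melsm <- function(object, ...) object$mu_mean

#' Residuals from the posterior-mean fit
#' @param object a fitted [melsm()] model.
#' @param type raw `"response"` residuals or `"pearson"` residuals scaled by
#'   the fitted trial-specific residual SD.
#' @param ... unused.
#' @export
residuals.melsm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$mu_mean
  if (type == "pearson") r <- r / exp(object$lsig_mean)
  r
}

#' Posterior-predictive simulation at the observed design
#'
#' Draws `nsim` replicate amplitude vectors using stored joint posterior
#' draws of the fixed effects and random effects.
#'
#' @param object a fitted [melsm()] model.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A (n observations x nsim) matrix.
#' @export
simulate.melsm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    dr <- melsm_draws(object)
    n <- length(object$y)
    kept <- object$iter - object$warmup
    if (is.null(object$re_draws)) {
      S <- nrow(dr)
      map <- seq_len(S)
    } else {
      # re_draws rows are chain-wise thinned kept iterations; map each row
      # back to its pooled draw row (chains stacked in chain order)
      S <- dim(object$re_draws)[1]
      len <- length(object$re_keep)
      map <- as.vector(outer(object$re_keep,
                             (seq_len(object$chains) - 1L) * kept, `+`))
    }
    out <- matrix(NA_real_, n, nsim)
    bn <- colnames(object$X); wn <- colnames(object$W)
    ql <- if (is.null(object$Zl)) 0L else ncol(object$Zl)
    qs <- if (is.null(object$Zs)) 0L else ncol(object$Zs)
    for (s in seq_len(nsim)) {
      k <- sample.int(S, 1)
      pars <- dr[map[k], ]
      mu <- drop(object$X %*% pars[paste0("loc_", bn)])
      lsig <- drop(object$W %*% pars[paste0("scl_", wn)])
      if (!is.null(object$re_draws)) {
        re <- object$re_draws[k, , , drop = TRUE]
        re <- matrix(re, dim(object$re_draws)[2], dim(object$re_draws)[3])
        if (ql > 0)
          mu <- mu + rowSums(object$Zl *
                               re[object$pidx, seq_len(ql), drop = FALSE])
        if (qs > 0)
          lsig <- lsig + rowSums(object$Zs *
                                   re[object$pidx, ql + seq_len(qs), drop = FALSE])
      }
      out[, s] <- stats::rnorm(n, mu, exp(lsig))
    }
    out
  })
}

#' Trace plots for reported parameters
#' @param x a fitted [melsm()] model.
#' @param pars parameter names (default: fixed effects).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.melsm <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- x$parameters[startsWith(x$parameters, "loc_") |
                           startsWith(x$parameters, "scl_")]
  pars <- intersect(pars, x$parameters)
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::matplot(x$draws[, , p], type = "l", lty = 1,
                      ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Posterior means of the random effects
#' @param fit a fitted [melsm()] model.
#' @return Data frame of per-participant posterior-mean random effects.
#' @export
melsm_ranef <- function(fit) {
  if (is.null(fit$re_mean)) return(NULL)
  ql <- if (is.null(fit$Zl)) 0L else ncol(fit$Zl)
  qs <- if (is.null(fit$Zs)) 0L else ncol(fit$Zs)
  nm <- c(if (ql > 0) paste0("loc_", colnames(fit$Zl)),
          if (qs > 0) paste0("scl_", colnames(fit$Zs)))
  out <- as.data.frame(fit$re_mean)
  names(out) <- nm
  cbind(participant_id = fit$participants, out)
}
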