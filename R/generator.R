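#' Configuration for the trial-level ERP generator
#'
#' Defines the generative model behind [simulate_trial_table()]: a Gaussian
#' mixed-effects location-scale process for single-trial ERP amplitudes with
#' two diagnostic groups (reference `"NP"`, never-psychotic) crossed with two
#' event types per component, person-specific means and person-specific
#' residual variability, and i.i.d. trial dropout emulating artifact
#' rejection.
#'
#' Fixed effects use treatment (dummy) coding with NP and the first event as
#' reference, in the order (intercept, event, group, event:group). `beta` is
#' in microvolts; `eta` is on the log-SD scale, so the residual SD for a trial
#' is `exp(x' eta + z' v_i)`. Defaults reproduce the duration-deviant
#' mismatch-negativity (MMN-D) study conditions: location effects
#' (1.63, -2.61, 0.02, 0.46) uV, scale effects (2.49, 0.01, 0.04, -0.02)
#' log-SD units (a within-person SD near exp(2.49) = 12.1 uV for reference
#' cells), random-effect SDs 1.34/1.39 uV for the mean structure and
#' 0.27/0.02 for the variance structure, 100 participants per group, 40
#' trials per condition, and 10% trial dropout.
#'
#' @param n_per_group participants per diagnostic group.
#' @param trials_per_condition nominal trials per event type.
#' @param dropout_rate probability in `[0, 1)` that a trial is deleted.
#' @param beta length-4 numeric, location fixed effects (uV).
#' @param eta length-4 numeric, scale fixed effects (log-SD units).
#' @param tau_loc length-2 nonnegative numeric, SDs of the location random
#'   intercept and event slope (uV).
#' @param tau_scale length-2 nonnegative numeric, SDs of the scale random
#'   intercept and event slope (log-SD units).
#' @param re_corr 4x4 correlation matrix over the random effects in the order
#'   (location intercept, location event, scale intercept, scale event).
#'   Identity by default.
#' @param groups,events labels; first entries are the reference levels.
#' @param seed integer RNG seed.
#' @return An object of class `"generator_config"`.
#' @seealso [simulate_trial_table()], [simulate_epochs()],
#'   [read_generator_config()]
#' @export
#' @examples
#' cfg <- generator_config(n_per_group = 10, trials_per_condition = 8)
#' tab <- simulate_trial_table(cfg)
#' head(tab)
generator_config <- function(n_per_group = 100,
                             trials_per_condition = 40,
                             dropout_rate = 0.1,
                             beta = c(1.63, -2.61, 0.02, 0.46),
                             eta = c(2.49, 0.01, 0.04, -0.02),
                             tau_loc = c(1.34, 1.39),
                             tau_scale = c(0.27, 0.02),
                             re_corr = diag(4),
                             groups = c("NP", "patient"),
                             events = c("standard", "deviant"),
                             seed = 1L) {
  cfg <- structure(list(
    n_per_group = n_per_group,
    trials_per_condition = trials_per_condition,
    dropout_rate = dropout_rate,
    beta = as.numeric(beta),
    eta = as.numeric(eta),
    tau_loc = as.numeric(tau_loc),
    tau_scale = as.numeric(tau_scale),
    re_corr = as.matrix(re_corr),
    groups = as.character(groups),
    events = as.character(events),
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!is_count(cfg$n_per_group)) stopf("n_per_group must be a positive integer")
  if (!is_count(cfg$trials_per_condition))
    stopf("trials_per_condition must be a positive integer (>= 1)")
  if (!is.numeric(cfg$dropout_rate) || cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  if (length(cfg$beta) != 4L || length(cfg$eta) != 4L)
    stopf("beta and eta must each have length 4")
  if (length(cfg$tau_loc) != 2L || any(cfg$tau_loc < 0))
    stopf("tau_loc must be 2 nonnegative SDs")
  if (length(cfg$tau_scale) != 2L || any(cfg$tau_scale < 0))
    stopf("tau_scale must be 2 nonnegative SDs")
  R <- cfg$re_corr
  if (!is.matrix(R) || !all(dim(R) == c(4L, 4L)))
    stopf("re_corr must be a 4x4 matrix")
  if (max(abs(R - t(R))) > 1e-8) stopf("re_corr must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stopf("re_corr must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("re_corr must be positive semi-definite")
  if (length(cfg$groups) != 2L || length(cfg$events) != 2L)
    stopf("exactly two group labels and two event labels are required")
  cfg
}

#' Read a generator configuration from YAML or JSON
#'
#' The file holds fields named as in [generator_config()]; missing fields take
#' the defaults.
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"generator_config"` object.
#' @export
read_generator_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(vals$re_corr)) vals$re_corr <- matrix(unlist(vals$re_corr), 4, 4)
  do.call(generator_config, vals)
}

#' Simulate a long-format table of single-trial ERP scores
#'
#' Draws amplitudes from the mixed-effects location-scale process
#' `y ~ Normal(X beta + Z u_i, exp(X eta + Z v_i))` with per-person random
#' effects `(u_i, v_i)` jointly multivariate normal
#' (`Sigma = diag(tau) re_corr diag(tau)`), then deletes trials independently
#' with probability `dropout_rate` to produce unbalanced cells. At least one
#' trial per (participant, event) cell is always retained. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return A `trial_table` data frame with columns `participant_id`, `group`,
#'   `event`, `trial`, `amplitude`, and an attribute `"truth"` holding the
#'   generating fixed effects and per-person random effects (useful for
#'   parameter-recovery studies).
#' @export
simulate_trial_table <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  with_seed(cfg$seed, {
    n_grp <- cfg$n_per_group
    J <- 2L * n_grp
    m <- cfg$trials_per_condition
    ids <- sprintf("P%03d", seq_len(J))
    grp <- rep(cfg$groups, each = n_grp)

    tau <- c(cfg$tau_loc, cfg$tau_scale)
    Sigma <- diag(tau) %*% cfg$re_corr %*% diag(tau)
    # PSD square root (tau entries may be 0, so eigen not chol)
    es <- eigen(Sigma, symmetric = TRUE)
    L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), 4)
    re <- matrix(stats::rnorm(J * 4), J, 4) %*% t(L)
    colnames(re) <- c("u_int", "u_event", "v_int", "v_event")

    # full crossing participant x event x trial, then dropout
    df <- data.frame(
      participant_id = rep(ids, each = 2L * m),
      group = rep(grp, each = 2L * m),
      event = rep(rep(cfg$events, each = m), times = J),
      trial = rep(seq_len(m), times = 2L * J),
      stringsAsFactors = FALSE
    )
    e <- as.numeric(df$event == cfg$events[2])
    g <- as.numeric(df$group == cfg$groups[2])
    idx <- match(df$participant_id, ids)
    mu <- cfg$beta[1] + cfg$beta[2] * e + cfg$beta[3] * g + cfg$beta[4] * e * g +
      re[idx, "u_int"] + re[idx, "u_event"] * e
    lsig <- cfg$eta[1] + cfg$eta[2] * e + cfg$eta[3] * g + cfg$eta[4] * e * g +
      re[idx, "v_int"] + re[idx, "v_event"] * e
    df$amplitude <- stats::rnorm(nrow(df), mu, exp(lsig))
    df$group <- factor(df$group, levels = cfg$groups)
    df$event <- factor(df$event, levels = cfg$events)

    if (cfg$dropout_rate > 0) {
      keep <- stats::runif(nrow(df)) >= cfg$dropout_rate
      # guarantee >= 1 trial per cell
      cell <- paste(df$participant_id, df$event)
      first_kept <- tapply(keep, cell, any)
      rescue <- !first_kept[cell] & !duplicated(cell)
      df <- df[keep | rescue, , drop = FALSE]
      rownames(df) <- NULL
    }

    truth <- list(beta = cfg$beta, eta = cfg$eta, tau_loc = cfg$tau_loc,
                  tau_scale = cfg$tau_scale, re_corr = cfg$re_corr,
                  ranef = data.frame(participant_id = ids, group = grp, re))
    structure(df, truth = truth, groups = cfg$groups, events = cfg$events,
              class = c("trial_table", "data.frame"))
  })
}

#' Validate a trial table
#'
#' Checks the contract assumed by every downstream stage: required columns,
#' at least one row per (participant, event) cell, unique trial indices within
#' cells, and group constant within participant.
#' @param table a data frame of single-trial scores.
#' @return The table, invisibly, with class `trial_table` added.
#' @export
validate_trial_table <- function(table) {
  need <- c("participant_id", "group", "event", "trial", "amplitude")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("trial table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(table$amplitude)) stopf("amplitude must be numeric")
  # fix reference levels by order of appearance (generator lists the
  # reference group/event first), not alphabetically
  if (!is.factor(table$event))
    table$event <- factor(table$event, levels = unique(as.character(table$event)))
  if (!is.factor(table$group))
    table$group <- factor(table$group, levels = unique(as.character(table$group)))
  cell <- paste(table$participant_id, table$event, sep = "\r")
  if (anyDuplicated(paste(cell, table$trial, sep = "\r")))
    stopf("trial indices must be unique within each (participant, event) cell")
  gmap <- tapply(as.character(table$group), table$participant_id,
                 function(g) length(unique(g)))
  if (any(gmap > 1L)) stopf("group must be constant within participant")
  if (!inherits(table, "trial_table"))
    class(table) <- c("trial_table", class(table))
  table
}

#' Write / read a trial table as CSV
#'
#' Plain CSV with header `participant_id,group,event,trial,amplitude`.
#' @param table a trial table.
#' @param path file path.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  utils::write.csv(
    table[, c("participant_id", "group", "event", "trial", "amplitude")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(df)
}
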