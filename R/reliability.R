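#' Variance components of single-trial scores for one group/event cell
#'
#' One-way random-effects decomposition of single-trial scores into
#' between-person true-score variance and within-person (person x trial)
#' residual variance, accommodating unbalanced trial counts. Estimation is
#' by restricted maximum likelihood (via an intercept-only multilevel fit);
#' if that fails, a method-of-moments (expected mean squares with the
#' unbalanced `n0` correction) fallback is used. Negative estimates are
#' truncated at zero with a warning.
#'
#' @param table a trial table.
#' @param group,event optional labels to subset before estimation.
#' @return An object of class `"variance_components"`: `sigma2_person`,
#'   `sigma2_residual` (uV^2), `n_participants`, `trial_counts`, `method`.
#' @export
estimate_variance_components <- function(table, group = NULL, event = NULL) {
  table <- validate_trial_table(table)
  sub <- table
  if (!is.null(group)) sub <- sub[sub$group == group, , drop = FALSE]
  if (!is.null(event)) sub <- sub[sub$event == event, , drop = FALSE]
  if (!nrow(sub)) stopf("no rows left after subsetting")
  counts <- table(as.character(sub$participant_id))
  if (length(counts) < 2L) stopf("at least 2 participants are required")
  if (all(counts < 2L)) stopf("all participants have a single trial; residual variance is not estimable")

  method <- "REML"
  est <- tryCatch({
    if (stats::var(sub$amplitude) == 0) {
      list(p = 0, r = 0)
    } else {
      fml <- stats::as.formula(paste("amplitude ~ 1 + (1 |", "participant_id)"))
      fit <- suppressMessages(lme4::lmer(fml, data = sub, REML = TRUE))
      vc <- as.data.frame(lme4::VarCorr(fit))
      list(p = vc$vcov[vc$grp == "participant_id"],
           r = vc$vcov[vc$grp == "Residual"])
    }
  }, error = function(e) NULL)
  if (is.null(est)) {
    method <- "method-of-moments"
    est <- mom_variance_components(sub)
  }
  p <- est$p; r <- est$r
  if (p < 0) { warnf("negative person variance truncated at 0"); p <- 0 }
  if (r < 0) { warnf("negative residual variance truncated at 0"); r <- 0 }
  structure(list(sigma2_person = p, sigma2_residual = r,
                 n_participants = length(counts),
                 trial_counts = as.integer(counts), method = method),
            class = "variance_components")
}

# expected-mean-squares estimator for the unbalanced one-way random model
mom_variance_components <- function(sub) {
  id <- as.character(sub$participant_id)
  y <- sub$amplitude
  ni <- tapply(y, id, length)
  mi <- tapply(y, id, mean)
  N <- length(y); a <- length(ni)
  gm <- mean(y)
  ssw <- sum((y - mi[id])^2)
  ssb <- sum(ni * (mi - gm)^2)
  msw <- ssw / (N - a)
  msb <- ssb / (a - 1)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  list(p = (msb - msw) / n0, r = msw)
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s): person %.3f uV^2, residual %.3f uV^2 (%d participants)\n",
              x$method, x$sigma2_person, x$sigma2_residual, x$n_participants))
  invisible(x)
}

#' Generalizability-theory coefficient of dependability
#'
#' `sigma2_person / (sigma2_person + sigma2_residual / n_trials)`: the
#' reliability of an average of `n_trials` single-trial scores.
#'
#' @param vc a `"variance_components"` object (or a list with
#'   `sigma2_person` and `sigma2_residual`).
#' @param n_trials number of trials averaged (>= 1; may be a vector).
#' @return Dependability value(s) in `[0, 1]`.
#' @export
dependability <- function(vc, n_trials) {
  stopifnot(all(n_trials >= 1))
  p <- vc$sigma2_person; r <- vc$sigma2_residual
  if (p == 0 && r == 0) stopf("dependability undefined: both variance components are zero")
  p / (p + r / n_trials)
}

#' Dependability as a function of trial count
#'
#' Evaluates [dependability()] over a grid of trial counts and records the
#' smallest integer count reaching `threshold` (default 0.70), `NA` if the
#' grid never reaches it.
#'
#' @param vc variance components.
#' @param trial_counts increasing integer grid.
#' @param threshold target dependability.
#' @return A data frame of class `"dependability_curve"` with columns
#'   `n_trials`, `dependability`; attributes `threshold` and
#'   `min_trials_at_threshold`.
#' @export
dependability_curve <- function(vc, trial_counts = 1:100, threshold = 0.70) {
  trial_counts <- sort(unique(as.integer(trial_counts)))
  dep <- dependability(vc, trial_counts)
  hit <- which(dep >= threshold)
  structure(data.frame(n_trials = trial_counts, dependability = dep),
            threshold = threshold,
            min_trials_at_threshold = if (length(hit)) trial_counts[hit[1]] else NA_integer_,
            class = c("dependability_curve", "data.frame"))
}

#' Standardized measurement error of a participant's cell mean
#'
#' Trial SD divided by the square root of the trial count, for one
#' (participant, event) cell: the expected SE of that person's average ERP
#' score.
#'
#' @param table a trial table.
#' @param participant,event cell selectors.
#' @return SME in uV.
#' @export
sme <- function(table, participant, event) {
  validate_trial_table(table)
  x <- table$amplitude[table$participant_id == participant &
                         table$event == event]
  if (length(x) < 2L)
    stopf("cell (%s, %s) has %d trial(s); at least 2 required", participant,
          event, length(x))
  stats::sd(x) / sqrt(length(x))
}

#' Per-cell SME summary
#' @param table a trial table.
#' @return Data frame with one row per (participant, event) cell having
#'   >= 2 trials: trial count, trial SD, and SME.
#' @export
sme_summary <- function(table) {
  validate_trial_table(table)
  key <- interaction(table$participant_id, table$event, drop = TRUE)
  spl <- split(seq_len(nrow(table)), key)
  rows <- lapply(spl, function(ix) {
    if (length(ix) < 2L) return(NULL)
    x <- table$amplitude[ix]
    data.frame(participant_id = table$participant_id[ix[1]],
               group = table$group[ix[1]],
               event = table$event[ix[1]],
               n_trials = length(ix), trial_sd = stats::sd(x),
               sme = stats::sd(x) / sqrt(length(ix)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-sample t test from summary statistics
#'
#' Classic pooled-variance t from group means, SDs and sizes (the form used
#' for demographic comparisons reported from summary tables).
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return List with `statistic` (t for group 1 minus group 2), `df`, `p`.
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stopf("zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test of independence from a count table
#'
#' Thin wrapper over the standard Pearson chi-square (no continuity
#' correction) for contingency tables of counts.
#'
#' @param counts a matrix of counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_counts <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(as.matrix(counts), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
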