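#' Percent change in within-person SD implied by a log-scale coefficient
#'
#' Scale-portion coefficients live on the log-SD scale; a coefficient
#' `eta` corresponds to a `100 * (exp(eta) - 1)` percent change in
#' within-person standard deviation (e.g. `eta = -0.02` is about 2% less
#' variability, `eta = log(2)` is a doubling, +100%).
#'
#' @param eta numeric vector of log-SD contrasts or coefficients.
#' @return Signed percent change(s) in within-person SD.
#' @export
#' @examples
#' percent_change_in_sd(c(-0.02, 0, log(2)))
percent_change_in_sd <- function(eta) {
  stopifnot(is.numeric(eta), all(is.finite(eta)))
  100 * (exp(eta) - 1)
}

#' Summarize a posterior functional as a contrast result
#'
#' Evaluates `functional` on every pooled post-warmup draw and reports the
#' posterior median, the 95% equal-tailed credible interval (linear
#' interpolation percentiles), and whether the interval excludes zero.
#'
#' @param fit a fitted [melsm()] model, or a numeric vector / one-column
#'   matrix of draws.
#' @param functional one of: a parameter name (e.g. `"scl_grouppatient"`); a
#'   named numeric vector of weights defining a linear combination of
#'   parameters; or a function taking the pooled draws matrix and returning
#'   one value per draw. Ignored when `fit` is already a vector of draws.
#' @param name label for the result.
#' @param prob interval mass (default 0.95).
#' @param scale set `TRUE` if the functional lives on the log-SD scale, to
#'   attach the percent-change back-transform.
#' @return A one-row data frame of class `"contrast_result"` with columns
#'   `name`, `median`, `cri_low`, `cri_high`, `excludes_zero` and (for scale
#'   contrasts) `scale_percent_change`.
#' @export
melsm_summarize <- function(fit, functional = NULL, name = NULL, prob = 0.95,
                            scale = FALSE) {
  if (is.numeric(fit)) {
    x <- as.numeric(fit)
    name <- name %||% "draws"
  } else {
    dr <- melsm_draws(fit)
    if (is.character(functional)) {
      if (!functional %in% colnames(dr))
        stopf("unknown parameter '%s'", functional)
      x <- dr[, functional]
      name <- name %||% functional
    } else if (is.numeric(functional) && !is.null(names(functional))) {
      bad <- setdiff(names(functional), colnames(dr))
      if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
      x <- drop(dr[, names(functional), drop = FALSE] %*% functional)
      name <- name %||% paste(names(functional), collapse = "+")
    } else if (is.function(functional)) {
      x <- functional(dr)
      name <- name %||% "functional"
    } else stopf("functional must be a parameter name, named weights, or function")
  }
  if (!all(is.finite(x))) stopf("non-finite draws in functional '%s'", name)
  a <- (1 - prob) / 2
  qs <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  out <- data.frame(name = name, median = qs[2], cri_low = qs[1],
                    cri_high = qs[3],
                    excludes_zero = qs[1] > 0 | qs[3] < 0,
                    row.names = NULL)
  if (scale) out$scale_percent_change <- percent_change_in_sd(qs[2])
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Pairwise group contrasts on location and scale
#'
#' Builds the patient-minus-reference-group contrasts reported for each
#' event level and their difference (the event-by-group interaction), on
#' both the location (uV) and scale (log-SD) portions. Scale rows carry the
#' percent-change back-transform of the median.
#'
#' Assumes treatment coding with two-level `event` and `group` factors in
#' both portions (the default [melsm()] design).
#'
#' @param fit a fitted [melsm()] model.
#' @param event,group names of the event and group columns.
#' @param prob interval mass.
#' @return A data frame of class `"contrast_result"`, one row per contrast,
#'   with a `portion` column (`"location"`/`"scale"`).
#' @export
group_contrasts <- function(fit, event = "event", group = "group", prob = 0.95) {
  dr <- melsm_draws(fit)
  find_cols <- function(prefix, design) {
    trm <- stats::terms(design)
    labs <- attr(trm, "term.labels")
    asg <- attr(if (prefix == "loc_") fit$X else fit$W, "assign")
    cn <- colnames(if (prefix == "loc_") fit$X else fit$W)
    g_i <- which(labs == group)
    int_i <- which(labs %in% c(paste0(event, ":", group), paste0(group, ":", event)))
    list(group = if (length(g_i)) paste0(prefix, cn[asg == g_i]) else character(0),
         inter = if (length(int_i)) paste0(prefix, cn[asg == int_i]) else character(0))
  }
  lv_event <- levels(factor(fit$data[[event]]))
  build <- function(prefix, design, portion) {
    cols <- find_cols(prefix, design)
    if (!length(cols$group) || !length(cols$inter))
      stopf("model %s portion lacks group and event:%s terms", portion, group)
    gcol <- cols$group[1]; icol <- cols$inter[1]
    is_scale <- portion == "scale"
    ref <- melsm_summarize(fit, stats::setNames(1, gcol),
                           name = lv_event[1], prob = prob, scale = is_scale)
    oth <- melsm_summarize(fit, stats::setNames(c(1, 1), c(gcol, icol)),
                           name = lv_event[2], prob = prob, scale = is_scale)
    dif <- melsm_summarize(fit, stats::setNames(1, icol),
                           name = paste0(lv_event[2], "-", lv_event[1]),
                           prob = prob, scale = is_scale)
    out <- rbind(ref, oth, dif)
    if (!is_scale) out$scale_percent_change <- NA_real_
    out$portion <- portion
    out[c("name", "median", "cri_low", "cri_high", "excludes_zero",
          "scale_percent_change", "portion")]
  }
  out <- rbind(build("loc_", fit$formula, "location"),
               build("scl_", fit$scale_formula, "scale"))
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Apply the registered credible-interval decision rule for one component
#'
#' For components where the prediction is higher patient variability
#' (`predicted = "greater"`), the hypothesis is supported when (1) the 95%
#' CrI of the group parameter on the scale portion excludes zero with the
#' patient group more variable, and/or (2) the CrI of the event-by-group
#' parameter excludes zero, the patient group is more variable for one event
#' and the groups are comparable for the other. If a tested scale contrast
#' excludes zero only in the direction of lower patient variability the
#' verdict is `"opposite-direction"`; otherwise `"not supported"`.
#'
#' For a component with a predicted null (`predicted = "null"`, reward
#' positivity), the hypothesis is supported exactly when both the group and
#' interaction CrIs on the scale portion contain zero.
#'
#' @param contrasts output of [group_contrasts()] (must include the scale
#'   portion rows).
#' @param predicted `"greater"` or `"null"`.
#' @param component optional component label carried into the record.
#' @return A list of class `"hypothesis_decision"` with elements `component`,
#'   `predicted`, `verdict` and `evidence`.
#' @export
decide_hypothesis <- function(contrasts, predicted = c("greater", "null"),
                              component = NULL) {
  predicted <- match.arg(predicted)
  sc <- contrasts[contrasts$portion == "scale", , drop = FALSE]
  if (nrow(sc) < 3L)
    stopf("contrasts must contain the three scale-portion group contrasts")
  grp <- sc[1, ]   # reference event == the group parameter
  oth <- sc[2, ]   # other event (group + interaction)
  int <- sc[3, ]   # difference == the event:group parameter
  verdict <- if (predicted == "null") {
    if (!grp$excludes_zero && !int$excludes_zero) "supported" else "not supported"
  } else {
    clause1 <- grp$excludes_zero && grp$median > 0
    one_up_other_flat <- (oth$excludes_zero && oth$median > 0 && !grp$excludes_zero) ||
      (grp$excludes_zero && grp$median > 0 && !oth$excludes_zero)
    clause2 <- int$excludes_zero && one_up_other_flat
    if (clause1 || clause2) "supported"
    else if ((grp$excludes_zero && grp$median < 0) ||
             (int$excludes_zero && int$median < 0) ||
             (oth$excludes_zero && oth$median < 0))
      "opposite-direction"
    else "not supported"
  }
  structure(list(component = component, predicted = predicted,
                 verdict = verdict, evidence = sc),
            class = "hypothesis_decision")
}

#' @export
print.hypothesis_decision <- function(x, ...) {
  cat(sprintf("Component %s: prediction '%s' -> %s\n",
              x$component %||% "(unnamed)", x$predicted, x$verdict))
  ev <- as.data.frame(x$evidence)
  num <- vapply(ev, is.numeric, TRUE)
  ev[num] <- lapply(ev[num], round, 4)
  print(ev, row.names = FALSE)
  invisible(x)
}
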