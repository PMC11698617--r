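# Kaplan-Meier estimation and single-covariate Cox proportional-hazards
# significance, via the survival package (product-limit estimator; Efron tie
# handling).

#' Kaplan-Meier product-limit estimate
#'
#' Tabulates the product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i/n_i)
#' at the distinct event times.  Censored observations remain at risk for
#' events at the same time (standard convention).  With no events the curve
#' is 1 everywhere and the table is empty.
#'
#' @param time positive survival/followup times in years.
#' @param event 1 = death observed, 0 = censored.
#' @return data.frame with \code{time}, \code{survival}, \code{at_risk},
#'   \code{n_events}, one row per distinct event time.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], survival = fit$surv[keep],
             at_risk = fit$n.risk[keep], n_events = fit$n.event[keep])
}

#' Cox proportional-hazards test for a binary grouping
#'
#' Fits a single-covariate Cox model (Efron handling of tied event times) for
#' a binary group indicator and reports the two-sided Wald p-value of the
#' group coefficient.  When the partial likelihood is monotone (e.g. complete
#' separation of event times, flagged by the fitter), the fit is marked as
#' not converged and the p-value falls back to the score test, whose
#' statistic at beta = 0 equals the log-rank statistic in the absence of
#' ties.
#'
#' @param time positive times in years.
#' @param event 1 = death, 0 = censored.
#' @param group binary group indicator (logical or 0/1); the coefficient is
#'   the log hazard ratio of group 1 versus group 0.
#' @return list with \code{coefficient}, \code{p_value}, \code{converged},
#'   \code{p_wald}, \code{p_score}, \code{score_stat}, \code{n},
#'   \code{n_events}.  With a single-group input or no events, \code{NULL}
#'   is returned with a warning (feature skipped).
#' @export
coxGroupP <- function(time, event, group) {
  group <- as.integer(group)
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(group %in% c(0L, 1L)), all(event %in% c(0, 1)))
  if (any(time <= 0)) {
    warning(sprintf("dropping %d observation(s) with non-positive time",
                    sum(time <= 0)))
    keep <- time > 0
    time <- time[keep]; event <- event[keep]; group <- group[keep]
  }
  if (!any(group == 0L) || !any(group == 1L)) {
    warning("a group has no members; survival comparison skipped")
    return(NULL)
  }
  if (!any(event == 1)) {
    warning("no events observed; survival comparison skipped")
    return(NULL)
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[1])
  pWald <- unname(sm$coefficients[1, "Pr(>|z|)"])
  scoreStat <- unname(sm$sctest["test"])
  pScore <- unname(sm$sctest["pvalue"])
  converged <- !flagged && is.finite(beta) && is.finite(pWald)
  list(coefficient = beta,
       p_value = if (converged) pWald else pScore,
       converged = converged,
       p_wald = pWald, p_score = pScore, score_stat = scoreStat,
       n = length(time), n_events = sum(event == 1))
}

#' Export grouped Kaplan-Meier curves
#'
#' Convenience wrapper producing a tidy per-group KM table for plotting.
#'
#' @inheritParams coxGroupP
#' @param labels length-2 character vector naming groups 0 and 1.
#' @return data.frame with \code{group}, \code{time}, \code{survival},
#'   \code{at_risk}, \code{n_events}.
#' @export
kmByGroup <- function(time, event, group, labels = c("0", "1")) {
  group <- as.integer(group)
  out <- lapply(c(0L, 1L), function(g) {
    sel <- group == g
    if (!any(sel)) return(NULL)
    km <- kmEstimate(time[sel], event[sel])
    if (!nrow(km)) return(NULL)
    cbind(group = labels[g + 1L], km, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(group = character(0), time = numeric(0),
                      survival = numeric(0), at_risk = integer(0),
                      n_events = integer(0))
  out
}
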