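## Disease-free survival statistics. Any recurrence (local, regional or
## distant) is an event; overall survival is out of scope. The product-limit
## estimator and the log-rank test are computed through the survival package
## behind a tabular interface.

#' Kaplan-Meier estimate of disease-free survival
#'
#' Product-limit estimator; censored times reduce the at-risk set only.
#'
#' @param time Follow-up in months (> 0).
#' @param event Logical (or 0/1) recurrence indicator.
#' @return List of class `km_curve`: `event_times` (distinct times with >= 1
#'   event, ascending), `survival` (S(t) just after each event time),
#'   `at_risk` (numbers at risk at each event time), `n`, `n_events`.
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("km_estimate: empty input")
  if (anyNA(time) || any(time <= 0))
    stop("km_estimate: all times must be positive and non-missing")
  event <- as.logical(event)
  if (anyNA(event)) stop("km_estimate: event indicator has missing values")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- list(event_times = fit$time[keep],
              survival = fit$surv[keep],
              at_risk = fit$n.risk[keep],
              n = length(time),
              n_events = sum(event))
  class(out) <- "km_curve"
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A [km_estimate()] result.
#' @param t Times (months).
#' @return S(t), a step function equal to 1 before the first event.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$event_times <= ti)
    if (length(i) == 0) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square on k-1 degrees of freedom with the
#' hypergeometric variance for tied event times; no continuity correction.
#'
#' @param time Follow-up in months (> 0).
#' @param event Logical recurrence indicator.
#' @param group Group labels (>= 2 non-empty groups required).
#' @return List with `chisq`, `df`, `p_value`, `n`, `groups`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2)
    stop("logrank_test: need at least 2 non-empty groups")
  if (anyNA(time) || any(time <= 0)) stop("logrank_test: times must be > 0")
  event <- as.logical(event)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = length(time), groups = levels(group))
}

#' Disease-free survival by risk class
#'
#' Convenience wrapper: one Kaplan-Meier curve per risk class present plus a
#' global log-rank test across them.
#'
#' @param cohort Cohort data frame with `dfs_months` and `recurrence_event`.
#' @param assignments Risk assignment table for the same patients.
#' @return List with `curves` (named list of `km_curve`), `logrank`, and `n`
#'   (patients with usable follow-up).
#' @export
survival_by_risk_class <- function(cohort, assignments) {
  d <- as.data.frame(cohort)
  cls <- assignments$risk_class[match(as.character(d$patient_id),
                                      as.character(assignments$patient_id))]
  if (anyNA(cls)) stop("assignments must cover every cohort patient")
  use <- !is.na(d$dfs_months) & d$dfs_months > 0 & !is.na(d$recurrence_event)
  d <- d[use, ]
  cls <- cls[use]
  if (nrow(d) == 0) stop("no patients with usable follow-up")
  present <- intersect(risk_classes(), unique(cls))
  curves <- lapply(present, function(k)
    km_estimate(d$dfs_months[cls == k], d$recurrence_event[cls == k]))
  names(curves) <- present
  lr <- if (length(present) >= 2)
    logrank_test(d$dfs_months, d$recurrence_event, cls) else NULL
  list(curves = curves, logrank = lr, n = nrow(d))
}
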