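#' Kaplan-Meier product-limit survival curve
#'
#' Nonparametric estimate of the survivor function under right censoring.
#' Subjects censored exactly at an event time are counted at risk at that
#' time (the standard convention); the estimate is a right-continuous step
#' function with S(0) = 1.
#'
#' @param table A survival table: data frame with `time` (non-negative,
#'   months) and `event` (1 = death observed, 0 = censored). A `sample_id`
#'   column is carried along if present.
#' @return Object of class `km_curve`: list with `steps` (tibble of distinct
#'   event times: `time`, `n_risk`, `n_event`, `n_censor`, `survival`),
#'   `n` subjects, and `n_event` total events. `tidy()` returns the steps.
#' @export
km_curve <- function(table) {
  st <- check_survival(table)
  if (nrow(st) < 1L) abort_param("Need at least one subject.")
  event_times <- sort(unique(st$time[st$event == 1]))
  n_risk <- vapply(event_times, function(t) sum(st$time >= t), numeric(1))
  n_event <- vapply(event_times, function(t) {
    sum(st$time == t & st$event == 1)
  }, numeric(1))
  n_censor <- vapply(event_times, function(t) {
    sum(st$time == t & st$event == 0)
  }, numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- list(
    steps = tibble(time = event_times, n_risk = n_risk, n_event = n_event,
                   n_censor = n_censor, survival = surv),
    n = nrow(st), n_event = sum(st$event)
  )
  class(out) <- "km_curve"
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param fit A `km_curve`.
#' @param times Non-negative times.
#' @return S(t) at each time (right-continuous).
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_curve"))
  vapply(times, function(t) {
    past <- fit$steps$time <= t
    if (!any(past)) 1 else fit$steps$survival[max(which(past))]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d event times\n",
              x$n, x$n_event, nrow(x$steps)))
  print(x$steps, ...)
  invisible(x)
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  med <- {
    below <- x$steps$survival <= 0.5
    if (any(below)) x$steps$time[which(below)[1L]] else NA_real_
  }
  tibble(n = x$n, n_event = x$n_event, median_survival = med)
}

#' Two-group log-rank test
#'
#' Compares survival between two groups by summing observed-minus-expected
#' events over the pooled distinct event times, with the hypergeometric
#' variance at each time (standard tie handling). The statistic is
#' chi-squared with 1 degree of freedom.
#'
#' @param table_a,table_b Survival tables (see [km_curve()]) for the two
#'   groups.
#' @return Object of class `logrank_test`: `chi2`, `p`, `observed` and
#'   `expected` per group (named `a`/`b`), `n` per group.
#' @export
logrank_test <- function(table_a, table_b) {
  a <- check_survival(table_a)
  b <- check_survival(table_b)
  if (nrow(a) < 1L || nrow(b) < 1L) abort_param("Both groups must be non-empty.")
  if (sum(a$event) + sum(b$event) < 1L) {
    abort_param("Log-rank test requires at least one event overall.")
  }
  times <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t); nt <- n1 + n2
    d1 <- sum(a$time == t & a$event == 1)
    d2 <- sum(b$time == t & b$event == 1)
    d <- d1 + d2
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / nt
    if (nt > 1) v <- v + d * (n1 / nt) * (n2 / nt) * (nt - d) / (nt - 1)
  }
  o2 <- sum(b$event); e2 <- (o1 + o2) - e1
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  out <- list(chi2 = chi2, p = p,
              observed = c(a = o1, b = o2), expected = c(a = e1, b = e2),
              n = c(a = nrow(a), b = nrow(b)))
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g (1 df), p = %.4g\n", x$chi2, x$p))
  cat(sprintf("  group a: n = %d, observed = %g, expected = %.3g\n",
              x$n[["a"]], x$observed[["a"]], x$expected[["a"]]))
  cat(sprintf("  group b: n = %d, observed = %g, expected = %.3g\n",
              x$n[["b"]], x$observed[["b"]], x$expected[["b"]]))
  invisible(x)
}

#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(group = c("a", "b"), n = as.numeric(x$n),
         observed = as.numeric(x$observed),
         expected = as.numeric(x$expected))
}

#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(chi2 = x$chi2, df = 1, p_value = x$p)
}

check_survival <- function(table) {
  if (!is.data.frame(table)) abort_param("Survival table must be a data frame.")
  missing <- setdiff(c("time", "event"), names(table))
  if (length(missing) > 0L) {
    abort_param(sprintf("Survival table missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(table$time)) || any(table$time < 0)) {
    abort_param("Survival times must be finite and non-negative.")
  }
  if (!all(table$event %in% c(0, 1))) {
    abort_param("`event` must be 0 (censored) or 1 (death observed).")
  }
  as_tibble(table)
}
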