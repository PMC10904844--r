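# Expression-stratified Kaplan-Meier estimation and the log-rank
# (Mantel-Cox) test, implemented from the product-limit and
# hypergeometric O-E formulas.

#' Construct a survival cohort
#'
#' @param id Subject identifiers.
#' @param time Follow-up times in months (positive, finite).
#' @param event Event indicator: 1 = death observed, 0 = censored.
#' @param expression Continuous expression value used for stratification.
#' @return A `"survival_cohort"` data frame.
#' @export
survival_cohort <- function(id, time, event, expression) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive")
  }
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (any(!is.finite(expression))) stop("expression must be finite")
  out <- data.frame(id = as.character(id), time = time, event = event,
                    expression = as.numeric(expression),
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Stratify a cohort by expression level
#'
#' `median` mode splits the cohort at the sample median into `low`
#' (bottom 50%) and `high` (top 50%) strata. `tertile` mode ranks patients
#' into `low`, `intermediate` and `high` thirds; the usual comparison then
#' contrasts the lower and higher groups, dropping the middle third. Ties
#' are broken by stable rank order (first occurrence ranks first), so the
#' strata always have the nominal sizes.
#'
#' @param cohort A `"survival_cohort"`.
#' @param mode `"median"` or `"tertile"`.
#' @return The cohort with a `stratum` factor column added.
#' @export
stratify_by_expression <- function(cohort, mode = c("median", "tertile")) {
  stopifnot(inherits(cohort, "survival_cohort"))
  mode <- match.arg(mode)
  n <- nrow(cohort)
  if (n < ifelse(mode == "median", 2L, 3L)) {
    stop(sprintf("need at least %d subjects for %s stratification",
                 ifelse(mode == "median", 2L, 3L), mode))
  }
  if (length(unique(cohort$expression)) == 1L) {
    stop("degenerate stratification: all expression values identical")
  }
  r <- rank(cohort$expression, ties.method = "first")
  if (mode == "median") {
    lev <- c("low", "high")
    stratum <- lev[1L + (r > n / 2)]
  } else {
    lev <- c("low", "intermediate", "high")
    stratum <- lev[cut(r, breaks = c(0, n / 3, 2 * n / 3, n), labels = FALSE)]
  }
  cohort$stratum <- factor(stratum, levels = lev)
  cohort
}

# Risk table at the distinct event times of a set of subjects:
# n_risk just before t, d events at t, c censorings at t. Tied events and
# censorings at the same time are resolved events-first (censored subjects
# are still at risk at their own time).
.risk_table <- function(time, event) {
  tt <- sort(unique(time))
  n <- length(time)
  data.frame(
    time = tt,
    n_risk = vapply(tt, function(t) sum(time >= t), numeric(1)),
    n_event = vapply(tt, function(t) sum(time == t & event == 1L), numeric(1)),
    n_censor = vapply(tt, function(t) sum(time == t & event == 0L), numeric(1))
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times
#' `t_i`, with `d_i` events among `n_i` subjects at risk. Censored subjects
#' leave the risk set after their censoring time.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A `"km_estimate"`: data frame with `time`, `n_risk`, `n_event`,
#'   `n_censor` and `surv` (rows at all distinct observation times).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("stratum is empty")
  rt <- .risk_table(as.numeric(time), as.integer(event))
  rt$surv <- cumprod(1 - rt$n_event / rt$n_risk)
  class(rt) <- c("km_estimate", "data.frame")
  rt
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events\n",
              x$n_risk[1], sum(x$n_event)))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Survival probability at given times
#'
#' Step-function evaluation of a Kaplan-Meier estimate (right-continuous;
#' `S(t) = 1` before the first observation time).
#'
#' @param km A `"km_estimate"`.
#' @param times Times at which to evaluate `S(t)`.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  idx <- findInterval(times, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Log-rank (Mantel-Cox) test
#'
#' Two-sample log-rank test: at every distinct event time the observed
#' events in group A are compared with the hypergeometric expectation
#' `E = d * nA / n`, with variance
#' `V = d (n - d) nA nB / (n^2 (n - 1))`; the statistic
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-square distribution with
#' one degree of freedom. A comparison with zero total variance (e.g. no
#' events) returns statistic 0 and p = 1 by convention.
#'
#' @param timeA,eventA Times and event indicators of the first stratum.
#' @param timeB,eventB Times and event indicators of the second stratum.
#' @return A `"logrank_test"` list: `statistic`, `p_value`, `observed`,
#'   `expected` (per group), `df`.
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0 || length(timeB) == 0) {
    stop("both strata must be non-empty")
  }
  time <- c(as.numeric(timeA), as.numeric(timeB))
  event <- c(as.integer(eventA), as.integer(eventB))
  grpA <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))
  tt <- sort(unique(time[event == 1L]))
  OmE <- 0; V <- 0; OA <- 0; EA <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); nA <- sum(at_risk & grpA)
    d <- sum(time == t & event == 1L)
    dA <- sum(time == t & event == 1L & grpA)
    e <- d * nA / n
    OmE <- OmE + (dA - e)
    OA <- OA + dA; EA <- EA + e
    if (n > 1) V <- V + d * (n - d) * nA * (n - nA) / (n^2 * (n - 1))
  }
  if (V <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- OmE^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p,
                 observed = c(A = OA, B = sum(event) - OA),
                 expected = c(A = EA, B = sum(event) - EA),
                 df = 1L),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox) test: chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  observed events A/B: %g/%g, expected: %.2f/%.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Expression-stratified survival comparison
#'
#' Stratifies a cohort by expression ([stratify_by_expression()]) and
#' compares the low vs high strata (tertile mode drops the middle third)
#' with Kaplan-Meier estimates and the log-rank test.
#'
#' @param cohort A `"survival_cohort"`.
#' @param mode Stratification mode, see [stratify_by_expression()].
#' @return A list with the labeled cohort, per-stratum `"km_estimate"`s
#'   (`km`), and the `"logrank_test"` (`test`).
#' @export
survival_comparison <- function(cohort, mode = c("median", "tertile")) {
  mode <- match.arg(mode)
  strat <- stratify_by_expression(cohort, mode)
  lo <- strat[strat$stratum == "low", ]
  hi <- strat[strat$stratum == "high", ]
  list(cohort = strat,
       km = list(low = km_estimate(lo$time, lo$event),
                 high = km_estimate(hi$time, hi$event)),
       test = logrank_test(lo$time, lo$event, hi$time, hi$event))
}
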