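# Censored-survival imputation from the Kaplan-Meier curve and the recursive
# two-way partition defining the four survival subgroups.
#
# The imputation rule: a censored observation at t0 receives
#   mean                                  if t0 <= mean/2
#   t0 + (1/S(t0)) * integral_{t0} S(t)dt if t0 >  mean/2
# where S is the product-limit estimate and "mean" is its restricted mean
# (area under S up to the last observed time). The second branch is the
# conditional expectation of survival given survival beyond t0; the first
# guards against low-information early censorings, which the conditional
# formula would otherwise always push above the mean.

#' Fit a Kaplan-Meier (product-limit) curve
#'
#' Ties between deaths and censorings at the same time are resolved with
#' deaths first (censored samples at time t are still at risk at t), the
#' standard product-limit convention.
#'
#' @param times positive observed times.
#' @param events 1 = death observed, 0 = censored.
#' @return an object of class `km_curve`: `event_times` (distinct death
#'   times, increasing), `surv` (S right after each death time), `n_at_risk`,
#'   `n_events`, `tmax` (last observed time, any status) and `mean_survival`
#'   (restricted mean: area under S on [0, tmax]).
#' @export
#' @examples
#' km <- fit_km(c(1, 2, 3), c(1, 1, 1))
#' km$surv  # 2/3, 1/3, 0
fit_km <- function(times, events) {
  .check_times_events(times, events)
  if (sum(events) == 0) {
    stop("Kaplan-Meier curve requires at least one observed event",
         call. = FALSE)
  }
  dt <- sort(unique(times[events == 1]))
  n_at_risk <- vapply(dt, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(dt, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  curve <- structure(list(event_times = dt, surv = surv,
                          n_at_risk = as.integer(n_at_risk),
                          n_events = as.integer(n_events),
                          tmax = max(times), mean_survival = NA_real_),
                     class = "km_curve")
  curve$mean_survival <- .km_integral(curve, 0, curve$tmax)
  curve
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step convention: `S(t) = 1` before the first death time.
#'
#' @param curve a `km_curve`.
#' @param t time(s) at which to evaluate S.
#' @return survival probabilities.
#' @export
km_surv <- function(curve, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$event_times)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

# Exact area under the step function S between a and b (a <= b).
.km_integral <- function(curve, a, b) {
  if (b <= a) return(0)
  knots <- curve$event_times
  pts <- c(a, knots[knots > a & knots < b], b)
  widths <- diff(pts)
  heights <- km_surv(curve, pts[-length(pts)])
  sum(widths * heights)
}

#' Conditionally expected survival time beyond a censoring time
#'
#' Implements `t0 + (1/S(t0)) * integral_{t0}^{tmax} S(t) dt`, the expected
#' survival of a subject known to be alive at `t0`. The integral is the exact
#' rectangle sum of the step function, truncated at the last observed time
#' (restricted-mean convention); when `t0` equals the last observed time the
#' function returns `t0` itself.
#'
#' @param curve a `km_curve`.
#' @param t0 censoring time, `0 <= t0 <= tmax`.
#' @return expected survival time (>= t0).
#' @export
expected_residual_survival <- function(curve, t0) {
  .check_scalar_number(t0, "t0", lower = 0)
  if (t0 >= curve$tmax) {
    if (t0 > curve$tmax) {
      stop("t0 lies beyond the last observed time of the curve", call. = FALSE)
    }
    return(t0)
  }
  s0 <- km_surv(curve, t0)
  if (s0 <= 0) {
    stop("S(t0) = 0: conditional expectation undefined; use the last event time as fallback",
         call. = FALSE)
  }
  t0 + .km_integral(curve, t0, curve$tmax) / s0
}

#' Impute survival times for censored samples
#'
#' Observed deaths keep their time. Censored samples receive the cohort mean
#' survival when censored early (`t0 <= mean/2`) and the conditional
#' expectation [expected_residual_survival()] when censored late.
#'
#' @param times observed times.
#' @param events event indicators.
#' @param mean_rule `"km"` (restricted mean of the KM curve, default) or
#'   `"arithmetic"` (plain average of observed times).
#' @return data.frame with columns `time`, `event`, `imputed_time`.
#' @export
impute_survival <- function(times, events, mean_rule = c("km", "arithmetic")) {
  mean_rule <- match.arg(mean_rule)
  .check_times_events(times, events)
  curve <- fit_km(times, events)
  mu <- if (mean_rule == "km") curve$mean_survival else mean(times)
  imputed <- times
  cens <- which(events == 0)
  for (i in cens) {
    t0 <- times[i]
    imputed[i] <- if (t0 <= mu / 2) {
      mu
    } else {
      expected_residual_survival(curve, t0)
    }
  }
  data.frame(time = times, event = events, imputed_time = imputed)
}

#' Split samples into short/long survival by 1-D variance minimization
#'
#' Exhaustively scans all cut points between consecutive distinct imputed
#' times and picks the one minimizing the total within-class sum of squares
#' (the 1-D, two-class analogue of k-means / Otsu thresholding). Both classes
#' are guaranteed non-empty; samples above the threshold are labelled
#' `"long"`. Deterministic and seed-free; criterion ties resolve to the
#' lowest admissible threshold.
#'
#' @param x imputed survival times (>= 2 distinct values).
#' @return character vector of `"short"`/`"long"` labels with attribute
#'   `threshold` (midpoint between the two straddling values).
#' @export
split_two_groups <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("need at least two samples to split", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("all imputed times identical: no admissible split", call. = FALSE)
  }
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs1 <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1)
  ss_left <- cs2[i] - cs1[i]^2 / i
  nr <- n - i
  s1r <- cs1[n] - cs1[i]
  s2r <- cs2[n] - cs2[i]
  ss_right <- s2r - s1r^2 / nr
  wss <- ss_left + ss_right
  valid <- xs[i] != xs[i + 1]  # cannot cut between tied values
  wss[!valid] <- Inf
  cut <- which.min(wss)
  threshold <- (xs[cut] + xs[cut + 1]) / 2
  labels <- ifelse(x > threshold, "long", "short")
  attr(labels, "threshold") <- threshold
  labels
}

#' Build the two-level survival tree (LL / LS / SL / SS)
#'
#' Imputes censored survival on the full cohort, splits it into long (L) and
#' short (S), then re-runs imputation *within* each side (the KM curve of the
#' subset) and splits again, yielding LL/LS under L and SL/SS under S. The
#' first letter of the leaf is always the level-1 label.
#'
#' The split criterion operates on the *log* of the imputed times by default
#' (`split_rule = "log_variance"`): survival times are strongly right-skewed,
#' and variance minimization on the raw scale degenerates into splitting off
#' the upper tail, which produces severely imbalanced groups. The raw-scale
#' rule (`"variance"`) and a median split (`"median"`) are available for
#' sensitivity analysis.
#'
#' @param times,events observed survival data.
#' @param sample_ids optional sample identifiers.
#' @param min_leaf smallest admissible level-1 group (default 10); below
#'   this, Gaussian parameter estimates downstream are unusable and the
#'   two-group model should be used instead.
#' @param mean_rule passed to [impute_survival()].
#' @param split_rule `"log_variance"` (default), `"variance"` or `"median"`.
#' @return data.frame: `sample_id`, `level1` (S/L), `level2` (LL/LS/SL/SS),
#'   `imputed_time` (cohort-level imputation), `imputed_within` (subset-level
#'   imputation used for the level-2 split).
#' @export
build_survival_tree <- function(times, events, sample_ids = NULL,
                                min_leaf = 10L, mean_rule = "km",
                                split_rule = c("log_variance", "variance",
                                               "median")) {
  split_rule <- match.arg(split_rule)
  .check_times_events(times, events)
  n <- length(times)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  do_split <- function(imputed) {
    switch(split_rule,
      log_variance = split_two_groups(log(imputed)),
      variance = split_two_groups(imputed),
      median = {
        med <- stats::median(imputed)
        if (all(imputed <= med) || all(imputed > med)) {
          stop("median split produced an empty group", call. = FALSE)
        }
        ifelse(imputed > med, "long", "short")
      })
  }
  imp <- impute_survival(times, events, mean_rule)
  lab1 <- do_split(imp$imputed_time)
  level1 <- ifelse(lab1 == "long", "L", "S")

  level2 <- character(n)
  imputed_within <- numeric(n)
  for (side in c("L", "S")) {
    idx <- which(level1 == side)
    if (length(idx) < max(2L, min_leaf)) {
      stop(sprintf("level-1 group '%s' has only %d samples (min_leaf = %d); use the two-group model",
                   side, length(idx), min_leaf), call. = FALSE)
    }
    imp2 <- impute_survival(times[idx], events[idx], mean_rule)
    lab2 <- do_split(imp2$imputed_time)
    level2[idx] <- paste0(side, ifelse(lab2 == "long", "L", "S"))
    imputed_within[idx] <- imp2$imputed_time
  }
  data.frame(sample_id = sample_ids, level1 = level1, level2 = level2,
             imputed_time = imp$imputed_time, imputed_within = imputed_within,
             stringsAsFactors = FALSE)
}
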