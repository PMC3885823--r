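#' Probe-trial response curve
#'
#' Empirical response rate as a function of time within the trial: in each
#' time bin, the fraction of sampled actions (across the selected trials)
#' that were `action`. Rates are valid frequencies in `[0, 1]`.
#'
#' @param session A `session_result` from [run_instrumental_session()] with
#'   per-step records for the selected trials.
#' @param bin_s Bin width in seconds.
#' @param trial_types Trial types to include (default peak probes).
#' @param trials Optional explicit trial indices to include (intersected
#'   with `trial_types`).
#' @param action Which action counts as a response.
#' @return A data frame of class `response_curve` with `bin_center_s`,
#'   `rate` and `n_obs` (action samples per bin); the number of
#'   contributing trials is attached as attribute `n_trials`.
#' @export
response_curve <- function(session, bin_s = 1, trial_types = "peak_probe",
                           trials = NULL, action = "respond") {
  stopifnot(inherits(session, "session_result"))
  st <- session$steps
  if (!nrow(st) || !"action" %in% names(st))
    stop("session has no recorded action steps")
  keep <- st$trial_type %in% trial_types & !is.na(st$action)
  if (!is.null(trials)) keep <- keep & st$trial %in% trials
  st <- st[keep, , drop = FALSE]
  if (!nrow(st)) stop("no matching trials with recorded actions")
  bin <- floor(st$time_s / bin_s)
  resp <- tapply(st$action == action, bin, mean)
  nobs <- tapply(st$action, bin, length)
  bins <- as.numeric(names(resp))
  out <- data.frame(bin_center_s = (bins + 0.5) * bin_s,
                    rate = as.numeric(resp), n_obs = as.integer(nobs))
  out <- out[order(out$bin_center_s), ]
  rownames(out) <- NULL
  structure(out, class = c("response_curve", "data.frame"),
            n_trials = length(unique(st$trial)), bin_s = bin_s)
}

# Moving-average smoother used by the argmax fallback.
smooth_ma <- function(y, k = 5L) {
  n <- length(y)
  if (n < k) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ifelse(is.na(s), y, s)
}

#' Peak time and spread of a response curve
#'
#' Fits `rate(t) = b + a * exp(-(t - m)^2 / (2 s^2))` by least squares; the
#' fitted mean `m` is the peak time (the subject's interval estimate) and
#' the fitted SD `s` the spread of timed responding. The constant baseline
#' `b` absorbs time-independent responding. If the nonlinear fit fails, the
#' function falls back to the argmax of a moving-average-smoothed curve
#' (window `smooth_k` bins), with the spread taken from the half-maximum
#' width and `fit_quality` set to `NA`.
#'
#' @param curve A [response_curve()] (or any data frame with
#'   `bin_center_s` and `rate`).
#' @param smooth_k Smoothing window (bins) for the fallback argmax.
#' @return A list of class `peak_stats`: `peak_time_s`, `spread_s`,
#'   `fit_quality` (R^2 of the Gaussian fit, `NA` if the fallback was
#'   used), `peak_time_raw_s` (smoothed argmax), `baseline`, `amplitude`,
#'   `method`.
#' @export
peak_statistics <- function(curve, smooth_k = 5L) {
  t <- curve$bin_center_s
  y <- curve$rate
  if (length(t) < 5) stop("response curve too short to characterize a peak")
  if (all(y == 0)) stop("all-zero response curve: peak undefined")
  ys <- smooth_ma(y, smooth_k)
  i0 <- which.max(ys)
  raw_peak <- t[i0]
  b0 <- stats::quantile(y, 0.25, names = FALSE)
  a0 <- max(ys) - b0
  s0 <- max(diff(range(t)) / 6, mean(diff(t)))
  fit <- NULL
  if (a0 > 0) {
    dat <- data.frame(t = t, y = y)
    fit <- tryCatch(
      nls(y ~ b + a * exp(-(t - m)^2 / (2 * s^2)), data = dat,
          start = list(b = b0, a = a0, m = raw_peak, s = s0),
          lower = c(b = -1, a = 1e-6, m = min(t), s = mean(diff(t)) / 2),
          upper = c(b = 2, a = 2, m = max(t), s = 2 * diff(range(t))),
          algorithm = "port",
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    out <- list(peak_time_s = unname(cf["m"]), spread_s = unname(abs(cf["s"])),
                fit_quality = if (tss > 0) 1 - rss / tss else NA_real_,
                peak_time_raw_s = raw_peak, baseline = unname(cf["b"]),
                amplitude = unname(cf["a"]), method = "gaussian")
  } else {
    half <- (min(ys) + max(ys)) / 2
    above <- range(which(ys >= half))
    fwhm <- t[above[2]] - t[above[1]]
    out <- list(peak_time_s = raw_peak,
                spread_s = max(fwhm, mean(diff(t))) / 2.355,
                fit_quality = NA_real_, peak_time_raw_s = raw_peak,
                baseline = min(ys), amplitude = max(ys) - min(ys),
                method = "smoothed_argmax")
  }
  class(out) <- "peak_stats"
  out
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("<peak_stats> peak = %.2f s, spread (SD) = %.2f s [%s, R2 = %s]\n",
              x$peak_time_s, x$spread_s, x$method,
              ifelse(is.na(x$fit_quality), "NA", sprintf("%.3f", x$fit_quality))))
  invisible(x)
}

#' Psychometric function from a bisection session
#'
#' Proportion of "long" choices as a function of probe cue duration, with
#' the indifference point (point of subjective equality) obtained by linear
#' interpolation of `p(long)` against *log* duration at 0.5 --- consistent
#' with the geometric-mean regularity of bisection. Trials on which no
#' choice was made are excluded. If `p(long)` never crosses 0.5, the
#' indifference point is reported as `NA` rather than extrapolated.
#'
#' @param session A `session_result` from a bisection task.
#' @param trial_types Trial types to include (default probes only).
#' @return A list of class `psychometric_result`: `table` (duration_s,
#'   p_long, n), `indifference_s`.
#' @export
psychometric <- function(session, trial_types = "bisection_probe") {
  stopifnot(inherits(session, "session_result"))
  tr <- session$trials
  dur_s <- session$task_meta$duration_s
  if (is.null(dur_s)) stop("session does not carry bisection durations")
  keep <- tr$trial_type %in% trial_types & !is.na(tr$choice)
  if (!any(keep)) stop("no choices recorded on the selected trials")
  d <- dur_s[tr$trial[keep]]
  long <- tr$choice[keep] == "long"
  p_long <- tapply(long, d, mean)
  n <- tapply(long, d, length)
  tab <- data.frame(duration_s = as.numeric(names(p_long)),
                    p_long = as.numeric(p_long), n = as.integer(n))
  tab <- tab[order(tab$duration_s), ]
  rownames(tab) <- NULL
  ind <- NA_real_
  crosses <- which(diff(sign(tab$p_long - 0.5)) != 0)
  if (any(tab$p_long == 0.5)) {
    ind <- exp(mean(log(tab$duration_s[tab$p_long == 0.5])))
  } else if (length(crosses)) {
    i <- crosses[1]
    lx <- log(tab$duration_s[i:(i + 1)])
    py <- tab$p_long[i:(i + 1)]
    ind <- exp(lx[1] + (0.5 - py[1]) * diff(lx) / diff(py))
  }
  structure(list(table = tab, indifference_s = ind),
            class = "psychometric_result")
}

#' @export
print.psychometric_result <- function(x, ...) {
  cat("<psychometric_result> indifference point:",
      ifelse(is.na(x$indifference_s), "not crossed",
             sprintf("%.2f s", x$indifference_s)), "\n")
  print(x$table)
  invisible(x)
}

#' Cue and reward prediction-error summary across intervals
#'
#' For a set of Pavlovian sessions run at different cue-reward intervals,
#' extracts the prediction error at the cue (the transition into the
#' cue-onset state) and at the reward step, averaged over the last `k_last`
#' trials of each session. With `k_last = 1` this is the final-trial
#' read-out.
#'
#' @param sessions List of `session_result`s, each from a task whose meta
#'   carries `interval_s`.
#' @param k_last Number of final trials to average (default 1).
#' @return Data frame with one row per session: `interval_s`, `cue_delta`,
#'   `reward_delta`, `n_trials`.
#' @export
event_pe_summary <- function(sessions, k_last = 1) {
  if (inherits(sessions, "session_result")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    stopifnot(inherits(s, "session_result"))
    n <- nrow(s$trials)
    if (k_last > n) stop("`k_last` exceeds the number of trials")
    idx <- seq.int(n - k_last + 1L, n)
    data.frame(interval_s = s$task_meta$interval_s %||% NA_real_,
               cue_delta = mean(s$trials$cue_delta[idx]),
               reward_delta = mean(s$trials$reward_delta[idx]),
               n_trials = n)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
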