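#' Critical performance measures
#'
#' Scalar summaries of a closed-loop run: root-mean-squared and
#' sum-of-absolute glucose error, mean-squared input, fall/settling/recovery
#' times, disturbance overshoot and peak infusion.
#'
#' @name cpm
NULL

#' @describeIn cpm root-mean-squared glucose error (mg/dL):
#'   `sqrt(mean(err^2))` over the sampled error series.
#' @param errors sampled glucose-error series `Gss - G` (mg/dL).
#' @export
e_rms <- function(errors) {
  if (length(errors) == 0L) stop("empty error series", call. = FALSE)
  sqrt(mean(errors^2))
}

#' @describeIn cpm sum of absolute glucose errors (mg/dL).
#' @export
e_sa <- function(errors) {
  if (length(errors) == 0L) stop("empty error series", call. = FALSE)
  sum(abs(errors))
}

#' @describeIn cpm mean-squared insulin infusion ((mU/min)^2).
#' @param u sampled infusion series (mU/min).
#' @export
u_ms <- function(u) {
  if (length(u) == 0L) stop("empty input series", call. = FALSE)
  mean(u^2)
}

#' @describeIn cpm time for the glucose level to first fall to +10% of the
#'   reference (i.e. `G <= 1.1 * Gref`), in minutes. Errors if never reached.
#' @param G sampled true glucose series (mg/dL).
#' @param time sample times (min); defaults to `0:(length(G)-1)`.
#' @param Gref reference glucose level (mg/dL).
#' @export
t_fall <- function(G, time = seq_along(G) - 1, Gref = 80) {
  idx <- which(G <= 1.1 * Gref)
  if (length(idx) == 0L)
    stop("glucose never falls to +10% of the reference; T_fall undefined",
         call. = FALSE)
  time[idx[1L]]
}

#' @describeIn cpm settling time: first time after which the glucose level
#'   stays within +/-5% of the reference for the remainder of the window.
#'   Errors if the series ends outside the band.
#' @param band half-width of the settling band as a fraction of `Gref`.
#' @export
t_set <- function(G, time = seq_along(G) - 1, Gref = 80, band = 0.05) {
  inside <- G >= (1 - band) * Gref & G <= (1 + band) * Gref
  out <- which(!inside)
  if (length(out) == 0L) return(time[1L]) # inside throughout the window
  last_out <- out[length(out)]
  if (last_out == length(G))
    stop("glucose does not settle within the band by the end of the window",
         call. = FALSE)
  time[last_out + 1L]
}

#' @describeIn cpm recovery time after a transient disturbance: the settling
#'   time of the post-event window, reported relative to the event time.
#' @param t_event disturbance event time (min).
#' @export
t_rec <- function(G, time = seq_along(G) - 1, t_event, Gref = 80,
                  band = 0.05) {
  sel <- time > t_event
  if (!any(sel)) stop("no samples after the event time", call. = FALSE)
  t_set(G[sel], time[sel], Gref = Gref, band = band) - t_event
}

#' @describeIn cpm overshoot after a transient disturbance: maximum of
#'   `G - Gref` over the post-event window, floored at zero.
#' @export
overshoot <- function(G, time = seq_along(G) - 1, t_event, Gref = 80) {
  sel <- time > t_event
  if (!any(sel)) stop("no samples after the event time", call. = FALSE)
  max(0, max(G[sel] - Gref))
}

#' @describeIn cpm peak infusion magnitude in a window: the start window is
#'   the initial hyperglycemic phase (before the settling time), the
#'   disturbance window everything after the event time.
#' @param window either `c(from, to)` in minutes or `"all"`.
#' @export
u_peak <- function(u, time = seq_along(u) - 1, window = "all") {
  sel <- if (identical(window, "all")) rep(TRUE, length(u))
  else time >= window[1L] & time <= window[2L]
  if (!any(sel)) stop("empty peak window", call. = FALSE)
  max(abs(u[sel]))
}

#' Tuning cost of a closed-loop run
#'
#' `J = |T_set| + integral(err^2 + u^2) dt` with the integral taken by the
#' trapezoidal rule over the sampled run. If the run never settles, `T_set`
#' is replaced by the run duration (maximal penalty), keeping the cost
#' finite and monotone for the tuning loop.
#'
#' @param result a `glycoreg_sim` (or a list with `time`, `G_true`,
#'   `G_meas`, `u` and a patient holding `Gss`).
#' @return Scalar cost.
#' @export
objective_j <- function(result) {
  tt <- result$time
  err <- result$patient$Gss - result$G_meas
  u <- result$u
  ts <- tryCatch(t_set(result$G_true, tt, Gref = result$patient$Gss),
                 error = function(e) max(tt))
  integrand <- err^2 + u^2
  quad <- sum(diff(tt) * (head2(integrand) + tail2(integrand)) / 2)
  abs(ts) + quad
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1L]

#' Full performance report of a run
#'
#' Computes the applicable critical performance measures of a closed-loop
#' run; timing metrics that are undefined for the run (e.g. a series that
#' never settles) are reported as `NA`.
#'
#' @param result a `glycoreg_sim`.
#' @return A one-row `data.frame` with columns `E_rms`, `E_sa`, `T_fall`,
#'   `T_set`, `T_rec`, `OS`, `U_ms`, `U_p_start`, `U_p_dist` (NA where not
#'   applicable).
#' @export
cpm_report <- function(result) {
  stopifnot(inherits(result, "glycoreg_sim"))
  tt <- result$time
  Gref <- result$patient$Gss
  err <- Gref - result$G_meas
  G <- result$G_true
  u <- result$u
  ev <- if (!is.null(result$scenario$meal)) result$scenario$meal$time
  else if (!is.null(result$scenario$stress)) result$scenario$stress$time
  else NULL
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  tset <- try_na(t_set(G, tt, Gref))
  data.frame(
    E_rms = e_rms(err), E_sa = e_sa(err),
    T_fall = try_na(t_fall(G, tt, Gref)),
    T_set = tset,
    T_rec = if (is.null(ev)) NA_real_ else try_na(t_rec(G, tt, ev, Gref)),
    OS = if (is.null(ev)) NA_real_ else try_na(overshoot(G, tt, ev, Gref)),
    U_ms = u_ms(u),
    U_p_start = if (is.finite(tset) && tset > 0)
      u_peak(u, tt, c(0, tset)) else u_peak(u, tt),
    U_p_dist = if (is.null(ev)) NA_real_
    else try_na(u_peak(u, tt, c(ev + tt[2L] - tt[1L], max(tt)))))
}

#' Normal-approximation confidence interval of a mean
#'
#' `mean +/- z * sd / sqrt(N)` with `z = qnorm((1 + level)/2)` (1.96 at the
#' 95% level).
#'
#' @param x numeric sample.
#' @param level confidence level in (0, 1).
#' @return List with `mean`, `half_width`, `lo`, `hi`, `sd`, `n`.
#' @export
confidence_interval <- function(x, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two samples for a confidence interval",
                   call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  hw <- qnorm((1 + level) / 2) * s / sqrt(n)
  list(mean = m, half_width = hw, lo = m - hw, hi = m + hw, sd = s, n = n)
}

#' Welch two-sample t-test with dual critical values
#'
#' Two-sided unequal-variance t-test of `mean(a) == mean(b)`. The decision
#' uses the exact Welch-Satterthwaite critical value; the large-sample
#' normal critical value (1.96 at `alpha = 0.05`) is reported alongside for
#' comparison with tabulated analyses that use it.
#'
#' @param a,b numeric samples.
#' @param alpha significance level in (0, 1).
#' @return Object of class `welch_t_test`: `t_stat`, `df`, `p_value`,
#'   `t_critical` (Welch), `t_critical_normal`, `reject`, `alpha`,
#'   `mean_diff`.
#' @export
welch_t_test <- function(a, b, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  df <- unname(ht$parameter)
  structure(list(t_stat = unname(ht$statistic), df = df,
                 p_value = ht$p.value,
                 t_critical = qt(1 - alpha / 2, df),
                 t_critical_normal = qnorm(1 - alpha / 2),
                 reject = ht$p.value < alpha, alpha = alpha,
                 mean_diff = mean(a) - mean(b)),
            class = "welch_t_test")
}

#' @export
print.welch_t_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.3f (df = %.1f), p = %.3g\n",
              x$t_stat, x$df, x$p_value))
  cat(sprintf("  critical |t|: %.3f (Welch), %.3f (normal approx.)\n",
              x$t_critical, x$t_critical_normal))
  cat(sprintf("  H0 %s at alpha = %g\n",
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}
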