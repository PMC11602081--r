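new_scenario <- function(name, duration, noise_sd, meal = NULL, stress = NULL,
                         fault = NULL, u_min = 0, u_max = 100) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (u_min >= u_max) stop("u_min must be < u_max", call. = FALSE)
  structure(list(name = name, duration = duration, dt = 1,
                 noise_sd = noise_sd, meal = meal, stress = stress,
                 fault = fault, u_min = u_min, u_max = u_max,
                 N = as.integer(round(duration / 1))),
            class = "scenario_config")
}

#' Scenario A: settle from initial hyperglycemia
#'
#' Brings the patient from the hyperglycemic initial state (200 mg/dL) down
#' to the 80 mg/dL setpoint under Gaussian sensor noise (zero mean,
#' variance 0.2 (mg/dL)^2), with no disturbance events. The controller
#' samples every 60 s, so `N = duration` samples are taken after t = 0.
#'
#' @param duration run length in minutes (default 500; tuning runs use 300).
#' @param noise logical, include measurement noise (default `TRUE`).
#' @return A `scenario_config`.
#' @export
scenario_hyperglycemia <- function(duration = 500, noise = TRUE) {
  new_scenario("hyperglycemia", duration,
               noise_sd = if (noise) sqrt(0.2) else 0)
}

#' Scenario B: transient meal disturbance
#'
#' A 1000-min run with sensor noise and an 80 mg/dL meal impulse at
#' t = 500 min. By default the impulse is realized as an instantaneous
#' +80 mg/dL jump of the glucose state (the reported post-meal excursions
#' reach the full impulse amplitude); `route = "pulse"` instead feeds an
#' 80-amplitude rectangular pulse of one controller-period width through the
#' meal input channel `Gm/V1`.
#'
#' @param duration run length (min).
#' @param amplitude impulse amplitude (mg/dL).
#' @param time event time (min).
#' @param route `"state-jump"` (default) or `"pulse"`.
#' @param noise logical, include measurement noise.
#' @return A `scenario_config`.
#' @export
scenario_meal <- function(duration = 1000, amplitude = 80, time = 500,
                          route = c("state-jump", "pulse"), noise = TRUE) {
  new_scenario("meal", duration, noise_sd = if (noise) sqrt(0.2) else 0,
               meal = list(time = time, amplitude = amplitude,
                           route = match.arg(route)))
}

#' Scenario C: stress-induced parameter change
#'
#' A 1000-min run with sensor noise in which physical/mental stress is
#' emulated at t = 500 min by switching the plant's rate parameters to
#' `p1 = 8.0e-3`, `p2 = 25.0e-3`, `p3 = 2.5e-6` (1/min): reduced glucose
#' effectiveness, faster waning of insulin action and reduced insulin
#' sensitivity, as counter-regulatory hormones would cause. The controller
#' keeps its nominal design (it is not informed of the change).
#'
#' @param duration run length (min).
#' @param time event time (min).
#' @param p1,p2,p3 post-event rate parameters (1/min).
#' @param noise logical, include measurement noise.
#' @return A `scenario_config`.
#' @export
scenario_stress <- function(duration = 1000, time = 500,
                            p1 = 8.0e-3, p2 = 25.0e-3, p3 = 2.5e-6,
                            noise = TRUE) {
  new_scenario("stress", duration, noise_sd = if (noise) sqrt(0.2) else 0,
               stress = list(time = time, p1 = p1, p2 = p2, p3 = p3))
}

#' Sensor drift-and-bias robustness scenario
#'
#' Adds the corruption `5 + 2 sin(0.2 t)` (mg/dL, t in minutes) to every
#' glucose measurement: a constant calibration bias of 5 mg/dL plus a
#' slow sinusoidal drift of amplitude 2 mg/dL (period `2*pi/0.2` = 10*pi
#' min), on top of the usual Gaussian sensor noise.
#'
#' @param duration run length (min), default 500 as for the settling runs.
#' @param bias constant offset (mg/dL).
#' @param amplitude drift amplitude (mg/dL).
#' @param omega drift angular rate (rad/min).
#' @param noise logical, include measurement noise.
#' @return A `scenario_config`.
#' @export
scenario_sensor_fault <- function(duration = 500, bias = 5, amplitude = 2,
                                  omega = 0.2, noise = TRUE) {
  new_scenario("sensor-fault", duration,
               noise_sd = if (noise) sqrt(0.2) else 0,
               fault = list(bias = bias, amplitude = amplitude, omega = omega))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': %g min, 60-s sampling (N = %d), noise sd = %.4g mg/dL\n",
              x$name, x$duration, x$N, x$noise_sd))
  if (!is.null(x$meal))
    cat(sprintf("  meal: +%g mg/dL (%s) at t = %g min\n",
                x$meal$amplitude, x$meal$route, x$meal$time))
  if (!is.null(x$stress))
    cat(sprintf("  stress at t = %g min: p1=%g p2=%g p3=%g\n",
                x$stress$time, x$stress$p1, x$stress$p2, x$stress$p3))
  if (!is.null(x$fault))
    cat(sprintf("  sensor fault: %g + %g sin(%g t) mg/dL\n",
                x$fault$bias, x$fault$amplitude, x$fault$omega))
  cat(sprintf("  infusion limits: [%g, %g] mU/min\n", x$u_min, x$u_max))
  invisible(x)
}

#' Scenario lookup by name
#' @param name one of `"hyperglycemia"` (alias `"A"`), `"meal"` (`"B"`),
#'   `"stress"` (`"C"`), `"sensor-fault"`.
#' @param ... passed to the scenario constructor.
#' @return A `scenario_config`.
#' @export
scenario_by_name <- function(name, ...) {
  switch(name,
         "A" = , "hyperglycemia" = scenario_hyperglycemia(...),
         "B" = , "meal" = scenario_meal(...),
         "C" = , "stress" = scenario_stress(...),
         "sensor-fault" = scenario_sensor_fault(...),
         stop("unknown scenario '", name,
              "'; valid: hyperglycemia (A), meal (B), stress (C), sensor-fault",
              call. = FALSE))
}
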