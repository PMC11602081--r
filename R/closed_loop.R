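#' Run the sampled-data glucose-regulation closed loop
#'
#' Integrates the nonlinear plant continuously between controller samples
#' (adaptive-step `lsoda`, tolerance 1e-8) while the controller runs at a
#' fixed 60-s period: at each sample the glucose measurement is corrupted by
#' sensor noise (and the drift/bias fault, if configured), the error
#' integral and sliding surface are updated from measured quantities, the
#' command is computed, clamped to the pump limits and held (zero-order
#' hold) until the next sample.
#'
#' Feedback information set: `X` and `I` are fed back as true plant states
#' (the control laws assume full state feedback); only the glucose channel
#' is measured through the noisy sensor; the error integral accumulates the
#' measured error by the trapezoidal rule; no anti-windup is applied to it
#' (the early phase with the command clamped at zero relies on the integral
#' winding up to build insulin drive).
#'
#' Disturbance events fire exactly at their configured times: the meal
#' impulse either jumps the glucose state or feeds the meal channel for one
#' sampling period; the stress event switches the plant's rate parameters
#' (the controller is not re-designed).
#'
#' @param patient a [patient_params()] object or preset id string.
#' @param controller a `controller_spec` (see [controller_lqir()]) or name.
#' @param scenario a `scenario_config` (see [scenario_hyperglycemia()]) or
#'   name.
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param form plant reading, `"deviation"` (default) or `"literal"`.
#' @param rtol,atol integrator tolerances.
#' @param d_max disturbance bound checked against the switching gain for
#'   the sliding-mode variants (mU/min).
#' @return Object of class `glycoreg_sim`: sampled series `time`, `G_true`,
#'   `G_meas`, `X`, `I`, `eps`, `s`, `M`, `u` (one entry per 60-s sample,
#'   `N + 1` in total), `flags` (`nonphysical`, `saturation_fraction`) and
#'   run provenance.
#' @export
run_closed_loop <- function(patient, controller, scenario, seed = 1L,
                            form = c("deviation", "literal"),
                            rtol = 1e-8, atol = 1e-8, d_max = 4) {
  form <- match.arg(form)
  if (is.character(patient)) patient <- preset_patient(patient)
  if (is.character(controller)) controller <- controller_by_name(controller)
  if (is.character(scenario)) scenario <- scenario_by_name(scenario)
  stopifnot(inherits(patient, "patient_params"),
            inherits(controller, "controller_spec"),
            inherits(scenario, "scenario_config"))
  is_smc <- controller$type %in% c("lq-smc", "lq-asmc")
  if (is_smc && !stability_condition(controller$sliding, d_max))
    stop(sprintf("switching gain beta = %g does not exceed the disturbance bound %g",
                 controller$sliding$beta, d_max), call. = FALSE)

  model <- linearize(patient, form = form)
  K <- controller$K
  cfg <- controller$sliding
  p <- patient
  sc <- scenario
  N <- sc$N
  dt <- sc$dt

  set.seed(as.integer(seed))
  noise <- if (sc$noise_sd > 0) rnorm(N + 1, 0, sc$noise_sd) else numeric(N + 1)

  tt <- seq(0, N) * dt
  G_true <- G_meas <- Xs <- Is <- epss <- ss <- Ms <- us <- numeric(N + 1)
  y <- initial_state(p)                     # (G, X, I, eps_true)
  eps_c <- p$eps0                           # controller-side error integral
  err_prev <- NA_real_
  surface <- NULL
  n_sat <- 0L
  nonphysical <- FALSE

  for (k in 0:N) {
    t_k <- k * dt
    stressed <- !is.null(sc$stress) && t_k >= sc$stress$time
    if (!is.null(sc$meal) && sc$meal$route == "state-jump" &&
        t_k == sc$meal$time)
      y[["G"]] <- y[["G"]] + sc$meal$amplitude

    fault_k <- if (!is.null(sc$fault))
      sc$fault$bias + sc$fault$amplitude * sin(sc$fault$omega * t_k) else 0
    g_meas <- y[["G"]] + noise[k + 1L] + fault_k
    err <- p$Gss - g_meas
    if (k > 0L) eps_c <- eps_c + dt * (err_prev + err) / 2
    err_prev <- err

    x_fb <- c(g_meas, y[["X"]], y[["I"]], eps_c)
    u_lq <- lqir_control(K, x_fb)

    M_k <- 0
    if (is_smc) {
      if (k == 0L) {
        surface <- init_surface(cfg, x_fb)
        surface$zdot <- surface_zdot(cfg$g, x_fb, u_lq, model)
      } else {
        surface <- surface_step(surface, x_fb, u_lq, model, dt)
      }
      if (controller$type == "lq-asmc") {
        M_k <- adaptive_gain(cfg$Mo, cfg$gamma, err)
        u_raw <- u_lq - M_k * tanh(surface$s)
      } else {
        M_k <- cfg$Mo
        lim <- if (cfg$mode == "sgn") sign(surface$s) else tanh(surface$s)
        u_raw <- u_lq - cfg$Mo * lim
      }
    } else {
      u_raw <- u_lq
    }
    u_app <- min(max(u_raw, sc$u_min), sc$u_max)
    if (u_raw < sc$u_min || u_raw > sc$u_max) n_sat <- n_sat + 1L

    G_true[k + 1L] <- y[["G"]]; G_meas[k + 1L] <- g_meas
    Xs[k + 1L] <- y[["X"]]; Is[k + 1L] <- y[["I"]]; epss[k + 1L] <- eps_c
    ss[k + 1L] <- if (is_smc) surface$s else 0
    Ms[k + 1L] <- M_k; us[k + 1L] <- u_app

    if (y[["G"]] < 0 || y[["I"]] < -p$Ib - 1e-9) nonphysical <- TRUE
    if (k == N) break

    gm_now <- if (!is.null(sc$meal) && sc$meal$route == "pulse" &&
                  t_k >= sc$meal$time && t_k < sc$meal$time + dt)
      sc$meal$amplitude else 0
    pars <- c(if (stressed) sc$stress$p1 else p$p1,
              if (stressed) sc$stress$p2 else p$p2,
              if (stressed) sc$stress$p3 else p$p3,
              p$n, p$Ib, p$Gss, p$V1, u_app, gm_now,
              if (form == "deviation") 0 else 1)
    sol <- deSolve::ode(y = y, times = c(t_k, t_k + dt),
                        func = "glycoreg_derivs", parms = pars,
                        dllname = "glycoreg", initfunc = "glycoreg_init",
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol[2L, -1L])))
      stop(sprintf("plant integration failed at t = %g min (last state: %s)",
                   t_k, paste(signif(y, 6), collapse = ", ")), call. = FALSE)
    y <- setNames(as.numeric(sol[2L, -1L]), .STATE_NAMES)
  }

  structure(list(
    time = tt, G_true = G_true, G_meas = G_meas, X = Xs, I = Is, eps = epss,
    s = ss, M = Ms, u = us,
    flags = list(nonphysical = nonphysical,
                 saturation_fraction = n_sat / (N + 1)),
    patient = p, controller = controller, scenario = sc,
    seed = as.integer(seed), form = form),
    class = "glycoreg_sim")
}

#' @export
print.glycoreg_sim <- function(x, ...) {
  cat(sprintf("Closed-loop run: %s / %s / %s (seed %d, form %s)\n",
              x$patient$id, x$controller$type, x$scenario$name, x$seed, x$form))
  cat(sprintf("  %d samples over %g min; final BG %.2f mg/dL; mean IIR %.3f mU/min\n",
              length(x$time), max(x$time), x$G_true[length(x$G_true)], mean(x$u)))
  cat(sprintf("  saturation active at %.1f%% of samples%s\n",
              100 * x$flags$saturation_fraction,
              if (x$flags$nonphysical) "; NONPHYSICAL STATE REACHED" else ""))
  invisible(x)
}

#' @export
as.data.frame.glycoreg_sim <- function(x, ...) {
  data.frame(t_min = x$time, G_true = x$G_true, G_meas = x$G_meas,
             X = x$X, I = x$I, eps = x$eps, s = x$s, M = x$M, u = x$u)
}

#' Write a simulation result to CSV with a JSON provenance sidecar
#'
#' @param result a `glycoreg_sim`.
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.json` unless `json_path` is given.
#' @param json_path optional explicit sidecar path (`NA` to skip).
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(result, path, json_path = NULL) {
  stopifnot(inherits(result, "glycoreg_sim"))
  write.csv(as.data.frame(result), path, row.names = FALSE)
  if (is.null(json_path))
    json_path <- sub("\\.[^.]+$", ".json", path)
  if (!is.na(json_path)) {
    prov <- list(
      patient = unclass(result$patient),
      controller = list(type = result$controller$type,
                        K = as.numeric(result$controller$K),
                        sliding = if (!is.null(result$controller$sliding))
                          unclass(result$controller$sliding)[
                            c("g", "m", "beta", "Mo", "gamma", "mode", "adaptive")]),
      scenario = unclass(result$scenario),
      seed = result$seed, plant_form = result$form,
      flags = result$flags,
      software = paste0("glycoreg ",
                        as.character(utils::packageVersion("glycoreg"))))
    jsonlite::write_json(prov, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
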