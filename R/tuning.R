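#' Specification of the offline tuning problem
#'
#' Declares the search ranges (regulator weights in \[0, 1\], surface
#' weights in \[0, 0.01\], switching gain in \[4, 10\] mU/min, adaptation
#' rate in \[0, 1\]), the per-parameter increments, the cost setpoint and
#' the trial budget of the greedy offline tuning loop. The benchmark run
#' normalizes Patient 1 from 200 to 80 mg/dL over 300 min.
#'
#' @param start named numeric vector of starting values; defaults to the
#'   tuning loop's documented initialization (`Q = diag(1,1,1,1)`, `R = 1`,
#'   `G = (0.01, 0.01, 0.01, 0.01)`, `beta = 4`, `gamma = 0.1`).
#' @param increments named numeric vector of per-parameter step sizes.
#' @param setpoint stop when the best cost falls to or below this value.
#' @param n_max maximum number of trials (>= 1).
#' @param patient benchmark patient (preset id or [patient_params()]).
#' @param scenario benchmark scenario; default 300-min settling run.
#' @return Object of class `tuning_spec`.
#' @export
tuning_spec <- function(start = NULL, increments = NULL, setpoint = 1e7,
                        n_max = 8, patient = "patient1",
                        scenario = scenario_hyperglycemia(duration = 300)) {
  if (!is.numeric(n_max) || n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  par_names <- c("qG", "qX", "qI", "qeps", "rho",
                 "g1", "g2", "g3", "g4", "beta", "gamma")
  lower <- c(rep(0, 4), 1e-6, rep(1e-6, 4), 4, 1e-6)
  upper <- c(rep(1, 4), 1,    rep(0.01, 4), 10, 1)
  names(lower) <- names(upper) <- par_names
  default_start <- c(qG = 1, qX = 1, qI = 1, qeps = 1, rho = 1,
                     g1 = 0.01, g2 = 0.01, g3 = 0.01, g4 = 0.01,
                     beta = 4, gamma = 0.1)
  default_inc <- c(qG = 0.1, qX = 0.1, qI = 0.1, qeps = 0.1, rho = 0.05,
                   g1 = 0.001, g2 = 0.001, g3 = 0.001, g4 = 0.001,
                   beta = 0.5, gamma = 0.02)
  start <- if (is.null(start)) default_start else
    modifyList(as.list(default_start), as.list(start)) |> unlist()
  increments <- if (is.null(increments)) default_inc else
    modifyList(as.list(default_inc), as.list(increments)) |> unlist()
  start <- pmin(pmax(start[par_names], lower), upper)
  structure(list(start = start, increments = increments[par_names],
                 lower = lower, upper = upper, setpoint = setpoint,
                 n_max = as.integer(n_max), patient = patient,
                 scenario = scenario),
            class = "tuning_spec")
}

tuning_cost <- function(par, spec, seed) {
  w <- lq_weights(par[["qG"]], par[["qX"]], par[["qI"]], par[["qeps"]],
                  par[["rho"]])
  cfg <- suppressWarnings(sliding_config(
    g1 = par[["g1"]], g2 = par[["g2"]], g3 = par[["g3"]], g4 = par[["g4"]],
    m = par[["g1"]] / par[["g3"]], beta = par[["beta"]],
    gamma = par[["gamma"]]))
  patient <- if (is.character(spec$patient)) preset_patient(spec$patient)
  else spec$patient
  des <- lqir_design(patient, w)
  ctrl <- controller_lq_asmc(K = des$K, sliding = cfg)
  # the benchmark settling run carries no exogenous disturbance, so the
  # reaching-law bound check is run against d_max = 0
  res <- run_closed_loop(patient, ctrl, spec$scenario, seed = seed, d_max = 0)
  objective_j(res)
}

#' Greedy offline parameter tuning
#'
#' Cyclic coordinate descent over the declared parameter set: each trial
#' perturbs one parameter by its increment in both directions (clipped to
#' its range), runs the benchmark simulation, computes the cost `J`
#' ([objective_j()]) and accepts the perturbation only if the cost
#' decreases. The loop stops when the best cost reaches the setpoint or the
#' trial budget `n_max` is exhausted. The accepted-cost sequence is
#' non-increasing by construction.
#'
#' @param spec a [tuning_spec()].
#' @param seed RNG seed used for every benchmark run (fixed so that cost
#'   differences reflect the parameters, not the noise draw).
#' @return List with `par` (tuned vector), `J` (best cost) and `log`
#'   (data.frame: trial, parameter, value, J, accepted).
#' @export
tune <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tuning_spec"))
  par <- spec$start
  par_names <- names(par)
  eval_cost <- function(p) tryCatch(tuning_cost(p, spec, seed),
                                    error = function(e) NA_real_)
  J_best <- eval_cost(par)
  if (is.na(J_best)) stop("benchmark simulation failed at the starting point",
                          call. = FALSE)
  log <- data.frame(trial = 0L, parameter = "(start)",
                    value = NA_real_, J = J_best, accepted = TRUE)
  for (n in seq_len(spec$n_max)) {
    nm <- par_names[((n - 1L) %% length(par_names)) + 1L]
    best_cand <- NULL
    for (dir in c(+1, -1)) {
      cand <- par
      cand[[nm]] <- min(max(par[[nm]] + dir * spec$increments[[nm]],
                            spec$lower[[nm]]), spec$upper[[nm]])
      if (cand[[nm]] == par[[nm]]) next
      Jc <- eval_cost(cand)
      if (!is.na(Jc) && (is.null(best_cand) || Jc < best_cand$J))
        best_cand <- list(par = cand, J = Jc, value = cand[[nm]])
    }
    accepted <- !is.null(best_cand) && best_cand$J < J_best
    log <- rbind(log, data.frame(
      trial = n, parameter = nm,
      value = if (is.null(best_cand)) NA_real_ else best_cand$value,
      J = if (is.null(best_cand)) NA_real_ else best_cand$J,
      accepted = accepted))
    if (accepted) {
      par <- best_cand$par
      J_best <- best_cand$J
    }
    if (J_best <= spec$setpoint) break
  }
  list(par = par, J = J_best, log = log)
}

#' Sensitivity sweep of the tuned parameter set
#'
#' Re-runs the closed loop with every tuned coefficient scaled by
#' `1 + delta`, `1` and `1 - delta` (multiplicatively) and tabulates the
#' critical performance measures per patient. Scaling the regulator weights
#' `Q` and `R` by a common factor leaves the feedback gain unchanged, so
#' the sweep effectively probes the sliding-surface side (`G`, `m`, `beta`,
#' `gamma`); with `beta_only = TRUE` only the switching gain is varied.
#'
#' @param base a [sliding_config()] giving the nominal (tuned) setting.
#' @param delta relative perturbation (default 0.10).
#' @param patients character vector of preset ids.
#' @param scenario a `scenario_config` (default 500-min settling run).
#' @param seed RNG seed shared by all runs.
#' @param K feedback gain (held fixed across the sweep).
#' @param beta_only vary only `beta`.
#' @return data.frame: patient, change (fraction), one column per CPM.
#' @export
sensitivity_sweep <- function(base = sliding_config(), delta = 0.10,
                              patients = c("patient1", "patient2", "patient3"),
                              scenario = scenario_hyperglycemia(),
                              seed = 1L, K = tuned_gain_published(),
                              beta_only = FALSE) {
  rows <- list()
  for (pat in patients) {
    for (ch in c(+delta, 0, -delta)) {
      f <- 1 + ch
      cfg <- suppressWarnings(if (beta_only)
        sliding_config(g1 = base$g[[1]], g2 = base$g[[2]], g3 = base$g[[3]],
                       g4 = base$g[[4]], m = base$m, beta = base$beta * f,
                       gamma = base$gamma)
        else
          sliding_config(g1 = base$g[[1]] * f, g2 = base$g[[2]] * f,
                         g3 = base$g[[3]] * f, g4 = base$g[[4]] * f,
                         m = base$m * f, beta = base$beta * f,
                         gamma = base$gamma * f))
      res <- run_closed_loop(pat, controller_lq_asmc(K = K, sliding = cfg),
                             scenario, seed = seed)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patient = pat, change = ch), cpm_report(res))
    }
  }
  do.call(rbind, rows)
}
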