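#' Bergman-minimal-model patient parameters
#'
#' Constructs a validated parameter set for the three-state Bergman minimal
#' model of glucose-insulin kinetics, augmented with the error-integral state
#' used by the integral regulator.
#'
#' @param p1 glucose effectiveness rate (1/min): insulin-independent glucose
#'   clearance.
#' @param p2 insulin clearance rate (1/min): decay of remote-compartment
#'   insulin action.
#' @param p3 insulin sensitivity rate (1/min per mU/L): gain from plasma
#'   insulin to remote insulin action.
#' @param n plasma insulin decay rate (1/min).
#' @param Ib basal plasma insulin (mU/L).
#' @param Gss setpoint / steady-state blood-glucose concentration (mg/dL).
#' @param V1 blood (glucose distribution) volume (L).
#' @param G0,X0,I0,eps0 initial state: blood glucose (mg/dL), remote insulin
#'   action (1/min), plasma insulin (mU/L) and error integral (mg min/dL).
#' @param id optional label for the parameter set.
#'
#' @return An object of class `patient_params`.
#' @seealso [preset_patient()] for the published presets.
#' @export
patient_params <- function(p1, p2, p3, n, Ib, Gss, V1,
                           G0 = 200, X0 = 0, I0 = 50, eps0 = 0,
                           id = "custom") {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  p <- list(p1 = num1(p1, "p1"), p2 = num1(p2, "p2"), p3 = num1(p3, "p3"),
            n = num1(n, "n"), Ib = num1(Ib, "Ib"), Gss = num1(Gss, "Gss"),
            V1 = num1(V1, "V1"), G0 = num1(G0, "G0"), X0 = num1(X0, "X0"),
            I0 = num1(I0, "I0"), eps0 = num1(eps0, "eps0"), id = as.character(id))
  for (nm in c("p1", "p2", "p3", "n"))
    if (p[[nm]] <= 0) stop(sprintf("rate constant '%s' must be > 0", nm), call. = FALSE)
  if (p$V1 <= 0) stop("blood volume 'V1' must be > 0", call. = FALSE)
  if (p$Gss <= 0) stop("setpoint 'Gss' must be > 0", call. = FALSE)
  structure(p, class = "patient_params")
}

# published model parameters: one healthy individual, three T1D patients
.PRESETS <- list(
  healthy  = list(p1 = 0.0317, p2 = 12.3e-3, p3 = 4.92e-6, n = 0.2659),
  patient1 = list(p1 = 0.012,  p2 = 20e-3,   p3 = 5.3e-6,  n = 0.3),
  patient2 = list(p1 = 0.011,  p2 = 7.2e-3,  p3 = 2.16e-6, n = 0.2465),
  patient3 = list(p1 = 0.015,  p2 = 14.2e-3, p3 = 99.4e-6, n = 0.2814)
)

#' Published virtual-patient presets
#'
#' Returns the published Bergman-minimal-model parameter column for a healthy
#' individual or one of three virtual type-1-diabetes patients. All presets
#' share `Ib = 7` mU/L, `Gss = 80` mg/dL, `V1 = 12` L and the initial state
#' `G(0) = 200` mg/dL, `X(0) = 0`, `I(0) = 50` mU/L.
#'
#' @param id one of `"healthy"`, `"patient1"`, `"patient2"`, `"patient3"`.
#' @return A [patient_params()] object.
#' @examples
#' preset_patient("patient1")$p1  # 0.012
#' @export
preset_patient <- function(id) {
  if (!is.character(id) || length(id) != 1L || !(id %in% names(.PRESETS)))
    stop("unknown patient id; valid ids: ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  p <- .PRESETS[[id]]
  patient_params(p1 = p$p1, p2 = p$p2, p3 = p$p3, n = p$n,
                 Ib = 7, Gss = 80, V1 = 12,
                 G0 = 200, X0 = 0, I0 = 50, eps0 = 0, id = id)
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf("Bergman minimal model patient '%s'\n", x$id))
  cat(sprintf("  p1=%g  p2=%g  p3=%g  n=%g  [1/min]\n", x$p1, x$p2, x$p3, x$n))
  cat(sprintf("  Ib=%g mU/L  Gss=%g mg/dL  V1=%g L\n", x$Ib, x$Gss, x$V1))
  cat(sprintf("  x(0) = (G=%g, X=%g, I=%g, eps=%g)\n", x$G0, x$X0, x$I0, x$eps0))
  invisible(x)
}

#' Initial plant state of a patient
#' @param params a [patient_params()] object.
#' @return Named numeric 4-vector `(G, X, I, eps)`.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "patient_params"))
  setNames(c(params$G0, params$X0, params$I0, params$eps0), .STATE_NAMES)
}

#' Time derivatives of the glucose-insulin plant
#'
#' Evaluates the right-hand side of the Bergman minimal model augmented with
#' the error-integral state, `deps/dt = Gss - G`.
#'
#' Two readings of the model are supported. The printed equations
#' (`form = "literal"`) are `dG/dt = -p1*G - X*(G - Gss) + Gm/V1` and
#' `dI/dt = -n*(I + Ib) + v/V1`; taken verbatim they place the open-loop
#' equilibrium away from `Gss` (the G-equation keeps pulling at `G = Gss`,
#' and plasma insulin decays toward `-Ib`). The default
#' (`form = "deviation"`) restores the equilibrium structure the parameter
#' tables imply: `dG/dt = -p1*(G - Gss) - X*(G - Gss) + Gm/V1` and
#' `dI/dt = -n*(I - Ib) + v/V1`, i.e. glucose relaxes to `Gss` and plasma
#' insulin to its basal level when undisturbed.
#'
#' @param state numeric 4-vector `(G, X, I, eps)`.
#' @param v insulin infusion rate (mU/min), must be >= 0.
#' @param Gm meal disturbance input (mg/dL per min, before the 1/V1 scaling).
#' @param params a [patient_params()] object.
#' @param form `"deviation"` (default) or `"literal"`, see Details.
#' @return Named numeric 4-vector of time derivatives (per minute).
#' @export
plant_derivatives <- function(state, v = 0, Gm = 0, params,
                              form = c("deviation", "literal")) {
  form <- match.arg(form)
  if (length(state) != 4L || !all(is.finite(state)))
    stop("state must be a finite numeric 4-vector", call. = FALSE)
  if (!is.finite(v) || v < 0) stop("infusion rate v must be >= 0", call. = FALSE)
  G <- state[[1L]]; X <- state[[2L]]; I <- state[[3L]]
  p <- params
  dG <- if (form == "deviation") -p$p1 * (G - p$Gss) else -p$p1 * G
  dG <- dG - X * (G - p$Gss) + Gm / p$V1
  dX <- -p$p2 * X + p$p3 * I
  dI <- if (form == "deviation") -p$n * (I - p$Ib) else -p$n * (I + p$Ib)
  dI <- dI + v / p$V1
  setNames(c(dG, dX, dI, p$Gss - G), .STATE_NAMES)
}

#' Linearized state-space model
#'
#' Builds the matrices of `dx/dt = A x + B u + F d + H * Gss` for the state
#' `x = (G, X, I, eps)`, input `u = v` (insulin infusion, mU/min) and
#' disturbance `d = Gm` (meal). The glucose row uses the coupling `-Gss` for
#' the remote-insulin action so that insulin action lowers glucose; the
#' control enters the plasma-insulin row as `1/V1` and the meal disturbance
#' the glucose row as `1/V1`.
#'
#' The affine column `H` depends on the plant reading: for
#' `form = "deviation"` it is `(p1, 0, n*Ib/Gss, 1)` so that `H * Gss`
#' reproduces the drift of the deviation-form plant (and the sliding surface
#' built on this model stays at zero along undisturbed trajectories); for
#' `form = "literal"` it is the printed `(1, 0, 0, 1)`.
#'
#' @inheritParams plant_derivatives
#' @return An object of class `linear_model` with fields `A` (4x4), `B`,
#'   `F`, `H` (4-vectors), `C` (1x4 output row), `D` (scalar 0), plus the
#'   originating `params` and `form`.
#' @export
linearize <- function(params, form = c("deviation", "literal")) {
  form <- match.arg(form)
  stopifnot(inherits(params, "patient_params"))
  p <- params
  A <- matrix(c(-p$p1, -p$Gss,     0, 0,
                     0, -p$p2, p$p3, 0,
                     0,      0, -p$n, 0,
                    -1,      0,    0, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(.STATE_NAMES, .STATE_NAMES))
  B <- setNames(c(0, 0, 1 / p$V1, 0), .STATE_NAMES)
  Fv <- setNames(c(1 / p$V1, 0, 0, 0), .STATE_NAMES)
  H <- if (form == "deviation")
    setNames(c(p$p1, 0, p$n * p$Ib / p$Gss, 1), .STATE_NAMES)
  else
    setNames(c(1, 0, 0, 1), .STATE_NAMES)
  structure(list(A = A, B = B, F = Fv, H = H,
                 C = matrix(c(1, 0, 0, 0), nrow = 1), D = 0,
                 params = p, form = form),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("Linearized glucose-insulin model (patient '%s', form '%s')\n",
              x$params$id, x$form))
  cat("A =\n"); print(signif(x$A, 4))
  cat("B =", paste(signif(x$B, 4), collapse = " "),
      "  F =", paste(signif(x$F, 4), collapse = " "),
      "  H =", paste(signif(x$H, 4), collapse = " "), "\n")
  invisible(x)
}

#' Controllability matrix rank of (A, B)
#' @param model a [linearize()] result.
#' @return Integer rank of `[B, AB, A^2B, A^3B]`.
#' @export
controllability_rank <- function(model) {
  A <- model$A; B <- matrix(model$B, ncol = 1)
  ctrb <- cbind(B, A %*% B, A %*% A %*% B, A %*% A %*% A %*% B)
  qr(ctrb)$rank
}

#' Write / read patient parameters as a flat config block
#'
#' Serializes a parameter set to YAML (or JSON by extension) using the
#' symbol names `p1, p2, p3, n, Ib, Gss, V1, G0, X0, I0, eps0`.
#'
#' @param params a [patient_params()] object.
#' @param path output (input) file path; `.json` selects JSON, anything else
#'   YAML.
#' @return `write_patient_config` returns `path` invisibly;
#'   `read_patient_config` returns a [patient_params()] object.
#' @export
write_patient_config <- function(params, path) {
  stopifnot(inherits(params, "patient_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_patient_config
#' @export
read_patient_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(patient_params, x[intersect(names(x),
    c("p1", "p2", "p3", "n", "Ib", "Gss", "V1",
      "G0", "X0", "I0", "eps0", "id"))])
}
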