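#' Quadratic weights for the LQ-integral regulator
#'
#' State penalties `q*` must be nonnegative and the control penalty `rho`
#' strictly positive (`Q = Q' >= 0`, `R = R' > 0`), which is what the
#' Lyapunov argument for closed-loop asymptotic stability requires.
#'
#' @param qG,qX,qI,qeps nonnegative penalties on glucose, remote insulin
#'   action, plasma insulin and the error integral.
#' @param rho positive penalty on the insulin infusion rate.
#' @return An object of class `lq_weights`.
#' @export
lq_weights <- function(qG, qX, qI, qeps, rho) {
  q <- c(qG = qG, qX = qX, qI = qI, qeps = qeps)
  if (any(!is.finite(q)) || any(q < 0))
    stop("state penalties must be finite and >= 0", call. = FALSE)
  if (!is.finite(rho) || rho <= 0)
    stop("control penalty 'rho' must be > 0", call. = FALSE)
  structure(list(qG = qG, qX = qX, qI = qI, qeps = qeps, rho = rho,
                 Q = diag(q), R = rho), class = "lq_weights")
}

#' Tuned regulator weights used in the study
#' @return `lq_weights(qG = 0.32, qX = 0.25, qI = 0.22, qeps = 0.61, rho = 1.05)`.
#' @export
tuned_weights <- function() lq_weights(0.32, 0.25, 0.22, 0.61, 1.05)

#' Published tuned state-feedback gain
#'
#' The gain vector reported with the tuned weights, used as the input
#' parameterization of all closed-loop simulations:
#' `K = (0.0038, 0.0021, 0.0024, 1.12e-4)`. Note that this published vector
#' is not recoverable as a Riccati solution of the linearized model with the
#' published weights (see the package vignette); [lqir_gain()] computes the
#' gain that actually solves that problem.
#'
#' @return Named numeric 4-vector.
#' @export
tuned_gain_published <- function() {
  setNames(c(0.0038, 0.0021, 0.0024, 1.12e-4), .STATE_NAMES)
}

#' Solve a continuous algebraic Riccati equation
#'
#' Solves `A'P + P A - P B R^-1 B' P + Q = 0` by the Hamiltonian
#' eigenvector method: the stable invariant subspace of
#' `[[A, -B R^-1 B'], [-Q, -A']]` spans `[X1; X2]` and `P = X2 X1^-1`.
#'
#' @param A square state matrix (n x n).
#' @param B input matrix (n x m or length-n vector).
#' @param Q symmetric positive semidefinite state penalty (n x n).
#' @param R symmetric positive definite control penalty (m x m or scalar).
#' @param tol relative residual tolerance for acceptance.
#' @return The symmetric solution matrix `P`.
#' @export
care <- function(A, B, Q, R, tol = 1e-8) {
  A <- as.matrix(A)
  n <- nrow(A)
  B <- matrix(B, nrow = n)
  Q <- as.matrix(Q); R <- as.matrix(R)
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("R must be positive definite", call. = FALSE)
  S <- B %*% solve(R, t(B))
  Ham <- rbind(cbind(A, -S), cbind(-Q, -t(A)))
  ed <- eigen(Ham)
  stable <- which(Re(ed$values) < 0)
  if (length(stable) != n)
    stop("Hamiltonian matrix has ", length(stable), " stable eigenvalues, ",
         "expected ", n, "; (A,B) may not be stabilizable or (A,Q) not ",
         "detectable", call. = FALSE)
  V <- ed$vectors[, stable, drop = FALSE]
  X1 <- V[seq_len(n), , drop = FALSE]
  X2 <- V[n + seq_len(n), , drop = FALSE]
  P <- tryCatch(Re(X2 %*% solve(X1)), error = function(e)
    stop("stable subspace is not complementary; Riccati solve failed",
         call. = FALSE))
  P <- (P + t(P)) / 2
  res <- t(A) %*% P + P %*% A - P %*% S %*% P + Q
  rel <- norm(res, "F") / max(1, norm(Q, "F") + norm(P, "F"))
  if (!is.finite(rel) || rel > tol)
    stop(sprintf("Riccati residual %.3g exceeds tolerance %.3g", rel, tol),
         call. = FALSE)
  P
}

#' Riccati solution for a linearized patient model
#'
#' @param model a [linearize()] result.
#' @param w an [lq_weights()] object.
#' @param tol relative residual tolerance.
#' @return Object of class `riccati_solution` with fields `P`, `residual`,
#'   `model`, `weights`.
#' @export
solve_care <- function(model, w, tol = 1e-8) {
  stopifnot(inherits(model, "linear_model"), inherits(w, "lq_weights"))
  P <- care(model$A, model$B, w$Q, w$R, tol = tol)
  S <- matrix(model$B, ncol = 1) %*% t(matrix(model$B, ncol = 1)) / w$rho
  res <- t(model$A) %*% P + P %*% model$A - P %*% S %*% P + w$Q
  structure(list(P = P, residual = norm(res, "F"),
                 residual_rel = norm(res, "F") /
                   max(1, norm(w$Q, "F") + norm(P, "F")),
                 model = model, weights = w),
            class = "riccati_solution")
}

#' Optimal state-feedback gain `K = R^-1 B' P`
#'
#' @param P a [solve_care()] result (or a bare symmetric matrix).
#' @param model a [linearize()] result.
#' @param w an [lq_weights()] object.
#' @return Named numeric 4-vector `(kG, kX, kI, keps)`.
#' @export
lqir_gain <- function(P, model, w) {
  Pm <- if (inherits(P, "riccati_solution")) P$P else as.matrix(P)
  K <- drop(t(matrix(model$B, ncol = 1)) %*% Pm) / w$rho
  setNames(K, .STATE_NAMES)
}

#' LQ-integral control law `u_lq = -K x`
#'
#' Returns the unsaturated insulin infusion command; saturation to the pump
#' limits is applied downstream by the simulator.
#'
#' @param K gain 4-vector.
#' @param x state 4-vector `(G, X, I, eps)`.
#' @return Scalar command (mU/min), possibly negative.
#' @export
lqir_control <- function(K, x) -sum(K * x)

#' Lyapunov verification of an LQ-integral design
#'
#' Checks that `P` is positive definite, that the quadratic Lyapunov
#' derivative matrix `-Q - P B R^-1 B' P` is negative semidefinite, and that
#' the closed loop `A - B K` is Hurwitz.
#'
#' @inheritParams lqir_gain
#' @param K gain vector as returned by [lqir_gain()].
#' @return A list with logical fields `P_positive_definite`,
#'   `lyapunov_derivative_nsd`, `closed_loop_hurwitz` and the conjunction
#'   `ok`; the closed-loop eigenvalues are attached as `eigenvalues`.
#' @export
verify_lyapunov <- function(model, w, P, K) {
  if (!inherits(w, "lq_weights") || w$rho <= 0)
    stop("weights must satisfy rho > 0", call. = FALSE)
  Pm <- if (inherits(P, "riccati_solution")) P$P else as.matrix(P)
  ev_P <- eigen((Pm + t(Pm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  # eigenvalue tolerances relative to the largest magnitude (P can be very
  # ill-conditioned when a state is weakly coupled to the input)
  tol_P <- length(ev_P) * .Machine$double.eps * max(abs(ev_P))
  Bm <- matrix(model$B, ncol = 1)
  Wdot <- -w$Q - Pm %*% Bm %*% t(Bm) %*% Pm / w$rho
  ev_W <- eigen((Wdot + t(Wdot)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol_W <- length(ev_W) * .Machine$double.eps * max(abs(ev_W), 1)
  Acl <- model$A - Bm %*% matrix(K, nrow = 1)
  ev_A <- eigen(Acl, only.values = TRUE)$values
  out <- list(P_positive_definite = all(ev_P > tol_P),
              lyapunov_derivative_nsd = all(ev_W <= tol_W),
              closed_loop_hurwitz = all(Re(ev_A) < 0),
              eigenvalues = ev_A)
  out$ok <- out$P_positive_definite && out$lyapunov_derivative_nsd &&
    out$closed_loop_hurwitz
  out
}

#' One-call LQ-integral synthesis
#'
#' Convenience wrapper: linearize, solve the Riccati equation, compute the
#' gain and run the Lyapunov verification.
#'
#' @param params a [patient_params()] object.
#' @param w an [lq_weights()] object, defaulting to [tuned_weights()].
#' @param form plant reading passed to [linearize()].
#' @return List with `model`, `P`, `K`, `check`.
#' @export
lqir_design <- function(params, w = tuned_weights(),
                        form = c("deviation", "literal")) {
  model <- linearize(params, form = match.arg(form))
  P <- solve_care(model, w)
  K <- lqir_gain(P, model, w)
  list(model = model, P = P, K = K, check = verify_lyapunov(model, w, P, K))
}
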