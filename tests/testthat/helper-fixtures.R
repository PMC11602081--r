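# A patient with no basal insulin and no initial plasma insulin: remote
# insulin action stays identically zero without infusion, so the open-loop
# glucose trajectory has the closed form Gss + (G0 - Gss) * exp(-p1 * t).
analytic_patient <- function(p1 = 0.012) {
  patient_params(p1 = p1, p2 = 0.02, p3 = 5.3e-6, n = 0.3,
                 Ib = 0, Gss = 80, V1 = 12, G0 = 200, X0 = 0, I0 = 0,
                 id = "analytic")
}

# controller that always commands zero insulin
zero_controller <- function() controller_lqir(K = c(0, 0, 0, 0))

tuned_cfg <- function(...) sliding_config(...)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
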