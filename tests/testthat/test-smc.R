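test_that("tuned configuration reproduces the published modulation gain", {
  cfg <- sliding_config()
  expect_equal(cfg$Mo, 1.59 * 4.48, tolerance = 1e-12)
  expect_equal(cfg$Mo, 7.1232, tolerance = 1e-12)
  expect_equal(unname(cfg$g), c(0.0088, 0.0051, 0.0052, 3.65e-4))
  # strict mode recomputes m = g1/g3 and warns about the published mismatch
  expect_warning(cfg_s <- sliding_config(strict = TRUE), "g1/g3")
  expect_equal(cfg_s$m, 0.0088 / 0.0052)
  expect_warning(sliding_config(beta = 10.1), "\\[4, 10\\]")
  expect_error(sliding_config(g1 = 0), "g1")
})

test_that("surface initialization cancels the reachability phase", {
  cfg <- sliding_config()
  # published worked value: z(0) = -(g1*200 + g3*50)
  st <- init_surface(cfg, c(200, 0, 50, 0))
  expect_equal(st$z, -(0.0088 * 200 + 0.0052 * 50), tolerance = 1e-12)
  expect_identical(init_surface(cfg, c(0, 0, 0, 0))$z, 0)
  set.seed(42)
  for (i in 1:25) {
    x0 <- rnorm(4, sd = 100)
    expect_equal(init_surface(cfg, x0)$s, 0, tolerance = 1e-12)
  }
})

test_that("surface derivative keeps only the affine term at the origin", {
  cfg <- sliding_config()
  m <- linearize(preset_patient("patient1"))
  st <- init_surface(cfg, c(0, 0, 0, 0))
  st2 <- surface_step(st, c(0, 0, 0, 0), u_lq = 0, m, dt = 1)
  expect_equal(st2$zdot, -sum(cfg$g * m$H * 80), tolerance = 1e-12)
})

test_that("surface stays at zero along an exact linear-model trajectory", {
  p <- preset_patient("patient1")
  m <- linearize(p)
  cfg <- sliding_config()
  K <- tuned_gain_published()
  # closed-loop linear dynamics xdot = (A - B K) x + H Gss, no disturbance
  rhs <- function(t, x, parms)
    list(drop(m$A %*% x) - m$B * sum(K * x) + m$H * p$Gss)
  x0 <- c(200, 0, 50, 0)
  sol <- deSolve::ode(x0, times = 0:60, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  run_surface <- function(times) {
    st <- init_surface(cfg, x0)
    st$zdot <- glycoreg:::surface_zdot(cfg$g, x0, lqir_control(K, x0), m)
    sol <- deSolve::ode(x0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
    s_max <- 0
    for (k in 2:nrow(sol)) {
      xk <- as.numeric(sol[k, -1])
      st <- surface_step(st, xk, lqir_control(K, xk), m,
                         dt = times[k] - times[k - 1])
      s_max <- max(s_max, abs(st$s))
    }
    s_max
  }
  # drift is pure quadrature truncation: small at the 1-min controller step
  # and shrinking ~quadratically as the step is refined
  s1 <- run_surface(0:60)
  s4 <- run_surface(seq(0, 60, by = 0.25))
  expect_lt(s1, 5e-3)
  expect_lt(s4, s1 / 8)
})

test_that("trapezoidal and rectangle surface steps differ at second order", {
  cfg <- sliding_config()
  m <- linearize(preset_patient("patient1"))
  # quadratically varying state path makes the integrand time-varying
  path <- function(t) c(200 - t^2, 1e-4 * t, 50 - t, -t^2 / 2)
  diff_at <- function(dt) {
    st <- init_surface(cfg, path(0))
    st$zdot <- glycoreg:::surface_zdot(cfg$g, path(0), 0, m)
    trap <- surface_step(st, path(dt), 0, m, dt)$z
    euler <- st$z + dt * glycoreg:::surface_zdot(cfg$g, path(dt), 0, m)
    trap - euler
  }
  d1 <- diff_at(0.2); d2 <- diff_at(0.1)
  expect_gt(abs(d1), 0)
  expect_equal(abs(d1) / abs(d2), 4, tolerance = 0.15)
})

test_that("reaching law implements the signed switching with dead zero", {
  expect_identical(reaching_law(0, 4.48, "sgn"), 0)
  expect_identical(reaching_law(0, 4.48, "tanh"), 0)
  expect_equal(reaching_law(-2, 4.48, "sgn"), 4.48)
  expect_equal(reaching_law(3, 4.48, "sgn"), -4.48)
  expect_equal(reaching_law(0.5, 4.48, "tanh"), -4.48 * tanh(0.5),
               tolerance = 1e-12)
  expect_error(reaching_law(1, -1), "beta")
})

test_that("adaptive gain is even, bounded and increasing in |error|", {
  expect_identical(adaptive_gain(7.12, 0.06, 0), 0)
  expect_equal(adaptive_gain(7.12, 0.06, 1e9), 7.12)
  expect_equal(adaptive_gain(7.12, 0.06, 120),
               7.12 * (1 - 1 / cosh(7.2)), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    Mo <- runif(1, 0.5, 20); gam <- runif(1, 0.01, 1)
    err <- runif(1, 0, 500)
    expect_equal(adaptive_gain(Mo, gam, err), adaptive_gain(Mo, gam, -err))
    M <- adaptive_gain(Mo, gam, err)
    expect_gte(M, 0)
    # strict in exact arithmetic; once sech(gamma*err) drops below machine
    # epsilon (argument above ~36) the product rounds to Mo exactly
    if (gam * err < 36) expect_lt(M, Mo) else expect_lte(M, Mo)
    expect_gte(adaptive_gain(Mo, gam, err * 1.3), M) # monotone in |err|
  }
  expect_error(adaptive_gain(-1, 0.06, 0), "Mo")
})

test_that("hybrid law reduces to the nominal input when inactive", {
  cfg_fix <- sliding_config(adaptive = FALSE)
  cfg_ad <- sliding_config(adaptive = TRUE)
  K <- tuned_gain_published()
  x <- c(200, 0, 50, 0)
  st0 <- init_surface(cfg_fix, x)           # s = 0
  expect_equal(hybrid_control(K, x, st0, cfg_fix), lqir_control(K, x))
  st1 <- st0; st1$s <- 1.4
  # adaptive law with zero error keeps the nominal input regardless of s
  expect_equal(hybrid_control(K, x, st1, cfg_ad, err = 0), lqir_control(K, x))
  # composed worked value at s = 1, err = 120
  st1$s <- 1
  expect_equal(hybrid_control(K, x, st1, cfg_ad, err = 120),
               lqir_control(K, x) - 7.1232 * (1 - 1 / cosh(7.2)) * tanh(1),
               tolerance = 1e-12)
  # fixed-gain law subtracts the full modulation gain through the limiter
  expect_equal(hybrid_control(K, x, st1, cfg_fix),
               lqir_control(K, x) - cfg_fix$Mo * tanh(1), tolerance = 1e-12)
  expect_error(hybrid_control(K, x, st1, cfg_ad), "err")
})

test_that("switching-gain stability condition is strict", {
  cfg <- sliding_config()
  expect_true(stability_condition(cfg, 4))
  expect_false(stability_condition(sliding_config(beta = 4.0), 4))
  expect_warning(
    stability_condition(suppressWarnings(sliding_config(beta = 10.1)), 1),
    "\\[4, 10\\]")
  expect_error(stability_condition(cfg, -1), "d_max")
})

test_that("scaled control channel matches the disturbance channel", {
  # with m = g1/g3:  (G B) m = G F = g1 / V1, exactly
  suppressWarnings(cfg <- sliding_config(strict = TRUE))
  m <- linearize(preset_patient("patient1"))
  expect_equal(sum(cfg$g * m$B) * cfg$m, sum(cfg$g * m$F), tolerance = 1e-15)
  expect_equal(sum(cfg$g * m$F), 0.0088 / 12, tolerance = 1e-15)
})

test_that("reduced sliding dynamics descend under a bounded disturbance", {
  # sdot = (g1/V1) (u_s + d), u_s = -beta sgn(s), sup|d| = 3.9 < beta = 4.48
  suppressWarnings(cfg <- sliding_config(strict = TRUE))
  gain <- 0.0088 / 12
  beta <- cfg$beta
  d_max <- 3
  d_fun <- function(t) d_max * sin(0.3 * t)
  dt <- 0.01
  s <- 0.2; Y_prev <- s^2 / 2; sg_prev <- sign(s)
  reached <- FALSE
  descent_ok <- TRUE
  for (k in 1:25000) {
    t <- k * dt
    u_s <- reaching_law(s, beta, "sgn")
    s <- s + dt * gain * (u_s + d_fun(t))
    Y <- s^2 / 2
    if (!reached && abs(s) < 1e-3) reached <- TRUE
    if (sign(s) == sg_prev && !reached && Y >= Y_prev) descent_ok <- FALSE
    Y_prev <- Y; sg_prev <- sign(s)
  }
  expect_true(descent_ok)  # Lyapunov descent between switching instants
  expect_true(reached)
  expect_lt(abs(s), 2 * gain * (beta + d_max) * dt + 1e-3)
})

test_that("sliding configuration round-trips through the config dialect", {
  cfg <- sliding_config(g1 = 0.004, g2 = 0.003, g3 = 0.002, g4 = 1e-4,
                        m = 2, beta = 5, gamma = 0.1, mode = "sgn",
                        adaptive = FALSE)
  f <- tempfile(fileext = ".yaml")
  write_sliding_config(cfg, f)
  cfg2 <- read_sliding_config(f)
  expect_equal(cfg2$g, cfg$g)
  expect_equal(cfg2$Mo, cfg$Mo)
  expect_identical(cfg2$mode, "sgn")
  expect_false(cfg2$adaptive)
  unlink(f)
})
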