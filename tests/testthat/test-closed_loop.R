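test_that("scenario constructors encode the study conditions", {
  a <- scenario_hyperglycemia()
  expect_equal(a$duration, 500)
  expect_equal(a$N, 500L)                       # N = duration / 60 s
  expect_equal(a$dt, 1)                         # one controller step per min
  expect_equal(a$noise_sd^2, 0.2, tolerance = 1e-12)
  expect_null(a$meal); expect_null(a$stress)
  expect_equal(scenario_hyperglycemia(duration = 300)$N, 300L)

  b <- scenario_meal()
  expect_equal(b$duration, 1000)
  expect_equal(b$meal$amplitude, 80)
  expect_equal(b$meal$time, 500)

  cc <- scenario_stress()
  expect_equal(c(cc$stress$p1, cc$stress$p2, cc$stress$p3),
               c(8.0e-3, 25.0e-3, 2.5e-6))
  expect_equal(cc$duration, 1000)

  f <- scenario_sensor_fault()
  corrupt <- function(t) f$fault$bias + f$fault$amplitude * sin(f$fault$omega * t)
  expect_equal(corrupt(0), 5)                   # pure bias at t = 0
  expect_equal(max(corrupt(seq(0, 100, by = 0.01))), 7, tolerance = 1e-4)
  expect_equal(2 * pi / f$fault$omega, 10 * pi) # drift period
  expect_equal(c(a$u_min, a$u_max), c(0, 100))
  expect_error(scenario_by_name("nope"), "valid")
})

test_that("open-loop glucose decay matches the closed form", {
  # no basal/initial insulin, zero controller: G(t) = Gss + (G0-Gss) e^(-p1 t)
  p <- analytic_patient()
  sc <- scenario_hyperglycemia(noise = FALSE)
  r <- run_closed_loop(p, zero_controller(), sc, seed = 1)
  expect_true(all(r$u == 0))
  closed_form <- 80 + 120 * exp(-p$p1 * r$time)
  expect_lt(max(abs(r$G_true - closed_form) / closed_form), 1e-6)
  expect_true(all(diff(r$G_true) < 0))          # monotone decay
})

test_that("the true error integral tracks its defining quadrature", {
  p <- analytic_patient()
  r <- run_closed_loop(p, zero_controller(),
                       scenario_hyperglycemia(duration = 200, noise = FALSE),
                       seed = 1)
  # eps recorded by the controller is the trapezoid of the measured error;
  # noise-free, it must agree with the closed-form integral of Gss - G
  analytic_eps <- -120 / p$p1 * (1 - exp(-p$p1 * r$time))
  expect_lt(max(abs(r$eps - analytic_eps)), 0.05 * max(abs(analytic_eps)))
})

test_that("runs are deterministic in the seed and bounded by the pump limits", {
  r1 <- run_closed_loop("patient1", "lq-asmc", "hyperglycemia", seed = 11)
  r2 <- run_closed_loop("patient1", "lq-asmc", "hyperglycemia", seed = 11)
  r3 <- run_closed_loop("patient1", "lq-asmc", "hyperglycemia", seed = 12)
  expect_identical(r1$G_meas, r2$G_meas)
  expect_identical(r1$u, r2$u)
  expect_false(identical(r1$G_meas, r3$G_meas))
  expect_equal(length(r1$time), 501L)
  expect_true(all(r1$u >= 0 & r1$u <= 100))
  expect_equal(r1$s[1], 0)                      # no reachability phase
})

test_that("meal event jumps the glucose state at exactly t = 500", {
  r <- run_closed_loop("patient1", "lqir", scenario_meal(noise = FALSE),
                       seed = 1)
  i <- which(r$time == 500)
  expect_gt(r$G_true[i] - r$G_true[i - 1], 75)  # ~80 minus one minute of decay
  # pulse realization routes the impulse through the meal channel instead
  rp <- run_closed_loop("patient1", "lqir",
                        scenario_meal(route = "pulse", noise = FALSE), seed = 1)
  expect_lt(max(rp$G_true[rp$time > 500]) - 80, 80 / 12 + 5)
  expect_gt(rp$G_true[i + 1], rp$G_true[i - 1]) # the pulse raises glucose
})

test_that("stress event changes the plant dynamics at t = 500", {
  sc <- scenario_stress(noise = FALSE)
  r <- run_closed_loop("patient1", "lqir", sc, seed = 1)
  # relinearized dynamics differ after the event
  p_pre <- preset_patient("patient1")
  p_post <- patient_params(p1 = sc$stress$p1, p2 = sc$stress$p2,
                           p3 = sc$stress$p3, n = p_pre$n, Ib = p_pre$Ib,
                           Gss = p_pre$Gss, V1 = p_pre$V1)
  ev_pre <- sort(Re(eigen(linearize(p_pre)$A)$values))
  ev_post <- sort(Re(eigen(linearize(p_post)$A)$values))
  expect_false(isTRUE(all.equal(ev_pre, ev_post)))
  # pre-event the trajectory matches the undisturbed scenario-A run
  ra <- run_closed_loop("patient1", "lqir",
                        scenario_hyperglycemia(noise = FALSE), seed = 1)
  pre <- r$time < 500
  expect_equal(r$G_true[pre], ra$G_true[ra$time < 500], tolerance = 1e-10)
})

test_that("sensor fault corrupts only the measurement channel", {
  r <- run_closed_loop("patient1", "lq-asmc", scenario_sensor_fault(noise = FALSE),
                       seed = 1)
  expect_equal(r$G_meas[1] - r$G_true[1], 5, tolerance = 1e-9) # bias at t = 0
  expect_true(all(abs(r$G_meas - r$G_true) <= 7 + 1e-9))
  expect_true(all(abs(r$G_meas - r$G_true) >= 3 - 1e-9))
})

test_that("every patient settles under every controller in scenario A", {
  for (pat in c("patient1", "patient2", "patient3")) {
    for (ctl in c("lqir", "lq-smc", "lq-asmc")) {
      r <- run_closed_loop(pat, ctl, "hyperglycemia", seed = 3)
      ts <- t_set(r$G_true, r$time, Gref = 80)
      expect_lt(ts, 500)
      expect_true(all(r$G_true[r$time >= ts] >= 76 &
                      r$G_true[r$time >= ts] <= 84))
      expect_false(r$flags$nonphysical)
    }
  }
})

test_that("adaptive law damps steady-state fluctuations at least as well as
           the fixed-gain law (paired seeds)", {
  diffs <- sapply(1:10, function(sd) {
    rA <- run_closed_loop("patient1", "lq-asmc", "hyperglycemia", seed = sd)
    rS <- run_closed_loop("patient1", "lq-smc", "hyperglycemia", seed = sd)
    w <- rA$time >= 400
    sd_of <- function(g) sqrt(mean((g - mean(g))^2))
    sd_of(rA$G_true[w]) - sd_of(rS$G_true[w])
  })
  expect_lte(mean(diffs), 0)
})

test_that("surface magnitude stays within a small envelope when undisturbed", {
  for (ctl in c("lq-smc", "lq-asmc")) {
    r <- run_closed_loop("patient1", ctl, "hyperglycemia", seed = 5)
    expect_lt(max(abs(r$s)), 5)
  }
})

test_that("literal plant form lets plasma insulin go negative", {
  # with the verbatim equations plasma insulin decays toward -Ib
  r <- run_closed_loop("patient1", zero_controller(),
                       scenario_hyperglycemia(duration = 100, noise = FALSE),
                       seed = 1, form = "literal")
  expect_true(min(r$I) < 0)
})

test_that("simulation results export to CSV with a provenance sidecar", {
  r <- run_closed_loop("patient1", "lq-asmc",
                       scenario_hyperglycemia(duration = 50), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_sim_result(r, f)
  df <- read.csv(f)
  expect_identical(names(df),
                   c("t_min", "G_true", "G_meas", "X", "I", "eps", "s", "M", "u"))
  expect_equal(nrow(df), 51L)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f), simplifyVector = TRUE)
  expect_equal(side$seed, 2L)
  expect_equal(side$controller$type, "lq-asmc")
  unlink(c(f, sub("\\.csv$", ".json", f)))
})
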