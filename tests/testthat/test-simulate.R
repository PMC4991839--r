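test_that("OU generator has exact stationary statistics", {
  z <- ou_series(mu = 5, sigma = 0, tau = 2, dt = 0.1, n = 100, seed = 1)
  expect_true(all(z$I == 5))
  wf <- ou_series(mu = -150, sigma = 30, tau = 2, dt = 0.1, n = 1e6,
                  seed = 42)
  x <- wf$I
  # standard errors account for the correlation time (tau = 2 ms)
  se_mean <- 30 * sqrt(2 * 2 / (length(x) * 0.1))
  expect_lt(abs(mean(x) + 150), 3 * se_mean)
  expect_lt(abs(sd(x) - 30), 3 * se_mean)
  # lag-tau autocorrelation ~ e^-1
  lag <- round(2 / 0.1)
  r <- cor(x[-(1:lag)], x[seq_len(length(x) - lag)])
  expect_equal(r, exp(-1), tolerance = 0.02)
})

test_that("dual-OU current reproduces the protocol's amplitude and memory", {
  wf <- dual_ou_current(mean = -50, sigma = 0, dt = 0.1,
                        duration_ms = 100, lead_ms = 10)
  expect_true(all(wf$I == -50))
  wf <- dual_ou_current(mean = 0, sigma = 153, dt = 0.1,
                        duration_ms = 60000, lead_ms = 0, seed = 7)
  x <- wf$I
  expect_equal(sd(x), 153, tolerance = 0.03)
  # autocorrelation is the equal-variance mix of 3 ms and 10 ms exponentials
  for (lag_ms in c(3, 10)) {
    lag <- round(lag_ms / 0.1)
    r <- cor(x[-(1:lag)], x[seq_len(length(x) - lag)])
    expect_lt(abs(r - (0.5 * exp(-lag_ms / 3) + 0.5 * exp(-lag_ms / 10))),
              0.03)
  }
})

test_that("biexponential events are normalized to peak amplitude", {
  z <- biexp_current(numeric(0), Am = 100, dt = 0.05, n = 1000)
  expect_true(all(z$I == 0))
  wf <- biexp_current(10, Am = 100, dt = 0.01, n = 2e4)
  expect_equal(max(wf$I), 100, tolerance = 5e-3)
  # frozen analytic values: K(1.5, 10) and the event integral Am/K
  expect_equal(biexp_K(1.5, 10), 0.0715491271, tolerance = 1e-8)
  expect_equal(sum(wf$I) * 0.01, 1397.641090, tolerance = 0.5)
  # linear superposition of two events
  wf2 <- biexp_current(c(10, 10), Am = 100, dt = 0.01, n = 2e4)
  expect_equal(max(wf2$I), 200, tolerance = 1e-2)
  expect_error(biexp_current(10, 100, 0.01, 1000, tau1 = 5, tau2 = 5),
               "tau1")
})

test_that("protocol builder produces the stated waveforms", {
  ramp <- build_protocol("ramp", dt = 0.1, ramp_rate = 0.9,
                         ramp_ms = 1000, trials = 2, start = -500)
  expect_equal(max(ramp$I) - ramp$I[1], 900, tolerance = 0.1)
  expect_equal(nrow(ramp$segments), 4)
  steps <- build_protocol("current_steps", dt = 0.1, start = -500,
                          step_pA = 50, n_steps = 30)
  expect_equal(nrow(steps$segments), 30)
  expect_true(all(diff(steps$segments$mean) == 50))
  ns <- build_protocol("noise_steps", dt = 0.1, mean = -150,
                       sigmas = seq(0, 500, 50), seed = 3)
  segs <- ns$segments
  expect_equal(sum(segs$label == "noise"), 11)
  expect_equal(segs$sigma[segs$label == "noise"], seq(0, 500, 50))
  expect_error(build_protocol("nope"), "arg")
})

test_that("integrator matches the analytic RC response and converges in dt", {
  p <- rc_cell()
  # analytic charging curve for a current step
  I0 <- 150
  dt <- 0.02
  n <- round(200 / dt)
  res <- integrate_aeif(p, current_waveform(dt, rep(I0, n)),
                        init = c(p$EL, 0))
  tt <- seq_len(n) * dt
  V_true <- p$EL + (I0 / p$gL) * (1 - exp(-tt / p$tau_m))
  expect_lt(max(abs(res$trace$V - V_true)), 0.05)
  # suprathreshold constant current: stable limit-cycle ISI after transient
  pr <- rep_cell()
  r2 <- integrate_aeif(pr, current_waveform(0.1, rep(200, 2e4)),
                       record = FALSE)
  isi <- diff(as.numeric(r2$spikes))
  late <- tail(isi, 5)
  expect_lt(diff(range(late)), 0.21)
  # dt refinement changes the 1 s noise-free spike count by <= 1
  n1 <- length(integrate_aeif(pr, current_waveform(0.1, rep(200, 1e4)),
                              record = FALSE)$spikes)
  n2 <- length(integrate_aeif(pr, current_waveform(0.05, rep(200, 2e4)),
                              record = FALSE)$spikes)
  expect_lte(abs(n1 - n2), 1)
})

test_that("rest state at -150 pA is stable over 30 s without noise", {
  p <- rep_cell()
  init <- rest_state(p, -150)
  res <- integrate_aeif(p, current_waveform(0.1, rep(-150, 3e5)),
                        init = init, record = FALSE)
  expect_equal(length(res$spikes), 0)
})

test_that("simulation is deterministic given a seed", {
  p <- rep_cell()
  run <- function() {
    wf <- ou_series(mu = -150, sigma = 60, tau = 2, dt = 0.1, n = 5e4,
                    seed = 99)
    integrate_aeif(p, wf, init = rest_state(p, -150),
                   record = FALSE)$spikes
  }
  expect_identical(as.numeric(run()), as.numeric(run()))
})

test_that("limit-cycle initialization reports the spiking state", {
  p <- rep_cell()
  lc <- limit_cycle_state(p, -150)
  expect_true(all(is.finite(lc)))
  # restarting on the cycle keeps spiking
  res <- integrate_aeif(p, current_waveform(0.1, rep(-150, 1e4)),
                        init = lc, record = FALSE)
  expect_gt(length(res$spikes), 10)
  # no limit cycle far below the bistable range
  expect_error(limit_cycle_state(p, -400), "limit cycle")
})
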