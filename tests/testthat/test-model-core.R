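test_that("aEIF vector field matches hand-evaluated values", {
  p <- rep_cell()
  # at V = EL the leak and adaptation terms vanish; only the (positive)
  # exponential drive remains
  d <- aeif_derivatives(c(p$EL, 0), p, I = 0)
  expect_gt(d[1], 0)
  expect_equal(d[2], 0)
  # frozen independent evaluation of the right-hand side at V = -60, w = 0
  d2 <- aeif_derivatives(c(-60, 0), p, I = 0)
  expect_equal(d2[1], 0.2746522460, tolerance = 1e-9)
  expect_equal(d2[2], -15.8186464355, tolerance = 1e-9)
  # small-DeltaT limit far below threshold: pure leaky integrator
  p_small <- aeif_params(p$C, p$gL, p$EL, p$VT, DeltaT = 1e-3, a = p$a,
                         b = p$b, tau_w = p$tau_w, Vr = p$Vr)
  d3 <- aeif_derivatives(c(-70, 5), p_small, I = 12)
  expect_equal(d3[1], (-p$gL * (-70 - p$EL) - 5 + 12) / p$C,
               tolerance = 1e-9)
  expect_error(aeif_derivatives(c(NaN, 0), p), "finite")
})

test_that("rescaling reproduces the printed parameter combinations and inverts", {
  p <- rep_cell()
  rs <- rescale_params(p, I = -150)
  expect_equal(rs$A, 4.46162928, tolerance = 1e-8)
  expect_equal(rs$T, 0.65610896, tolerance = 1e-8)
  # a = 0 gives A = 0
  p0 <- aeif_params(p$C, p$gL, p$EL, p$VT, p$DeltaT, a = 0, b = p$b,
                    tau_w = p$tau_w, Vr = p$Vr)
  expect_equal(rescale_params(p0)$A, 0)
  # round trip on random valid parameter sets
  set.seed(11)
  for (k in 1:20) {
    q <- aeif_params(C = runif(1, 80, 400), gL = runif(1, 4, 60),
                     EL = runif(1, -60, -45), VT = runif(1, -62, -50),
                     DeltaT = runif(1, 0.3, 3), a = runif(1, 0, 60),
                     b = runif(1, 50, 800), tau_w = runif(1, 4, 40),
                     Vr = runif(1, -70, -55))
    I <- runif(1, -300, 100)
    back <- unscale_params(rescale_params(q, I))
    for (f in c("C", "gL", "EL", "VT", "DeltaT", "a", "b", "tau_w", "Vr"))
      expect_equal(back$params[[f]], q[[f]], tolerance = 1e-12)
    expect_equal(back$I, I, tolerance = 1e-12)
  }
})

test_that("excitability classification follows the a/gL vs tau_m/tau_w rule", {
  p <- rep_cell()
  expect_identical(classify_excitability(p), "type_II")
  expect_identical(classify_excitability(type1_cell()), "type_I")
  # population-mean parameters are type II (independent arithmetic oracle)
  pop <- aeif_params(C = 195.4, gL = 195.4 / 4.4, EL = -51.9, VT = -54.1,
                     DeltaT = 1.0, a = 36.1, b = 408, tau_w = 14.8,
                     Vr = -60)
  expect_identical(classify_excitability(pop), "type_II")
  # boundary case: warning, assigned type I
  pb <- aeif_params(p$C, p$gL, p$EL, p$VT, p$DeltaT,
                    a = p$gL * p$tau_m / p$tau_w, b = p$b,
                    tau_w = p$tau_w, Vr = p$Vr)
  expect_warning(cls <- classify_excitability(pb), "boundary")
  expect_identical(cls, "type_I")
})

test_that("closed-form rheobase matches independent evaluation and scales", {
  p <- rep_cell()
  expect_equal(rheobase_up(p), -70.584440, tolerance = 1e-5)
  expect_error(rheobase_up(type1_cell()), "type II")
  # degenerate boundary: second term vanishes (evaluate the formula's
  # structure by comparing against the first term alone)
  gb <- p$gL
  ab <- gb * p$tau_m / p$tau_w
  first <- (gb + ab) * (p$VT - p$EL - p$DeltaT +
                          p$DeltaT * log(1 + p$tau_m / p$tau_w))
  pb <- suppressWarnings(
    aeif_params(p$C, gb, p$EL, p$VT, p$DeltaT, a = ab + 1e-9, b = p$b,
                tau_w = p$tau_w, Vr = p$Vr))
  expect_equal(rheobase_up(pb), first, tolerance = 1e-6)
  # homogeneity of degree 1 in (C, gL, a, b)
  k <- 2.5
  ps <- aeif_params(k * p$C, k * p$gL, p$EL, p$VT, p$DeltaT, k * p$a,
                    k * p$b, p$tau_w, Vr = p$Vr)
  expect_equal(rheobase_up(ps), k * rheobase_up(p), tolerance = 1e-10)
})

test_that("two-compartment model reduces to aEIF when decoupled", {
  p <- rep_cell()
  tc <- two_compartment_params(p, gc = 1e-12, Cd = 50, gLd = 2)
  d2 <- two_compartment_derivatives(c(-60, 10, -55), tc, I = -100)
  d1 <- aeif_derivatives(c(-60, 10), p, I = -100)
  expect_equal(d2[1:2], d1, tolerance = 1e-9)
  expect_error(two_compartment_params(p, gc = -1, Cd = 50, gLd = 2), "gc")
  # all-at-EL equilibrium: dendrite derivative is zero
  tc2 <- two_compartment_params(p, gc = 10.2, Cd = 100, gLd = 4)
  d3 <- two_compartment_derivatives(c(p$EL, 0, p$EL), tc2, I = 0)
  expect_equal(d3[3], 0)
  # constant subthreshold input: dendritic steady state between EL and V
  wf <- current_waveform(0.1, rep(-300, 20000))
  res <- integrate_aeif(tc2, wf)
  st <- res$state_end
  expect_equal(length(res$spikes), 0)
  expect_true(st["Vd"] > st["V"] && st["Vd"] < p$EL)
})

test_that("fixed points satisfy the vector field to high precision", {
  p <- rep_cell()
  fps <- find_fixed_points(p, I = -150)
  for (f in fps) {
    d <- aeif_derivatives(c(f$V, f$w), p, I = -150)
    expect_lt(max(abs(d)) * p$C, 1e-6)
  }
})

test_that("rescaled and physical models produce identical spike counts", {
  p <- rep_cell()
  I <- -100
  rs <- rescale_params(p, I)
  dt <- 0.1
  n <- round(1000 / dt)
  # oracle: Euler integration of the dimensionless system
  dtbar <- dt / p$tau_m
  vb <- (p$Vr - p$VT) / p$DeltaT
  wb <- (p$b + p$a * (p$EL - p$VT)) / (p$gL * p$DeltaT)
  vspike_bar <- (p$Vspike - p$VT) / p$DeltaT
  V <- vb; w <- wb
  count_bar <- 0
  for (i in seq_len(n)) {
    ex <- min(V, 16)
    dV <- -V + exp(ex) - w + rs$Ibar
    dw <- (rs$A * V - w) / rs$T
    V <- V + dtbar * dV
    w <- w + dtbar * dw
    if (V > vspike_bar) {
      count_bar <- count_bar + 1
      V <- rs$Vbar_r
      w <- w + rs$bbar
    }
  }
  res <- integrate_aeif(p, current_waveform(dt, rep(I, n)),
                        init = c(p$Vr, p$b), record = FALSE)
  expect_identical(length(res$spikes), as.integer(count_bar))
  expect_gt(count_bar, 5)
})
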