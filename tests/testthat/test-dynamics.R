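test_that("fixed-point structure matches the bifurcation picture", {
  p <- rep_cell()
  # bistable operating point: a stable focus and an unstable point
  fps <- find_fixed_points(p, I = -150)
  expect_length(fps, 2)
  expect_identical(fps[[1]]$class, "stable_focus")
  expect_false(startsWith(fps[[2]]$class, "stable"))
  # far above the fold: no fixed points, purely spiking
  expect_length(find_fixed_points(p, I = 500), 0)
  # brute-force sign-change oracle on a linear-subthreshold variant
  p0 <- aeif_params(p$C, p$gL, p$EL, p$VT, p$DeltaT, a = 0, b = p$b,
                    tau_w = p$tau_w, Vr = p$Vr)
  I0 <- -50
  g <- function(V) -p0$gL * (V - p0$EL) +
    p0$gL * p0$DeltaT * exp((V - p0$VT) / p0$DeltaT) + I0
  Vs <- seq(-90, 0, by = 0.001)
  gv <- g(Vs)
  oracle <- Vs[which(gv[-1] * gv[-length(gv)] < 0)]
  found <- vapply(find_fixed_points(p0, I0), `[[`, numeric(1), "V")
  expect_equal(length(found), length(oracle))
  expect_true(all(abs(sort(found) - sort(oracle)) < 0.002))
})

test_that("Hopf scan finds the destabilization current of the rest state", {
  p <- rep_cell()
  hb <- hopf_scan(p, I_range = c(-200, 0))
  expect_false(hb$not_found)
  expect_true(hb$hopf)
  expect_gt(hb$omega, 0)
  # dense eigenvalue sweep oracle at 0.1 pA resolution
  re_at <- function(I) {
    fps <- find_fixed_points(p, I)
    if (!length(fps)) return(NA_real_)
    max(Re(fps[[1]]$eigenvalues))
  }
  grid <- seq(-90, -50, by = 0.1)
  vals <- vapply(grid, re_at, numeric(1))
  cross <- grid[which(!is.na(vals) & vals > 0)[1]]
  expect_lt(abs(hb$I_HB - cross), 0.2)
  # for the type II aEIF the Hopf current is the closed-form rheobase
  expect_lt(abs(hb$I_HB - rheobase_up(p)), 0.5)
  # far below the bifurcation the rest state is strongly stable
  expect_lt(re_at(-200), 0)
  # type I parameter set: the rest state disappears in a saddle-node
  p1 <- type1_cell()
  hb1 <- hopf_scan(p1, I_range = c(-300, 100))
  expect_false(hb1$not_found)
  expect_true(hb1$saddle_node)
  expect_lt(hb1$omega, 1e-6)
})

test_that("rest-state basin has the expected membership geometry", {
  p <- rep_cell()
  mask <- rest_basin(p, -150, dV = 1, dw = 25)
  fp <- mask$fixed_point
  expect_true(in_basin(mask, fp[1], fp[2]))
  # a point just below the spike cut fires immediately
  expect_false(in_basin(mask, p$Vspike - 1, 0))
  # the post-spike reset point lies outside the basin, so the limit cycle
  # never crosses the attraction basin
  lc <- limit_cycle_state(p, -150)
  res <- integrate_aeif(p, current_waveform(0.1, rep(-150, 2000)),
                        init = lc, record = FALSE)
  w_after <- res$state_end["w"]
  expect_false(in_basin(mask, p$Vr, p$b + 100))
  # refining the grid never flips the fixed point's membership
  mask2 <- rest_basin(p, -150, dV = 0.5, dw = 10)
  expect_true(in_basin(mask2, fp[1], fp[2]))
  expect_error(rest_basin(p, 100), "stable fixed point")
})

test_that("spiking probability is minimized near the optimal noise", {
  p <- rep_cell()
  mask <- rest_basin(p, -150, dV = 0.5, dw = 10)
  # deterministic edges
  fp <- mask$fixed_point
  r0 <- spiking_probability(p, -150, sigma = 0, reps = 1, T_ms = 2000,
                            init = fp, mask = mask, seed = 1)
  expect_equal(r0$P_sp, 0, tolerance = 1e-6)
  r1 <- spiking_probability(p, -150, sigma = 0, reps = 1, T_ms = 2000,
                            mask = mask, seed = 1)
  expect_gt(r1$P_sp, 0.95)
  # noise tuning: strong inhibition near 30 pA
  ps <- vapply(c(10, 30, 60), function(s)
    spiking_probability(p, -150, sigma = s, reps = 6, T_ms = 10000,
                        mask = mask, seed = 100 + s)$P_sp, numeric(1))
  expect_lt(ps[2], ps[1])
  expect_lt(ps[2], ps[3])
  # above the fold: no rest state, P_sp = 1 by convention
  expect_equal(spiking_probability(p, 100, sigma = 10)$P_sp, 1)
})

test_that("P_sp and mean-rate noise-tuning curves share their shape", {
  p <- rep_cell()
  mask <- rest_basin(p, -150, dV = 0.5, dw = 10)
  sig <- c(10, 20, 30, 40, 60, 80)
  set.seed(21)
  psp <- vapply(sig, function(s)
    spiking_probability(p, -150, sigma = s, reps = 6, T_ms = 10000,
                        mask = mask)$P_sp, numeric(1))
  ic <- isr_curve_model(p, sigmas = sig, reps = 6, T_ms = 10000,
                        seed = 22)
  expect_gt(cor(psp, ic$rate, method = "spearman"), 0.9)
})
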