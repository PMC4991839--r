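test_that("spike binning uses half-open bins and presence symbols", {
  expect_equal(as.integer(bin_spike_train(numeric(0), b = 25, T_ms = 250)),
               rep(0L, 10))
  # a spike exactly at t = b falls in the second bin
  x <- bin_spike_train(c(25), b = 25, T_ms = 100)
  expect_equal(as.integer(x), c(0L, 1L, 0L, 0L))
  # periodic 40 Hz train: every 25 ms bin occupied
  x2 <- bin_spike_train(seq(0, 999, by = 25), b = 25, T_ms = 1000)
  expect_true(all(x2 == 1L))
})

test_that("CTW entropy rate matches analytic rates of simple sources", {
  set.seed(5)
  # fair coin
  x <- sample(0:1, 1e5, replace = TRUE)
  expect_lt(abs(ctw_entropy_rate(x, depth = 40) - 1), 0.02)
  # constant sequence approaches zero from above
  h_const <- ctw_entropy_rate(rep(1L, 1e4), depth = 10)
  expect_lt(h_const, 0.01)
  expect_gt(h_const, 0)
  # first-order Markov chain with known transition matrix
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  pi_st <- c(0.75, 0.25)
  h_true <- -sum(pi_st * rowSums(P * log2(P)))
  markov <- function(n) {
    y <- integer(n); y[1] <- 0L
    u <- runif(n)
    for (i in 2:n) y[i] <- if (u[i] < P[y[i - 1] + 1, 1]) 0L else 1L
    y
  }
  y <- markov(1e5)
  expect_lt(abs(ctw_entropy_rate(y, depth = 20) - h_true), 0.03)
  # convergence: error shrinks as the sequence grows
  errs <- vapply(c(1e3, 1e4, 1e5), function(n)
    abs(ctw_entropy_rate(y[seq_len(n)], depth = 20) - h_true), numeric(1))
  expect_true(all(diff(errs) < 0))
  # plug-in block estimator agrees on the short-memory source
  expect_lt(abs(block_entropy_rate(y, k = 1) - h_true), 0.02)
})

test_that("mutual information rate behaves on known channel fixtures", {
  set.seed(9)
  n <- 1e5
  mk <- function(v) structure(as.integer(v), b = 25, duration = n * 25,
                              class = "binned_train")
  x <- mk(rbinom(n, 1, 0.2))
  y_ind <- mk(rbinom(n, 1, 0.3))
  mi0 <- mi_rate(x, y_ind, depth = 20)
  expect_lt(abs(mi0$mi_bits_per_bin), 0.02)
  # perfect copy: MI equals the input entropy rate
  mi1 <- mi_rate(x, x, depth = 20)
  expect_lt(abs(mi1$mi_bits_per_bin - mi1$H_X), 0.02)
  # symmetry within estimator tolerance
  z <- mk(as.integer(xor(as.logical(x), rbinom(n, 1, 0.1))))
  expect_lt(abs(mi_rate(x, z, depth = 15)$mi_bits_per_bin -
                  mi_rate(z, x, depth = 15)$mi_bits_per_bin), 0.01)
  expect_error(mi_rate(x, mk(rbinom(10, 1, 0.5))), "bin size and length")
})

test_that("MI estimates are stable under doubling of the context depth", {
  # hidden-state channel with ~100 ms memory, mirroring the up/down states
  set.seed(31)
  n <- 4e4
  state <- integer(n); state[1] <- 0L
  x <- rbinom(n, 1, 0.05)
  for (i in 2:n) {
    state[i] <- if (x[i]) 1L
    else if (runif(1) < 0.1) 1L - state[i - 1] else state[i - 1]
  }
  y <- ifelse(state == 1L, rbinom(n, 1, 0.8), rbinom(n, 1, 0.05))
  mk <- function(v) structure(as.integer(v), b = 25, duration = n * 25,
                              class = "binned_train")
  m1 <- mi_rate(mk(x), mk(y), depth = 40)$mi_bits_per_bin
  m2 <- mi_rate(mk(x), mk(y), depth = 80)$mi_bits_per_bin
  expect_lt(abs(m2 - m1), 0.05 * max(abs(m1), 0.1))
})
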