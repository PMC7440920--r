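test_that("STDP kernel reproduces the exponential rule", {
  p <- stdp_params()
  expect_equal(stdp_kernel(20, p), 0.002 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_kernel(-20, p), -0.002 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_kernel(1e-9, p), p$a_plus, tolerance = 1e-6)
  expect_equal(stdp_kernel(0, p), 0)  # exact tie: no update
})

test_that("STDP kernel sign, monotonicity and decay properties hold", {
  p <- stdp_params()
  dts <- c(0.1, 1, 5, 10, 20, 50, 100)
  expect_true(all(stdp_kernel(dts, p) > 0))
  expect_true(all(stdp_kernel(-dts, p) < 0))
  expect_true(all(diff(abs(stdp_kernel(dts, p))) < 0))
  expect_true(all(diff(abs(stdp_kernel(-dts, p))) < 0))
  expect_lt(abs(stdp_kernel(1e4, p)), 1e-12)
  # balanced defaults: mean change over a sign-symmetric jittered
  # ensemble of pairings is zero
  set.seed(7)
  jitter <- runif(2000, 0.1, 60)
  ensemble <- c(jitter, -jitter)
  expect_equal(mean(stdp_kernel(ensemble, p)), 0, tolerance = 1e-15)
  # training phase halves only the depression amplitude
  tr <- stdp_params(phase = "training")
  expect_equal(tr$a_minus, 0.001)
  expect_equal(tr$a_plus, 0.002)
  expect_equal(stdp_params(phase = "ltd_biased")$a_plus, 0.0019)
  expect_equal(stdp_params(phase = "ltp_biased")$a_plus, 0.0021)
})

test_that("apply_stdp clips weights to [0, g_max] and floors mini amplitudes", {
  p <- stdp_params(g_max = 0.1)
  expect_equal(apply_stdp(0.1, 0.03, 20, p)$weight, 0.1)   # saturation
  expect_equal(apply_stdp(0, 0.03, -20, p)$weight, 0)      # floor
  got <- apply_stdp(0.05, 0.03, 20, p)
  expect_equal(got$weight, 0.05 + 0.1 * 0.002 * exp(-1), tolerance = 1e-12)
  expect_equal(got$mini_amplitude, 0.03 + 0.01 * 0.03 * 0.002 * exp(-1),
               tolerance = 1e-12)
  expect_error(apply_stdp(0.2, 0.03, 5, p))
})

test_that("short-term depression recovers according to the resource formula", {
  p <- depression_params()
  expect_equal(p$U, 0.073)
  expect_equal(depression_update(0.5, 1e7, p), 1)            # full recovery
  expect_equal(depression_update(1, 0, p), 1 - 0.073)        # just after a spike
  expect_equal(depression_update(0.927, 700, p),
               1 - (1 - 0.927 * 0.927) * exp(-1), tolerance = 1e-12)
  # monotone in elapsed time
  el <- seq(0, 3000, by = 100)
  expect_true(all(diff(depression_update(0.5, el, p)) > 0))
  expect_error(depression_update(0.5, -1, p), "non-negative")
  # periodic spiking converges to the fixed point of the update map
  D <- 1
  for (i in 1:1000) D <- depression_update(D, 100, p)
  expect_equal(D, depression_update(D, 100, p), tolerance = 1e-10)
})

test_that("mini release rate follows the sigmoidal recovery expression", {
  expect_equal(mini_rate(0, 0), 0)
  expect_equal(mini_rate(1e6, 0), 1 / 250, tolerance = 1e-9)
  t <- seq(0, 300, by = 10)
  expect_true(all(diff(mini_rate(t, 0)) > 0))
})

test_that("sampled release times match the analytic first-release distribution", {
  # independent oracle: the CDF of the first release after t0 is
  # 1 - exp(-Lambda(t)) with Lambda the integral of the hazard
  upsilon <- 30
  cdf <- function(t) {
    1 - exp(-vapply(t, function(ti)
      integrate(mini_rate, 0, ti, t0 = 0, upsilon = upsilon,
                rel.tol = 1e-9)$value, 0))
  }
  set.seed(11)
  first <- replicate(4000, {
    r <- mini_release_times(0, 5000, upsilon)
    if (length(r)) r[1] else NA
  })
  first <- first[!is.na(first)]
  expect_gt(length(first), 3500)
  ks <- suppressWarnings(stats::ks.test(first, cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("synaptic current is ohmic in the open fraction and driving force", {
  expect_equal(synaptic_current(0.1, 0.5, 0, 0, 1), 0)       # reversal
  expect_equal(synaptic_current(0.1, 0, -70, 0, 1), 0)       # closed
  expect_equal(synaptic_current(0.1, 0.5, -70, 0, 0.133),
               0.133 * 0.1 * 0.5 * (-70), tolerance = 1e-12)
  expect_error(synaptic_current(0.1, 1.5, -70))
})

test_that("channel open fraction rises on release and decays otherwise", {
  grid <- seq(0, 100, by = 0.5)
  # no events: monotone decay from 0 stays 0
  o0 <- advance_channel_kinetics(numeric(0), grid)
  expect_true(all(o0$O == 0))
  # single event: one transient with a single local maximum
  o1 <- advance_channel_kinetics(20, grid)
  peak <- which.max(o1$O)
  expect_true(all(diff(o1$O[seq_len(peak)]) >= 0))
  expect_true(all(diff(o1$O[peak:length(grid)]) <= 0))
  expect_equal(max(o1$O), 0, tolerance = 1)
  # paired events with depression: the second increment is scaled by
  # the available resources at the second event
  dp <- depression_params()
  o2 <- advance_channel_kinetics(c(20, 25), grid, tau_decay = 2,
                                 weight = 0.075, g_max = 0.15,
                                 depression = dp)
  base <- 0.075 / 0.15
  at <- function(t) o2$O[match(t, grid)]
  inc2 <- at(25) - at(24.5) * exp(-0.5 / 2)
  D2 <- depression_update(1, 5, dp)
  expect_equal(inc2, base * D2 * (1 - at(24.5) * exp(-0.5 / 2)),
               tolerance = 0.02 * inc2)
  expect_error(advance_channel_kinetics(c(5, 1), grid), "sorted")
})
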