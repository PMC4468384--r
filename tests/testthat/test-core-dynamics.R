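# Single-neuron and single-synapse primitives against their closed forms.

test_that("euler_membrane_step matches the hand-evaluated update", {
  # one step toward a 1 mV drive from rest: 0 + (0.5/5) * (1 - 0) = 0.1
  expect_equal(euler_membrane_step(0, 1, tau = 5, dt = 0.5), 0.1)
  # fixed point: v = v_ext is invariant for any tau/dt
  for (v in c(-10, 0, 7.3)) {
    expect_equal(euler_membrane_step(v, v, tau = 4, dt = 0.5), v)
  }
  # free decay over t = tau approaches e^-1 of the start, within Euler error
  v <- 10
  tau <- 5
  dt <- 0.05
  for (i in seq_len(tau / dt)) v <- euler_membrane_step(v, 0, tau, dt)
  expect_equal(v, 10 * exp(-1), tolerance = 0.01)
  expect_error(euler_membrane_step(0, 1, tau = 5, dt = 5), "dt")
  expect_error(euler_membrane_step(NaN, 1, tau = 5, dt = 0.5), "non-finite")
})

test_that("transfer reproduces the piecewise power law", {
  p <- cell_params(tau = 5, beta = 2, theta_min = -2, theta_max = 6)
  expect_equal(transfer(p$theta_min, p), 0)
  expect_equal(transfer(p$theta_max, p), 1)
  expect_equal(transfer((p$theta_min + p$theta_max) / 2, p), 0.25)
  # granule cells at rest: the mechanism for spontaneous bulbar activity
  expect_equal(transfer(0, gr_params()), (1 / 7)^2, tolerance = 1e-12)
  # saturation above theta_max, silence below theta_min
  expect_equal(transfer(c(-100, 100), p), c(0, 1))
})

test_that("transfer is non-decreasing and continuous at the branch points", {
  for (beta in c(1, 2, 3)) {
    p <- cell_params(tau = 5, beta = beta, theta_min = -1.4, theta_max = 9)
    v <- seq(-5, 12, by = 0.01)
    f <- transfer(v, p)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    eps <- 1e-9
    expect_equal(transfer(p$theta_min + eps, p), 0, tolerance = 1e-6)
    expect_equal(transfer(p$theta_max - eps, p), 1, tolerance = 1e-6)
  }
})

test_that("conductance_kernel rises, peaks at the closed-form time, decays", {
  k <- synapse_kernel(g_max = 1, e_nernst = 70, tau1 = 1, tau2 = 2)
  expect_equal(conductance_kernel(0, k), 0)
  t_peak <- log(2) / (1 / 1 - 1 / 2) # 2 ln 2
  expect_equal(t_peak, 2 * log(2))
  # stationary point: numerically the maximum over a fine grid
  tt <- seq(0, 20, by = 1e-3)
  g <- conductance_kernel(tt, k)
  expect_equal(tt[which.max(g)], t_peak, tolerance = 1e-3)
  expect_lt(conductance_kernel(100, k), 1e-12)
  expect_true(all(g >= 0))
  # closed form at machine precision against an independent evaluation
  expect_equal(g, 1 * (exp(-tt / 2) - exp(-tt / 1)), tolerance = 1e-15)
  expect_error(conductance_kernel(-1, k), ">= 0")
})

test_that("conductance_kernel integrates to g_max * (tau2 - tau1)", {
  # analytic integral of the difference of exponentials
  k <- synapse_kernel(g_max = 0.18, e_nernst = -10, tau1 = 4, tau2 = 8)
  num <- stats::integrate(function(t) conductance_kernel(t, k), 0, Inf)
  expect_equal(num$value, 0.18 * (8 - 4), tolerance = 1e-6)
})

test_that("synaptic_drive follows the driving-force convention", {
  expect_equal(synaptic_drive(1, 0.5, e_nernst = 70, v_post = 10), 30)
  expect_equal(synaptic_drive(1, 1, e_nernst = -10, v_post = -10), 0)
  # inhibitory pathway below reversal: strictly negative drive
  expect_lt(synaptic_drive(0.7, 0.2, e_nernst = -10, v_post = 0), 0)
  expect_error(synaptic_drive(-1, 1, 70, 0), ">= 0")
})

test_that("spike_and_reset respects probability, reset and refractoriness", {
  p <- cell_params(tau = 5, beta = 2, theta_min = 0, theta_max = 10)
  st <- neuron_state(5, v = -5) # below threshold: transfer = 0
  out <- spike_and_reset(st, p, t = 0, rng = function(n) runif(n))
  expect_false(any(out$spiked))
  # certain spiking: v at saturation, fresh state
  st <- neuron_state(5, v = 10)
  out <- spike_and_reset(st, p, t = 0, rng = function(n) runif(n))
  expect_true(all(out$spiked))
  expect_true(all(out$v == p$v_hyper))
  expect_true(all(out$t_last_spike == 0))
  # 1 ms later the neuron is still refractory even at saturation
  out$v[] <- 10
  out2 <- spike_and_reset(out, p, t = 1, rng = function(n) runif(n))
  expect_false(any(out2$spiked))
  # after t_refrac it may spike again
  out3 <- spike_and_reset(out, p, t = 2, rng = function(n) runif(n))
  expect_true(all(out3$spiked))
  expect_error(spike_and_reset(st, p, t = 0), "rng")
})

test_that("spike counts stay within binomial bounds for constant p", {
  # transfer held at p = 0.2 by clamping v mid-range with beta = 1
  p <- cell_params(tau = 5, beta = 1, theta_min = 0, theta_max = 10,
                   t_refrac = 0)
  st <- neuron_state(1, v = 2) # transfer = 0.2
  n_steps <- 2000
  count <- 0
  set.seed(7)
  for (i in seq_len(n_steps)) {
    out <- spike_and_reset(st, p, t = i, rng = function(n) runif(n))
    count <- count + sum(out$spiked)
    # keep v clamped (ignore the reset for this statistical check)
    st$v[] <- 2
    st$t_last_spike[] <- -Inf
  }
  bounds <- qbinom(c(0.005, 0.995), n_steps, 0.2)
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("ahp_step relaxes toward A*X and decays with tau_ahc", {
  p <- cell_params(tau = 10, beta = 2, theta_min = 0, theta_max = 15,
                   a_ahc = 40, tau_ahc = 100, e_ahc = -15)
  # no spikes ever: stays identically zero, zero drive
  st <- ahp_step(numeric(3), rep(FALSE, 3), p, dt = 0.5)
  expect_equal(st$v_ahc, numeric(3))
  expect_equal(st$drive, numeric(3))
  # single spike: jump, then decay to e^-1 of the jump after tau_ahc
  st <- ahp_step(0, TRUE, p, dt = 0.5)
  jump <- st$v_ahc
  expect_gt(jump, 0)
  v <- jump
  for (i in seq_len(100 / 0.5)) v <- ahp_step(v, FALSE, p, dt = 0.5)$v_ahc
  expect_equal(v, jump * exp(-1), tolerance = 0.01)
  # full NE modulation: amplitude 0 silences the adaptation drive
  p0 <- cell_params(tau = 10, beta = 2, theta_min = 0, theta_max = 15,
                    a_ahc = 0, tau_ahc = 100, e_ahc = -15)
  st <- ahp_step(numeric(2), c(TRUE, TRUE), p0, dt = 0.5, v = c(5, 5))
  expect_equal(st$drive, numeric(2))
})

test_that("mitral compartment coupling is the literal voltage difference", {
  expect_equal(couple_mitral_compartments(5, 2), 3)
  expect_equal(couple_mitral_compartments(c(1, 2), c(1, 2)), c(0, 0))
  # monotone: hyperpolarizing the apical compartment lowers the soma drive
  v_soma <- 1
  drives <- couple_mitral_compartments(seq(2, -2, by = -0.5),
                                       rep(v_soma, 9))
  expect_true(all(diff(drives) < 0))
  expect_error(couple_mitral_compartments(1:3, 1:2), "length")
})

test_that("adaptation lowers the steady firing rate of a driven cell", {
  # paired-seed comparison through the full engine: identical networks and
  # stimuli, only the unmodulated adaptation amplitude differs (40 vs 0)
  cfg_on <- small_config()
  cfg_off <- small_config(modulation = list(pyr_a_ahc = list(off = 0)))
  od <- generate_odor(22, concentration = 0.8, cfg = cfg_on)
  on <- run_simulation(build_network(cfg_on, seed = 21), od,
                       ne_state(0, 0), seed = 23)
  off <- run_simulation(build_network(cfg_off, seed = 21), od,
                        ne_state(0, 0), seed = 23)
  expect_lt(mean(on$rates$pyr), mean(off$rates$pyr))
})
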