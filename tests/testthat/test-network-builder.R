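# Odor generation, perturbation, connectivity construction, and the
# simulation loop's structural contracts.

test_that("generate_odor permutes a fixed affinity array", {
  cfg <- network_config()
  a <- generate_odor(1, cfg = cfg)
  b <- generate_odor(1, cfg = cfg)
  expect_identical(a$affinities, b$affinities) # determinism
  c2 <- generate_odor(2, cfg = cfg)
  expect_false(identical(a$affinities, c2$affinities))
  # same multiset of values: equal average response across odorants
  expect_equal(sort(a$affinities), sort(c2$affinities))
  const <- sum(dnorm(1:100, 50, 10)) # direct summation oracle
  for (s in c(1, 2, 99)) {
    expect_equal(sum(generate_odor(s, cfg = cfg)$affinities), const)
  }
  expect_error(generate_odor(1, concentration = 1.2), "concentration")
})

test_that("osn_drive scales linearly and anchors saturation", {
  cfg <- quiet_config() # zero tonic baseline isolates the odor term
  od0 <- generate_odor(3, concentration = 0, cfg = cfg)
  expect_equal(osn_drive(od0, cfg), numeric(100))
  od1 <- generate_odor(3, concentration = 1, cfg = cfg)
  d1 <- osn_drive(od1, cfg)
  # peak channel driven osn_gain-fold past the saturation threshold
  expect_equal(max(d1), cfg$odor$osn_gain * 15)
  odh <- generate_odor(3, concentration = 0.5, cfg = cfg)
  expect_equal(osn_drive(odh, cfg), d1 / 2) # linearity in concentration
  # tonic spontaneous baseline is additive and odor-independent
  cfgb <- network_config()
  expect_equal(osn_drive(NULL, cfgb),
               rep(cfgb$odor$osn_baseline_mv, 100))
  expect_equal(osn_drive(od1, cfgb) - osn_drive(NULL, cfgb), d1)
  bad <- od1
  bad$concentration <- 2
  expect_error(osn_drive(bad, cfgb), "\\[0, 1\\]")
})

test_that("perturb_odor hits the requested normalized distance", {
  cfg <- network_config()
  od <- generate_odor(11, concentration = 0.5, cfg = cfg)
  expect_identical(perturb_odor(od, 0, seed = 1, cfg = cfg), od)
  for (d in c(0.1, 0.4, 0.8, 1)) {
    pert <- perturb_odor(od, d, seed = 5, cfg = cfg)
    got <- euclidean_distance(pert$affinities, od$affinities,
                              normalized = TRUE, cfg = cfg)
    expect_equal(got, d, tolerance = 0.02)
    expect_true(all(pert$affinities >= 0))
    expect_equal(pert$concentration, od$concentration)
  }
  expect_error(perturb_odor(od, 1.5, seed = 1, cfg = cfg), "\\[0, 1\\]")
})

test_that("interodor distance constant is cached and sane", {
  cfg <- network_config()
  k1 <- interodor_distance_constant(cfg)
  expect_identical(k1, interodor_distance_constant(cfg))
  # distance between two random odors is ~1 on the normalized scale
  d <- euclidean_distance(generate_odor(1, cfg = cfg)$affinities,
                          generate_odor(2, cfg = cfg)$affinities,
                          normalized = TRUE, cfg = cfg)
  expect_gt(d, 0.5)
  expect_lt(d, 1.5)
})

test_that("build_network honours the stated connectivity fractions", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 4)
  adj <- net$adjacency
  expect_equal(unname(rowSums(adj$mi_gr)), rep(40, 100)) # 40% fan-out
  expect_identical(adj$gr_mi, t(adj$mi_gr)) # reciprocal dendrodendritic
  expect_equal(unname(colSums(adj$mi_pyr)), rep(20, 100)) # 20% fan-in
  expect_equal(unname(colSums(adj$mi_ff)), rep(40, 100)) # 40% fan-in
  expect_equal(unname(colSums(adj$ff_pyr)), rep(30, 100)) # 30% fan-in
  expect_equal(unname(rowSums(adj$pyr_pyr)), rep(20, 100)) # 20% fan-out
  expect_true(all(diag(adj$pyr_pyr) == 0)) # no self-connections
  # fixed-pathway weights are the adjacency itself (unit weights)
  expect_true(all(adj$mi_pyr %in% c(0, 1)))
  # association-fiber weights: initialized on-adjacency, normalized copy
  expect_true(all(net$w_raw[adj$pyr_pyr == 0] == 0))
  expect_true(all(net$w_raw[adj$pyr_pyr != 0] >= 0 &
                    net$w_raw[adj$pyr_pyr != 0] <= 0.04))
  expect_equal(sum(net$w_norm), 1)
  # reproducibility at the adjacency level
  net2 <- build_network(cfg, seed = 4)
  expect_identical(net$adjacency, net2$adjacency)
  expect_identical(net$w_raw, net2$w_raw)
  expect_error(
    build_network(network_config(connectivity = list(mi_gr_frac = 0)), 1),
    "fraction")
})

test_that("run_simulation is bit-identical under identical seeds", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 8)
  od <- generate_odor(9, concentration = 0.6, cfg = cfg)
  a <- run_simulation(net, od, ne_state(1, 1), seed = 10,
                      record_raster = TRUE)
  b <- run_simulation(net, od, ne_state(1, 1), seed = 10,
                      record_raster = TRUE)
  expect_identical(a$rates, b$rates)
  expect_identical(a$raster, b$raster)
  c2 <- run_simulation(net, od, ne_state(1, 1), seed = 11)
  expect_false(identical(a$rates, c2$rates))
})

test_that("a zero-input network with non-negative thresholds is silent", {
  # lift the two negative thresholds (the model's only intrinsic sources
  # of spontaneous activity): with no drive and no noise, transfer(0) = 0
  # everywhere, so every population must stay exactly silent
  cfg <- quiet_config(n = 50,
                      populations = list(mi = list(theta_min = 0.1)),
                      modulation = list(gr_theta_min_a1 = list(off = 0.1)))
  net <- build_network(cfg, seed = 2)
  sim <- run_simulation(net, NULL, ne_state(0, 0), seed = 3)
  for (p in c("osn", "pg", "mi", "gr", "ff", "pyr", "fb")) {
    expect_equal(sim$rates[[p]], numeric(50))
  }
  # with the shipped negative thresholds the bulb is spontaneously active
  net2 <- build_network(quiet_config(n = 50), seed = 2)
  sim2 <- run_simulation(net2, NULL, ne_state(0, 0), seed = 3)
  expect_gt(mean(sim2$rates$gr), 0)
})

test_that("spontaneous bulbar activity exists with the default profile", {
  net <- build_network(network_config(), seed = 31)
  sim <- run_simulation(net, NULL, ne_state(1, 1), seed = 32)
  expect_gt(mean(sim$rates$mi), 0)
  expect_gt(mean(sim$rates$gr), 0)
})

test_that("mitral odor response grows with concentration", {
  # stochastic ordering over paired seeds
  cfg <- network_config()
  wins <- 0
  for (r in 1:5) {
    net <- build_network(cfg, seed = derive_seed(60, r))
    lo <- run_simulation(net, generate_odor(derive_seed(61, r), 0.2, cfg),
                         ne_state(1, 1), seed = derive_seed(62, r))
    hi <- run_simulation(net, generate_odor(derive_seed(61, r), 0.8, cfg),
                         ne_state(1, 1), seed = derive_seed(62, r))
    wins <- wins + (mean(hi$rates$mi) > mean(lo$rates$mi))
  }
  expect_gte(wins, 4)
})

test_that("naive cortical pattern correlates with its bulbar input", {
  cfg <- network_config()
  ok <- 0
  for (r in 1:3) {
    net <- build_network(cfg, seed = derive_seed(70, r))
    od <- generate_odor(derive_seed(71, r), 0.8, cfg)
    sim <- run_simulation(net, od, ne_state(1, 1), seed = derive_seed(72, r))
    # projected bulbar drive per pyramidal cell
    drive <- as.numeric(sim$rates$mi %*% net$adjacency$mi_pyr)
    rho <- cor(drive, sim$rates$pyr, method = "spearman")
    ok <- ok + (rho > 0)
  }
  expect_gte(ok, 2)
})

test_that("simulation exports write well-formed text files", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 1)
  sim <- run_simulation(net, generate_odor(2, 0.8, cfg), ne_state(1, 1),
                        seed = 3, record_raster = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  write_raster(sim, tmp)
  ras <- read.delim(tmp)
  expect_named(ras, c("time_ms", "population", "neuron_id"))
  expect_true(all(ras$population %in% c("mi", "gr", "ff", "pyr", "fb")))
  tmp2 <- tempfile(fileext = ".csv")
  write_rates(sim, tmp2)
  rates <- read.csv(tmp2)
  expect_named(rates, c("population", "neuron_id", "rate_hz"))
  expect_equal(nrow(rates), 7 * cfg$n_per_type)
  unlink(c(tmp, tmp2))
})

test_that("graded populations match an R-side Euler oracle", {
  # deterministic chain OSN -> PG is independent of spiking; replicate it
  # with plain R updates and compare window means exactly
  cfg <- quiet_config(n = 20)
  net <- build_network(cfg, seed = 5)
  od <- generate_odor(6, concentration = 0.7, cfg = cfg)
  duration <- 300
  settle <- 100
  sim <- run_simulation(net, od, ne_state(0, 0), duration_ms = duration,
                        settle_ms = settle, seed = 7)
  drive <- osn_drive(od, cfg)
  p_osn <- cfg$populations$osn
  p_pg <- cfg$populations$pg
  kk <- cfg$pathways$osn_pg
  v_osn <- v_pg <- numeric(20)
  acc_osn <- acc_pg <- numeric(20)
  n_steps <- duration / cfg$dt
  for (s in seq_len(n_steps)) {
    v_osn <- euler_membrane_step(v_osn, drive, p_osn$tau, cfg$dt)
    f_osn <- transfer(v_osn, p_osn)
    v_pg <- euler_membrane_step(
      v_pg, synaptic_drive(1, kk$g_max * f_osn, kk$e_nernst, v_pg),
      p_pg$tau, cfg$dt)
    if (s > settle / cfg$dt) {
      acc_osn <- acc_osn + f_osn
      acc_pg <- acc_pg + transfer(v_pg, p_pg)
    }
  }
  win <- (duration - settle) / cfg$dt
  expect_equal(sim$rates$osn, acc_osn / win, tolerance = 1e-12)
  expect_equal(sim$rates$pg, acc_pg / win, tolerance = 1e-12)
})

test_that("network_config loads and round-trips profiles", {
  cfg <- network_config()
  tmp <- tempfile(fileext = ".json")
  write_network_config(cfg, tmp)
  cfg2 <- network_config(file = tmp)
  expect_equal(cfg2$populations$gr$theta_min, cfg$populations$gr$theta_min)
  expect_equal(cfg2$pathways$pyr_pyr$g_max, cfg$pathways$pyr_pyr$g_max)
  expect_equal(cfg2$n_per_type, cfg$n_per_type)
  # overrides merge recursively
  cfg3 <- network_config(populations = list(gr = list(theta_min = -2)))
  expect_equal(cfg3$populations$gr$theta_min, -2)
  expect_equal(cfg3$populations$gr$theta_max, 6)
  expect_error(network_config(file = "no/such/file.json"), "not found")
  # the shipped default profile matches the built-in defaults
  shipped <- system.file("extdata", "default_params.json",
                         package = "obpcsim")
  cfg4 <- network_config(file = shipped)
  expect_equal(cfg4$pathways$gr_mi$g_max, 0.18)
  unlink(tmp)
})
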