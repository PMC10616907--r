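test_that("network structure honors density, composition, and Dale's principle", {
  cfg <- simulation_config(n_neurons = 100, connection_density = 0.03,
                           frac_inhibitory = 0.2, seed = 7,
                           duration_ms = 60000)
  truth <- simulate_network(cfg)
  m <- sum(truth$adjacency)
  expect_gte(m, qbinom(0.0005, 9900, 0.03))
  expect_lte(m, qbinom(0.9995, 9900, 0.03))
  expect_equal(sum(truth$signs == "inhibitory"), 20)
  expect_false(any(diag(truth$adjacency)))
  # Dale: out-edge sign is the sender's sign, carried per neuron
  expect_true(all(truth$weights[truth$adjacency] > 0))
  expect_true(all(truth$delays_ms[truth$adjacency] %in% 1:10))
  expect_true(all(truth$delays_ms[!truth$adjacency] == 0))
  # empty graph at density 0
  cfg0 <- simulation_config(n_neurons = 20, connection_density = 0,
                            seed = 1, duration_ms = 60000)
  expect_equal(sum(simulate_network(cfg0)$adjacency), 0)
})

test_that("identical config and seed reproduce truth and raster exactly", {
  cfg <- simulation_config(n_neurons = 30, duration_ms = 60000, seed = 99)
  t1 <- simulate_network(cfg); t2 <- simulate_network(cfg)
  expect_identical(t1$adjacency, t2$adjacency)
  expect_identical(t1$weights, t2$weights)
  expect_identical(t1$neuron_table, t2$neuron_table)
  r1 <- simulate_spikes(t1, cfg); r2 <- simulate_spikes(t2, cfg)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(delay_range_ms = c(0, 5)), "delay")
  expect_error(simulation_config(delay_range_ms = c(2, 15)), "delay")
  expect_error(simulation_config(duration_ms = 500), "duration")
  expect_error(simulation_config(baseline_rate_hz = c(0, 2)), "positive")
  expect_error(simulation_config(region_group = "XX"), "region")
  expect_error(simulation_config(frac_inhibitory = 1.5))
})

test_that("uncoupled neurons fire at their configured baseline", {
  cfg <- simulation_config(n_neurons = 20, connection_density = 0,
                           baseline_rate_hz = c(2, 2),
                           baseline_rate_hz_inh = c(2, 2),
                           duration_ms = 600000, seed = 5)
  truth <- simulate_network(cfg)
  raster <- simulate_spikes(truth, cfg)
  rates <- firing_rates(raster)
  expect_true(all(rates >= 1.5 & rates <= 2.5))
})

test_that("a strong excitatory edge raises the conditional spike probability", {
  cfg <- simulation_config(n_neurons = 2, connection_density = 0,
                           baseline_rate_hz = c(2, 2),
                           baseline_rate_hz_inh = c(2, 2),
                           frac_inhibitory = 0, duration_ms = 600000, seed = 8)
  truth <- simulate_network(cfg)
  truth$adjacency[1, 2] <- TRUE
  truth$delays_ms[1, 2] <- 3L
  truth$weights[1, 2] <- 5
  raster <- simulate_spikes(truth, cfg)
  m <- as.matrix(raster)
  src_t <- which(m[1, ] == 1)
  src_t <- src_t[src_t + 3 <= ncol(m)]
  p_cond <- mean(m[2, src_t + 3])
  p_base <- mean(m[2, ])
  expect_gt(p_cond, 3 * p_base)
})

test_that("degenerate spike configurations are handled", {
  cfg <- simulation_config(n_neurons = 5, duration_ms = 0, seed = 2)
  truth <- simulate_network(cfg)
  raster <- simulate_spikes(truth, cfg)
  expect_equal(raster$n_bins, 0)
  expect_equal(sum(lengths(raster$spikes)), 0)
})

test_that("layer profile peaks land where configured and bad profiles fail", {
  cfg <- simulation_config(duration_ms = 60000)
  prof <- make_layer_profile(cfg)
  lm <- find_landmarks(prof, smooth = 1)
  expect_equal(lm$convex_um, c(305, 545, 905), tolerance = 10)
  bad <- simulation_config(duration_ms = 60000,
                           layer_profile = list(peaks_um = c(300, 320, 900),
                                                widths_um = c(120, 120, 120),
                                                amplitudes = c(1, 1, 1),
                                                thickness_um = 1100))
  expect_error(make_layer_profile(bad), "peaks")
  zero <- simulation_config(duration_ms = 60000,
                            layer_profile = list(peaks_um = c(300, 550, 900),
                                                 widths_um = c(80, 70, 120),
                                                 amplitudes = c(0, 0.8, 0.9),
                                                 thickness_um = 1100))
  expect_error(make_layer_profile(zero), "positive")
})

test_that("neuron table is internally consistent", {
  cfg <- simulation_config(n_neurons = 60, duration_ms = 60000, seed = 12,
                           region_group = "RFV")
  truth <- simulate_network(cfg)
  tab <- truth$neuron_table
  expect_true(all(tab$depth_um >= 0 & tab$depth_um <= 1100))
  expect_true(all(tab$hemisphere == "R"))
  expect_true(all(tab$region_group == "RFV"))
  # layer labels agree with the boundary rules applied to the same profile
  reassigned <- assign_layers(tab, truth$boundaries)
  expect_equal(reassigned$layer, tab$layer)
})
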