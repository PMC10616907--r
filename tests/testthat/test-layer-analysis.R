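three_peak_profile <- function(peaks = c(300, 550, 900),
                               widths = c(80, 70, 120),
                               amps = c(1, 0.8, 0.9), thick = 1100) {
  depth <- seq(5, thick - 5, by = 10)
  dens <- sapply(1:3, function(k) amps[k] * exp(-0.5 * ((depth - peaks[k]) / widths[k])^2))
  structure(list(depth_um = depth, density = rowSums(dens),
                 thickness_um = thick),
            class = "layer_profile")
}

test_that("landmarks are found at planted peaks and bad profiles error", {
  lm <- find_landmarks(three_peak_profile(), smooth = 5)
  expect_equal(lm$convex_um, c(305, 545, 905), tolerance = 11)
  expect_length(lm$concave_um, 2)
  expect_true(all(lm$concave_um > lm$convex_um[1] &
                    lm$concave_um < lm$convex_um[3]))
  expect_error(find_landmarks(seq(0, 1, length.out = 50)), "found 0")
  four <- rep(0, 100)
  for (c0 in c(15, 40, 60, 85)) four <- four + exp(-0.5 * ((1:100 - c0) / 4)^2)
  expect_error(find_landmarks(four, smooth = 1), "found 4")
  expect_error(find_landmarks(c(1, 2, 1)), "20 depth bins")
})

test_that("trough positions match a dense-grid oracle on the analytic mixture", {
  peaks <- c(300, 550, 900); widths <- c(75, 75, 75); amps <- c(1, 1, 1)
  mix <- function(x) rowSums(sapply(1:3, function(k)
    amps[k] * exp(-0.5 * ((x - peaks[k]) / widths[k])^2)))
  fine <- seq(0, 1100, by = 0.1)
  dens <- mix(fine)
  m1 <- fine[300 / 0.1 + which.min(dens[fine >= 300 & fine <= 550])]
  m2 <- fine[550 / 0.1 + which.min(dens[fine >= 550 & fine <= 900])]
  lm <- find_landmarks(three_peak_profile(peaks, widths, amps), smooth = 1)
  expect_equal(lm$concave_um[1], m1, tolerance = 11)
  expect_equal(lm$concave_um[2], m2, tolerance = 11)
})

test_that("boundary rules reproduce hand-computed positions", {
  lm <- list(convex_um = c(300, 550, 900), concave_um = c(430, 700),
             surface_um = 0)
  b <- layer_boundaries(lm, bottom = 1100)
  expect_equal(unname(b$boundaries_um),
               c(100, 200, 430, (550 + 700) / 2, (700 + 900) / 2))
  expect_equal(sum(b$thickness_um), 1100)
  # literal alternatives
  b2 <- layer_boundaries(lm, bottom = 1100, rule_l23 = "second_convex")
  expect_equal(unname(b2$boundaries_um[2]), 2 * 550 / 3, tolerance = 1e-9)
  lm3 <- list(convex_um = c(300, 550, 900), concave_um = c(430, 700, 1000))
  b3 <- layer_boundaries(lm3, bottom = 1100, rule_l56 = "concave_concave")
  expect_equal(unname(b3$boundaries_um[5]), (700 + 1000) / 2)
  expect_error(layer_boundaries(lm, bottom = 1100,
                                rule_l56 = "concave_concave"), "third")
  # translation equivariance of the affine rules
  lm_t <- list(convex_um = lm$convex_um + 50, concave_um = lm$concave_um + 50)
  b_t <- layer_boundaries(lm_t, surface = 50, bottom = 1150)
  expect_equal(unname(b_t$boundaries_um), unname(b$boundaries_um) + 50)
})

test_that("layer assignment uses half-open intervals toward the deeper layer", {
  lm <- list(convex_um = c(300, 550, 900), concave_um = c(430, 700))
  b <- layer_boundaries(lm, bottom = 1100)
  nt <- data.frame(neuron_id = paste0("n", 1:6),
                   depth_um = c(50, 100, 200, 430, 1100, 1200))
  out <- assign_layers(nt, b)
  expect_equal(out$layer, c(1L, 2L, 3L, 4L, 6L, NA))
  expect_equal(out$in_analysis, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("active densities are strict-threshold counts per area", {
  nt <- data.frame(neuron_id = paste0("n", 1:8),
                   firing_rate_hz = c(0.05, 0.1, 0.5, 2, 1, 3, 0.2, 0),
                   ei_label = rep(c("excitatory", "inhibitory"), 4),
                   layer = c(2, 2, 3, 3, 5, 5, 6, 6),
                   in_analysis = TRUE)
  d <- active_density(nt, area_mm2 = 2)
  all_exc <- d[d$layer == "all" & d$ei_label == "excitatory", ]
  expect_equal(all_exc$n_active, 3)     # 0.5, 1, 0.2 (0.05 and 0.1 excluded)
  expect_equal(all_exc$density_per_mm2, 1.5)
  # strict: the layer-2 neurons at 0.05 and exactly 0.1 Hz are not active
  expect_equal(sum(d$n_active[d$layer == "2"]), 0)
  expect_error(active_density(nt, area_mm2 = 0), "positive")
  # additivity of per-layer densities to the all-layer value
  per_layer <- d[d$layer != "all" & d$ei_label == "excitatory", ]
  expect_equal(sum(per_layer$density_per_mm2), all_exc$density_per_mm2)
})

test_that("E/I balance covers fractions and the empty case", {
  nt <- data.frame(firing_rate_hz = c(rep(1, 80), rep(2, 20)),
                   ei_label = rep(c("excitatory", "inhibitory"), c(80, 20)))
  expect_equal(unname(ei_balance(nt)), c(0.8, 0.2))
  all_inh <- data.frame(firing_rate_hz = rep(1, 5),
                        ei_label = rep("inhibitory", 5))
  expect_equal(unname(ei_balance(all_inh)), c(0, 1))
  silent <- data.frame(firing_rate_hz = rep(0.01, 5),
                       ei_label = rep("excitatory", 5))
  expect_warning(b <- ei_balance(silent), "no active")
  expect_true(all(is.na(b)))
})

test_that("firing rates and stationarity behave on simple rasters", {
  r <- spike_raster(list(seq(1, 60000, length.out = 120), integer()), 60000)
  expect_equal(unname(firing_rates(r)), c(2, 0))
  set.seed(6)
  m <- matrix(rbinom(20 * 40000, 1, rep(runif(20, 0.001, 0.02), 40000)),
              20, 40000)
  rs <- rate_stationarity(raster_from_matrix(m))
  expect_gt(rs, 0.9)
})
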