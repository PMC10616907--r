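test_that("radar aggregation averages per group and ignores row order", {
  tab <- data.frame(region_group = c("LF", "LF", "RD", "LO"),
                    metric = "thickness",
                    value = c(1, 3, 5, 7))
  agg <- radar_aggregate(tab, "thickness")
  expect_equal(agg$means$mean[agg$means$region_group == "LF"], 2)
  expect_equal(agg$means$mean[agg$means$region_group == "RD"], 5)
  expect_true(is.na(agg$means$mean[agg$means$region_group == "ROV"]))
  shuffled <- tab[c(3, 1, 4, 2), ]
  expect_equal(radar_aggregate(shuffled, "thickness")$means, agg$means)
  expect_equal(nrow(agg$means), 16)
})

test_that("Mann-Whitney wrapper handles separation, ties, and correction", {
  sep <- group_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$effect_size, 1)
  swapped <- group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(swapped$effect_size, 0)
  expect_equal(sep$p_raw, swapped$p_raw)
  same <- group_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_raw, 1)
  expect_equal(same$effect_size, 0.5)
  r <- group_test(c(1, 5, 9, 2), c(3, 4, 8), n_comparisons = 6)
  expect_equal(r$p_corrected, min(1, r$p_raw * 6))
  expect_gte(r$p_corrected, r$p_raw)
  expect_equal(r$n, c(4, 3))
  expect_error(group_test(numeric(), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p matches full rank-assignment enumeration", {
  set.seed(17)
  sizes <- list(c(3, 3), c(4, 5), c(6, 4), c(8, 8))
  for (sz in sizes) {
    x <- sample(seq(1, 100), sz[1])
    y <- sample(setdiff(seq(1, 100), x), sz[2])
    got <- group_test(x, y)$p_raw
    expect_equal(got, oracle_mw_p(x, y), tolerance = 1e-10)
  }
})

test_that("effect-size symmetry holds across random samples", {
  set.seed(23)
  for (r in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    a <- group_test(x, y); b <- group_test(y, x)
    expect_equal(a$effect_size, 1 - b$effect_size, tolerance = 1e-12)
  }
})

test_that("interlayer matrices average weights by sender/receiver layer", {
  nodes <- data.frame(neuron_id = paste0("n", 1:4),
                      ei_label = "excitatory",
                      layer = c(2, 2, 6, 6))
  edges <- data.frame(src = c("n1", "n2", "n3", "n3"),
                      dst = c("n3", "n3", "n1", "n2"),
                      weight = c(1, 3, 5, 7),
                      strength = 1, sharpness = 1, d_peak = 1L,
                      category = "EE")
  net <- structure(list(nodes = nodes, edges = edges,
                        acceptance_maps = list()),
                   class = "effective_network")
  w <- interlayer_weights(net)
  expect_equal(w["L2", "L6"], 2)    # (1 + 3) / 2
  expect_equal(w["L6", "L2"], 6)    # (5 + 7) / 2
  expect_true(is.na(w["L3", "L4"]))
})

test_that("identical groups give permutation p of 1 everywhere testable", {
  set.seed(31)
  mats <- lapply(1:3, function(k) matrix(rnorm(25), 5, 5,
                                         dimnames = list(paste0("L", 2:6),
                                                         paste0("L", 2:6))))
  res <- nbs_interlayer(mats, mats, n_perm = 200, seed = 4)
  expect_true(all(res$p[res$testable] == 1))
  expect_true(all(abs(res$effect_size[res$testable]) < 1e-12))
})

test_that("NBS effect sizes negate when groups swap", {
  set.seed(37)
  ga <- lapply(1:4, function(k) matrix(rnorm(25, 1), 5, 5))
  gb <- lapply(1:4, function(k) matrix(rnorm(25), 5, 5))
  ab <- nbs_interlayer(ga, gb, n_perm = 100, seed = 9)
  ba <- nbs_interlayer(gb, ga, n_perm = 100, seed = 9)
  expect_equal(ab$effect_size, -ba$effect_size, tolerance = 1e-12)
})

test_that("permutation p-values are seeded and within add-one bounds", {
  set.seed(41)
  ga <- lapply(1:4, function(k) matrix(rnorm(25, 0.5), 5, 5))
  gb <- lapply(1:4, function(k) matrix(rnorm(25), 5, 5))
  r1 <- nbs_interlayer(ga, gb, n_perm = 300, seed = 12)
  r2 <- nbs_interlayer(ga, gb, n_perm = 300, seed = 12)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p[r1$testable] >= 1 / 301))
  expect_true(all(r1$p[r1$testable] <= 1))
})

test_that("frontal contrast wraps the group test with the right groups", {
  set.seed(43)
  groups <- rep(region_groups(), each = 2)
  tab <- data.frame(region_group = groups, metric = "w",
                    value = rnorm(length(groups)) +
                      ifelse(groups %in% c("LF", "LFV", "RF", "RFV"), 2, 0))
  res <- frontal_contrast(tab, "w")
  expect_equal(res$n, c(8, 24))
  expect_lt(res$p_corrected, 0.05)
  expect_gt(res$effect_size, 0.8)
  # degenerate single-recording target still reports sizes
  tab1 <- tab[c(which(groups == "LF")[1], which(!groups %in% c("LF", "LFV", "RF", "RFV"))), ]
  res1 <- frontal_contrast(tab1, "w")
  expect_equal(res1$n[1], 1)
})
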