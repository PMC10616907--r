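test_that("degenerate series carry no transfer entropy", {
  T <- 200
  i <- rbinom(T, 1, 0.2)
  zeros <- rep(0L, T)
  for (d in c(0, 1, 5, 30)) {
    expect_equal(transfer_entropy(i, zeros, d), 0)
    expect_equal(transfer_entropy(zeros, i, d), 0)
    expect_equal(sorted_local_te(i, zeros, d), 0)
  }
  expect_equal(transfer_entropy(zeros, zeros, 3), 0)
})

test_that("TE and SLTE match the exhaustive-histogram oracle on fixed cases", {
  i <- rep(c(0L, 1L), 10)
  j <- rep(c(1L, 0L), 10)
  expect_equal(transfer_entropy(i, j, 1), oracle_te(i, j, 1), tolerance = 1e-14)
  expect_equal(sorted_local_te(i, j, 1), oracle_te(i, j, 1, sorted = TRUE),
               tolerance = 1e-14)
  set.seed(7)
  for (r in 1:10) {
    T <- sample(100:1500, 1)
    i <- rbinom(T, 1, runif(1, 0.02, 0.3))
    j <- rbinom(T, 1, runif(1, 0.02, 0.3))
    for (d in c(0, 1, 4, 17, 30)) {
      expect_equal(transfer_entropy(i, j, d), oracle_te(i, j, d),
                   tolerance = 1e-12)
      expect_equal(sorted_local_te(i, j, d), oracle_te(i, j, d, sorted = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("a perfect lag-1 copy transfers the source entropy", {
  set.seed(11)
  T <- 1e5
  j <- rbinom(T, 1, 0.3)
  i <- c(0L, j[-T])
  te <- transfer_entropy(i, j, 1)
  expect_equal(te, oracle_te(i, j, 1), tolerance = 1e-12)
  h <- -(0.3 * log(0.3) + 0.7 * log(0.7))
  expect_equal(te, h, tolerance = 0.02)
})

test_that("SLTE sign tracks the coupling sign", {
  set.seed(12)
  T <- 1e5
  j <- rbinom(T, 1, 0.1)
  i_exc <- c(0L, j[-T])
  expect_gt(sorted_local_te(i_exc, j, 1), 0)
  i_inh <- rbinom(T, 1, 0.2)
  i_inh[pmin(which(j == 1) + 1, T)] <- 0L
  expect_lt(sorted_local_te(i_inh, j, 1), 0)
})

test_that("TE is nonnegative and input validation rejects bad calls", {
  set.seed(3)
  for (r in 1:20) {
    T <- sample(50:400, 1)
    i <- rbinom(T, 1, 0.3); j <- rbinom(T, 1, 0.3)
    d <- sample(0:30, 1)
    expect_gte(transfer_entropy(i, j, d), 0)
  }
  expect_error(transfer_entropy(c(0, 1), c(0, 1, 1), 1), "equal length")
  expect_error(transfer_entropy(c(0, 1, 0), c(0, 1, 1), -1), "nonnegative")
  expect_error(transfer_entropy(rep(0, 5), rep(0, 5), 4), "shorter")
  expect_error(transfer_entropy(c(0, 2, 0, 1), c(0, 1, 0, 1), 1), "binary")
})

test_that("sharpness follows the windowed-mass formula", {
  te <- rep(0, 31); te[6] <- 0.4          # all mass at d = 5
  expect_equal(sharpness(te, 5, tau = 4), 1)
  te_c <- rep(0.2, 31)                    # constant profile, peak tie at d = 0
  expect_equal(sharpness(te_c, 0, tau = 4), 5 / 31)
  te_l <- rep(0, 31); te_l[30] <- 1; te_l[31] <- 2  # late mass, clipped window
  expect_equal(sharpness(te_l, 29, tau = 4), 1)
  expect_true(is.na(sharpness(rep(0, 31), 0)))
  expect_error(sharpness(c(-0.1, rep(0.1, 30)), 0), "nonnegative")
})

test_that("normalized TE divides by the binary entropy magnitude", {
  expect_equal(normalized_te(0, 0.2), 0)
  h5 <- -(0.5 * log(0.5) + 0.5 * log(0.5))
  expect_equal(normalized_te(h5, 0.5), 1)
  h01 <- -(0.01 * log(0.01) + 0.99 * log(0.99))
  expect_equal(normalized_te(0.02, 0.01), 0.02 / h01)
  expect_true(is.na(normalized_te(0.1, 0)))
  expect_true(is.na(normalized_te(0.1, 1)))
})

test_that("delay profiles locate planted delays and break ties low", {
  set.seed(21)
  T <- 6e4
  j <- rbinom(T, 1, 0.02)
  i <- rbinom(T, 1, 0.005)
  hit <- which(j == 1) + 3
  i[hit[hit <= T]] <- 1L
  prof <- delay_profile(i, j)
  expect_s3_class(prof, "delay_profile")
  expect_equal(prof$d_peak, 3)
  expect_equal(prof$strength, max(prof$te))
  expect_equal(prof$ei_bias, prof$slte[prof$d_peak + 1])
  expect_gt(prof$sharpness, 0.5)
  # identically zero TE flags no-signal
  z <- delay_profile(rep(0L, 100), rep(0L, 100))
  expect_true(z$no_signal)
  expect_true(is.na(z$sharpness))
  # tie break: which.max takes the smallest delay
  te <- rep(0, 31); te[c(3, 9)] <- 1
  expect_equal(which.max(te) - 1L, 2L)
})

test_that("all-pairs matrices agree with single-pair calls and are equivariant", {
  set.seed(31)
  T <- 4000
  m <- matrix(rbinom(3 * T, 1, 0.05), 3, T)
  raster <- raster_from_matrix(m)
  pw <- all_pairs_profiles(raster, d_max = 10, tau = 4)
  expect_equal(sum(!is.na(pw$strength)), 6)
  for (jj in 1:3) for (ii in 1:3) {
    if (ii == jj) next
    single <- delay_profile(m[ii, ], m[jj, ], d_max = 10, tau = 4)
    expect_equal(pw$strength[jj, ii], single$strength, tolerance = 1e-12)
    expect_equal(pw$sharpness[jj, ii], single$sharpness, tolerance = 1e-12)
    expect_equal(pw$ei_bias[jj, ii], single$ei_bias, tolerance = 1e-12)
    expect_equal(pw$d_peak[jj, ii], single$d_peak)
  }
  # permuting neurons permutes the matrices identically
  perm <- c(3, 1, 2)
  pw_p <- all_pairs_profiles(raster_from_matrix(m[perm, ]), d_max = 10)
  expect_equal(unname(pw_p$strength), unname(pw$strength[perm, perm]))
  expect_equal(unname(pw_p$d_peak), unname(pw$d_peak[perm, perm]))
})

test_that("TE of independent neurons shrinks with recording length", {
  set.seed(41)
  te_at <- function(T) {
    i <- rbinom(T, 1, 0.02); j <- rbinom(T, 1, 0.02)
    median(delay_profile(i, j, d_max = 10)$te)
  }
  short <- median(replicate(5, te_at(5e3)))
  long <- median(replicate(5, te_at(2e5)))
  expect_lt(long, short)
})
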