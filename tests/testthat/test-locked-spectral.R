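# Randomization trials, Cliff's Delta and effect-size maps.

test_that("randomization trials average k epochs and keep the grand mean", {
  fs <- 1000
  n_tr <- 30; n_t <- 1001
  dat <- array(withr::with_seed(1, rnorm(n_tr * 1 * n_t)),
               dim = c(n_tr, 1, n_t))
  labels <- data.frame(class = rep("echolocation", n_tr), subclass = "none",
                       onset_s = seq_len(n_tr))
  ep <- epoch_set(dat, fs, c(-0.5, 0.5), labels,
                  data.frame(structure = "CN", depth_um = 200))

  # identical epochs: every trial equals that epoch
  dat1 <- dat; for (i in seq_len(n_tr)) dat1[i, 1, ] <- dat[1, 1, ]
  ep1 <- epoch_set(dat1, fs, c(-0.5, 0.5), labels, ep$channel_meta)
  rs1 <- build_randomization_trials(ep1, "echolocation", 20, 10, rng_seed = 5)
  expect_lt(max(abs(sweep(rs1$trials[, 1, ], 2, dat[1, 1, ]))), 1e-12)

  # N(0,1) epochs, k = 100 (with replacement here): trial std ~ 1/sqrt(100)
  rs <- suppressWarnings(
    build_randomization_trials(ep, "echolocation", 200, 100, rng_seed = 6))
  sd_per_sample <- mean(apply(rs$trials[, 1, ], 2, stats::sd))
  expect_lt(abs(sd_per_sample - 0.1) / 0.1, 0.2)

  # determinism and the mean-preservation contract
  rs2 <- suppressWarnings(
    build_randomization_trials(ep, "echolocation", 200, 100, rng_seed = 6))
  expect_identical(rs$trials, rs2$trials)
  expect_lt(max(abs(colMeans(rs$trials[, 1, ]) - colMeans(dat[, 1, ]))), 0.05)

  expect_error(build_randomization_trials(ep, "echolocation", 0, 10), "positive")
  expect_error(build_randomization_trials(ep, "communication", 10, 10),
               "at least 2")
})

test_that("cliffs_delta matches brute force and the 2*AUC - 1 identity", {
  brute <- function(a, b) {
    (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) / (length(a) * length(b))
  }
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(2, 3), c(0, 1)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)), -5 / 9)

  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(2:12, 1); m <- sample(2:12, 1)
      a <- sample(0:6, n, replace = TRUE) + rbinom(n, 1, 0.5) * 0.5
      b <- sample(0:6, m, replace = TRUE) + rbinom(m, 1, 0.5) * 0.5
      d <- cliffs_delta(a, b)
      expect_equal(d, brute(a, b))
      u <- suppressWarnings(stats::wilcox.test(a, b)$statistic)
      expect_equal(d, unname(2 * u / (n * m) - 1))
      # antisymmetry and monotone invariance
      expect_equal(cliffs_delta(b, a), -d)
      expect_equal(cliffs_delta(exp(a), exp(b)), d)
    }
  })
  expect_error(cliffs_delta(numeric(0), 1), "empty")
})

test_that("effect maps are null for identical trial sets and saturate under dominance", {
  made <- make_lfp_epochs(n_calls = 30, seed = 9)
  rs_e <- build_randomization_trials(made$epochs, "echolocation", 150, 20,
                                     rng_seed = 1)
  rs_c <- build_randomization_trials(made$epochs, "communication", 150, 20,
                                     rng_seed = 2)
  # same set on both sides: d identically 0
  m0 <- effect_size_map(rs_e, rs_e, step_s = 0.05)
  expect_lt(max(abs(m0$values)), 0.05)
  expect_equal(attr(m0, "borders"), c(small = 0.147, medium = 0.333,
                                      large = 0.474))
  # condition A = condition B scaled by sqrt(10): power x10 -> d ~ +1
  rs_big <- rs_c
  rs_big$trials <- rs_e$trials * sqrt(10)
  mdom <- effect_size_map(rs_big, rs_e, step_s = 0.05)
  expect_gt(min(mdom$values), 0.85)
  expect_gt(mean(mdom$values), 0.95)

  bad <- rs_c
  bad$time <- bad$time + 1
  expect_error(effect_size_map(rs_e, bad), "grids")
})

test_that("an injected band-limited pre-call burst is recovered in the effect map", {
  burst <- burst_entry("echolocation", "FAF", c(50, 800), c(12, 20),
                       c(-300, -100), gain = 2)
  made <- make_lfp_epochs(n_calls = 150, seed = 10, burst_table = burst)
  rs_e <- build_randomization_trials(made$epochs, "echolocation", 300, 50,
                                     rng_seed = 3)
  rs_c <- build_randomization_trials(made$epochs, "communication", 300, 50,
                                     rng_seed = 4)
  m <- effect_size_map(rs_e, rs_c, channel = 1, step_s = 0.025)
  sel_t <- m$time >= -0.3 & m$time <= -0.1
  sel_f <- m$freq >= 12 & m$freq <= 20
  expect_gt(mean(m$values[sel_t, sel_f]), 0.33)
  # argmax of the map lies inside the injected band/window
  am <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  expect_true(m$time[am[1]] >= -0.35 && m$time[am[1]] <= -0.05)
  expect_true(m$freq[am[2]] >= 10 && m$freq[am[2]] <= 22)
})

test_that("band_depth_profile averages the band rows and orders by depth", {
  mk <- function(v) tf_map(time = c(0, 0.1), freq = c(5, 10, 15),
                           values = matrix(v, 2, 3, byrow = TRUE),
                           kind = "delta")
  m1 <- mk(c(0.2, 0.6, 0)) # theta-alpha rows at 5 and 10 Hz
  prof <- band_depth_profile(list(m1), c(4, 12), depths_um = 300)
  expect_equal(unname(prof$profile[1, ]), c(0.4, 0.4))
  m2 <- mk(c(0.4, 0.4, 0))
  p2 <- band_depth_profile(list(m2, m1), c(4, 12), depths_um = c(800, 300))
  expect_equal(p2$depths_um, c(300, 800))
  expect_equal(unname(p2$profile[, 1]), c(0.4, 0.4))
  expect_error(band_depth_profile(list(m1), c(60, 80)), "no frequency bins")
})
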