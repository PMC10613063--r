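# Synthetic-session generator: movie surrogate, locomotion trace, Poisson
# spiking and the behaviour-modulation modes.

test_that("generated movies are bounded, temporally correlated and deterministic", {
  m <- generate_movie(30, 32, 32, smoothness = 0.8, seed = 7)
  expect_equal(n_frames(m), 30)
  expect_true(all(m$frames >= 0 & m$frames <= 1))

  cc <- cor(t(m$frames))
  lag1 <- mean(cc[cbind(1:29, 2:30)])
  lag5plus <- mean(cc[abs(row(cc) - col(cc)) >= 5])
  expect_gt(lag1, lag5plus)

  # independence limit: smoothness 0 gives near-zero adjacent correlation
  m0 <- generate_movie(30, 32, 32, smoothness = 0, seed = 7)
  cc0 <- cor(t(m0$frames))
  expect_lt(abs(mean(cc0[cbind(1:29, 2:30)])), 0.1)

  expect_identical(generate_movie(30, 32, 32, 0.8, seed = 7)$frames, m$frames)
  expect_error(generate_movie(1, 32, 32), class = "popdecode_invalid_argument")
  expect_error(generate_movie(30, 2, 32), class = "popdecode_invalid_argument")
})

test_that("speed traces realise the configured two-state structure", {
  cfg0 <- simulation_config(speed_state_fraction = 0, seed = 5)
  sp0 <- generate_speed_trace(20, 30, cfg0)
  expect_true(all(sp0 >= 0))
  expect_true(all(rowMeans(sp0) < 2))

  cfg1 <- simulation_config(speed_state_fraction = 1, seed = 5)
  sp1 <- generate_speed_trace(20, 30, cfg1)
  expect_true(all(rowMeans(sp1) >= 2))

  # mixed fraction: repeat means straddle the threshold consistently with the
  # generator's own latent states
  cfgm <- simulation_config(speed_state_fraction = 0.5, seed = 6)
  spm <- generate_speed_trace(20, 30, cfgm)
  states <- attr(spm, "latent_state")
  expect_setequal(unique(states), c("H", "L"))
  expect_equal(sum(states == "H"), 10)  # round(0.5 * 20), deterministic count
  expect_true(all(rowMeans(spm)[states == "H"] >= 2))
  expect_true(all(rowMeans(spm)[states == "L"] < 2))
})

test_that("simulated counts follow the configured Poisson rates", {
  # law of large numbers: untuned units' mean count approaches baseline
  cfg <- simulation_config(n_repeats = 200, seed = 31)
  s <- simulate_session(cfg, untuned_units(5, rate = 5))
  unit_means <- apply(s$counts, 1, mean)
  expect_true(all(abs(unit_means - 5) < 3 * sqrt(5 / (200 * 30))))

  # Poisson mean and variance agree within Monte-Carlo error at n >= 1e4
  draws <- as.vector(s$counts[1, , ])
  n <- length(draws)
  m <- mean(draws); v <- var(draws)
  expect_lt(abs(m - 5) / sqrt(5 / n), 4)                 # z-test on the mean
  expect_lt(abs(v - 5) / sqrt((2 * 25 + 5) / n), 4)      # z-test on the variance
})

test_that("zero-strength modulation is identical to mode none", {
  cfg <- simulation_config(n_repeats = 10, seed = 41)
  mk <- function(mode) {
    units <- lapply(1:4, function(i)
      unit_spec(3, c(rep(0, 10), 5, rep(0, 19)), modulation_mode = mode,
                modulation_strength = 0))
    simulate_session(cfg, units)
  }
  expect_identical(mk("none")$counts, mk("additive")$counts)
  expect_identical(mk("none")$counts, mk("multiplicative")$counts)
})

test_that("multiplicative gain at constant speed rescales the generating rates exactly", {
  units <- lapply(1:3, function(i)
    unit_spec(2, seq(0, 2.9, by = 0.1), modulation_mode = "multiplicative",
              modulation_strength = 0.5))
  units_none <- lapply(units, function(u) {
    u$modulation_mode <- "none"; u$modulation_strength <- 0; u
  })
  v <- 4
  speed <- matrix(v, 6, 30)
  r_mult <- session_rates(units, speed)$rates
  r_none <- session_rates(units_none, speed)$rates
  expect_identical(r_mult, r_none * (1 + 0.5 * v))
})

test_that("negative additive rates are clipped at zero and the clipping is recorded", {
  units <- list(unit_spec(1, rep(0, 5), modulation_mode = "additive",
                          modulation_strength = -2))
  speed <- matrix(c(0, 5), 2, 5)
  rt <- session_rates(units, speed)
  expect_true(all(rt$rates >= 0))
  expect_equal(rt$n_clipped, 5)  # the five bins of the fast repeat go negative
})

test_that("identical config and seed reproduce sessions bit-exactly", {
  cfg <- simulation_config(c(V1 = 8, CA1 = 4), n_repeats = 10, seed = 99)
  s1 <- simulate_region_session(cfg, modulation_mode = "additive", modulation_strength = 0.3)
  s2 <- simulate_region_session(cfg, modulation_mode = "additive", modulation_strength = 0.3)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$speed, s2$speed)
  expect_identical(s1$ground_truth$latent_state, s2$ground_truth$latent_state)
})

test_that("frame-count mismatches and invalid unit specs are rejected", {
  cfg <- simulation_config(n_frames = 30, seed = 1)
  expect_error(simulate_session(cfg, untuned_units(2, n_frames = 10)),
               class = "popdecode_invalid_argument")
  movie10 <- generate_movie(10, 8, 8, seed = 1)
  expect_error(simulate_session(cfg, untuned_units(2, n_frames = 30), movie = movie10),
               class = "popdecode_invalid_argument")
  expect_error(unit_spec(-1, rep(0, 5)), class = "popdecode_invalid_argument")
  expect_error(unit_spec(1, c(0, NA, 0)), class = "popdecode_invalid_argument")
})

test_that("unit specs locate the preferred frame with lowest-index tie-break", {
  u <- unit_spec(1, c(0, 3, 3, 1))
  expect_equal(u$preferred_frame, 2)
})
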