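# Two-stage gaussian log-link encoding model.

test_that("min-max normalization maps the range onto [0, 1]", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  spanning <- c(0, 0.25, 0.8, 1)
  expect_equal(minmax_normalize(spanning), spanning)  # idempotent on spanning input
  expect_warning(z <- minmax_normalize(c(3, 3, 3)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_error(minmax_normalize(c(1, NA)), class = "popdecode_invalid_argument")
})

test_that("fit metrics follow the MSE formula and flag degenerate correlations", {
  ev <- evaluate_fit(c(0.2, 0.4), c(0.1, 0.5))
  expect_equal(ev$mse, 0.01)
  ev2 <- evaluate_fit(1:5 / 5, 1:5 / 5)
  expect_equal(ev2$mse, 0)
  expect_equal(ev2$cc, 1)
  ev3 <- evaluate_fit(c(0.1, 0.9, 0.4), rep(0.5, 3))
  expect_equal(ev3$cc, 0)
  expect_true(ev3$cc_flagged)
  expect_error(evaluate_fit(1:3, 1:4), class = "popdecode_invalid_argument")
})

test_that("one-hot designs encode exactly one frame per sample", {
  d <- stimulus_design(c(2, 1, 3, 3), 3)
  expect_true(all(rowSums(d) == 1))
  expect_equal(d[1, ], c(frame1 = 0, frame2 = 1, frame3 = 0))
  expect_error(stimulus_design(c(0, 1), 3), class = "popdecode_invalid_argument")
})

test_that("stage-1 GLM recovers the preferred frame of tuned units", {
  hits <- 0
  for (i in 1:25) {
    us <- region_archetype_units("dLGN", 1, seed = 900 + i, amplitude = 12,
                                 baseline = 2, sigma = 1.5)
    s <- simulate_session(simulation_config(c(dLGN = 1), n_repeats = 20,
                                            seed = 900 + i), us)
    enc <- fit_unit_encoding(s, 1)
    hits <- hits + (enc$best_frame == us[[1]]$preferred_frame)
    expect_true(enc$stage1$converged)
  }
  expect_gte(hits / 25, 0.9)
})

test_that("stage-1 GLM converges on untuned activity and ties break to frame 1", {
  # flat activity: all stimulus coefficients equal, argmax falls to frame 1
  act <- rep(0.5, 60)
  design <- stimulus_design(rep(1:3, 20), 3)
  res <- fit_stimulus_glm(act, design)
  expect_true(res$fit$converged)
  expect_equal(unname(diff(range(res$fit$coefficients))), 0, tolerance = 1e-8)
  expect_equal(res$best_frame, 1)

  # noisy untuned unit: the fit must still converge
  s <- untuned_session(n_units = 1, n_repeats = 20, seed = 88)
  enc <- fit_unit_encoding(s, 1)
  expect_true(enc$stage1$converged)
})

test_that("stage-2 fitted means stay positive and degenerate speed is rejected", {
  s <- archetype_session("dLGN", n_units = 2, seed = 60)
  enc <- fit_unit_encoding(s, 1)
  expect_true(all(enc$stage2$fitted > 0))  # log link keeps predictions positive
  expect_equal(enc$stage2$link, "log")
  expect_error(fit_interaction_glm(runif(30), 1, rep(0.5, 30),
                                   frame_labels = rep(1:3, 10)),
               class = "popdecode_ill_conditioned")
})

test_that("IRLS coefficients match an independent numerical optimizer", {
  # small instances: direct BFGS minimization of the same squared-error
  # objective on the response scale is the oracle
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60
    ind <- rbinom(n, 1, 0.2)
    v <- runif(n)
    x <- cbind(intercept = 1, stimulus = ind, speed = v, interaction = ind * v)
    mu <- exp(-1 + 0.9 * ind + 0.5 * v - 0.4 * ind * v)
    y <- pmax(mu + rnorm(n, 0, 0.04), 1e-3)
    fit <- fit_interaction_glm(y, 1, v, frame_labels = ifelse(ind == 1, 1, 2))
    obj <- function(b) sum((y - exp(drop(x %*% b)))^2)
    opt <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    rel <- abs(fit$coefficients - opt$par) / pmax(abs(opt$par), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("speed coefficients recover the generator's behavioural modulation", {
  # no modulation: speed and interaction coefficients stay near zero
  b_none <- sapply(1:12, function(i) {
    us <- region_archetype_units("dLGN", 1, seed = 1200 + i, amplitude = 12)
    s <- simulate_session(simulation_config(c(dLGN = 1), n_repeats = 20,
                                            seed = 1200 + i), us)
    fit_unit_encoding(s, 1)$stage2$coefficients[c("speed", "interaction")]
  })
  expect_lt(abs(mean(b_none["speed", ])), 0.15)
  expect_lt(abs(mean(b_none["interaction", ])), 0.2)

  # additive modulation: positive speed coefficient
  b_add <- sapply(1:12, function(i) {
    us <- region_archetype_units("dLGN", 1, modulation_mode = "additive",
                                 modulation_strength = 0.3, seed = 1300 + i,
                                 amplitude = 12)
    s <- simulate_session(simulation_config(c(dLGN = 1), n_repeats = 20,
                                            speed_state_fraction = 0.5,
                                            seed = 1300 + i), us)
    fit_unit_encoding(s, 1)$stage2$coefficients[["speed"]]
  })
  expect_gt(mean(b_add), 0.2)
})

test_that("population interaction analysis splits at the median and compares fit quality", {
  fits <- lapply(1:10, function(i) {
    structure(list(coefficients = c(intercept = 0, stimulus = 1, speed = 0,
                                    interaction = i / 10),
                   cc = 0.5 + i / 100, mse = 0.01, converged = TRUE),
              class = "unit_glm")
  })
  res <- population_interaction_analysis(fits)
  expect_equal(sum(res$group == "small"), 5)
  expect_true(all(abs(res$interaction_coefficients[res$group == "small"]) <=
                    abs(res$interaction_coefficients[res$group == "large"])[1]))
  expect_true(is.finite(res$test$p_value))
  expect_error(population_interaction_analysis(fits[1]),
               class = "popdecode_invalid_argument")
})
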