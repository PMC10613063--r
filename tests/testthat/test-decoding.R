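# Binary pairwise and one-vs-all multi-class decoding.

test_that("design matrices have one sample per repeat-frame cell", {
  s <- untuned_session(n_units = 20, n_repeats = 20, seed = 2)
  d <- make_design(s, 1:20, c(1, 6))
  expect_equal(dim(d$x), c(40, 20))
  expect_equal(sort(unique(d$y)), c(1, 6))

  d_all <- make_design(s, 1:20, 1:30)
  expect_equal(nrow(d_all$x), 600)

  # samples carry the right counts: spot-check one cell
  expect_equal(d$x[1, ], as.numeric(s$counts[1:20, 1, 1]))

  expect_error(make_design(s, 1:20, integer(0)), class = "popdecode_invalid_argument")
  expect_error(make_design(s, 1:20, 31), class = "popdecode_invalid_argument")
})

test_that("accuracy equals the confusion-matrix fraction on direct and random cases", {
  expect_equal(compute_accuracy(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(compute_accuracy(c(6, 6, 6), c(1, 6, 6)), 2 / 3)
  expect_equal(compute_accuracy(1:10, 1:10), 1)
  expect_error(compute_accuracy(1:3, 1:4), class = "popdecode_invalid_argument")

  # oracle equivalence: brute-force confusion-matrix count over random labelings
  confusion_accuracy <- function(pred, true) {
    classes <- union(pred, true)
    tab <- table(factor(pred, classes), factor(true, classes))
    sum(diag(tab)) / sum(tab)
  }
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:6, 1); n <- sample(5:50, 1)
    pred <- sample(k, n, replace = TRUE); true <- sample(k, n, replace = TRUE)
    expect_equal(compute_accuracy(pred, true), confusion_accuracy(pred, true))
  }
})

test_that("chance levels follow the stated formulas", {
  expect_equal(chance_level("binary", 2), 0.5)
  expect_equal(chance_level("multiclass", 30), 1 / 900)
  expect_equal(chance_level("multiclass", 2), 0.25)
  expect_equal(chance_level("multiclass", 30, empirical = TRUE), 1 / 30)
  expect_error(chance_level("multiclass", 1), class = "popdecode_invalid_argument")
})

test_that("binary decoding separates tuned frames and sits at chance on the diagonal", {
  sv <- archetype_session("V1", seed = 5)
  # disjoint strongly tuned responses: near-perfect separation
  acc <- train_test_binary(sv, 1:20, 1, 15, n_randomizations = 5, seed = 3)
  expect_gte(acc, 0.99)

  # same-frame diagnostic: random pseudo-labels give chance accuracy
  acc_diag <- mean(sapply(1:8, function(k)
    train_test_binary(sv, 1:20, 4, 4, n_randomizations = 10, seed = k)))
  expect_lt(abs(acc_diag - 0.5), 0.1)

  tiny <- session_recording(array(0L, dim = c(3, 4, 30)), rep("V1", 3),
                            matrix(1, 4, 30))
  expect_error(train_test_binary(tiny, 1:3, 1, 2),
               class = "popdecode_split_infeasible")
})

test_that("pairwise matrices are symmetric with the triangle mean over 435 pairs", {
  s <- archetype_session("dLGN", seed = 8)
  am <- pairwise_accuracy_matrix(s, 1:20, n_randomizations = 2, seed = 4)
  expect_equal(dim(am$values), c(30, 30))
  expect_equal(sum(!is.na(am$values[upper.tri(am$values)])), 435)
  expect_identical(am$values[upper.tri(am$values)], t(am$values)[upper.tri(am$values)])
  expect_true(all(is.na(diag(am$values))))
  expect_equal(am$mean_offdiag, mean(am$values[upper.tri(am$values)]))
  expect_gt(am$mean_offdiag, 0.85)
})

test_that("one-vs-all training yields one oriented classifier per frame", {
  s <- archetype_session("V1", seed = 9)
  model <- train_multiclass(s, 1:20, seed = 2)
  expect_equal(nrow(model$weights), 30)
  expect_equal(length(model$intercepts), 30)

  # 1:29 positive:negative label ratio in every constituent problem
  d <- make_design(s, 1:20, 1:30, model$trained_on$train_repeats)
  for (f in c(1, 17)) {
    expect_equal(sum(d$y == f) / sum(d$y != f), 1 / 29)
  }

  # held-out prediction is far above both chance constants
  test <- make_design(s, 1:20, 1:30, model$trained_on$test_repeats)
  acc <- compute_accuracy(predict_multiclass(model, test$x), test$y)
  expect_gt(acc, 1 / 30 + 0.2)
})

test_that("multiclass prediction takes the argmax score with lowest-index ties", {
  model <- structure(
    list(weights = rbind(c(1, 0), c(0, 1)), intercepts = c(0, 0),
         class_labels = 1:2, trained_on = list()),
    class = "decoder_model")
  # manual dot-product oracle on listed samples
  x <- rbind(c(2, 1), c(0, 3), c(1, 1))
  expect_equal(predict_multiclass(model, x), c(1, 2, 1))  # tie on the third row
  # all-zero scores resolve to the first class
  model0 <- structure(
    list(weights = matrix(0, 3, 2), intercepts = rep(0, 3),
         class_labels = 1:3, trained_on = list()),
    class = "decoder_model")
  expect_equal(predict_multiclass(model0, x), c(1, 1, 1))
  expect_error(predict_multiclass(model, cbind(1, 2, 3)),
               class = "popdecode_invalid_argument")
})

test_that("two-class one-vs-all agrees with plain binary decoding on separable data", {
  cfg <- simulation_config(n_repeats = 10, n_frames = 2, seed = 14)
  units <- c(
    replicate(3, unit_spec(0.5, c(20, 0)), simplify = FALSE),
    replicate(3, unit_spec(0.5, c(0, 20)), simplify = FALSE))
  s <- simulate_session(cfg, units)
  sp <- list(train = 1:8, test = 9:10)
  model <- train_multiclass(s, 1:6, split = sp)
  test <- make_design(s, 1:6, 1:2, sp$test)
  expect_equal(predict_multiclass(model, test$x), test$y)
  expect_equal(train_test_binary(s, 1:6, 1, 2, n_randomizations = 3, seed = 1), 1)
})

test_that("label permutation drives decoding to its empirical chance floor", {
  s <- archetype_session("V1", seed = 33)
  # destroy the count-frame association by cyclically shifting each repeat's
  # bins by a random offset
  set.seed(71)
  perm <- s
  for (r in seq_len(dim(s$counts)[2])) {
    shift <- sample(29, 1)
    perm$counts[, r, ] <- s$counts[, r, ((seq_len(30) - 1 + shift) %% 30) + 1]
  }
  frames <- c(3, 11, 19, 27)
  accs <- apply(combn(frames, 2), 2, function(p)
    train_test_binary(perm, 1:20, p[1], p[2], n_randomizations = 5, seed = 6))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
  mc <- multiclass_accuracy(perm, 1:20, n_randomizations = 3, seed = 7)
  expect_lt(abs(mc$accuracy - 1 / 30), 0.05)
})

test_that("unit-count sweeps rise for tuned regions and stay flat for untuned", {
  sv <- archetype_session("dLGN", n_units = 25, seed = 51)
  sw <- unit_count_sweep(sv, "dLGN", max_units = 20, n_draws = 2, seed = 3,
                         n_pairs = 10, n_randomizations = 2)
  expect_equal(nrow(sw), 20)
  expect_gte(sw$mean_accuracy[20], sw$mean_accuracy[5])

  su <- untuned_session(n_units = 25, seed = 52)
  su$unit_regions[] <- "CA1"
  swu <- unit_count_sweep(su, "CA1", max_units = 1, n_draws = 2, seed = 3,
                          n_pairs = 10, n_randomizations = 2)
  expect_equal(nrow(swu), 1)  # degenerate single-point sweep
  expect_lt(abs(swu$mean_accuracy[1] - 0.5), 0.1)
})
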