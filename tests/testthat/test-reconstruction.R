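# Decoder receptive fields and image similarity.

test_that("class-averaged activity equals the brute-force per-frame mean", {
  s <- untuned_session(n_units = 5, n_repeats = 20, seed = 70)
  A <- class_activity_matrix(s, 1:5, 1:20)
  # direct-loop oracle
  for (u in c(1, 4)) {
    for (f in c(2, 30)) {
      expect_equal(A[u, f], mean(s$counts[u, 1:20, f]))
    }
  }
  # single repeat: the matrix is that repeat's counts
  A1 <- class_activity_matrix(s, 1:5, 3)
  expect_equal(A1, matrix(s$counts[1:5, 3, ], 5, 30))
  # constant counts give a constant matrix
  sc <- session_recording(array(4L, dim = c(2, 6, 5)), rep("V1", 2), matrix(1, 6, 5))
  expect_true(all(class_activity_matrix(sc) == 4))
  expect_error(class_activity_matrix(s, 1:5, integer(0)),
               class = "popdecode_invalid_argument")
})

test_that("dRF equals the manual triple product and honours the identity case", {
  movie <- generate_movie(3, 4, 4, 0.5, seed = 2)
  W <- rbind(c(1, -1), c(0.5, 2), c(-1, 0))   # 3 classes x 2 units
  A <- rbind(c(1, 0, 2), c(3, 1, 0))          # 2 units x 3 frames
  drf <- compute_drf(W, A, movie)
  expect_equal(drf$images, W %*% A %*% movie$frames)

  # brute-force triple loop on random small instances
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:4, 1); u <- sample(2:5, 1)
    m <- generate_movie(k, 4, 4, 0.3, seed = seed)
    W <- matrix(rnorm(k * u), k, u); A <- matrix(rpois(u * k, 3), u, k)
    got <- compute_drf(W, A, m)$images
    want <- matrix(0, k, 16)
    for (i in 1:k) for (p in 1:16) {
      for (f in 1:k) for (q in 1:u) {
        want[i, p] <- want[i, p] + W[i, q] * A[q, f] * m$frames[f, p]
      }
    }
    expect_equal(got, want)
  }

  # ideal one-hot decoder on one-hot activity reproduces the movie exactly
  movie30 <- generate_movie(5, 6, 6, 0.5, seed = 3)
  drf_id <- compute_drf(diag(5), diag(5), movie30)
  expect_equal(drf_id$images, movie30$frames)
  sim <- image_similarity(drf_id, movie30)
  expect_equal(unname(diag(sim$recon_vs_actual)), rep(1, 5))

  # zero weights: all-zero images, flagged-zero similarities
  drf0 <- compute_drf(matrix(0, 5, 5), diag(5), movie30)
  expect_true(all(drf0$images == 0))
  sim0 <- image_similarity(drf0, movie30)
  expect_true(all(sim0$recon_vs_actual[, 1] == 0))
  expect_true(all(sim0$flagged))

  expect_error(compute_drf(matrix(0, 3, 4), A = matrix(0, 2, 3), movie),
               class = "popdecode_dim_error")
  expect_error(compute_drf(matrix(0, 3, 2), A = matrix(0, 2, 5), movie),
               class = "popdecode_dim_error")
})

test_that("similarity is sign-agnostic, scale-invariant and band-structured", {
  movie <- generate_movie(10, 8, 8, 0.8, seed = 4)
  # sign-flipped reconstruction: absolute diagonal still 1
  drf_neg <- compute_drf(-diag(10), diag(10), movie)
  sim <- image_similarity(drf_neg, movie)
  expect_equal(unname(diag(sim$recon_vs_actual)), rep(1, 10))
  expect_equal(unname(diag(sim$recon_vs_actual_signed)), rep(-1, 10))

  # per-class positive rescaling of W rows leaves the diagonal unchanged
  scales <- diag(c(0.1, 1, 5, 0.5, 2, 3, 0.2, 1.5, 4, 0.7))
  sim_sc <- image_similarity(compute_drf(scales, diag(10), movie), movie)
  expect_equal(diag(sim_sc$recon_vs_actual), rep(1, 10), ignore_attr = TRUE)

  # the smooth movie's own similarity matrix is band-diagonal: adjacent
  # frames correlate more than distant ones
  ap <- sim$actual_pairwise
  adj <- mean(ap[cbind(1:9, 2:10)])
  far <- mean(ap[abs(row(ap) - col(ap)) >= 5])
  expect_gt(adj, far + 0.2)
})

test_that("cross-block reconstruction requires two blocks and degrades with behavioural change", {
  movie <- generate_movie(30, 16, 16, 0.8, seed = 42)
  one_block <- session_recording(array(1L, dim = c(3, 6, 30)), rep("V1", 3),
                                 matrix(1, 6, 30), block_of_repeat = rep(1, 6))
  expect_error(cross_block_experiment(one_block, movie),
               class = "popdecode_invalid_argument")

  low <- sapply(1:4, function(i)
    cross_block_experiment(cross_block_session("low", 820 + i), movie)$mean_diag_cc)
  high <- sapply(1:4, function(i)
    cross_block_experiment(cross_block_session("high", 820 + i), movie)$mean_diag_cc)
  expect_gt(mean(low), 0.4)           # matched blocks reconstruct well
  expect_gt(mean(low), mean(high))    # behavioural change lowers similarity

  cmp <- cross_block_group_comparison(
    lapply(821:824, function(i) cross_block_session("low", i)),
    lapply(821:824, function(i) cross_block_session("high", i)), movie)
  expect_equal(cmp$test$test, "paired_t")
  expect_length(cmp$low_cc, 4)
})
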