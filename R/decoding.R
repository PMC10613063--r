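# Linear-SVM decoding of movie frames from population spike counts: binary
# pairwise classification, the pairwise accuracy matrix, and one-vs-all
# multi-class decoding.

#' Build a decoding design from a session
#'
#' One decoding sample is one (repeat, frame) cell: the vector of 1-s spike
#' counts of the selected units in the bin showing that frame. Samples are
#' ordered frame-major (all repeats of the first requested frame, then the
#' next frame, ...).
#'
#' @param session a [session_recording()].
#' @param unit_indices units to use as features.
#' @param frame_subset frame indices (1-based) to include.
#' @param repeat_subset repeats to include (default: all).
#' @return list with `x` (`samples x units` count matrix), `y` (frame label
#'   per sample) and `repeat_of_sample`.
#' @export
make_design <- function(session, unit_indices, frame_subset,
                        repeat_subset = seq_len(dim(session$counts)[2])) {
  stopifnot(inherits(session, "session_recording"))
  d <- dim(session$counts)
  if (length(unit_indices) == 0 || length(frame_subset) == 0 || length(repeat_subset) == 0) {
    pd_stop("popdecode_invalid_argument", "unit, frame and repeat selections must be non-empty")
  }
  if (any(frame_subset < 1) || any(frame_subset > d[3])) {
    pd_stop("popdecode_invalid_argument", sprintf("frame indices must be in 1..%d", d[3]))
  }
  if (any(unit_indices < 1) || any(unit_indices > d[1])) {
    pd_stop("popdecode_invalid_argument", sprintf("unit indices must be in 1..%d", d[1]))
  }
  n_r <- length(repeat_subset); n_f <- length(frame_subset)
  x <- matrix(0, n_r * n_f, length(unit_indices))
  y <- integer(n_r * n_f)
  rep_of <- integer(n_r * n_f)
  row <- 1L
  for (f in frame_subset) {
    block <- session$counts[unit_indices, repeat_subset, f, drop = FALSE]
    x[row:(row + n_r - 1), ] <- t(matrix(block, nrow = length(unit_indices)))
    y[row:(row + n_r - 1)] <- f
    rep_of[row:(row + n_r - 1)] <- repeat_subset
    row <- row + n_r
  }
  list(x = x, y = y, repeat_of_sample = rep_of)
}

#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the true label, i.e.
#' (TP + TN) / (TP + FP + TN + FN) of the confusion matrix, which for any
#' labelling (binary or multi-class) reduces to the matching fraction.
#'
#' @param predicted,true equal-length label vectors.
#' @return accuracy in `[0, 1]`.
#' @examples
#' compute_accuracy(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
compute_accuracy <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 1) {
    pd_stop("popdecode_invalid_argument",
            "`predicted` and `true` must have equal length >= 1")
  }
  mean(predicted == true)
}

#' Chance level of a decoding task
#'
#' Binary classification between a positive and a negative class has a 50%
#' chance level. For the one-vs-all multi-class scheme the reported constant
#' is `(1/n_classes)^2` (each of the `n_classes` classifiers identifies its
#' positive class with probability `1/n_classes`, and the predicted class is
#' drawn from `n_classes` candidates), i.e. 1/900 ~ 0.11% for 30 frames. The
#' empirical null of an uninformed argmax rule instead sits at `1/n_classes`;
#' request it with `empirical = TRUE`. Both values are reported by the
#' summary functions, clearly distinguished.
#'
#' @param task `"binary"` or `"multiclass"`.
#' @param n_classes number of classes (>= 2).
#' @param empirical for multiclass, return the empirical argmax null
#'   `1/n_classes` instead of the reported constant.
#' @return chance accuracy in `[0, 1]`.
#' @examples
#' chance_level("binary", 2)            # 0.5
#' chance_level("multiclass", 30)       # 1/900
#' chance_level("multiclass", 30, TRUE) # 1/30
#' @export
chance_level <- function(task = c("binary", "multiclass"), n_classes = 2,
                         empirical = FALSE) {
  task <- match.arg(task)
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2 ||
      n_classes != floor(n_classes)) {
    pd_stop("popdecode_invalid_argument", "`n_classes` must be a single integer >= 2")
  }
  if (task == "binary") return(0.5)
  if (empirical) 1 / n_classes else (1 / n_classes)^2
}

# Fit a soft-margin linear SVM on raw counts. Counts are used unstandardized
# by default; `scale` forwards to e1071.
fit_linear_svm <- function(x, y, cost = 1, scale = FALSE) {
  e1071::svm(x, factor(y), kernel = "linear", cost = cost, scale = scale)
}

# Resolve train/test repeat indices for one randomization. Control splits are
# uniform-random with floor((1 - train_fraction) * R) test repeats (min 1);
# behavioural conditions delegate to build_condition_split (deterministic
# given the session's speeds).
resolve_split <- function(session, split, seed) {
  n_rep <- dim(session$counts)[2]
  if (n_rep < 5) {
    pd_stop("popdecode_split_infeasible",
            sprintf("session has %d repeats; at least 5 are required for an 80/20 split", n_rep))
  }
  if (split$condition == "control") {
    n_test <- max(1L, floor((1 - split$train_fraction) * n_rep + 1e-9))
    test <- with_seed(seed, sort(sample.int(n_rep, n_test)))
    out <- list(train = setdiff(seq_len(n_rep), test), test = test)
  } else {
    labels <- label_repeats(session$speed, split$threshold)
    out <- build_condition_split(labels, split$condition, split$train_fraction,
                                 rowMeans(session$speed), seed = seed)
  }
  stopifnot(length(intersect(out$train, out$test)) == 0)  # invariant: disjoint split
  out
}

#' Binary pairwise frame decoding
#'
#' Trains a linear-kernel SVM to distinguish two movie frames from the
#' selected units' spike counts, using a repeat-level train/test split (80%
#' of repeats train, the rest test; all bins of a repeat move together), and
#' returns the test accuracy averaged over `n_randomizations` independent
#' splits. With `frame_i == frame_j` a diagnostic null is run instead: the
#' repeats of that single frame are randomly halved into two pseudo-classes,
#' so the expected accuracy is the 50% chance level.
#'
#' @param session a [session_recording()].
#' @param unit_indices feature units.
#' @param frame_i,frame_j the two frame classes.
#' @param split a [split_spec()]; `"control"` gives random splits, the
#'   behavioural conditions give state-matched/mismatched deterministic
#'   splits.
#' @param n_randomizations number of random splits averaged (splits of
#'   non-control conditions are deterministic, so one evaluation is
#'   performed).
#' @param seed RNG seed.
#' @param cost,scale SVM hyperparameters (soft-margin constant; whether to
#'   standardize features).
#' @return mean test accuracy in `[0, 1]`.
#' @export
train_test_binary <- function(session, unit_indices, frame_i, frame_j,
                              split = split_spec("control"), n_randomizations = 10,
                              seed = 1, cost = 1, scale = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  assert_scalar_count(frame_i, "frame_i"); assert_scalar_count(frame_j, "frame_j")
  n_rand <- if (split$condition == "control") n_randomizations else 1L
  seeds <- derive_seeds(seed, max(n_rand, 2L))
  acc <- numeric(n_rand)
  for (k in seq_len(n_rand)) {
    sp <- resolve_split(session, split, seeds[k])
    if (frame_i == frame_j) {
      acc[k] <- diagonal_null_accuracy(session, unit_indices, frame_i, sp,
                                       seeds[k], cost, scale)
    } else {
      train <- make_design(session, unit_indices, c(frame_i, frame_j), sp$train)
      test <- make_design(session, unit_indices, c(frame_i, frame_j), sp$test)
      model <- fit_linear_svm(train$x, train$y, cost = cost, scale = scale)
      pred <- as.integer(as.character(stats::predict(model, test$x)))
      acc[k] <- compute_accuracy(pred, test$y)
    }
  }
  mean(acc, na.rm = TRUE)
}

# Same-frame diagnostic: pseudo-labels assigned by random halving of the
# frame's repeats; a correct decoder has no signal to exploit.
diagonal_null_accuracy <- function(session, unit_indices, frame, sp, seed, cost, scale) {
  n_rep <- dim(session$counts)[2]
  pseudo <- with_seed(seed + 1L, {
    lab <- rep(1L, n_rep)
    lab[sample.int(n_rep, floor(n_rep / 2))] <- 2L
    lab
  })
  train <- make_design(session, unit_indices, frame, sp$train)
  test <- make_design(session, unit_indices, frame, sp$test)
  y_train <- pseudo[train$repeat_of_sample]
  y_test <- pseudo[test$repeat_of_sample]
  if (length(unique(y_train)) < 2) return(NA_real_)
  model <- fit_linear_svm(train$x, y_train, cost = cost, scale = scale)
  pred <- as.integer(as.character(stats::predict(model, test$x)))
  compute_accuracy(pred, y_test)
}

#' Pairwise classification accuracy matrix
#'
#' Runs [train_test_binary()] for every unordered pair of frames and arranges
#' the accuracies as a symmetric `F x F` matrix. The summary accuracy
#' `mean_offdiag` averages one triangle of the matrix so that no pair is
#' counted twice, excluding the diagonal (435 pairs for 30 frames).
#'
#' @param session a [session_recording()].
#' @param unit_indices feature units.
#' @param split a [split_spec()].
#' @param n_randomizations random splits per pair.
#' @param seed RNG seed.
#' @param frame_subset frames to include (default all; the matrix is indexed
#'   by this subset).
#' @param include_diagonal also run the same-frame diagnostic nulls on the
#'   diagonal (default `FALSE`, leaving it `NA`).
#' @param cost,scale SVM hyperparameters.
#' @return an object of class `accuracy_matrix`: list with `values` (F x F),
#'   `frames`, `n_randomizations`, `mean_offdiag` and `chance`.
#' @export
pairwise_accuracy_matrix <- function(session, unit_indices,
                                     split = split_spec("control"),
                                     n_randomizations = 10, seed = 1,
                                     frame_subset = NULL, include_diagonal = FALSE,
                                     cost = 1, scale = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  n_bins <- dim(session$counts)[3]
  frames <- frame_subset %||% seq_len(n_bins)
  nf <- length(frames)
  if (nf < 2) pd_stop("popdecode_invalid_argument", "need at least two frames")
  values <- matrix(NA_real_, nf, nf, dimnames = list(frames, frames))
  seeds <- derive_seeds(seed, nf * nf)
  for (a in seq_len(nf - 1)) {
    for (b in (a + 1):nf) {
      acc <- train_test_binary(session, unit_indices, frames[a], frames[b],
                               split = split, n_randomizations = n_randomizations,
                               seed = seeds[(a - 1) * nf + b], cost = cost, scale = scale)
      values[a, b] <- acc
      values[b, a] <- acc
    }
  }
  if (include_diagonal) {
    for (a in seq_len(nf)) {
      values[a, a] <- train_test_binary(session, unit_indices, frames[a], frames[a],
                                        split = split, n_randomizations = n_randomizations,
                                        seed = seeds[(a - 1) * nf + a],
                                        cost = cost, scale = scale)
    }
  }
  structure(
    list(values = values, frames = frames, n_randomizations = n_randomizations,
         mean_offdiag = mean(values[upper.tri(values)]),
         chance = chance_level("binary")),
    class = "accuracy_matrix")
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  cat(sprintf("<accuracy_matrix> %d frames, %d randomizations; mean off-diagonal accuracy %.3f (chance %.2f)\n",
              length(x$frames), x$n_randomizations, x$mean_offdiag, x$chance))
  invisible(x)
}

#' Train a one-vs-all multi-class frame decoder
#'
#' Fits one binary linear SVM per frame, each trained to separate that frame
#' (positive class) from all other frames pooled (negative class, giving a
#' 1:(F-1) label ratio). The hyperplanes are extracted into an explicit
#' weight matrix `W` (classes x units) and intercept vector, oriented so that
#' the decision score `x . w + b` is larger for the positive class.
#'
#' @param session a [session_recording()].
#' @param unit_indices feature units.
#' @param split a [split_spec()] or an explicit list
#'   `list(train = repeats, test = repeats)`.
#' @param seed RNG seed for the split.
#' @param cost,scale SVM hyperparameters.
#' @return an object of class `decoder_model` with fields `weights`,
#'   `intercepts`, `class_labels` and `trained_on` (train/test repeats, units,
#'   seed).
#' @export
train_multiclass <- function(session, unit_indices, split = split_spec("control"),
                             seed = 1, cost = 1, scale = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  sp <- if (is.list(split) && !inherits(split, "split_spec") &&
            all(c("train", "test") %in% names(split))) {
    split
  } else {
    resolve_split(session, split, seed)
  }
  n_bins <- dim(session$counts)[3]
  design <- make_design(session, unit_indices, seq_len(n_bins), sp$train)
  present <- sort(unique(design$y))
  if (!identical(present, seq_len(n_bins))) {
    pd_stop("popdecode_invalid_training",
            "training repeats do not contain every frame class")
  }
  n_units <- length(unit_indices)
  weights <- matrix(0, n_bins, n_units)
  intercepts <- numeric(n_bins)
  for (f in seq_len(n_bins)) {
    y <- ifelse(design$y == f, "pos", "neg")
    model <- fit_linear_svm(design$x, y, cost = cost, scale = scale)
    w <- crossprod(model$coefs, model$SV)
    b <- -model$rho
    dec <- design$x %*% t(w) + b
    if (mean(dec[y == "pos"]) < mean(dec[y == "neg"])) {  # orient towards positive class
      w <- -w; b <- -b
    }
    weights[f, ] <- w
    intercepts[f] <- b
  }
  structure(
    list(weights = weights, intercepts = intercepts, class_labels = seq_len(n_bins),
         trained_on = list(train_repeats = sp$train, test_repeats = sp$test,
                           unit_indices = unit_indices, seed = seed, cost = cost)),
    class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d one-vs-all classifiers over %d units (trained on %d repeats)\n",
              nrow(x$weights), ncol(x$weights), length(x$trained_on$train_repeats)))
  invisible(x)
}

#' Predict frame labels with a one-vs-all decoder
#'
#' Scores every sample with all classifiers and returns the class of the
#' highest decision score; exact ties are broken towards the lowest class
#' index.
#'
#' @param model a [train_multiclass()] decoder.
#' @param x `samples x units` feature matrix.
#' @return integer vector of predicted frame labels.
#' @export
predict_multiclass <- function(model, x) {
  stopifnot(inherits(model, "decoder_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$weights)) {
    pd_stop("popdecode_invalid_argument",
            sprintf("features have %d columns but the model expects %d",
                    ncol(x), ncol(model$weights)))
  }
  scores <- x %*% t(model$weights) +
    matrix(model$intercepts, nrow(x), length(model$intercepts), byrow = TRUE)
  model$class_labels[apply(scores, 1, which.max)]
}

#' Multi-class decoding accuracy over random splits
#'
#' Convenience wrapper: trains the one-vs-all decoder and evaluates it on the
#' held-out repeats, averaged over `n_randomizations` splits.
#'
#' @inheritParams train_multiclass
#' @param n_randomizations number of random splits.
#' @return list with `accuracy` (mean), `per_split`, `chance_reported`
#'   (the `(1/F)^2` constant) and `chance_empirical` (`1/F`).
#' @export
multiclass_accuracy <- function(session, unit_indices, split = split_spec("control"),
                                n_randomizations = 5, seed = 1, cost = 1, scale = FALSE) {
  n_bins <- dim(session$counts)[3]
  n_rand <- if (split$condition == "control") n_randomizations else 1L
  seeds <- derive_seeds(seed, max(n_rand, 2L))
  acc <- numeric(n_rand)
  for (k in seq_len(n_rand)) {
    sp <- resolve_split(session, split, seeds[k])
    model <- train_multiclass(session, unit_indices, split = sp, seed = seeds[k],
                              cost = cost, scale = scale)
    test <- make_design(session, unit_indices, seq_len(n_bins), sp$test)
    acc[k] <- compute_accuracy(predict_multiclass(model, test$x), test$y)
  }
  list(accuracy = mean(acc), per_split = acc,
       chance_reported = chance_level("multiclass", n_bins),
       chance_empirical = chance_level("multiclass", n_bins, empirical = TRUE))
}

#' Decoding accuracy as a function of unit count
#'
#' Repeatedly draws `1..max_units` units from one region and measures mean
#' pairwise binary accuracy, averaging over draws (and sessions if several
#' are given). Regions ineligible at a given count are skipped and recorded.
#'
#' @param sessions a [session_recording()] or list of them.
#' @param region region label to sample units from.
#' @param max_units largest unit count.
#' @param n_draws random unit draws per count and session.
#' @param seed RNG seed.
#' @param n_pairs number of random frame pairs evaluated per draw (`NULL`
#'   for all pairs).
#' @param split,n_randomizations,cost,scale decoding settings.
#' @return data frame with columns `n_units`, `mean_accuracy`,
#'   `n_evaluations`.
#' @export
unit_count_sweep <- function(sessions, region, max_units = 25, n_draws = 3, seed = 1,
                             n_pairs = NULL, split = split_spec("control"),
                             n_randomizations = 3, cost = 1, scale = FALSE) {
  if (inherits(sessions, "session_recording")) sessions <- list(sessions)
  assert_scalar_count(max_units, "max_units")
  seeds <- derive_seeds(seed, max_units * n_draws * length(sessions) + 1L)
  out <- data.frame(n_units = seq_len(max_units), mean_accuracy = NA_real_,
                    n_evaluations = 0L)
  k <- 0L
  for (n_units in seq_len(max_units)) {
    accs <- c()
    for (s in sessions) {
      for (dr in seq_len(n_draws)) {
        k <- k + 1L
        idx <- tryCatch(select_region_units(s, region, n_units, seed = seeds[k]),
                        popdecode_region_ineligible = function(e) NULL)
        if (is.null(idx)) next
        accs <- c(accs, mean_pairwise_accuracy(s, idx, n_pairs = n_pairs, split = split,
                                               n_randomizations = n_randomizations,
                                               seed = seeds[k], cost = cost, scale = scale))
      }
    }
    if (length(accs)) {
      out$mean_accuracy[n_units] <- mean(accs)
      out$n_evaluations[n_units] <- length(accs)
    }
  }
  out
}

#' Mean pairwise binary accuracy over (a sample of) frame pairs
#'
#' The session-level summary used for region and behaviour comparisons: the
#' average of [train_test_binary()] over frame pairs, either all `F(F-1)/2`
#' of them or a random subsample (for large experiment grids).
#'
#' @inheritParams pairwise_accuracy_matrix
#' @param n_pairs number of random unordered pairs (`NULL` = all pairs).
#' @return mean accuracy in `[0, 1]`.
#' @export
mean_pairwise_accuracy <- function(session, unit_indices, n_pairs = NULL,
                                   split = split_spec("control"),
                                   n_randomizations = 10, seed = 1,
                                   cost = 1, scale = FALSE) {
  n_bins <- dim(session$counts)[3]
  pairs <- utils::combn(n_bins, 2)
  if (!is.null(n_pairs) && n_pairs < ncol(pairs)) {
    keep <- with_seed(seed, sample.int(ncol(pairs), n_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  seeds <- derive_seeds(seed, ncol(pairs) + 1L)
  accs <- vapply(seq_len(ncol(pairs)), function(k) {
    train_test_binary(session, unit_indices, pairs[1, k], pairs[2, k], split = split,
                      n_randomizations = n_randomizations, seed = seeds[k],
                      cost = cost, scale = scale)
  }, numeric(1))
  mean(accs)
}
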