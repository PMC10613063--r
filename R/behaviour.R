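# Behavioural-state labelling and the state-matched / state-mismatched
# train/test split conditions (control, H-H, L-L, H-L, L-H).

SPLIT_CONDITIONS <- c("control", "HH", "LL", "HL", "LH")

#' Specify a train/test split condition
#'
#' @param condition `"control"` (random 80/20 repeat split) or one of the
#'   behavioural conditions `"HH"`, `"LL"`, `"HL"`, `"LH"`, where the first
#'   letter is the training state and the second the test state (H = high
#'   locomotion, L = low).
#' @param train_fraction fraction of repeats used for training.
#' @param threshold locomotion threshold in cm/s separating the states
#'   (default 2, the trough of the bimodal running-speed distribution).
#' @param seed default seed carried with the spec.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(condition = "control", train_fraction = 0.8, threshold = 2.0,
                       seed = 1) {
  condition <- match.arg(condition, SPLIT_CONDITIONS)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    pd_stop("popdecode_invalid_argument", "`train_fraction` must be in (0, 1)")
  }
  structure(list(condition = condition, train_fraction = train_fraction,
                 threshold = threshold, seed = seed),
            class = "split_spec")
}

#' Label repeats by behavioural state
#'
#' A repeat is high-speed (`"H"`) if its average running speed over bins is
#' at or above the threshold, otherwise low-speed (`"L"`).
#'
#' @param speed `repeats x bins` speed matrix (cm/s, no NaN).
#' @param threshold cm/s boundary; means `>= threshold` are `"H"`.
#' @return character vector of `"H"`/`"L"`, one per repeat.
#' @examples
#' label_repeats(rbind(rep(1.99, 5), rep(2.0, 5)))  # "L" "H"
#' @export
label_repeats <- function(speed, threshold = 2.0) {
  if (!is.matrix(speed) || nrow(speed) < 1 || ncol(speed) < 1) {
    pd_stop("popdecode_invalid_argument", "`speed` must be a non-empty repeats x bins matrix")
  }
  if (anyNA(speed) || !all(is.finite(speed))) {
    pd_stop("popdecode_invalid_argument", "`speed` contains invalid values; clean the session first")
  }
  ifelse(rowMeans(speed) >= threshold, "H", "L")
}

#' Build a condition train/test split over repeats
#'
#' For the control condition, a uniform-random split. For a behavioural
#' condition "XY" (train state X, test state Y), the test set is the
#' `ceiling((1 - train_fraction) * R)` repeats with the most extreme mean
#' speeds in the test-state direction (lowest means for test-L, highest for
#' test-H) and the training set is every remaining repeat. The session is
#' eligible only if every test repeat carries the test-state label and every
#' train repeat the train-state label; otherwise a
#' `popdecode_session_ineligible` error names the violated constraint.
#'
#' @param labels per-repeat `"H"`/`"L"` labels from [label_repeats()].
#' @param condition one of `"control"`, `"HH"`, `"LL"`, `"HL"`, `"LH"`.
#' @param train_fraction training fraction.
#' @param speed_means per-repeat mean speeds (needed for the extreme-speed
#'   test selection; ignored for control).
#' @param seed RNG seed (control only).
#' @return list with integer vectors `train` and `test` (disjoint; jointly
#'   exhaustive for non-control conditions).
#' @export
build_condition_split <- function(labels, condition, train_fraction = 0.8,
                                  speed_means = NULL, seed = 1) {
  condition <- match.arg(condition, SPLIT_CONDITIONS)
  n_rep <- length(labels)
  if (n_rep < 5) {
    pd_stop("popdecode_split_infeasible",
            sprintf("%d repeats; at least 5 are required", n_rep))
  }
  if (condition == "control") {
    n_test <- max(1L, floor((1 - train_fraction) * n_rep + 1e-9))
    test <- with_seed(seed, sort(sample.int(n_rep, n_test)))
    return(list(train = setdiff(seq_len(n_rep), test), test = test))
  }
  if (is.null(speed_means) || length(speed_means) != n_rep) {
    pd_stop("popdecode_invalid_argument", "`speed_means` must align with `labels`")
  }
  train_state <- substr(condition, 1, 1)
  test_state <- substr(condition, 2, 2)
  n_test <- ceiling((1 - train_fraction) * n_rep - 1e-9)
  ord <- order(speed_means, decreasing = (test_state == "H"))
  test <- sort(ord[seq_len(n_test)])
  train <- setdiff(seq_len(n_rep), test)
  if (!all(labels[test] == test_state)) {
    pd_stop("popdecode_session_ineligible",
            sprintf("condition %s: the %d most extreme repeats are not all in test state %s",
                    condition, n_test, test_state))
  }
  if (!all(labels[train] == train_state)) {
    pd_stop("popdecode_session_ineligible",
            sprintf("condition %s: remaining repeats are not all in train state %s",
                    condition, train_state))
  }
  list(train = train, test = test)
}

#' Decoding accuracy under behavioural conditions vs control
#'
#' For every session, region and requested condition: selects units, measures
#' mean pairwise binary decoding accuracy under the condition split and under
#' the control split on the same session and unit/pair selection, and reports
#' the difference. Sessions ineligible for a condition (or lacking the
#' region) are skipped and recorded as missing. Per region and condition, the
#' condition and control accuracy distributions across sessions are compared
#' with the Mann-Whitney U test.
#'
#' @param sessions list of [session_recording()].
#' @param regions region labels to analyse.
#' @param conditions subset of `"HH"`, `"LL"`, `"HL"`, `"LH"`.
#' @param n_units units per region (default 20).
#' @param n_pairs random frame pairs per accuracy estimate (`NULL` = all).
#' @param n_randomizations control-split randomizations.
#' @param threshold state threshold in cm/s.
#' @param seed RNG seed.
#' @param cost,scale SVM hyperparameters.
#' @return list with `table` (one row per session x region x condition:
#'   `accuracy`, `control_accuracy`, `delta`), `stats` (per region x
#'   condition Mann-Whitney U vs control) and `skipped`.
#' @export
run_behaviour_experiment <- function(sessions, regions = "V1",
                                     conditions = c("HH", "LL", "HL", "LH"),
                                     n_units = 20, n_pairs = NULL,
                                     n_randomizations = 5, threshold = 2.0,
                                     seed = 1, cost = 1, scale = FALSE) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  conditions <- match.arg(conditions, SPLIT_CONDITIONS[-1], several.ok = TRUE)
  seeds <- derive_seeds(seed, length(sessions) * length(regions) + 1L)
  rows <- list(); skipped <- list()
  k <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    sid <- s$session_id
    for (region in regions) {
      k <- k + 1L
      idx <- tryCatch(select_region_units(s, region, n_units, seed = seeds[k]),
                      popdecode_error = function(e) NULL)
      if (is.null(idx)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          session = sid, region = region, condition = "all",
          reason = "region ineligible")
        next
      }
      control_acc <- mean_pairwise_accuracy(
        s, idx, n_pairs = n_pairs, split = split_spec("control", threshold = threshold),
        n_randomizations = n_randomizations, seed = seeds[k], cost = cost, scale = scale)
      for (cond in conditions) {
        acc <- tryCatch(
          mean_pairwise_accuracy(
            s, idx, n_pairs = n_pairs,
            split = split_spec(cond, threshold = threshold),
            n_randomizations = 1, seed = seeds[k], cost = cost, scale = scale),
          popdecode_session_ineligible = function(e) NA_real_)
        if (is.na(acc)) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            session = sid, region = region, condition = cond,
            reason = "session ineligible for condition")
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          session = sid, region = region, condition = cond,
          accuracy = acc, control_accuracy = control_acc, delta = acc - control_acc)
      }
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(session = character(), region = character(), condition = character(),
               accuracy = numeric(), control_accuracy = numeric(), delta = numeric())
  stats <- behaviour_group_stats(table)
  list(table = table, stats = stats,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

behaviour_group_stats <- function(table) {
  if (nrow(table) == 0) return(NULL)
  combos <- unique(table[, c("region", "condition")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- table$region == combos$region[i] & table$condition == combos$condition[i]
    tst <- compare_groups(list(condition = table$accuracy[sel],
                               control = table$control_accuracy[sel]),
                          test = "mann_whitney_u")
    data.frame(region = combos$region[i], condition = combos$condition[i],
               n_sessions = sum(sel), mean_delta = mean(table$delta[sel]),
               statistic = tst$statistic, p_value = tst$p_value)
  })
  do.call(rbind, out)
}
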