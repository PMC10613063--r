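# Two-stage generalised linear encoding model of single-unit activity:
# stage 1 regresses min-max normalized activity on the one-hot frame
# indicators to find the preferred stimulus; stage 2 regresses it on the
# preferred-frame indicator, normalized running speed and their interaction.
# Family is gaussian with a log link, which keeps every fitted rate strictly
# positive.

GLM_EPS <- 1e-6  # offset applied to exactly-zero normalized activities

#' Min-max normalize a vector to [0, 1]
#'
#' `(x - min) / (max - min)`; order preserving, the minimum maps to 0 and the
#' maximum to 1. A constant vector has no scale and is returned as all zeros
#' with a warning.
#'
#' @param x numeric vector of finite values.
#' @return vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(0, 5, 10))  # 0 0.5 1
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 1 || anyNA(x) || !all(is.finite(x))) {
    pd_stop("popdecode_invalid_argument", "`x` must be non-empty and finite")
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant vector has no min-max scale; returning all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' One-hot stimulus design matrix
#'
#' Binary encoding of the presented frame: each sample's row has a 1 in the
#' column of the frame shown in that bin and 0 elsewhere (rows sum to 1).
#'
#' @param frame_labels integer frame shown per sample.
#' @param n_frames total number of frames `F`.
#' @return `samples x F` 0/1 matrix with columns `frame1..frameF`.
#' @export
stimulus_design <- function(frame_labels, n_frames) {
  assert_scalar_count(n_frames, "n_frames", min = 2)
  if (any(frame_labels < 1) || any(frame_labels > n_frames)) {
    pd_stop("popdecode_invalid_argument", sprintf("frame labels must be in 1..%d", n_frames))
  }
  x <- matrix(0L, length(frame_labels), n_frames,
              dimnames = list(NULL, paste0("frame", seq_len(n_frames))))
  x[cbind(seq_along(frame_labels), frame_labels)] <- 1L
  x
}

#' Per-unit normalized activity trace and aligned covariates
#'
#' Flattens one unit's counts into a single time series (repeat after repeat,
#' bins in order), min-max normalizes it, and returns the aligned frame
#' labels and per-bin speed (speed min-max normalized per session).
#'
#' @param session a [session_recording()].
#' @param unit unit index.
#' @return list with `activity` (normalized, in `[0,1]`), `frame`, `speed`
#'   (normalized) and `raw_speed`.
#' @export
unit_activity <- function(session, unit) {
  stopifnot(inherits(session, "session_recording"))
  d <- dim(session$counts)
  assert_scalar_count(unit, "unit")
  if (unit > d[1]) pd_stop("popdecode_invalid_argument", "unit index out of range")
  counts <- session$counts[unit, , ]              # repeats x bins
  activity <- as.vector(t(counts))                # time order: r1b1..r1bB, r2b1..
  frame <- rep(seq_len(d[3]), d[2])
  raw_speed <- as.vector(t(session$speed))
  list(activity = minmax_normalize(activity), frame = frame,
       speed = minmax_normalize(raw_speed), raw_speed = raw_speed)
}

# Gaussian log-link GLM by IRLS (stats::glm.fit), with a least-squares-on-
# log start for stability. Returns coefficients, fitted means, convergence.
glm_gaussian_log <- function(x, y, start = NULL) {
  y <- ifelse(y == 0, GLM_EPS, y)
  if (is.null(start)) {
    start <- stats::lm.fit(x, log(pmax(y, GLM_EPS)))$coefficients
    start[!is.finite(start)] <- 0
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(x, y, family = stats::gaussian(link = "log"),
                                    start = start,
                                    control = stats::glm.control(maxit = 200))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    # fall back to direct minimization of the same least-squares objective
    obj <- function(beta) sum((y - exp(drop(x %*% beta)))^2)
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    co <- opt$par
    names(co) <- colnames(x)
    return(list(coefficients = co, fitted = exp(drop(x %*% co)),
                converged = opt$convergence == 0))
  }
  list(coefficients = fit$coefficients, fitted = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

#' Stage-1 GLM: find the preferred stimulus
#'
#' Fits the gaussian log-link GLM of normalized activity on the `F` one-hot
#' frame indicators (no separate intercept; the indicators span every
#' sample). The preferred frame is the indicator with the largest
#' coefficient, ties broken towards the lowest frame index. Exactly-zero
#' activities are offset by 1e-6 so every fitted mean stays positive.
#'
#' @param activity normalized activity vector (from [unit_activity()]).
#' @param design one-hot `samples x F` matrix (from [stimulus_design()]).
#' @return list with `fit` (a `unit_glm`: coefficients, mse, cc, converged)
#'   and `best_frame`.
#' @export
fit_stimulus_glm <- function(activity, design) {
  if (length(activity) != nrow(design)) {
    pd_stop("popdecode_invalid_argument", "`activity` and `design` are not aligned")
  }
  if (!all(rowSums(design) == 1)) {
    pd_stop("popdecode_invalid_argument", "each design row must one-hot encode exactly one frame")
  }
  # group means are the natural start: the model is saturated per frame
  y <- ifelse(activity == 0, GLM_EPS, activity)
  mstart <- log(pmax(tapply(y, max.col(design), mean), GLM_EPS))
  start <- rep(log(mean(y)), ncol(design))
  start[as.integer(names(mstart))] <- mstart
  res <- glm_gaussian_log(design, activity, start = start)
  ev <- evaluate_fit(activity, res$fitted)
  best_frame <- which.max(res$coefficients)
  fit <- structure(
    list(coefficients = stats::setNames(res$coefficients, colnames(design)),
         family = "gaussian", link = "log", mse = ev$mse, cc = ev$cc,
         cc_flagged = ev$cc_flagged, converged = res$converged,
         fitted = res$fitted, stage = "stimulus"),
    class = "unit_glm")
  list(fit = fit, best_frame = unname(best_frame))
}

#' Stage-2 GLM: preferred stimulus, speed and their interaction
#'
#' Fits normalized activity on an intercept, the preferred-frame indicator,
#' the normalized running speed, and their elementwise product. A nonzero
#' interaction coefficient means the effect of the preferred stimulus on the
#' (log-scale) predicted rate changes with locomotion.
#'
#' @param activity normalized activity vector.
#' @param best_frame preferred frame from [fit_stimulus_glm()].
#' @param speed normalized per-bin speed aligned with `activity`.
#' @param design one-hot stimulus matrix (used to derive the preferred-frame
#'   indicator), or `NULL` to pass `frame_labels`.
#' @param frame_labels integer frame per sample (alternative to `design`).
#' @return a `unit_glm` with coefficients `(intercept, stimulus, speed,
#'   interaction)`, fit metrics and convergence flag.
#' @export
fit_interaction_glm <- function(activity, best_frame, speed, design = NULL,
                                frame_labels = NULL) {
  if (is.null(frame_labels)) {
    if (is.null(design)) {
      pd_stop("popdecode_invalid_argument", "supply `design` or `frame_labels`")
    }
    frame_labels <- max.col(design)
  }
  if (length(activity) != length(speed) || length(activity) != length(frame_labels)) {
    pd_stop("popdecode_invalid_argument", "activity, speed and frames are not aligned")
  }
  if (stats::var(speed) == 0) {
    pd_stop("popdecode_ill_conditioned",
            "running speed has zero variance; the speed and interaction terms are not identifiable")
  }
  ind <- as.numeric(frame_labels == best_frame)
  x <- cbind(intercept = 1, stimulus = ind, speed = speed, interaction = ind * speed)
  res <- glm_gaussian_log(x, activity)
  ev <- evaluate_fit(activity, res$fitted)
  structure(
    list(coefficients = res$coefficients, family = "gaussian", link = "log",
         mse = ev$mse, cc = ev$cc, cc_flagged = ev$cc_flagged,
         converged = res$converged, fitted = res$fitted, stage = "interaction",
         best_frame = best_frame),
    class = "unit_glm")
}

#' @export
print.unit_glm <- function(x, ...) {
  cat(sprintf("<unit_glm> %s stage (gaussian, log link): mse %.4g, cc %.3f%s\n",
              x$stage, x$mse, x$cc, if (x$converged) "" else " [not converged]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Goodness of fit: MSE and correlation coefficient
#'
#' Mean squared error `mean((actual - predicted)^2)` and the Pearson
#' correlation between the actual and fitted traces. If either trace has
#' zero variance the correlation is undefined and returned as 0 with
#' `cc_flagged = TRUE`.
#'
#' @param actual,predicted equal-length numeric vectors (length >= 2).
#' @return list with `mse`, `cc`, `cc_flagged`.
#' @examples
#' evaluate_fit(c(0.2, 0.4), c(0.1, 0.5))  # mse 0.01
#' @export
evaluate_fit <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2) {
    pd_stop("popdecode_invalid_argument", "`actual` and `predicted` must have equal length >= 2")
  }
  mse <- mean((actual - predicted)^2)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    return(list(mse = mse, cc = 0, cc_flagged = TRUE))
  }
  list(mse = mse, cc = stats::cor(actual, predicted), cc_flagged = FALSE)
}

#' Run the two-stage encoding model for one unit
#'
#' @param session a [session_recording()].
#' @param unit unit index.
#' @return list with `stage1` (`unit_glm`), `best_frame`, `stage2`
#'   (`unit_glm`).
#' @export
fit_unit_encoding <- function(session, unit) {
  ua <- unit_activity(session, unit)
  design <- stimulus_design(ua$frame, max(ua$frame))
  s1 <- fit_stimulus_glm(ua$activity, design)
  s2 <- fit_interaction_glm(ua$activity, s1$best_frame, ua$speed,
                            frame_labels = ua$frame)
  list(stage1 = s1$fit, best_frame = s1$best_frame, stage2 = s2)
}

#' Encode a population of units
#'
#' Runs [fit_unit_encoding()] for each requested unit and tabulates the
#' stage-2 coefficients and fit metrics.
#'
#' @param session a [session_recording()].
#' @param unit_indices units to fit (default all).
#' @return list with `fits` (per-unit stage-2 `unit_glm`s), `best_frames`
#'   and `table` (one row per unit: best_frame, coefficients, mse, cc,
#'   converged).
#' @export
encode_population <- function(session, unit_indices = seq_len(dim(session$counts)[1])) {
  fits <- vector("list", length(unit_indices))
  rows <- vector("list", length(unit_indices))
  best <- integer(length(unit_indices))
  for (i in seq_along(unit_indices)) {
    enc <- fit_unit_encoding(session, unit_indices[i])
    fits[[i]] <- enc$stage2
    best[i] <- enc$best_frame
    co <- enc$stage2$coefficients
    rows[[i]] <- data.frame(unit = unit_indices[i], best_frame = enc$best_frame,
                            intercept = co[["intercept"]], stimulus = co[["stimulus"]],
                            speed = co[["speed"]], interaction = co[["interaction"]],
                            mse = enc$stage2$mse, cc = enc$stage2$cc,
                            converged = enc$stage2$converged)
  }
  list(fits = fits, best_frames = best, table = do.call(rbind, rows))
}

#' Population analysis of interaction coefficients
#'
#' Summarizes the distribution of stage-2 interaction coefficients across
#' units and compares the fit quality (CC between actual and fitted traces)
#' of units with small vs large absolute interaction coefficients, split at
#' the median, using the Mann-Whitney U test.
#'
#' @param fits list of stage-2 `unit_glm` objects (length >= 2).
#' @return list with `interaction_coefficients`, `group` (small/large per
#'   unit), `cc_small`, `cc_large`, and `test` (statistic + p-value).
#' @export
population_interaction_analysis <- function(fits) {
  if (!is.list(fits) || length(fits) < 2) {
    pd_stop("popdecode_invalid_argument", "need at least two fits")
  }
  beta <- vapply(fits, function(f) f$coefficients[["interaction"]], numeric(1))
  cc <- vapply(fits, function(f) f$cc, numeric(1))
  med <- stats::median(abs(beta))
  group <- ifelse(abs(beta) <= med, "small", "large")
  tst <- compare_groups(list(small = cc[group == "small"], large = cc[group == "large"]),
                        test = "mann_whitney_u")
  list(interaction_coefficients = beta, group = group,
       cc_small = cc[group == "small"], cc_large = cc[group == "large"],
       test = tst)
}
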