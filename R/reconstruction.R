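# Decoder receptive fields: dRF = W . A . M, where W are the one-vs-all
# decoder weights (classes x units), A is the class-averaged activity matrix
# (units x frames) and M the movie pixel matrix (frames x pixels).

#' Class-averaged activity matrix
#'
#' Entry `(u, f)` is unit `u`'s mean spike count in the bins showing frame
#' `f`, averaged over the chosen repeats.
#'
#' @param session a [session_recording()].
#' @param unit_indices units (rows of `A`); default all.
#' @param repeat_subset repeats averaged over (non-empty).
#' @return `units x frames` matrix.
#' @export
class_activity_matrix <- function(session, unit_indices = seq_len(dim(session$counts)[1]),
                                  repeat_subset = seq_len(dim(session$counts)[2])) {
  stopifnot(inherits(session, "session_recording"))
  if (length(repeat_subset) == 0 || length(unit_indices) == 0) {
    pd_stop("popdecode_invalid_argument", "unit and repeat selections must be non-empty")
  }
  sub <- session$counts[unit_indices, repeat_subset, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Reconstruct decoder receptive fields
#'
#' The triple product `W . A . M` projects the class-averaged neural
#' activity through the decoder weights onto the movie pixels, giving one
#' reconstructed image per class: what the linear decoder "sees" when it
#' identifies that frame.
#'
#' @param model a [train_multiclass()] `decoder_model` (supplies `W`).
#' @param A `units x frames` class-averaged activity from
#'   [class_activity_matrix()].
#' @param movie a [movie_stimulus()] (supplies `M`, frames x pixels).
#' @param center_units subtract each unit's mean class-response from its row
#'   of `A` before projecting (default `FALSE`, the plain triple product).
#'   Centering removes the arbitrary common score offset each one-vs-all
#'   classifier assigns to every class, which otherwise injects a large
#'   multiple of the global mean frame into every reconstruction.
#' @return an object of class `decoder_rf`: list with `images`
#'   (`classes x pixels`), `weights`, `activity`, `height`, `width`,
#'   `class_labels`.
#' @export
compute_drf <- function(model, A, movie, center_units = FALSE) {
  W <- if (inherits(model, "decoder_model")) model$weights else as.matrix(model)
  if (!is.matrix(A)) pd_stop("popdecode_invalid_argument", "`A` must be a units x frames matrix")
  if (center_units) A <- A - rowMeans(A)
  stopifnot(inherits(movie, "movie_stimulus"))
  M <- movie$frames
  if (ncol(W) != nrow(A)) {
    pd_stop("popdecode_dim_error",
            sprintf("weights x activity: W has %d units but A has %d", ncol(W), nrow(A)))
  }
  if (ncol(A) != nrow(M)) {
    pd_stop("popdecode_dim_error",
            sprintf("activity x movie: A has %d frames but M has %d", ncol(A), nrow(M)))
  }
  images <- W %*% A %*% M
  structure(
    list(images = images, weights = W, activity = A,
         height = movie$height, width = movie$width,
         class_labels = seq_len(nrow(W))),
    class = "decoder_rf")
}

#' @export
print.decoder_rf <- function(x, ...) {
  cat(sprintf("<decoder_rf> %d reconstructed class images of %d x %d px\n",
              nrow(x$images), x$height, x$width))
  invisible(x)
}

# Pairwise Pearson correlation over pixels between the rows of two image
# stacks; zero-variance images yield flagged-0 entries.
image_cor <- function(a, b) {
  suppressWarnings(out <- stats::cor(t(a), t(b)))
  flagged <- !is.finite(out)
  out[flagged] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Similarity matrices between reconstructed and actual images
#'
#' Computes pixelwise Pearson correlations: reconstruction vs actual frame
#' for every pair (absolute values, since a linear decoder is agnostic to
#' the sign of its reconstruction; the raw signed matrix is retained for
#' diagnostics), plus the pairwise similarity among reconstructions and
#' among actual frames. Zero-variance images give flagged-0 entries.
#'
#' @param recon a [compute_drf()] `decoder_rf`.
#' @param movie the [movie_stimulus()] to compare against.
#' @return list with `recon_vs_actual` (absolute), `recon_vs_actual_signed`,
#'   `recon_pairwise`, `actual_pairwise`, `mean_diag_cc` (mean absolute
#'   diagonal correlation) and `flagged`.
#' @export
image_similarity <- function(recon, movie) {
  stopifnot(inherits(recon, "decoder_rf"), inherits(movie, "movie_stimulus"))
  if (ncol(recon$images) != ncol(movie$frames)) {
    pd_stop("popdecode_dim_error",
            sprintf("reconstruction has %d pixels but movie has %d",
                    ncol(recon$images), ncol(movie$frames)))
  }
  signed <- image_cor(recon$images, movie$frames)
  list(recon_vs_actual = abs(signed),
       recon_vs_actual_signed = signed,
       recon_pairwise = image_cor(recon$images, recon$images),
       actual_pairwise = image_cor(movie$frames, movie$frames),
       mean_diag_cc = mean(abs(diag(signed))),
       flagged = attr(signed, "flagged"))
}

#' Cross-block reconstruction experiment
#'
#' Trains the one-vs-all decoder on the first presentation block (50% of the
#' repeats), builds the class-averaged activity matrix from the second block,
#' reconstructs the decoder receptive fields and measures their similarity
#' to the actual movie frames. Sessions whose blocks differ in behavioural
#' state probe reconstruction under high behavioural change.
#'
#' @param session a two-block [session_recording()].
#' @param movie the [movie_stimulus()] shown in the session.
#' @param unit_indices units used (default all).
#' @param seed RNG seed (decoder training is deterministic given the block
#'   split; kept for interface symmetry).
#' @param center_units remove each unit's mean class-response before the
#'   projection (default `TRUE`; see [compute_drf()]). The one-vs-all score
#'   offsets carry no class information, so the centred projection isolates
#'   the decoder's discriminative structure.
#' @param cost,scale SVM hyperparameters.
#' @return list with `model`, `drf`, `similarity` and `mean_diag_cc` (mean
#'   absolute correlation between each reconstruction and its actual frame).
#' @export
cross_block_experiment <- function(session, movie,
                                   unit_indices = seq_len(dim(session$counts)[1]),
                                   seed = 1, center_units = TRUE, cost = 1, scale = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  blocks <- session$block_of_repeat
  if (length(unique(blocks)) < 2) {
    pd_stop("popdecode_invalid_argument", "session must contain two presentation blocks")
  }
  sp <- list(train = which(blocks == 1), test = which(blocks == 2))
  model <- train_multiclass(session, unit_indices, split = sp, seed = seed,
                            cost = cost, scale = scale)
  A <- class_activity_matrix(session, unit_indices, repeat_subset = sp$test)
  drf <- compute_drf(model, A, movie, center_units = center_units)
  sim <- image_similarity(drf, movie)
  list(model = model, drf = drf, similarity = sim, mean_diag_cc = sim$mean_diag_cc)
}

#' Compare reconstruction quality across behavioural-change groups
#'
#' Runs [cross_block_experiment()] on matched (low behavioural change) and
#' mismatched (high change) sessions and compares the per-session mean
#' diagonal reconstruction correlations with a paired t-test (sessions are
#' paired by position in the two lists).
#'
#' @param low_sessions,high_sessions equal-length lists of two-block
#'   sessions.
#' @param movie the shared [movie_stimulus()].
#' @param ... forwarded to [cross_block_experiment()].
#' @return list with `low_cc`, `high_cc` (per-session mean diagonal
#'   correlations) and `test` (paired t statistic + p-value).
#' @export
cross_block_group_comparison <- function(low_sessions, high_sessions, movie, ...) {
  stopifnot(length(low_sessions) == length(high_sessions), length(low_sessions) >= 2)
  low_cc <- vapply(low_sessions, function(s)
    cross_block_experiment(s, movie, ...)$mean_diag_cc, numeric(1))
  high_cc <- vapply(high_sessions, function(s)
    cross_block_experiment(s, movie, ...)$mean_diag_cc, numeric(1))
  list(low_cc = low_cc, high_cc = high_cc,
       test = compare_groups(list(low = low_cc, high = high_cc), test = "paired_t"))
}
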