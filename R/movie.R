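# Movie stimulus container and the synthetic movie generator.

#' Construct a movie stimulus
#'
#' A movie stimulus is the stack of per-bin snapshot images against which
#' decoding labels are defined: one image per 1-s analysis bin. Frames are
#' stored flattened as an `F x (H*W)` matrix (the pixel matrix `M` used in
#' decoder receptive-field reconstruction), with intensities in `[0, 1]`.
#'
#' @param frames numeric `F x (H*W)` matrix of pixel intensities in `[0, 1]`,
#'   or an `F x H x W` array (flattened internally).
#' @param height,width image dimensions in pixels.
#' @param fps native frame rate of the source movie (frames per second).
#' @param bin_seconds duration of one analysis bin in seconds.
#' @return an object of class `movie_stimulus`.
#' @export
movie_stimulus <- function(frames, height, width, fps = 30, bin_seconds = 1.0) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    height <- d[2]; width <- d[3]
    frames <- matrix(frames, nrow = d[1])
  }
  if (!is.matrix(frames) || !is.numeric(frames)) {
    pd_stop("popdecode_invalid_argument", "`frames` must be a numeric matrix or 3-d array")
  }
  assert_scalar_count(height, "height"); assert_scalar_count(width, "width")
  if (ncol(frames) != height * width) {
    pd_stop("popdecode_invalid_argument",
            sprintf("frames have %d pixels but height*width = %d", ncol(frames), height * width))
  }
  if (anyNA(frames) || !all(is.finite(frames)) || any(frames < 0) || any(frames > 1)) {
    pd_stop("popdecode_invalid_argument", "pixel intensities must be finite and in [0, 1]")
  }
  structure(
    list(frames = frames, height = as.integer(height), width = as.integer(width),
         fps = fps, bin_seconds = bin_seconds),
    class = "movie_stimulus")
}

#' Number of frames in a movie stimulus
#' @param movie a `movie_stimulus`.
#' @return integer frame count `F`.
#' @export
n_frames <- function(movie) nrow(movie$frames)

#' @export
print.movie_stimulus <- function(x, ...) {
  cat(sprintf("<movie_stimulus> %d frames of %d x %d px (%g fps, %g s bins)\n",
              n_frames(x), x$height, x$width, x$fps, x$bin_seconds))
  invisible(x)
}

#' Generate a synthetic natural-movie surrogate
#'
#' Produces a stack of temporally correlated noise images standing in for the
#' per-second snapshots of a natural movie. Frames follow a first-order
#' autoregressive process over the frame index (coefficient `smoothness`), and
#' each frame is lightly spatially smoothed, so adjacent frames are more
#' similar than distant ones -- the property that gives real natural-movie
#' similarity matrices their band-diagonal structure.
#'
#' @param n_frames number of frames (>= 2).
#' @param height,width image size in pixels (>= 4).
#' @param smoothness temporal AR(1) coefficient in `[0, 1)`; 0 gives
#'   independent frames.
#' @param seed integer RNG seed.
#' @return a [movie_stimulus()] with intensities min-max scaled to `[0, 1]`.
#' @examples
#' m <- generate_movie(30, 16, 16, smoothness = 0.8, seed = 7)
#' range(m$frames)
#' @export
generate_movie <- function(n_frames, height, width, smoothness = 0.8, seed = 1) {
  assert_scalar_count(n_frames, "n_frames", min = 2)
  assert_scalar_count(height, "height", min = 4)
  assert_scalar_count(width, "width", min = 4)
  if (!is.numeric(smoothness) || length(smoothness) != 1L ||
      smoothness < 0 || smoothness >= 1) {
    pd_stop("popdecode_invalid_argument", "`smoothness` must be in [0, 1)")
  }
  with_seed(seed, {
    p <- height * width
    frames <- matrix(0, n_frames, p)
    innov_sd <- sqrt(1 - smoothness^2)
    frames[1, ] <- stats::rnorm(p)
    if (n_frames > 1) {
      for (f in 2:n_frames) {
        frames[f, ] <- smoothness * frames[f - 1, ] + innov_sd * stats::rnorm(p)
      }
    }
    # mild 3x3 box blur per frame for spatial structure
    for (f in seq_len(n_frames)) {
      img <- matrix(frames[f, ], height, width)
      frames[f, ] <- as.vector(box_blur3(img))
    }
    rng <- range(frames)
    frames <- (frames - rng[1]) / (rng[2] - rng[1])
    movie_stimulus(frames, height, width)
  })
}

# 3x3 box blur with edge replication; small and dependency-free
box_blur3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1, 1:(h - 1)), , drop = FALSE]
  down <- img[c(2:h, h), , drop = FALSE]
  vert <- img + up + down
  left <- vert[, c(1, 1:(w - 1)), drop = FALSE]
  right <- vert[, c(2:w, w), drop = FALSE]
  (vert + left + right) / 9
}
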