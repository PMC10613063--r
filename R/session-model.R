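# Shared session data model: binned spike counts, region labels, running
# speed, presentation blocks.

#' Construct a session recording
#'
#' The common container for all analysis stages: spike counts of `U` units
#' over `R` movie repeats in `B` one-second bins (bin `b` of every repeat
#' shows movie frame `b`), per-unit brain-region labels, the per-bin running
#' speed, and the presentation block of each repeat.
#'
#' @param counts `units x repeats x bins` array of nonnegative integer spike
#'   counts (NA allowed before cleaning).
#' @param unit_regions character vector of region labels, one per unit.
#' @param speed `repeats x bins` running speed in cm/s (NaN/NA allowed before
#'   cleaning).
#' @param block_of_repeat integer vector (1 or 2), one per repeat; defaults to
#'   first half = block 1.
#' @param session_id opaque identifier.
#' @param ground_truth optional list of generator ground truth (synthetic
#'   sessions only).
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(counts, unit_regions, speed, block_of_repeat = NULL,
                              session_id = "session", ground_truth = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    pd_stop("popdecode_invalid_argument", "`counts` must be a units x repeats x bins array")
  }
  d <- dim(counts)
  if (length(unit_regions) != d[1]) {
    pd_stop("popdecode_format_error",
            sprintf("unit_regions has length %d but counts has %d units",
                    length(unit_regions), d[1]))
  }
  if (!is.matrix(speed) || nrow(speed) != d[2] || ncol(speed) != d[3]) {
    pd_stop("popdecode_format_error",
            sprintf("speed must be a %d x %d matrix matching counts repeats x bins", d[2], d[3]))
  }
  finite_counts <- counts[!is.na(counts)]
  if (any(finite_counts < 0) || any(finite_counts != floor(finite_counts))) {
    pd_stop("popdecode_invalid_argument", "`counts` must be nonnegative integers")
  }
  block_of_repeat <- block_of_repeat %||%
    rep(1:2, c(ceiling(d[2] / 2), d[2] - ceiling(d[2] / 2)))
  if (length(block_of_repeat) != d[2] || !all(block_of_repeat %in% 1:2)) {
    pd_stop("popdecode_format_error", "block_of_repeat must assign every repeat to block 1 or 2")
  }
  structure(
    list(counts = counts, unit_regions = as.character(unit_regions), speed = speed,
         block_of_repeat = as.integer(block_of_repeat),
         session_id = as.character(session_id), ground_truth = ground_truth),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<session_recording> '%s': %d units, %d repeats, %d bins\n",
              x$session_id, d[1], d[2], d[3]))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$unit_regions)),
                                  table(x$unit_regions)), collapse = ", "), "\n")
  invisible(x)
}

#' Remove repeats containing invalid intervals
#'
#' Invalid intervals are recorded as NaN/NA in the speed trace or the count
#' tensor. Any repeat containing at least one invalid bin is dropped whole
#' (decoding samples are repeat-by-bin cells and splitting is at the repeat
#' level, so partial repeats would unbalance classes). Idempotent.
#'
#' @param session a [session_recording()].
#' @param verbose emit a message with the number of dropped repeats.
#' @return the cleaned session; the count of dropped repeats is attached as
#'   attribute `n_dropped_repeats`.
#' @export
clean_invalid_intervals <- function(session, verbose = FALSE) {
  stopifnot(inherits(session, "session_recording"))
  bad_speed <- apply(session$speed, 1, function(r) any(!is.finite(r)))
  bad_counts <- apply(session$counts, 2, function(m) any(!is.finite(m)))
  keep <- !(bad_speed | bad_counts)
  if (!any(keep)) {
    pd_stop("popdecode_empty_session", "all repeats contain invalid (NaN) intervals")
  }
  n_dropped <- sum(!keep)
  out <- session_recording(
    counts = session$counts[, keep, , drop = FALSE],
    unit_regions = session$unit_regions,
    speed = session$speed[keep, , drop = FALSE],
    block_of_repeat = session$block_of_repeat[keep],
    session_id = session$session_id,
    ground_truth = session$ground_truth)
  if (verbose && n_dropped > 0) {
    message(sprintf("dropped %d repeat(s) with invalid intervals", n_dropped))
  }
  attr(out, "n_dropped_repeats") <- n_dropped
  out
}

#' Randomly select units from one region
#'
#' Uniform sampling without replacement among the units carrying the region
#' label. Regions with fewer than `n_units` units are ineligible and raise a
#' `popdecode_region_ineligible` error (region comparisons use a fixed unit
#' count so that decoder capacity is matched across regions).
#'
#' @param session a [session_recording()].
#' @param region region label to sample from.
#' @param n_units number of units to draw (default 20, the count at which
#'   decoding accuracy plateaus).
#' @param seed RNG seed.
#' @return integer vector of `n_units` distinct unit indices.
#' @export
select_region_units <- function(session, region, n_units = 20, seed = 1) {
  stopifnot(inherits(session, "session_recording"))
  assert_scalar_count(n_units, "n_units")
  pool <- which(session$unit_regions == region)
  if (length(pool) == 0) {
    pd_stop("popdecode_invalid_argument",
            sprintf("region '%s' not present in session '%s'", region, session$session_id))
  }
  if (length(pool) < n_units) {
    pd_stop("popdecode_region_ineligible",
            sprintf("region '%s' has %d units, fewer than the %d required",
                    region, length(pool), n_units))
  }
  with_seed(seed, sort(pool[sample.int(length(pool), n_units)]))
}
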