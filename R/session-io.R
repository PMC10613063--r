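# On-disk session container: a directory of plain-text members listed by a
# JSON manifest. Counts and speed are long-format CSV (speed printed at full
# double precision so that read(write(s)) is bit-exact).

MANIFEST_NAME <- "manifest.json"

#' Write a session to a directory container
#'
#' Members: `manifest.json` (dimensions + member list), `counts.csv`
#' (unit, repeat, bin, count), `units.csv` (unit, region), `repeats.csv`
#' (repeat, block), `speed.csv` (repeat, bin, speed at 17 significant
#' digits) and, for synthetic sessions, `ground_truth.json`.
#'
#' @param session a [session_recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(session$counts)
  members <- c("counts.csv", "units.csv", "repeats.csv", "speed.csv")

  idx <- expand.grid(unit = seq_len(d[1]), repeat_ = seq_len(d[2]), bin = seq_len(d[3]))
  counts_df <- data.frame(unit = idx$unit, repeat_ = idx$repeat_, bin = idx$bin,
                          count = as.vector(session$counts))
  utils::write.csv(counts_df, file.path(path, "counts.csv"), row.names = FALSE)

  utils::write.csv(data.frame(unit = seq_len(d[1]), region = session$unit_regions),
                   file.path(path, "units.csv"), row.names = FALSE)
  utils::write.csv(data.frame(repeat_ = seq_len(d[2]), block = session$block_of_repeat),
                   file.path(path, "repeats.csv"), row.names = FALSE)

  sp <- expand.grid(repeat_ = seq_len(d[2]), bin = seq_len(d[3]))
  speed_lines <- c("repeat_,bin,speed",
                   sprintf("%d,%d,%.17g", sp$repeat_, sp$bin, as.vector(session$speed)))
  writeLines(speed_lines, file.path(path, "speed.csv"))

  if (!is.null(session$ground_truth)) {
    members <- c(members, "ground_truth.json")
    gt <- session$ground_truth
    gt$rates <- NULL  # regenerable from units + speed via session_rates()
    jsonlite::write_json(serialize_ground_truth(gt),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- list(format = "popdecode-session", version = 1L,
                   session_id = session$session_id,
                   n_units = d[1], n_repeats = d[2], n_bins = d[3],
                   members = members)
  jsonlite::write_json(manifest, file.path(path, MANIFEST_NAME),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

serialize_ground_truth <- function(gt) {
  if (!is.null(gt$units)) {
    gt$units <- lapply(gt$units, function(u) unclass(u))
  }
  if (!is.null(gt$config)) gt$config <- unclass(gt$config)
  gt
}

#' Read a session from a directory container
#'
#' Validates the manifest and every member; missing or inconsistent members
#' raise a `popdecode_format_error` naming the offending member. Counts,
#' labels and speed round-trip bit-exactly through [write_session()].
#'
#' @param path directory written by [write_session()].
#' @return a [session_recording()].
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, MANIFEST_NAME)
  if (!file.exists(mf_path)) {
    pd_stop("popdecode_format_error", sprintf("missing member '%s' in %s", MANIFEST_NAME, path))
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (m in c("counts.csv", "units.csv", "repeats.csv", "speed.csv")) {
    if (!m %in% mf$members || !file.exists(file.path(path, m))) {
      pd_stop("popdecode_format_error", sprintf("missing member '%s' in %s", m, path))
    }
  }
  d <- c(mf$n_units, mf$n_repeats, mf$n_bins)

  counts_df <- utils::read.csv(file.path(path, "counts.csv"))
  if (nrow(counts_df) != prod(d)) {
    pd_stop("popdecode_format_error",
            sprintf("member 'counts.csv' has %d rows, expected %d", nrow(counts_df), prod(d)))
  }
  counts <- array(NA_integer_, dim = d)
  counts[cbind(counts_df$unit, counts_df$repeat_, counts_df$bin)] <- counts_df$count

  units_df <- utils::read.csv(file.path(path, "units.csv"))
  if (nrow(units_df) != d[1]) {
    pd_stop("popdecode_format_error",
            sprintf("member 'units.csv' has %d rows but manifest declares %d units",
                    nrow(units_df), d[1]))
  }
  repeats_df <- utils::read.csv(file.path(path, "repeats.csv"))
  if (nrow(repeats_df) != d[2]) {
    pd_stop("popdecode_format_error",
            sprintf("member 'repeats.csv' has %d rows but manifest declares %d repeats",
                    nrow(repeats_df), d[2]))
  }
  speed_df <- utils::read.csv(file.path(path, "speed.csv"),
                              colClasses = c("integer", "integer", "numeric"))
  if (nrow(speed_df) != d[2] * d[3]) {
    pd_stop("popdecode_format_error",
            sprintf("member 'speed.csv' has %d rows, expected %d", nrow(speed_df), d[2] * d[3]))
  }
  speed <- matrix(NA_real_, d[2], d[3])
  speed[cbind(speed_df$repeat_, speed_df$bin)] <- speed_df$speed

  gt <- NULL
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  session_recording(counts = counts,
                    unit_regions = units_df$region[order(units_df$unit)],
                    speed = speed,
                    block_of_repeat = repeats_df$block[order(repeats_df$repeat_)],
                    session_id = mf$session_id,
                    ground_truth = gt)
}
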