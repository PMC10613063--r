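# Experiment orchestration and the group-comparison statistics used in the
# reports (delegated to the standard stats implementations).

#' Group-comparison statistics
#'
#' Dispatches to the standard tests: Kruskal-Wallis for comparing multiple
#' groups, Mann-Whitney U (two-sample Wilcoxon) for two groups, and the
#' paired t-test for matched pairs. Degenerate paired input with all-zero
#' differences returns statistic 0 and p-value 1 rather than an error.
#'
#' @param samples named list mapping group name to numeric values (exactly 2
#'   groups for `mann_whitney_u`/`paired_t`, >= 2 for `kruskal_wallis`;
#'   equal lengths for `paired_t`).
#' @param test one of `"kruskal_wallis"`, `"mann_whitney_u"`, `"paired_t"`.
#' @return list with `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(samples, test = c("kruskal_wallis", "mann_whitney_u", "paired_t")) {
  test <- match.arg(test)
  if (!is.list(samples) || length(samples) < 2 ||
      !all(vapply(samples, is.numeric, logical(1)))) {
    pd_stop("popdecode_invalid_argument", "`samples` must be a list of >= 2 numeric groups")
  }
  if (test == "kruskal_wallis") {
    res <- stats::kruskal.test(samples)
    return(list(test = test, statistic = unname(res$statistic), p_value = res$p.value))
  }
  if (length(samples) != 2) {
    pd_stop("popdecode_invalid_argument", sprintf("`%s` compares exactly two groups", test))
  }
  a <- samples[[1]]; b <- samples[[2]]
  if (test == "mann_whitney_u") {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    return(list(test = test, statistic = unname(res$statistic), p_value = res$p.value))
  }
  if (length(a) != length(b)) {
    pd_stop("popdecode_invalid_argument", "`paired_t` requires equal-length paired samples")
  }
  diffs <- a - b
  if (stats::sd(diffs) == 0) {
    return(list(test = test, statistic = 0, p_value = 1))
  }
  res <- stats::t.test(a, b, paired = TRUE)
  list(test = test, statistic = unname(res$statistic), p_value = res$p.value)
}

#' Default end-to-end experiment configuration
#'
#' A compact synthetic experiment exercising every stage: simulate archetype
#' sessions, decode pairwise per region, fit the encoding GLM on a few
#' units, and run the cross-block reconstruction.
#'
#' @param seed global seed; every stochastic stage receives a derived,
#'   logged sub-seed.
#' @param out_dir output directory for reports.
#' @return nested configuration list.
#' @export
default_experiment_config <- function(seed = 1, out_dir = tempfile("popdecode_run")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(n_sessions = 2, n_units_per_region = c(V1 = 20, CA1 = 20),
                    n_repeats = 20, n_frames = 30, speed_state_fraction = 0.5),
    decode = list(regions = c("V1", "CA1"), n_units = 20, n_pairs = 20,
                  n_randomizations = 3),
    encode = list(region = "V1", n_units = 5),
    reconstruct = list(movie_px = 16)
  )
}

#' Run an end-to-end synthetic experiment
#'
#' Executes the stages in order (simulate, decode, encode, reconstruct),
#' writes machine-readable outputs (`report.json`, per-stage CSVs) into the
#' configured output directory and returns the report. Reports embed the
#' fully resolved configuration including all derived sub-seeds, so a run is
#' reproducible from `config` alone. Alternatively `config$input_sessions`
#' may name session directories written by [write_session()] to analyse
#' instead of simulating.
#'
#' @param config a configuration list as produced by
#'   [default_experiment_config()].
#' @return the report list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_experiment <- function(config = default_experiment_config()) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  config$sub_seeds <- list(simulate = seeds[1], decode = seeds[2],
                           encode = seeds[3], reconstruct = seeds[4])

  # --- stage: sessions (simulate or load) ---------------------------------
  if (!is.null(config$input_sessions)) {
    missing <- config$input_sessions[!dir.exists(config$input_sessions)]
    if (length(missing)) {
      pd_stop("popdecode_invalid_argument",
              sprintf("stage 'simulate': session directory not found: %s", missing[1]))
    }
    sessions <- lapply(config$input_sessions, read_session)
  } else {
    sim <- config$simulate
    sess_seeds <- derive_seeds(config$sub_seeds$simulate, sim$n_sessions)
    sessions <- lapply(seq_len(sim$n_sessions), function(i) {
      cfg <- simulation_config(n_units_per_region = sim$n_units_per_region,
                               n_repeats = sim$n_repeats, n_frames = sim$n_frames,
                               speed_state_fraction = sim$speed_state_fraction,
                               seed = sess_seeds[i])
      simulate_region_session(cfg, session_id = sprintf("sim%02d", i))
    })
  }

  # --- stage: decode ------------------------------------------------------
  dec <- config$decode
  dec_seeds <- derive_seeds(config$sub_seeds$decode, length(sessions) * length(dec$regions))
  dec_rows <- list(); k <- 0L
  for (si in seq_along(sessions)) {
    for (region in dec$regions) {
      k <- k + 1L
      idx <- tryCatch(select_region_units(sessions[[si]], region, dec$n_units,
                                          seed = dec_seeds[k]),
                      popdecode_error = function(e) NULL)
      if (is.null(idx)) next
      acc <- mean_pairwise_accuracy(sessions[[si]], idx, n_pairs = dec$n_pairs,
                                    n_randomizations = dec$n_randomizations,
                                    seed = dec_seeds[k])
      mc <- multiclass_accuracy(sessions[[si]], idx,
                                n_randomizations = dec$n_randomizations,
                                seed = dec_seeds[k])
      dec_rows[[k]] <- data.frame(session = sessions[[si]]$session_id, region = region,
                                  pairwise_accuracy = acc,
                                  multiclass_accuracy = mc$accuracy,
                                  chance_binary = chance_level("binary"),
                                  chance_multiclass_reported = mc$chance_reported,
                                  chance_multiclass_empirical = mc$chance_empirical)
    }
  }
  decode_table <- do.call(rbind, dec_rows)

  # --- stage: encode ------------------------------------------------------
  enc <- config$encode
  enc_idx <- tryCatch(
    select_region_units(sessions[[1]], enc$region, enc$n_units,
                        seed = config$sub_seeds$encode),
    popdecode_error = function(e) seq_len(min(enc$n_units, dim(sessions[[1]]$counts)[1])))
  encode_res <- encode_population(sessions[[1]], enc_idx)

  # --- stage: reconstruct -------------------------------------------------
  rec <- config$reconstruct
  movie <- generate_movie(dim(sessions[[1]]$counts)[3], rec$movie_px, rec$movie_px,
                          seed = config$sub_seeds$reconstruct)
  recon <- cross_block_experiment(sessions[[1]], movie,
                                  seed = config$sub_seeds$reconstruct)

  report <- list(
    config = config,
    n_sessions = length(sessions),
    decode = decode_table,
    encode = encode_res$table,
    reconstruct = list(mean_diag_cc = recon$mean_diag_cc))
  utils::write.csv(decode_table, file.path(config$out_dir, "decode.csv"),
                   row.names = FALSE)
  utils::write.csv(encode_res$table, file.path(config$out_dir, "encode.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
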