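# Synthetic-session generator: frame-tuned inhomogeneous-Poisson spiking with
# bimodal locomotion and selectable behaviour-stimulus interaction.
#
# Rate model per unit, repeat and 1-s bin (frame f shown in that bin):
#   base(f)           = baseline_rate + tuning_weights[f]
#   none:             rate = base(f)
#   additive:         rate = base(f) + strength * speed
#   multiplicative:   rate = base(f) * (1 + strength * speed)
# Counts are Poisson draws from the rate; negative rates (possible under
# additive modulation with negative strength) are clipped at 0 and the number
# of clipped cells is recorded.

MODULATION_MODES <- c("none", "additive", "multiplicative")

#' Specify a synthetic unit
#'
#' @param baseline_rate baseline firing, spikes per 1-s bin (>= 0).
#' @param tuning_weights length-`F` vector of per-frame rate increments
#'   (spikes per bin, all finite and >= 0).
#' @param modulation_mode how running speed enters the rate: `"none"`,
#'   `"additive"` (independent additive modulation) or `"multiplicative"`
#'   (gain scaling of the stimulus-evoked rate).
#' @param modulation_strength modulation per cm/s (dimensionless for the
#'   multiplicative gain; spikes/bin/(cm/s) for additive).
#' @param region_label brain-region code carried by the unit (e.g. "V1").
#' @return an object of class `unit_spec`; `preferred_frame` is the argmax of
#'   the tuning weights (ties broken towards the lowest frame index).
#' @export
unit_spec <- function(baseline_rate, tuning_weights, modulation_mode = "none",
                      modulation_strength = 0, region_label = "V1") {
  if (!is.numeric(baseline_rate) || length(baseline_rate) != 1L ||
      !is.finite(baseline_rate) || baseline_rate < 0) {
    pd_stop("popdecode_invalid_argument", "`baseline_rate` must be a single finite value >= 0")
  }
  if (!is.numeric(tuning_weights) || length(tuning_weights) < 1L ||
      anyNA(tuning_weights) || !all(is.finite(tuning_weights)) || any(tuning_weights < 0)) {
    pd_stop("popdecode_invalid_argument", "`tuning_weights` must be finite and >= 0")
  }
  modulation_mode <- match.arg(modulation_mode, MODULATION_MODES)
  if (!is.numeric(modulation_strength) || length(modulation_strength) != 1L ||
      !is.finite(modulation_strength)) {
    pd_stop("popdecode_invalid_argument", "`modulation_strength` must be a single finite value")
  }
  structure(
    list(baseline_rate = baseline_rate,
         tuning_weights = as.numeric(tuning_weights),
         preferred_frame = which.max(tuning_weights),
         modulation_mode = modulation_mode,
         modulation_strength = modulation_strength,
         region_label = as.character(region_label)),
    class = "unit_spec")
}

default_speed_params <- function() {
  list(low = list(meanlog = log(0.5), sdlog = 0.5),
       high = list(meanlog = log(8), sdlog = 0.35),
       bin_sdlog = 0.25)
}

#' Configure a synthetic session
#'
#' @param n_units_per_region named integer vector or list mapping region label
#'   to unit count (used by [simulate_region_session()]; [simulate_session()]
#'   takes explicit unit specs).
#' @param n_repeats number of movie repeats (>= 5; source data present the
#'   movie in two blocks of 10 repeats).
#' @param n_frames number of 1-s bins / movie frames `F` (>= 2; 30 in the
#'   source movie).
#' @param speed_state_fraction fraction of repeats in the high-locomotion
#'   state; either a scalar or a length-2 vector giving per-block fractions.
#'   The high-state repeat count is `round(fraction * repeats)`, assigned to
#'   random repeats.
#' @param speed_params list with components `low`, `high` (each
#'   `list(meanlog, sdlog)` of the lognormal repeat-level speed components, in
#'   cm/s) and `bin_sdlog` (lognormal within-repeat bin jitter).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   sessions.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_units_per_region = c(V1 = 20), n_repeats = 20,
                              n_frames = 30, speed_state_fraction = 0.5,
                              speed_params = default_speed_params(), seed = 1) {
  assert_scalar_count(n_repeats, "n_repeats", min = 5)
  assert_scalar_count(n_frames, "n_frames", min = 2)
  if (!is.numeric(speed_state_fraction) ||
      !length(speed_state_fraction) %in% c(1L, 2L) ||
      any(speed_state_fraction < 0) || any(speed_state_fraction > 1)) {
    pd_stop("popdecode_invalid_argument",
            "`speed_state_fraction` must be 1 or 2 values in [0, 1]")
  }
  stopifnot(is.list(speed_params),
            all(c("low", "high", "bin_sdlog") %in% names(speed_params)))
  structure(
    list(n_units_per_region = n_units_per_region, n_repeats = as.integer(n_repeats),
         n_frames = as.integer(n_frames), speed_state_fraction = speed_state_fraction,
         speed_params = speed_params, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Generate a running-speed trace with two behavioural states
#'
#' Each repeat is assigned a latent locomotion state (`"H"` or `"L"`); its
#' base speed is drawn from the corresponding lognormal mixture component and
#' per-bin speeds jitter multiplicatively around the base. With
#' `0 < speed_state_fraction < 1` the pooled distribution is bimodal with one
#' mode below and one above the conventional 2 cm/s threshold.
#'
#' @param n_repeats,n_bins trace dimensions (>= 1).
#' @param config a [simulation_config()] supplying the mixture parameters and
#'   state fraction. When `speed_state_fraction` has length 2 the repeats are
#'   split into two equal blocks with per-block fractions.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return `n_repeats x n_bins` matrix of nonnegative speeds (cm/s) with a
#'   character attribute `latent_state` giving each repeat's generating state.
#' @export
generate_speed_trace <- function(n_repeats, n_bins, config, seed = config$seed) {
  assert_scalar_count(n_repeats, "n_repeats")
  assert_scalar_count(n_bins, "n_bins")
  sp <- config$speed_params
  frac <- config$speed_state_fraction
  with_seed(seed, {
    if (length(frac) == 2L) {
      half <- c(ceiling(n_repeats / 2), n_repeats - ceiling(n_repeats / 2))
      states <- c(draw_states(half[1], frac[1]), draw_states(half[2], frac[2]))
    } else {
      states <- draw_states(n_repeats, frac)
    }
    base <- ifelse(states == "H",
                   stats::rlnorm(n_repeats, sp$high$meanlog, sp$high$sdlog),
                   stats::rlnorm(n_repeats, sp$low$meanlog, sp$low$sdlog))
    jitter <- matrix(stats::rlnorm(n_repeats * n_bins, 0, sp$bin_sdlog), n_repeats, n_bins)
    speed <- base * jitter
    attr(speed, "latent_state") <- states
    speed
  })
}

draw_states <- function(n, frac) {
  n_high <- round(frac * n)
  states <- rep("L", n)
  if (n_high > 0) states[sample.int(n, n_high)] <- "H"
  states
}

#' Per-cell Poisson rates implied by unit specs and a speed trace
#'
#' The generating rate tensor before Poisson sampling; exposed so that tests
#' can assert rate-level identities exactly (e.g. multiplicative gain at
#' constant speed equals unmodulated rates rescaled).
#'
#' @param units list of [unit_spec()].
#' @param speed `repeats x bins` speed matrix (cm/s).
#' @return list with `rates` (`units x repeats x bins` array, clipped at 0)
#'   and `n_clipped` (number of cells clipped).
#' @export
session_rates <- function(units, speed) {
  n_units <- length(units)
  n_repeats <- nrow(speed); n_bins <- ncol(speed)
  rates <- array(0, dim = c(n_units, n_repeats, n_bins))
  for (u in seq_len(n_units)) {
    spec <- units[[u]]
    base <- spec$baseline_rate + spec$tuning_weights  # length n_bins (frame f in bin f)
    base_mat <- matrix(base, n_repeats, n_bins, byrow = TRUE)
    r <- switch(spec$modulation_mode,
                none = base_mat,
                additive = base_mat + spec$modulation_strength * speed,
                multiplicative = base_mat * (1 + spec$modulation_strength * speed))
    rates[u, , ] <- r
  }
  n_clipped <- sum(rates < 0)
  rates[rates < 0] <- 0
  list(rates = rates, n_clipped = n_clipped)
}

#' Simulate a recorded session
#'
#' Draws Poisson spike counts for every unit, repeat and 1-s bin under the
#' rate model described above, together with a two-state running-speed trace.
#' Repeats are split into two presentation blocks (first half = block 1). The
#' generating ground truth (latent states, unit specs, rate tensor, clip
#' count) is retained in the returned session's `ground_truth` field for
#' recovery tests.
#'
#' @param config a [simulation_config()].
#' @param units list of [unit_spec()]; each must carry `config$n_frames`
#'   tuning weights.
#' @param movie optional [movie_stimulus()]; if supplied its frame count must
#'   equal `config$n_frames`.
#' @param session_id identifier stored with the session.
#' @return a [session_recording()].
#' @examples
#' cfg <- simulation_config(n_repeats = 10, n_frames = 10, seed = 3)
#' units <- replicate(5, unit_spec(5, rep(0, 10)), simplify = FALSE)
#' s <- simulate_session(cfg, units)
#' dim(s$counts)
#' @export
simulate_session <- function(config, units, movie = NULL, session_id = "synthetic") {
  stopifnot(inherits(config, "simulation_config"), is.list(units), length(units) > 0)
  for (u in units) {
    if (!inherits(u, "unit_spec")) {
      pd_stop("popdecode_invalid_argument", "`units` must be a list of unit_spec objects")
    }
    if (length(u$tuning_weights) != config$n_frames) {
      pd_stop("popdecode_invalid_argument",
              sprintf("unit has %d tuning weights but config$n_frames is %d",
                      length(u$tuning_weights), config$n_frames))
    }
  }
  if (!is.null(movie) && n_frames(movie) != config$n_frames) {
    pd_stop("popdecode_invalid_argument",
            sprintf("movie has %d frames but config$n_frames is %d",
                    n_frames(movie), config$n_frames))
  }
  with_seed(config$seed, {
    speed <- generate_speed_trace(config$n_repeats, config$n_frames, config, seed = NULL)
    states <- attr(speed, "latent_state")
    attr(speed, "latent_state") <- NULL
    rt <- session_rates(units, speed)
    counts <- array(stats::rpois(length(rt$rates), rt$rates), dim = dim(rt$rates))
    block <- rep(1:2, c(ceiling(config$n_repeats / 2),
                        config$n_repeats - ceiling(config$n_repeats / 2)))
    session_recording(
      counts = counts,
      unit_regions = vapply(units, function(u) u$region_label, character(1)),
      speed = speed,
      block_of_repeat = block,
      session_id = session_id,
      ground_truth = list(latent_state = states, units = units, rates = rt$rates,
                          n_clipped = rt$n_clipped, config = config))
  })
}

# Region archetype tuning parameters: amplitude of the circular-Gaussian
# tuning bump (spikes/bin), its width in frames, and the baseline rate.
# Ordered to mirror the qualitative region ranking of decodability:
# primary visual cortex >> thalamic relay > midbrain > hippocampus.
REGION_ARCHETYPES <- list(
  V1   = list(baseline = 1, amplitude = 30, sigma = 1.5),
  dLGN = list(baseline = 2, amplitude = 6,  sigma = 2),
  APN  = list(baseline = 3, amplitude = 1.5, sigma = 3),
  CA1  = list(baseline = 5, amplitude = 0,  sigma = 2)
)

#' Build a population of archetypal units for a region
#'
#' Units get circular-Gaussian tuning curves over the frame cycle with
#' preferred frames spread evenly (plus jitter) and region-specific tuning
#' signal-to-noise: "V1"-like units are strongly frame-tuned, "dLGN"-like
#' moderately, "APN"-like weakly and "CA1"-like not at all.
#'
#' @param region one of `"V1"`, `"dLGN"`, `"APN"`, `"CA1"`.
#' @param n_units number of units.
#' @param n_frames frames per movie cycle.
#' @param modulation_mode,modulation_strength behavioural modulation passed to
#'   [unit_spec()]; per-unit strengths are jittered uniformly in
#'   `[0.5, 1.5] * modulation_strength`.
#' @param seed RNG seed.
#' @param amplitude,baseline,sigma optional overrides of the archetype.
#' @return list of [unit_spec()].
#' @export
region_archetype_units <- function(region, n_units, n_frames = 30,
                                   modulation_mode = "none", modulation_strength = 0,
                                   seed = 1, amplitude = NULL, baseline = NULL,
                                   sigma = NULL) {
  if (!region %in% names(REGION_ARCHETYPES)) {
    pd_stop("popdecode_invalid_argument",
            sprintf("unknown region archetype '%s' (have: %s)", region,
                    paste(names(REGION_ARCHETYPES), collapse = ", ")))
  }
  assert_scalar_count(n_units, "n_units")
  arch <- REGION_ARCHETYPES[[region]]
  amplitude <- amplitude %||% arch$amplitude
  baseline <- baseline %||% arch$baseline
  sigma <- sigma %||% arch$sigma
  with_seed(seed, {
    # preferred frames evenly spread over the cycle with +/-1 frame jitter
    pref <- (round(seq(0, n_frames, length.out = n_units + 1)[seq_len(n_units)]) +
               sample(-1:1, n_units, replace = TRUE)) %% n_frames + 1
    lapply(seq_len(n_units), function(u) {
      d <- abs(seq_len(n_frames) - pref[u])
      d <- pmin(d, n_frames - d)  # circular frame distance
      amp_u <- amplitude * stats::runif(1, 0.8, 1.2)
      tw <- if (amplitude > 0) amp_u * exp(-d^2 / (2 * sigma^2)) else rep(0, n_frames)
      unit_spec(baseline_rate = baseline * stats::runif(1, 0.8, 1.2),
                tuning_weights = tw,
                modulation_mode = modulation_mode,
                modulation_strength = modulation_strength * stats::runif(1, 0.5, 1.5),
                region_label = region)
    })
  })
}

#' Simulate a session from region archetypes
#'
#' Convenience wrapper: builds archetypal units for each region named in
#' `config$n_units_per_region` and simulates one session.
#'
#' @param config a [simulation_config()].
#' @param modulation_mode,modulation_strength behavioural modulation applied
#'   to every unit (per-unit strength jitter as in
#'   [region_archetype_units()]).
#' @param movie,session_id passed to [simulate_session()].
#' @return a [session_recording()].
#' @export
simulate_region_session <- function(config, modulation_mode = "none",
                                    modulation_strength = 0, movie = NULL,
                                    session_id = "synthetic") {
  counts <- config$n_units_per_region
  units <- list()
  seeds <- derive_seeds(config$seed, length(counts) + 1L)
  for (i in seq_along(counts)) {
    units <- c(units, region_archetype_units(
      names(counts)[i], counts[[i]], n_frames = config$n_frames,
      modulation_mode = modulation_mode, modulation_strength = modulation_strength,
      seed = seeds[i]))
  }
  cfg <- config
  cfg$seed <- seeds[length(seeds)]
  simulate_session(cfg, units, movie = movie, session_id = session_id)
}
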