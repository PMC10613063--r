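# Session builders shared across test files. All fixtures are generated in
# code; seeds are fixed so every run sees the same sessions.

untuned_units <- function(n_units = 20, rate = 5, n_frames = 30) {
  replicate(n_units, unit_spec(rate, rep(0, n_frames)), simplify = FALSE)
}

untuned_session <- function(n_units = 20, rate = 5, n_repeats = 20, n_frames = 30,
                            seed = 11) {
  cfg <- simulation_config(n_repeats = n_repeats, n_frames = n_frames, seed = seed)
  simulate_session(cfg, untuned_units(n_units, rate, n_frames),
                   session_id = sprintf("untuned_%d", seed))
}

archetype_session <- function(region = "V1", n_units = 20, n_repeats = 20,
                              speed_state_fraction = 0.5, seed = 21,
                              modulation_mode = "none", modulation_strength = 0) {
  cfg <- simulation_config(stats::setNames(n_units, region), n_repeats = n_repeats,
                           speed_state_fraction = speed_state_fraction, seed = seed)
  simulate_region_session(cfg, modulation_mode = modulation_mode,
                          modulation_strength = modulation_strength,
                          session_id = sprintf("%s_%d", region, seed))
}

# Behavioural-mismatch study sessions: dLGN-like tuning, per-condition state
# composition dictated by the strict screening rule.
behaviour_sessions <- function(condition, mode, strength, n_sessions, seed0) {
  frac <- c(HH = 1, LL = 0, HL = 0.8, LH = 0.2)[[condition]]
  lapply(seq_len(n_sessions), function(i) {
    archetype_session("dLGN", speed_state_fraction = frac, seed = seed0 + i,
                      modulation_mode = mode, modulation_strength = strength)
  })
}

# Two-block cross-block sessions: matched (L-L blocks) or mismatched (L block
# then H block), strongly additively modulated.
cross_block_session <- function(change = c("low", "high"), seed,
                                mode = "additive", strength = 1.0) {
  change <- match.arg(change)
  fracs <- if (change == "low") c(0, 0) else c(0, 1)
  cfg <- simulation_config(c(dLGN = 20), n_repeats = 20,
                           speed_state_fraction = fracs, seed = seed)
  simulate_region_session(cfg, modulation_mode = mode,
                          modulation_strength = strength,
                          session_id = sprintf("%s_change_%d", change, seed))
}

random_small_session <- function(seed) {
  with_seed_local(seed, {
    n_u <- sample(2:6, 1); n_r <- sample(5:8, 1); n_b <- sample(3:6, 1)
    counts <- array(rpois(n_u * n_r * n_b, 4), dim = c(n_u, n_r, n_b))
    speed <- matrix(rlnorm(n_r * n_b, 0, 1), n_r, n_b)
    session_recording(counts, sample(c("V1", "CA1"), n_u, replace = TRUE), speed,
                      session_id = sprintf("rand_%d", seed))
  })
}

scratch_session_dir <- function() {
  d <- tempfile("popdecode_test_")
  dir.create(d)
  d
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
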