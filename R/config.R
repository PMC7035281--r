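#' Default conformational rate matrix
#'
#' Generator matrix (s^-1) for the 4-state emission model. State 1 is the
#' zero-FRET dark state; it is photophysical (entered through blinking or
#' bleaching) and therefore kinetically disconnected from the conformational
#' chain. States 2-4 are the low (0.47), intermediate (0.63) and high (0.79)
#' FRET conformations. The default chain exchanges low and intermediate at
#' order-1 s^-1 rates, while the high state is a weakly populated satellite
#' of the intermediate, emulating the regime where the intermediate dominates
#' at ligand saturation.
#'
#' @param k_low_inter,k_inter_low Low <-> intermediate rates (s^-1).
#' @param k_inter_high,k_high_inter Intermediate <-> high rates (s^-1).
#' @return 4x4 generator matrix with rows summing to zero.
#' @export
default_rate_matrix <- function(k_low_inter = 1, k_inter_low = 2.04,
                                k_inter_high = 0.1, k_high_inter = 2) {
  q <- matrix(0, 4, 4)
  q[2, 3] <- k_low_inter
  q[3, 2] <- k_inter_low
  q[3, 4] <- k_inter_high
  q[4, 3] <- k_high_inter
  diag(q) <- -rowSums(q)
  q
}

#' Ligand coupling of one transition pair
#'
#' Describes a substrate binding step that modulates exactly one forward
#' transition of the conformational chain: the forward rate becomes
#' `k_on * concentration` and the reverse rate `k_off`. By default the
#' low <-> intermediate pair is coupled, matching substrate action on the
#' low-to-intermediate FRET transition.
#'
#' @param k_on Association rate constant, per molar per second.
#' @param k_off Dissociation-coupled reverse rate, s^-1.
#' @param pair Integer pair `c(from, to)` of 1-based state indices whose
#'   forward rate is concentration dependent.
#' @return A `ligand_coupling` list.
#' @export
ligand_coupling <- function(k_on = 4e5, k_off = 2.04, pair = c(2L, 3L)) {
  stopifnot(k_on >= 0, k_off >= 0, length(pair) == 2, pair[1] != pair[2])
  structure(list(k_on = k_on, k_off = k_off, pair = as.integer(pair)),
            class = "ligand_coupling")
}

#' Trace simulation configuration
#'
#' Bundles every parameter of the synthetic smFRET trace generator. Defaults
#' reflect typical TIRF recordings at 40 frames per second with the fixed
#' 4-state emission model (FRET means 0, 0.47, 0.63, 0.79).
#'
#' @param n_molecules Number of molecules (traces).
#' @param n_frames Frames per trace.
#' @param frame_period Frame duration in seconds (default 0.025, i.e. 40 fps).
#' @param state_means Strictly increasing FRET means; the first must be 0.
#' @param noise_sd Gaussian channel noise as a fraction of `total_intensity`
#'   (approximately the FRET-efficiency noise SD).
#' @param total_intensity Summed donor+acceptor intensity of a live molecule.
#' @param bleed_through_fraction Fraction of donor intensity detected in the
#'   raw acceptor channel (default 0.165).
#' @param bleach_rate Photobleach rate, s^-1 (0 disables bleaching).
#' @param blink_rate Rate of entering a dark blink, s^-1 (0 disables).
#' @param blink_recovery_rate Rate of recovery from a blink, s^-1.
#' @param rate_matrix Generator matrix (s^-1); rows must sum to 0 with
#'   non-negative off-diagonals.
#' @param ligand_coupling Optional [ligand_coupling()] description.
#' @param start_state Optional fixed 1-based start state; default samples the
#'   stationary distribution of the active sub-chain.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated `trace_sim_config` list.
#' @export
trace_sim_config <- function(n_molecules = 100, n_frames = 2000,
                             frame_period = 0.025,
                             state_means = c(0, 0.47, 0.63, 0.79),
                             noise_sd = 0.06, total_intensity = 1000,
                             bleed_through_fraction = 0.165,
                             bleach_rate = 0.02, blink_rate = 0.02,
                             blink_recovery_rate = 2,
                             rate_matrix = default_rate_matrix(),
                             ligand_coupling = NULL, start_state = NULL,
                             seed = 1L) {
  cfg <- structure(
    list(n_molecules = as.integer(n_molecules),
         n_frames = as.integer(n_frames), frame_period = frame_period,
         state_means = state_means, noise_sd = noise_sd,
         total_intensity = total_intensity,
         bleed_through_fraction = bleed_through_fraction,
         bleach_rate = bleach_rate, blink_rate = blink_rate,
         blink_recovery_rate = blink_recovery_rate, rate_matrix = rate_matrix,
         ligand_coupling = ligand_coupling, start_state = start_state,
         seed = as.integer(seed)),
    class = "trace_sim_config")
  validate_trace_sim_config(cfg)
}

validate_trace_sim_config <- function(cfg) {
  m <- cfg$state_means
  if (any(diff(m) <= 0))
    abort("state_means must be strictly increasing", class = "fretgate_config_error")
  if (m[1] != 0)
    abort("the first state mean must be exactly 0 (dark / zero-FRET state)",
          class = "fretgate_config_error")
  if (cfg$frame_period <= 0)
    abort("frame_period must be positive", class = "fretgate_config_error")
  if (cfg$bleed_through_fraction < 0 || cfg$bleed_through_fraction >= 1)
    abort("bleed_through_fraction must lie in [0, 1)", class = "fretgate_config_error")
  if (cfg$total_intensity <= 0)
    abort("total_intensity must be positive", class = "fretgate_config_error")
  q <- cfg$rate_matrix
  if (!is.matrix(q) || nrow(q) != length(m) || ncol(q) != length(m))
    abort("rate_matrix must be square with one row per state",
          class = "fretgate_config_error")
  off <- q; diag(off) <- 0
  if (any(off < 0) || any(abs(rowSums(q)) > 1e-9))
    abort("rate_matrix must have non-negative off-diagonals and rows summing to 0",
          class = "fretgate_config_error")
  if (cfg$n_molecules < 1 || cfg$n_frames < 1)
    abort("n_molecules and n_frames must be at least 1", class = "fretgate_config_error")
  if (cfg$noise_sd < 0 || cfg$bleach_rate < 0 || cfg$blink_rate < 0 ||
      cfg$blink_recovery_rate < 0)
    abort("rates and noise_sd must be non-negative", class = "fretgate_config_error")
  cfg
}

#' Trace selection criteria
#'
#' Thresholds of the five-point filter applied to corrected traces:
#' (i) single-step donor photobleaching, (ii) background SNR at least
#' `snr_background_min`, (iii) bleach-step SNR at least `snr_signal_min`,
#' (iv) at most `max_blink_events` donor blinks ("less than four"), and
#' (v) FRET efficiency above `fret_floor` for at least `min_frames` frames.
#'
#' @param require_single_step_bleach Require one-step donor photobleaching.
#' @param snr_background_min Minimum background SNR (default 8).
#' @param snr_signal_min Minimum bleach-step SNR (default 5).
#' @param max_blink_events Maximum allowed blink count (default 3).
#' @param min_frames Minimum frames above `fret_floor` (default 300).
#' @param fret_floor FRET-efficiency floor for criterion (v) (default 0.15).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(require_single_step_bleach = TRUE,
                               snr_background_min = 8, snr_signal_min = 5,
                               max_blink_events = 3, min_frames = 300,
                               fret_floor = 0.15) {
  stopifnot(snr_background_min >= 0, snr_signal_min >= 0,
            max_blink_events >= 0, min_frames >= 0, fret_floor >= 0)
  structure(list(require_single_step_bleach = require_single_step_bleach,
                 snr_background_min = snr_background_min,
                 snr_signal_min = snr_signal_min,
                 max_blink_events = as.integer(max_blink_events),
                 min_frames = as.integer(min_frames),
                 fret_floor = fret_floor),
            class = "selection_criteria")
}

#' Fixed-mean emission model for idealization
#'
#' Emission means are held fixed during segmental K-means idealization; only
#' the transition matrix and a single shared Gaussian noise SD are
#' re-estimated from the assignments.
#'
#' @param means Ascending state FRET means (default 0, 0.47, 0.63, 0.79).
#' @param sigma Initial shared emission SD in FRET units.
#' @return A `state_model` list.
#' @export
state_model <- function(means = c(0, 0.47, 0.63, 0.79), sigma = 0.06) {
  if (any(diff(means) <= 0))
    abort("state means must be sorted ascending", class = "fretgate_config_error")
  if (sigma <= 0) abort("sigma must be positive", class = "fretgate_config_error")
  structure(list(means = means, sigma = sigma), class = "state_model")
}

#' Pipeline configuration document
#'
#' Collects every numeric default of the package in one structured list that
#' can be written to and read back from YAML, so an analysis can be pinned to
#' an explicit, versioned parameter set.
#'
#' @param trace_sim A [trace_sim_config()].
#' @param selection A [selection_criteria()].
#' @param model A [state_model()].
#' @param gates A [gate_definition()].
#' @param hydration A [hydration_criteria()].
#' @param tdp_bin_width Transition-density bin width (FRET units).
#' @param cv_bin_width Microstate-map bin width (Angstrom).
#' @param hill Fixed Hill coefficient for dose-response fits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trace_sim = trace_sim_config(),
                            selection = selection_criteria(),
                            model = state_model(),
                            gates = gate_definition(),
                            hydration = hydration_criteria(),
                            tdp_bin_width = 0.05, cv_bin_width = 0.25,
                            hill = 1.0) {
  structure(list(version = 1L, trace_sim = trace_sim, selection = selection,
                 model = model, gates = gates, hydration = hydration,
                 tdp_bin_width = tdp_bin_width, cv_bin_width = cv_bin_width,
                 hill = hill),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' `read_config()` rejects documents containing keys that are not part of the
#' configuration schema, so typos cannot silently fall back to defaults.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- rapply(unclass(config), identity, how = "list")
  x$trace_sim$rate_matrix <- as.vector(config$trace_sim$rate_matrix)
  x$trace_sim$n_states <- length(config$trace_sim$state_means)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  template <- pipeline_config()
  check_keys <- function(got, want, where) {
    extra <- setdiff(names(got), names(want))
    if (length(extra) > 0)
      abort(paste0("unknown configuration key(s) in ", where, ": ",
                   paste(extra, collapse = ", ")),
            class = "fretgate_config_error")
  }
  x$trace_sim$rate_matrix <- matrix(unlist(x$trace_sim$rate_matrix),
                                    x$trace_sim$n_states, x$trace_sim$n_states)
  x$trace_sim$n_states <- NULL
  check_keys(x, unclass(template), "top level")
  for (part in c("trace_sim", "selection", "model", "gates", "hydration"))
    check_keys(x[[part]], unclass(template[[part]]), part)
  ts <- x$trace_sim
  ts$state_means <- unlist(ts$state_means)
  if (!is.null(ts$ligand_coupling))
    ts$ligand_coupling <- do.call(ligand_coupling, ts$ligand_coupling)
  pipeline_config(
    trace_sim = do.call(trace_sim_config, ts),
    selection = do.call(selection_criteria, x$selection),
    model = do.call(state_model, lapply(x$model, unlist)),
    gates = do.call(gate_definition, lapply(x$gates, unlist)),
    hydration = do.call(hydration_criteria, lapply(x$hydration, unlist)),
    tdp_bin_width = x$tdp_bin_width, cv_bin_width = x$cv_bin_width,
    hill = x$hill)
}
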