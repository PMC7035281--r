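# dwell-to-dwell transitions between temporally adjacent non-dark dwells;
# pairs separated by a zero-FRET (dark) dwell are dropped, since dark frames
# are photophysics rather than conformation
conformational_transitions <- function(dwells) {
  dwells |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::mutate(
      next_state = dplyr::lead(.data$state),
      next_mean = dplyr::lead(.data$mean_fret),
      next_start = dplyr::lead(.data$start_frame)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_state), .data$state > 1L,
                  .data$next_state > 1L,
                  .data$next_start == .data$start_frame + .data$n_frames) |>
    dplyr::transmute(
      molecule_id = .data$molecule_id,
      from = .data$state, to = .data$next_state,
      fret_before = .data$mean_fret, fret_after = .data$next_mean)
}

#' Transition density plot
#'
#' Bins every dwell-to-dwell transition by the mean observed FRET of the
#' dwell just prior to and just after the transition. Also reports the
#' overall transition frequency: total transitions divided by total
#' (non-dark) observation time.
#'
#' @param skm An `skm_fit` from [idealize_skm()].
#' @param bin_width FRET bin width on both axes (default 0.05).
#' @param frame_period Frame duration (s); taken from the fit when absent.
#' @return Object of class `tdp`: `counts` matrix (before x after), bin
#'   `edges`, `total_transitions`, `total_time` (s) and
#'   `transitions_per_second`.
#' @export
transition_density <- function(skm, bin_width = 0.05, frame_period = NULL) {
  stopifnot(inherits(skm, "skm_fit"))
  frame_period <- frame_period %||% skm$frame_period
  if (is.na(frame_period))
    abort("frame_period is needed (not present in the fit)",
          class = "fretgate_input_error")
  tr <- conformational_transitions(skm$dwells)
  total_time <- sum(skm$frames$state > 1L) * frame_period
  lo <- floor(min(0, tr$fret_before, tr$fret_after) / bin_width) * bin_width
  hi <- ceiling(max(1, tr$fret_before, tr$fret_after) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, nb,
                   dimnames = list(before = utils::head(edges, -1),
                                   after = utils::head(edges, -1)))
  if (nrow(tr) > 0) {
    i <- findInterval(tr$fret_before, edges, rightmost.closed = TRUE)
    j <- findInterval(tr$fret_after, edges, rightmost.closed = TRUE)
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  }
  structure(list(counts = counts, edges = edges, bin_width = bin_width,
                 total_transitions = nrow(tr), total_time = total_time,
                 transitions_per_second =
                   if (total_time > 0) nrow(tr) / total_time else NA_real_,
                 transitions = tr),
            class = "tdp")
}

#' @export
tidy.tdp <- function(x, ...) {
  mids <- utils::head(x$edges, -1) + x$bin_width / 2
  expand.grid(fret_before = mids, fret_after = mids) |>
    tibble::as_tibble() |>
    dplyr::mutate(count = as.vector(x$counts)) |>
    dplyr::filter(.data$count > 0)
}

#' @export
print.tdp <- function(x, ...) {
  cat(sprintf("Transition density: %d transitions over %.1f s (%.3f s^-1)\n",
              x$total_transitions, x$total_time, x$transitions_per_second))
  invisible(x)
}

#' Estimate transition rate constants by dwell-time maximum likelihood
#'
#' `k_ij = N_ij / T_i`, the number of observed i to j transitions divided by
#' the total time spent in state i, with standard error `sqrt(N_ij) / T_i`.
#' Zero-FRET (dark) dwells are excluded from both counts and occupancy
#' times. Entries with `T_i = 0` are flagged undefined rather than zero; a
#' path with no transitions out of a visited state yields `k = 0` which is
#' an upper bound only (flagged). Dwell-time estimation does not correct for
#' events shorter than the frame integration time; a dead-time caveat is
#' attached when sub-2-frame dwells are present.
#'
#' @param skm An `skm_fit` from [idealize_skm()].
#' @param frame_period Frame duration (s); taken from the fit when absent.
#' @return Object of class `rate_estimate` with matrices `k`, `se`, `n`,
#'   occupancy times `time_in_state` and a tidy accessor.
#' @export
estimate_rates <- function(skm, frame_period = NULL) {
  stopifnot(inherits(skm, "skm_fit"))
  frame_period <- frame_period %||% skm$frame_period
  if (is.na(frame_period))
    abort("frame_period is needed (not present in the fit)",
          class = "fretgate_input_error")
  ns <- length(skm$model$means)
  tr <- conformational_transitions(skm$dwells)
  n_mat <- matrix(0L, ns, ns)
  if (nrow(tr) > 0)
    for (k in seq_len(nrow(tr)))
      n_mat[tr$from[k], tr$to[k]] <- n_mat[tr$from[k], tr$to[k]] + 1L
  t_i <- vapply(seq_len(ns), function(s)
    sum(skm$frames$state == s) * frame_period, numeric(1))
  t_i[1] <- 0  # dark state carries no kinetic information
  k_mat <- matrix(NA_real_, ns, ns)
  se_mat <- matrix(NA_real_, ns, ns)
  for (i in 2:ns) {
    if (t_i[i] > 0) {
      k_mat[i, ] <- n_mat[i, ] / t_i[i]
      se_mat[i, ] <- sqrt(n_mat[i, ]) / t_i[i]
      k_mat[i, i] <- NA_real_
      se_mat[i, i] <- NA_real_
    }
  }
  short <- sum(skm$dwells$n_frames < 2 & skm$dwells$state > 1L)
  structure(list(k = k_mat, se = se_mat, n = n_mat, time_in_state = t_i,
                 frame_period = frame_period, n_short_dwells = short,
                 dead_time_caveat = short > 0),
            class = "rate_estimate")
}

#' @export
tidy.rate_estimate <- function(x, ...) {
  ns <- nrow(x$k)
  grid <- expand.grid(from = 2:ns, to = 2:ns) |>
    tibble::as_tibble() |>
    dplyr::filter(.data$from != .data$to)
  grid |>
    dplyr::mutate(
      n = x$n[cbind(.data$from, .data$to)],
      time_in_state = x$time_in_state[.data$from],
      rate = x$k[cbind(.data$from, .data$to)],
      se = x$se[cbind(.data$from, .data$to)],
      flag = dplyr::case_when(
        .data$time_in_state == 0 ~ "undefined (state unvisited)",
        .data$n == 0 ~ "upper bound (no events)",
        TRUE ~ ""))
}

#' @export
print.rate_estimate <- function(x, ...) {
  print(tidy(x))
  if (x$dead_time_caveat)
    cat(sprintf(
      "note: %d dwell(s) shorter than 2 frames retained; rates near or above\n%s",
      x$n_short_dwells,
      "the frame rate are biased by missed events (no dead-time correction)\n"))
  invisible(x)
}

#' Rates relative to a reference condition
#'
#' Elementwise ratio of two [estimate_rates()] results, with first-order
#' propagated standard errors, for reporting fold-changes relative to a
#' no-ligand reference.
#'
#' @param est,reference `rate_estimate` objects.
#' @return Tidy tibble with `ratio` and `ratio_se` columns.
#' @export
relative_rates <- function(est, reference) {
  a <- tidy(est)
  b <- tidy(reference) |>
    dplyr::select("from", "to", ref_rate = "rate", ref_se = "se")
  dplyr::left_join(a, b, by = c("from", "to")) |>
    dplyr::mutate(
      ratio = .data$rate / .data$ref_rate,
      ratio_se = .data$ratio *
        sqrt((.data$se / .data$rate)^2 + (.data$ref_se / .data$ref_rate)^2))
}

#' Ensemble state occupancy per condition
#'
#' Fraction of non-dark frames assigned to each of the non-zero FRET states,
#' computed per molecule and averaged over molecules within each condition
#' (mean and standard error across molecules). Zero-FRET frames are
#' photophysics and are excluded from the denominator by default.
#'
#' @param skm An `skm_fit` from [idealize_skm()].
#' @param include_zero_state Include the zero-FRET state in the denominator
#'   (and as a reported state). Default `FALSE`.
#' @return Tibble: `condition`, `concentration` (when present), `state`,
#'   `occupancy`, `se`, `n_molecules`.
#' @export
occupancy <- function(skm, include_zero_state = FALSE) {
  stopifnot(inherits(skm, "skm_fit"))
  fr <- skm$frames
  if (!"condition" %in% names(fr)) fr$condition <- "default"
  if (!"concentration" %in% names(fr)) fr$concentration <- NA_real_
  ns <- length(skm$model$means)
  states <- if (include_zero_state) 1:ns else 2:ns
  if (!include_zero_state) fr <- dplyr::filter(fr, .data$state > 1L)
  dropped <- fr |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  if (nrow(dropped) == 0)
    abort("all frames are dark; occupancy undefined",
          class = "fretgate_input_error")
  per_mol <- fr |>
    dplyr::count(.data$condition, .data$concentration, .data$molecule_id,
                 .data$state) |>
    dplyr::group_by(.data$condition, .data$concentration,
                    .data$molecule_id) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("condition"), !!rlang::sym("concentration"),
                     !!rlang::sym("molecule_id")),
      state = states, fill = list(frac = 0))
  per_mol |>
    dplyr::group_by(.data$condition, .data$concentration, .data$state) |>
    dplyr::summarise(
      occupancy = mean(.data$frac),
      se = sd(.data$frac) / sqrt(dplyr::n()),
      n_molecules = dplyr::n(), .groups = "drop")
}
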