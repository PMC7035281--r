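#' Correct acceptor bleed-through
#'
#' Subtracts a set fraction of the donor intensity from the raw acceptor
#' channel, `I_A = I_A_raw - f * I_D`; the donor is unchanged.
#'
#' @param traces Tibble with `donor` and `acceptor_raw` columns.
#' @param bleed_fraction Bleed-through fraction (default 0.165).
#' @return The input tibble with an `acceptor` column added.
#' @export
correct_bleed_through <- function(traces, bleed_fraction = 0.165) {
  stopifnot(is.data.frame(traces))
  if (!all(c("donor", "acceptor_raw") %in% names(traces)))
    abort("traces must have donor and acceptor_raw columns",
          class = "fretgate_input_error")
  if (bleed_fraction < 0 || bleed_fraction >= 1)
    abort("bleed_fraction must lie in [0, 1)", class = "fretgate_input_error")
  dplyr::mutate(traces, acceptor = .data$acceptor_raw -
                  bleed_fraction * .data$donor)
}

#' Compute FRET efficiency traces
#'
#' `E = I_A / (I_A + I_D)` per frame on the corrected channels. Frames
#' flagged dark (donor dark state: blinks and everything after the detected
#' bleach) are set to exactly 0, as are frames whose total intensity is not
#' positive (pure background noise, where the ratio is meaningless).
#'
#' @param traces Tibble with `donor` and `acceptor` columns (see
#'   [correct_bleed_through()]).
#' @param detection Optional per-molecule detection table from
#'   [detect_bleach_and_blinks()]; its bleach index and blink intervals
#'   define the dark mask. If `traces` already has a logical `dark` column it
#'   is honoured as well.
#' @return The input tibble with `efficiency` and `dark` columns.
#' @export
compute_fret <- function(traces, detection = NULL) {
  if (!all(c("donor", "acceptor") %in% names(traces)))
    abort("traces must have donor and acceptor columns (run correct_bleed_through first)",
          class = "fretgate_input_error")
  dark <- if ("dark" %in% names(traces)) traces$dark else
    rep(FALSE, nrow(traces))
  if (!is.null(detection)) {
    dk <- detection |>
      dplyr::select("molecule_id", "bleach_index", "blink_frames")
    traces2 <- dplyr::left_join(traces, dk, by = "molecule_id")
    post_bleach <- !is.na(traces2$bleach_index) &
      traces2$frame_index >= traces2$bleach_index
    in_blink <- purrr::map2_lgl(traces2$frame_index, traces2$blink_frames,
                                function(f, bl) !is.null(bl) && f %in% bl)
    dark <- dark | post_bleach | in_blink
  }
  total <- traces$donor + traces$acceptor
  dark <- dark | total <= 0   # background-only frames are treated as dark
  eff <- ifelse(total > 0, traces$acceptor / total, 0)
  eff[dark] <- 0
  traces$efficiency <- eff
  traces$dark <- dark
  traces
}

# per-molecule bleach/blink/SNR analysis of one total-intensity vector
analyze_total_intensity <- function(total) {
  n <- length(total)
  sm <- if (n >= 7) stats::runmed(total, 5) else total
  m_max <- max(sm)
  w <- max(10L, n %/% 10L)
  m_end <- median(tail(total, w))
  res <- list(bleach_index = NA_integer_, n_blinks = 0L,
              blink_frames = integer(0), snr_background = NA_real_,
              snr_signal = NA_real_, single_step = FALSE)
  if (!(m_max > 0) || m_end > 0.5 * m_max) return(res)  # never goes dark
  thr <- m_end + 0.3 * (m_max - m_end)
  above <- total >= thr
  b <- max(which(above))            # last frame at signal level (1-based)
  if (n - b < 5) return(res)        # no sustained final dark stretch
  pre <- total[seq_len(b)]
  post <- total[(b + 1):n]
  dark_pre <- pre < thr             # blinks: dark runs before bleach
  runs <- rle(dark_pre)
  blink_frames <- integer(0)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    blink_frames <- unlist(lapply(keep, function(k) starts[k]:ends[k]))
  }
  sig_frames <- pre[!dark_pre]
  sig_mean <- mean(sig_frames)
  post_sd <- sd(post)
  pre_sd <- sd(sig_frames)
  step <- sig_mean - mean(post)
  # single-step check: no sustained intermediate level among lit frames
  lev <- (pre[!dark_pre] - m_end) / max(m_max - m_end, 1e-12)
  midruns <- rle(lev > 0.25 & lev < 0.75)
  multi <- any(midruns$values & midruns$lengths >= 5)
  list(bleach_index = b,            # 0-based index of first dark frame
       n_blinks = sum(runs$values),
       blink_frames = blink_frames - 1L,
       snr_background = if (isTRUE(post_sd > 0)) sig_mean / post_sd else Inf,
       snr_signal = if (isTRUE(pre_sd > 0)) step / pre_sd else Inf,
       single_step = !multi)
}

#' Detect photobleaching, blinking and SNR of each trace
#'
#' The bleach point is the last sustained drop of the total intensity
#' (donor + corrected acceptor) to the background level; dark intervals
#' before it with recovery are counted as blink events.
#' `SNR_background` is the mean pre-bleach total intensity divided by the SD
#' of the post-bleach background; `SNR_signal` is the bleach step amplitude
#' divided by the SD of the pre-bleach total intensity.
#'
#' @param traces Tibble with `molecule_id`, `frame_index`, `donor` and
#'   `acceptor` (or `acceptor_raw`) columns; at least 10 frames per molecule.
#' @return One row per molecule: `bleach_index` (0-based first dark frame,
#'   `NA` when no bleach is detectable), `n_blinks`, `blink_frames`
#'   (list column of 0-based frame indices), `snr_background`, `snr_signal`
#'   and `single_step`.
#' @export
detect_bleach_and_blinks <- function(traces) {
  acc <- if ("acceptor" %in% names(traces)) traces$acceptor else
    traces$acceptor_raw
  if (is.null(acc))
    abort("traces must have an acceptor or acceptor_raw column",
          class = "fretgate_input_error")
  df <- tibble::tibble(molecule_id = traces$molecule_id,
                       frame_index = traces$frame_index,
                       total = traces$donor + acc)
  df |>
    dplyr::arrange(.data$molecule_id, .data$frame_index) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 10)
        abort("bleach detection needs at least 10 frames per trace",
              class = "fretgate_input_error")
      r <- analyze_total_intensity(d$total)
      tibble::tibble(bleach_index = r$bleach_index, n_blinks = r$n_blinks,
                     blink_frames = list(r$blink_frames),
                     snr_background = r$snr_background,
                     snr_signal = r$snr_signal, single_step = r$single_step)
    }) |>
    dplyr::ungroup()
}

#' Apply the five-point trace selection filter
#'
#' A trace is accepted iff it shows (i) single-step donor photobleaching,
#' (ii) `SNR_background` at or above threshold, (iii) `SNR_signal` at or
#' above threshold, (iv) no more than the allowed number of blink events,
#' and (v) FRET efficiency above the floor for at least the minimum number
#' of frames.
#'
#' @param traces Tibble with computed `efficiency` (see [compute_fret()]).
#' @param criteria A [selection_criteria()].
#' @param detection Optional precomputed [detect_bleach_and_blinks()] table;
#'   computed from `traces` when absent.
#' @return A list with `traces` (the accepted subset) and `report` (one row
#'   per molecule with one logical column per criterion and `accepted`).
#' @export
select_traces <- function(traces, criteria = selection_criteria(),
                          detection = NULL) {
  if (!"efficiency" %in% names(traces))
    abort("traces must have an efficiency column (run compute_fret first)",
          class = "fretgate_input_error")
  if (is.null(detection)) detection <- detect_bleach_and_blinks(traces)
  fret_frames <- traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(
      n_above_floor = sum(.data$efficiency > criteria$fret_floor),
      .groups = "drop")
  report <- detection |>
    dplyr::left_join(fret_frames, by = "molecule_id") |>
    dplyr::mutate(
      crit_single_step_bleach = !criteria$require_single_step_bleach |
        (!is.na(.data$bleach_index) & .data$single_step),
      crit_snr_background = !is.na(.data$snr_background) &
        .data$snr_background >= criteria$snr_background_min,
      crit_snr_signal = !is.na(.data$snr_signal) &
        .data$snr_signal >= criteria$snr_signal_min,
      crit_blinks = .data$n_blinks <= criteria$max_blink_events,
      crit_fret_frames = .data$n_above_floor >= criteria$min_frames,
      accepted = .data$crit_single_step_bleach & .data$crit_snr_background &
        .data$crit_snr_signal & .data$crit_blinks & .data$crit_fret_frames) |>
    dplyr::select("molecule_id", dplyr::starts_with("crit_"), "accepted")
  keep <- report$molecule_id[report$accepted]
  list(traces = dplyr::filter(traces, .data$molecule_id %in% keep),
       report = report)
}
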