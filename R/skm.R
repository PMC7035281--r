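#' Idealize FRET traces by segmental K-means
#'
#' Iterates Viterbi assignment under the current transition matrix and fixed
#' Gaussian emission means with a re-estimation of the transition matrix and
#' the shared emission SD from the assignments, until the assignment no
#' longer changes (or 100 iterations, in which case the best path is
#' returned and flagged as non-converged). Likelihood ties in the Viterbi
#' maximization are broken toward the lowest state index.
#'
#' @param traces Tibble with `molecule_id`, `frame_index` and `efficiency`
#'   columns (see [compute_fret()]); extra columns such as `condition`,
#'   `concentration` and `dark` are carried through.
#' @param model A [state_model()]; means are held fixed.
#' @param max_iter Maximum assignment/re-estimation sweeps.
#' @return An object of class `skm_fit` with elements `frames` (input plus a
#'   `state` column, 1 = zero-FRET state), `dwells` (maximal runs of
#'   constant state: `molecule_id`, `state`, `start_frame` 0-based,
#'   `n_frames`, `mean_fret`), `fits` (per-molecule log-likelihood,
#'   iterations, convergence flag, estimated sigma), `model` and
#'   `frame_period`.
#' @export
idealize_skm <- function(traces, model = state_model(), max_iter = 100L) {
  if (!"efficiency" %in% names(traces))
    abort("traces must have an efficiency column (run compute_fret first)",
          class = "fretgate_input_error")
  traces <- dplyr::arrange(traces, .data$molecule_id, .data$frame_index)
  mols <- split(seq_len(nrow(traces)), traces$molecule_id)
  if (any(lengths(mols) < 2))
    abort("idealization needs at least 2 frames per trace",
          class = "fretgate_input_error")
  means <- model$means
  ns <- length(means)
  state <- integer(nrow(traces))
  fits <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    idx <- mols[[i]]
    x <- traces$efficiency[idx]
    n <- length(x)
    # K-means step: hard nearest-mean assignment seeds the model estimates
    prev <- apply(outer(x, means, function(a, b) abs(a - b)), 1, which.min)
    reestimate <- function(path) {
      counts <- matrix(1 / n, ns, ns)
      from <- path[-n]
      to <- path[-1]
      for (k in seq_len(n - 1))
        counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
      freq <- tabulate(path, ns) + 1 / n
      list(a = counts / rowSums(counts), p0 = freq / sum(freq),
           sigma = max(sqrt(mean((x - means[path])^2)), 1e-4))
    }
    est <- reestimate(prev)
    converged <- FALSE
    iter <- 0L
    path <- prev
    for (it in seq_len(max_iter)) {
      iter <- it
      path <- viterbi_gauss_cpp(x, means, est$sigma, log(est$a), log(est$p0))
      if (identical(as.integer(path), prev)) {
        converged <- TRUE
        break
      }
      prev <- as.integer(path)
      est <- reestimate(prev)
    }
    sigma <- est$sigma
    state[idx] <- as.integer(path)
    fits[[i]] <- tibble::tibble(
      molecule_id = traces$molecule_id[idx[1]],
      loglik = attr(path, "loglik"), iterations = iter,
      converged = converged, sigma = sigma)
  }
  if (!all(purrr::map_lgl(fits, "converged")))
    warn("SKM did not converge for some traces; best paths returned")
  frames <- traces
  frames$state <- state
  out <- structure(
    list(frames = frames, dwells = dwell_table(frames), model = model,
         fits = dplyr::bind_rows(fits),
         frame_period = if ("frame_period" %in% names(traces))
           traces$frame_period[1] else NA_real_),
    class = "skm_fit")
  out
}

#' Dwell list of an idealized assignment
#'
#' Maximal runs of consecutive frames in one state. Dwells tile each trace
#' exactly and adjacent dwells are in different states by construction.
#'
#' @param frames Tibble with `molecule_id`, `frame_index`, `state` and
#'   `efficiency` columns.
#' @return Tibble: `molecule_id`, `state`, `start_frame` (0-based),
#'   `n_frames`, `mean_fret` (mean observed efficiency over the dwell).
#' @export
dwell_table <- function(frames) {
  frames |>
    dplyr::arrange(.data$molecule_id, .data$frame_index) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(d$state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(
        state = r$values,
        start_frame = d$frame_index[starts],
        n_frames = r$lengths,
        mean_fret = purrr::map2_dbl(starts, ends,
                                    function(a, b) mean(d$efficiency[a:b])))
    }) |>
    dplyr::ungroup()
}

#' @export
tidy.skm_fit <- function(x, ...) x$dwells

#' @export
glance.skm_fit <- function(x, ...) {
  tibble::tibble(
    n_molecules = nrow(x$fits), n_frames = nrow(x$frames),
    n_dwells = nrow(x$dwells),
    median_sigma = median(x$fits$sigma),
    total_loglik = sum(x$fits$loglik),
    converged = all(x$fits$converged))
}

#' @export
print.skm_fit <- function(x, ...) {
  g <- glance(x)
  cat("Segmental K-means idealization\n")
  cat(sprintf("  %d molecules, %d frames, %d dwells\n",
              g$n_molecules, g$n_frames, g$n_dwells))
  cat(sprintf("  state means: %s (fixed)\n",
              paste(x$model$means, collapse = ", ")))
  cat(sprintf("  shared sigma (median): %.4f; converged: %s\n",
              g$median_sigma, g$converged))
  invisible(x)
}
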