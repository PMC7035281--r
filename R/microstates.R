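#' Microstate map: 2D density of the gate collective variables
#'
#' Projects frames onto the two gate distances, bins them into a 2D
#' histogram with bins anchored at the origin, and labels the top-k strict
#' 8-neighbourhood local maxima as microstates ("a", "b", "c", ...), each
#' with a representative frame (the frame nearest to the peak bin center).
#'
#' @param series Tibble from [gate_distances()] (columns `frame`,
#'   `d_r5_d369`, `d_y268_q361`), or any tibble with those columns.
#' @param bin_width Bin width in Angstrom (default 0.25).
#' @param k Maximum number of microstates to label (default 3).
#' @return Object of class `microstate_map` with `counts` (matrix),
#'   `xedges`, `yedges`, `microstates` (tibble: label, d_r5_d369,
#'   d_y268_q361, count, frame) and `n_frames`.
#' @export
cv_density <- function(series, bin_width = 0.25, k = 3) {
  need <- c("d_r5_d369", "d_y268_q361")
  if (!all(need %in% names(series)))
    abort("series needs d_r5_d369 and d_y268_q361 columns",
          class = "fretgate_input_error")
  if (nrow(series) == 0)
    abort("need at least one frame", class = "fretgate_input_error")
  if (nrow(series) < 100)
    warn("fewer than 100 frames; the density map will be sparse")
  x <- series$d_r5_d369
  y <- series$d_y268_q361
  xe <- seq(floor(min(x) / bin_width) * bin_width,
            ceiling(max(x) / bin_width) * bin_width + bin_width,
            by = bin_width)
  ye <- seq(floor(min(y) / bin_width) * bin_width,
            ceiling(max(y) / bin_width) * bin_width + bin_width,
            by = bin_width)
  i <- findInterval(x, xe, rightmost.closed = TRUE)
  j <- findInterval(y, ye, rightmost.closed = TRUE)
  counts <- matrix(0L, length(xe) - 1L, length(ye) - 1L)
  for (n in seq_along(i)) counts[i[n], j[n]] <- counts[i[n], j[n]] + 1L
  stopifnot(sum(counts) == nrow(series))

  # strict local maxima over the 8-neighbourhood
  padded <- matrix(-1L, nrow(counts) + 2L, ncol(counts) + 2L)
  padded[2:(nrow(counts) + 1L), 2:(ncol(counts) + 1L)] <- counts
  peaks <- list()
  for (a in seq_len(nrow(counts))) {
    for (b in seq_len(ncol(counts))) {
      v <- counts[a, b]
      if (v == 0L) next
      nb <- padded[a:(a + 2L), b:(b + 2L)]
      nb[2, 2] <- -1L
      if (v > max(nb)) peaks[[length(peaks) + 1L]] <- c(a, b, v)
    }
  }
  micro <- tibble::tibble(label = character(0), d_r5_d369 = numeric(0),
                          d_y268_q361 = numeric(0), count = integer(0),
                          frame = integer(0))
  if (length(peaks) > 0) {
    pk <- do.call(rbind, peaks)
    pk <- pk[order(-pk[, 3], pk[, 1], pk[, 2]), , drop = FALSE]
    pk <- utils::head(pk, k)
    micro <- purrr::map_dfr(seq_len(nrow(pk)), function(r) {
      cx <- xe[pk[r, 1]] + bin_width / 2
      cy <- ye[pk[r, 2]] + bin_width / 2
      rep_idx <- which.min((x - cx)^2 + (y - cy)^2)
      tibble::tibble(label = letters[r], d_r5_d369 = cx, d_y268_q361 = cy,
                     count = as.integer(pk[r, 3]),
                     frame = if ("frame" %in% names(series))
                       as.integer(series$frame[rep_idx]) else rep_idx)
    })
  }
  structure(list(counts = counts, xedges = xe, yedges = ye,
                 bin_width = bin_width, microstates = micro,
                 n_frames = nrow(series)),
            class = "microstate_map")
}

#' @export
tidy.microstate_map <- function(x, ...) {
  xm <- utils::head(x$xedges, -1) + x$bin_width / 2
  ym <- utils::head(x$yedges, -1) + x$bin_width / 2
  expand.grid(d_r5_d369 = xm, d_y268_q361 = ym) |>
    tibble::as_tibble() |>
    dplyr::mutate(count = as.vector(x$counts)) |>
    dplyr::filter(.data$count > 0)
}

#' @export
print.microstate_map <- function(x, ...) {
  cat(sprintf("Microstate map: %d frames, %.2f A bins\n",
              x$n_frames, x$bin_width))
  print(x$microstates)
  invisible(x)
}
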