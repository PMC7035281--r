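#' Write fluorescence traces in the tabular trace dialect
#'
#' One row per (molecule, frame) with mandatory header; columns
#' `molecule_id`, `frame_index` (0-based, contiguous per molecule),
#' `donor`, `acceptor_raw`, `condition` and optional `concentration_molar`.
#'
#' @param traces Trace tibble (see [simulate_traces()]).
#' @param path Output file; `.tsv` extension writes tab-separated,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  need <- c("molecule_id", "frame_index", "donor", "acceptor_raw")
  if (!all(need %in% names(traces)))
    abort(paste("traces must have columns:", paste(need, collapse = ", ")),
          class = "fretgate_io_error")
  out <- tibble::tibble(
    molecule_id = traces$molecule_id,
    frame_index = traces$frame_index,
    donor = traces$donor,
    acceptor_raw = traces$acceptor_raw,
    condition = if ("condition" %in% names(traces)) traces$condition else "default",
    concentration_molar = if ("concentration" %in% names(traces))
      traces$concentration else NA_real_)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read fluorescence traces from the tabular trace dialect
#'
#' Autodetects comma- or tab-separation from the header line. Errors are
#' specific: missing columns, malformed numeric fields (named by row),
#' duplicate (molecule, frame) rows, and frame indices that are not
#' contiguous from 0 within each molecule each raise a distinct condition
#' class.
#'
#' @param path Input file.
#' @return Trace tibble with columns `molecule_id`, `frame_index`, `donor`,
#'   `acceptor_raw`, `condition`, `concentration` (molar), ordered by
#'   molecule and frame.
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    abort(paste("no such file:", path), class = "fretgate_io_error")
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  # readr warnings are surfaced below as classed errors instead
  tb <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      molecule_id = readr::col_character(),
      frame_index = readr::col_integer(),
      donor = readr::col_double(),
      acceptor_raw = readr::col_double(),
      .default = readr::col_guess())))
  need <- c("molecule_id", "frame_index", "donor", "acceptor_raw")
  missing <- setdiff(need, names(tb))
  if (length(missing) > 0)
    abort(paste("missing column(s):", paste(missing, collapse = ", ")),
          class = "fretgate_io_missing_column")
  probs <- readr::problems(tb)
  if (nrow(probs) > 0)
    abort(sprintf("malformed value at row %d, column %d (expected %s)",
                  probs$row[1], probs$col[1], probs$expected[1]),
          class = "fretgate_io_parse_error")
  if (anyDuplicated(tb[, c("molecule_id", "frame_index")]) > 0)
    abort("duplicate (molecule_id, frame_index) rows",
          class = "fretgate_io_duplicate_rows")
  tb <- dplyr::arrange(tb, .data$molecule_id, .data$frame_index)
  bad <- tb |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(ok = identical(.data$frame_index,
                                    seq_len(dplyr::n()) - 1L),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    abort(paste("frame_index not contiguous from 0 for molecule(s):",
                paste(utils::head(bad$molecule_id, 5), collapse = ", ")),
          class = "fretgate_io_noncontiguous_frames")
  if (!"condition" %in% names(tb)) tb$condition <- "default"
  if ("concentration_molar" %in% names(tb)) {
    tb$concentration <- as.numeric(tb$concentration_molar)
    tb$concentration_molar <- NULL
  } else if (!"concentration" %in% names(tb)) {
    tb$concentration <- NA_real_
  }
  tb
}
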