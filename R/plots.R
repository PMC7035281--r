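#' @export
autoplot.skm_fit <- function(object, molecule = NULL, ...) {
  fr <- object$frames
  molecule <- molecule %||% fr$molecule_id[1]
  d <- dplyr::filter(fr, .data$molecule_id == molecule)
  dt <- object$frame_period
  if (is.na(dt)) dt <- 1
  d$time <- d$frame_index * dt
  d$ideal <- object$model$means[d$state]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$efficiency),
                       colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ideal), colour = "red") +
    ggplot2::labs(x = if (is.na(object$frame_period)) "frame" else "time (s)",
                  y = "FRET efficiency", title = molecule) +
    ggplot2::coord_cartesian(ylim = c(-0.1, 1)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tdp <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$fret_before, y = .data$fret_after,
                                 fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "FRET before transition", y = "FRET after transition",
                  subtitle = sprintf("%.2f transitions s^-1",
                                     object$transitions_per_second)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dose_response_fit <- function(object, ...) {
  d <- object$data
  concs <- range(d$concentration)
  grid <- exp(seq(log(concs[1]), log(concs[2]), length.out = 100))
  curves <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                  y = .data$occupancy,
                                  colour = factor(.data$state))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$occupancy - .data$se,
                                        ymax = .data$occupancy + .data$se),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (M)", y = "state occupancy",
                  colour = "state",
                  subtitle = sprintf("shared EC50 = %.2f uM (Hill fixed at %.1f)",
                                     object$ec50 * 1e6, object$hill)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.binding_fit <- function(object, percent_of_max = TRUE, ...) {
  d <- dplyr::filter(object$data, !.data$nonspecific)
  grid <- exp(seq(log(min(d$concentration_nM)), log(max(d$concentration_nM)),
                  length.out = 100))
  spec_curve <- object$bmax * grid / (object$kd + grid)
  if (percent_of_max) {
    d$y <- 100 * (d$signal - object$ns_slope * d$concentration_nM) / object$bmax
    curve <- tibble::tibble(concentration_nM = grid,
                            y = 100 * spec_curve / object$bmax)
    ylab <- "binding (% of max)"
  } else {
    d$y <- d$signal
    curve <- tibble::tibble(concentration_nM = grid,
                            y = spec_curve + object$ns_slope * grid)
    ylab <- "signal"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_nM, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand (nM)", y = ylab,
                  subtitle = sprintf("Kd = %.3g +/- %.2g nM",
                                     object$kd, object$kd_se)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.microstate_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$d_r5_d369, y = .data$d_y268_q361)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::geom_label(data = object$microstates,
                        ggplot2::aes(label = .data$label), fill = "white") +
    ggplot2::labs(x = "d(R5-D369) (Å)", y = "d(Y268-Q361) (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hydration_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$count, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("%s waters per frame", object$value_col),
                  y = "probability") +
    ggplot2::theme_minimal()
}
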