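#' Simulate saturation-binding data
#'
#' Total signal follows the one-site model plus a linear nonspecific
#' component, `S(L) = Bmax L / (Kd + L) + ns L`, multiplied by lognormal
#' noise with coefficient of variation `cv` (mean 1). Paired nonspecific
#' measurements (`ns L` with the same noise model) are emitted alongside,
#' mimicking wells measured in the presence of excess cold ligand.
#'
#' @param kd Dissociation constant (nM), positive.
#' @param bmax Maximal specific signal (arbitrary units), positive.
#' @param ns_slope Nonspecific signal per nM of ligand.
#' @param concentrations Ligand concentrations (nM), all positive.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble: `concentration_nM`, `signal`, `replicate`, `nonspecific`.
#' @export
simulate_binding <- function(kd, bmax, ns_slope = 0, concentrations,
                             cv = 0.05, replicates = 3, seed = 1L) {
  if (kd <= 0 || bmax <= 0 || cv < 0)
    abort("kd and bmax must be positive and cv non-negative",
          class = "fretgate_config_error")
  if (any(concentrations <= 0))
    abort("concentrations must be positive", class = "fretgate_config_error")
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) if (cv == 0) rep(1, n) else
    exp(rnorm(n, -sdlog^2 / 2, sdlog))
  grid <- tidyr::expand_grid(concentration_nM = concentrations,
                             replicate = seq_len(replicates))
  l <- grid$concentration_nM
  total <- (bmax * l / (kd + l) + ns_slope * l) * noise(nrow(grid))
  nsp <- (ns_slope * l) * noise(nrow(grid))
  dplyr::bind_rows(
    dplyr::mutate(grid, signal = total, nonspecific = FALSE),
    dplyr::mutate(grid, signal = nsp, nonspecific = TRUE)) |>
    dplyr::arrange(.data$concentration_nM, .data$replicate,
                   .data$nonspecific)
}

#' Fit a one-site specific binding model
#'
#' Nonlinear least squares of `B(L) = Bmax L / (Kd + L)` for specific
#' binding. By default total and nonspecific rows are fitted jointly, the
#' nonspecific component modelled as a straight line `NS(L) = m L` shared
#' between them; with `subtract_paired = TRUE` the mean nonspecific signal
#' per concentration is subtracted from the paired totals first and only
#' the specific model is fitted. Standard errors come from the covariance
#' matrix of the fit; a residual bootstrap is available behind a flag.
#' The normalized (percent-of-max) curve uses the fitted Bmax.
#'
#' @param data Tibble with `concentration_nM`, `signal` and optionally
#'   `nonspecific` (logical) and `replicate` columns; at least 4 distinct
#'   positive concentrations.
#' @param subtract_paired Subtract paired nonspecific means instead of
#'   fitting jointly.
#' @param bootstrap Number of case-resampling bootstrap replicates for SEs
#'   (0 disables; fixed internal seed offset keeps it reproducible).
#' @param seed Seed used when `bootstrap > 0`.
#' @return Object of class `binding_fit` with `kd`, `bmax`, `ns_slope`,
#'   their SEs, residual summary, the percent-of-max table, and flags.
#' @export
fit_one_site <- function(data, subtract_paired = FALSE, bootstrap = 0,
                         seed = 1L) {
  if (!all(c("concentration_nM", "signal") %in% names(data)))
    abort("data needs concentration_nM and signal columns",
          class = "fretgate_input_error")
  if (!"nonspecific" %in% names(data)) data$nonspecific <- FALSE
  if (any(data$concentration_nM <= 0))
    abort("concentrations must be positive", class = "fretgate_input_error")
  if (length(unique(data$concentration_nM[!data$nonspecific])) < 4)
    abort("need at least 4 distinct concentrations",
          class = "fretgate_input_error")

  fit_data <- data
  if (subtract_paired && any(data$nonspecific)) {
    ns_mean <- data |>
      dplyr::filter(.data$nonspecific) |>
      dplyr::group_by(.data$concentration_nM) |>
      dplyr::summarise(ns = mean(.data$signal), .groups = "drop")
    fit_data <- data |>
      dplyr::filter(!.data$nonspecific) |>
      dplyr::left_join(ns_mean, by = "concentration_nM") |>
      dplyr::mutate(signal = .data$signal - dplyr::coalesce(.data$ns, 0),
                    nonspecific = FALSE) |>
      dplyr::select(-"ns")
  }

  l <- fit_data$concentration_nM
  y <- fit_data$signal
  is_ns <- fit_data$nonspecific
  spec_tbl <- fit_data[!is_ns, ]
  bmax0 <- max(spec_tbl$signal)
  half <- spec_tbl$concentration_nM[
    which.min(abs(spec_tbl$signal - bmax0 / 2))]
  kd0 <- max(half, min(l) / 2)
  m0 <- if (any(is_ns))
    sum(y[is_ns] * l[is_ns]) / sum(l[is_ns]^2) else 0
  use_ns <- any(is_ns) || m0 > 0

  df <- data.frame(l = l, y = y, spec = as.numeric(!is_ns))
  fit <- if (use_ns) {
    minpack.lm::nlsLM(
      y ~ spec * bmax * l / (kd + l) + m * l, data = df,
      start = list(kd = kd0, bmax = bmax0, m = m0),
      lower = c(kd = 1e-9, bmax = 1e-9, m = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      y ~ bmax * l / (kd + l), data = df,
      start = list(kd = kd0, bmax = bmax0),
      lower = c(kd = 1e-9, bmax = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  at_bound <- cf[["kd"]] <= 2e-9

  if (bootstrap > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap, {
      idx <- sample.int(nrow(fit_data), replace = TRUE)
      bf <- tryCatch(
        fit_one_site(fit_data[idx, ], subtract_paired = FALSE),
        error = function(e) NULL)
      if (is.null(bf)) NA_real_ else bf$kd
    })
    se[["kd"]] <- sd(boots, na.rm = TRUE)
  }

  curve_l <- sort(unique(spec_tbl$concentration_nM))
  normalized <- tibble::tibble(
    concentration_nM = curve_l,
    percent_of_max = 100 * curve_l / (cf[["kd"]] + curve_l))
  structure(list(
    kd = cf[["kd"]], kd_se = se[["kd"]],
    bmax = cf[["bmax"]], bmax_se = se[["bmax"]],
    ns_slope = if (use_ns) cf[["m"]] else 0,
    ns_slope_se = if (use_ns) se[["m"]] else 0,
    residual_sd = sd(residuals(fit)),
    normalized = normalized, at_bound = at_bound,
    subtract_paired = subtract_paired, fit = fit, data = data),
    class = "binding_fit")
}

#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "bmax", "ns_slope"),
    estimate = c(x$kd, x$bmax, x$ns_slope),
    std.error = c(x$kd_se, x$bmax_se, x$ns_slope_se))
}

#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, kd_se = x$kd_se, bmax = x$bmax,
                 bmax_se = x$bmax_se, ns_slope = x$ns_slope,
                 residual_sd = x$residual_sd, at_bound = x$at_bound)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-site specific binding fit\n")
  cat(sprintf("  Kd   = %.4g +/- %.3g nM%s\n", x$kd, x$kd_se,
              if (x$at_bound) "  [estimate at bound]" else ""))
  cat(sprintf("  Bmax = %.4g +/- %.3g\n", x$bmax, x$bmax_se))
  cat(sprintf("  nonspecific slope = %.4g +/- %.3g per nM\n",
              x$ns_slope, x$ns_slope_se))
  invisible(x)
}

#' Affinity fold-change between two binding fits
#'
#' Ratio `Kd_a / Kd_b` with first-order propagated standard error.
#'
#' @param fit_a,fit_b `binding_fit` objects.
#' @return Tibble with `ratio` and `se`.
#' @export
fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  if (!is.finite(fit_a$kd) || !is.finite(fit_b$kd) || fit_b$kd <= 0)
    abort("both fits need finite positive Kd estimates",
          class = "fretgate_fit_error")
  r <- fit_a$kd / fit_b$kd
  se <- r * sqrt((fit_a$kd_se / fit_a$kd)^2 + (fit_b$kd_se / fit_b$kd)^2)
  tibble::tibble(ratio = r, se = se)
}
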