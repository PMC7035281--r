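#' Fit a shared-EC50 dose-response model to state occupancies
#'
#' Weighted least squares of
#' `occ_s(c) = base_s + amp_s * c^h / (c^h + EC50^h)` jointly over states,
#' with one shared EC50 and the Hill coefficient `h` held fixed (1.0 by
#' default, as a single binding event drives all occupancy changes).
#' Weights are `1 / se^2` with a floor to keep noiseless data usable. The
#' EC50 is estimated on the log scale so positivity is automatic.
#'
#' @param occ Occupancy table from [occupancy()]: columns `concentration`
#'   (molar), `state`, `occupancy` and optionally `se`.
#' @param hill Fixed Hill coefficient (default 1.0).
#' @return Object of class `dose_response_fit` with `ec50`, `ec50_se`
#'   (molar), per-state `coefficients` (base, amplitude, SEs), `hill`,
#'   flags for extrapolation beyond the tested range, and the data.
#' @export
fit_dose_response <- function(occ, hill = 1.0) {
  need <- c("concentration", "state", "occupancy")
  if (!all(need %in% names(occ)))
    abort(paste("occupancy table needs columns:", paste(need, collapse = ", ")),
          class = "fretgate_input_error")
  occ <- dplyr::filter(occ, !is.na(.data$concentration), .data$state > 1L)
  concs <- sort(unique(occ$concentration))
  if (length(concs) < 4)
    abort("dose-response fitting needs at least 4 concentrations",
          class = "fretgate_input_error")
  states <- sort(unique(occ$state))
  if (!"se" %in% names(occ)) occ$se <- NA_real_
  w_se <- pmax(occ$se, 1e-4)
  w_se[is.na(w_se)] <- 1e-4
  # identifiability: some state must actually move with concentration
  moves <- occ |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(range = diff(range(.data$occupancy)), .groups = "drop")
  if (all(moves$range < 1e-8))
    abort("occupancies do not vary with concentration; EC50 unidentifiable",
          class = "fretgate_fit_error")

  sidx <- match(occ$state, states)
  npar_s <- length(states)
  resid_fun <- function(p) {
    ec50 <- exp(p[1])
    base <- p[2:(1 + npar_s)]
    amp <- p[(2 + npar_s):(1 + 2 * npar_s)]
    frac <- occ$concentration^hill / (occ$concentration^hill + ec50^hill)
    pred <- base[sidx] + amp[sidx] * frac
    (occ$occupancy - pred) / w_se
  }
  base0 <- vapply(states, function(s)
    occ$occupancy[occ$state == s & occ$concentration == min(concs)][1],
    numeric(1))
  top0 <- vapply(states, function(s)
    occ$occupancy[occ$state == s & occ$concentration == max(concs)][1],
    numeric(1))
  p0 <- c(log(exp(mean(log(concs)))), base0, top0 - base0)
  fit <- minpack.lm::nls.lm(
    p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000))
  if (fit$info %in% c(0, 9))
    abort("dose-response fit did not converge", class = "fretgate_fit_error")
  converged <- !fit$info %in% 5
  if (!converged)
    warn("dose-response fit stopped at the evaluation limit; estimates flagged")
  p <- fit$par
  ec50 <- exp(p[1])
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, length(p)))
  coefs <- tibble::tibble(
    state = states,
    base = p[2:(1 + npar_s)], base_se = ses[2:(1 + npar_s)],
    amplitude = p[(2 + npar_s):(1 + 2 * npar_s)],
    amplitude_se = ses[(2 + npar_s):(1 + 2 * npar_s)])
  structure(list(
    ec50 = ec50, ec50_se = ec50 * ses[1], hill = hill,
    coefficients = coefs, data = occ,
    extrapolated = ec50 < min(concs) | ec50 > max(concs),
    deviance = fit$deviance, converged = converged),
    class = "dose_response_fit")
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  x$coefficients |>
    dplyr::mutate(ec50 = x$ec50, ec50_se = x$ec50_se, hill = x$hill)
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, ec50_se = x$ec50_se, hill = x$hill,
                 deviance = x$deviance, extrapolated = x$extrapolated,
                 converged = x$converged)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (Hill fixed at %.1f)\n", x$hill))
  cat(sprintf("  EC50 = %.3g +/- %.2g M (%.2f uM)%s\n", x$ec50, x$ec50_se,
              x$ec50 * 1e6,
              if (x$extrapolated) "  [extrapolated beyond tested range]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Predicted dose-response curves
#'
#' @param object A `dose_response_fit`.
#' @param concentrations Molar concentrations to predict at.
#' @param ... Unused.
#' @return Tibble with `concentration`, `state`, `occupancy`.
#' @export
predict.dose_response_fit <- function(object, concentrations, ...) {
  frac <- concentrations^object$hill /
    (concentrations^object$hill + object$ec50^object$hill)
  purrr::pmap_dfr(object$coefficients, function(state, base, amplitude, ...) {
    tibble::tibble(concentration = concentrations, state = state,
                   occupancy = base + amplitude * frac)
  })
}
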