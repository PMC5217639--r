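# Michaelis-Menten kinetics: velocity model, nonlinear least-squares
# fitting of Km and Vmax, and wild-type vs mutant comparison.

#' Michaelis-Menten velocity
#'
#' `v = Vmax * S / (Km + S)`.
#'
#' @param S Substrate concentration(s), uM, `>= 0`.
#' @param Km Michaelis constant, uM, `> 0`.
#' @param Vmax Maximal velocity, pmol/min, `> 0`.
#' @return Velocity in pmol/min (vectorized over `S`).
#' @export
mm_velocity <- function(S, Km, Vmax) {
  if (!is.numeric(Km) || Km <= 0) stop_validation("Km must be positive")
  if (!is.numeric(Vmax) || Vmax <= 0) stop_validation("Vmax must be positive")
  if (any(S < 0)) stop_validation("substrate concentrations must be non-negative")
  Vmax * S / (Km + S)
}

#' Fit the Michaelis-Menten model by nonlinear least squares
#'
#' Levenberg-Marquardt least squares of `v = Vmax * S / (Km + S)` on a
#' velocity dataset. Replicates enter as independent points. Starting
#' values: `Vmax0 = 1.2 * max(v)`; `Km0` is the concentration whose
#' velocity is nearest half of `max(v)`. Standard errors come from the
#' local curvature of the residual surface. Non-convergence is flagged on
#' the result, not thrown.
#'
#' @param data A tibble with columns `concentration_uM` and
#'   `velocity_pmol_min` (plus optional `peptide`, `replicate`), e.g. from
#'   [simulate_velocities()] or `readr::read_csv()`.
#' @return An object of class `kinetic_fit`: list with `peptide`, `Km`,
#'   `Vmax`, `se_Km`, `se_Vmax`, `efficiency` (`Vmax/Km`), `rss`,
#'   `converged`, `n`, and the fitting `data`. Use [tidy()], [glance()]
#'   and [autoplot()] on it.
#' @export
fit_michaelis_menten <- function(data) {
  need <- c("concentration_uM", "velocity_pmol_min")
  if (!all(need %in% names(data))) {
    stop_validation("data needs columns concentration_uM and velocity_pmol_min")
  }
  S <- data$concentration_uM
  v <- data$velocity_pmol_min
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop_validation("concentrations must be finite and positive")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop_validation("velocities must be finite and non-negative")
  }
  if (dplyr::n_distinct(S) < 3) {
    stop_validation("at least 3 distinct concentrations are required for fitting")
  }
  vmax0 <- 1.2 * max(v)
  km0 <- S[which.min(abs(v - max(v) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      velocity_pmol_min ~ Vmax * concentration_uM / (Km + concentration_uM),
      data = data,
      start = list(Vmax = vmax0, Km = km0),
      lower = c(Vmax = 1e-12, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  peptide <- if ("peptide" %in% names(data)) data$peptide[1] else NA_character_
  if (is.null(fit)) {
    return(structure(
      list(peptide = peptide, Km = NA_real_, Vmax = NA_real_,
           se_Km = NA_real_, se_Vmax = NA_real_, efficiency = NA_real_,
           rss = NA_real_, converged = FALSE, n = length(v), data = data,
           fit = NULL),
      class = "kinetic_fit"
    ))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  # a flat velocity profile drives Km to the box bound: not identified
  converged <- fit$convInfo$isConv && est[["Km"]] > 1e-9 &&
    est[["Vmax"]] > 1e-9 && all(is.finite(se))
  structure(
    list(
      peptide = peptide,
      Km = est[["Km"]], Vmax = est[["Vmax"]],
      se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
      efficiency = est[["Vmax"]] / est[["Km"]],
      rss = sum(stats::resid(fit)^2),
      converged = converged, n = length(v), data = data, fit = fit
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit%s (%d points)\n  Km   = %.4g +/- %.3g uM\n  Vmax = %.4g +/- %.3g pmol/min\n  Vmax/Km = %.4g; RSS = %.4g; converged: %s\n",
    if (is.na(x$peptide)) "" else paste0(" [", x$peptide, "]"),
    x$n, x$Km, x$se_Km, x$Vmax, x$se_Vmax, x$efficiency, x$rss, x$converged
  ))
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Vmax", "Km"),
    estimate = c(x$Vmax, x$Km),
    std.error = c(x$se_Vmax, x$se_Km)
  )
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `peptide`, `Km`, `Vmax`, `efficiency`, `rss`,
#'   `n`, `converged`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    peptide = x$peptide, Km = x$Km, Vmax = x$Vmax,
    efficiency = x$efficiency, rss = x$rss, n = x$n, converged = x$converged
  )
}

#' Saturation-curve plot of a Michaelis-Menten fit
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object: measured points and the fitted curve.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$concentration_uM) * 1.05, length.out = 200)
  curve <- tibble::tibble(
    concentration_uM = s_grid,
    velocity_pmol_min = mm_velocity(s_grid, object$Km, object$Vmax)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_uM,
                               y = .data$velocity_pmol_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(
      x = "substrate concentration (uM)", y = "velocity (pmol/min)",
      title = if (is.na(object$peptide)) NULL else object$peptide,
      subtitle = sprintf("Km = %.3g uM, Vmax = %.3g pmol/min",
                         object$Km, object$Vmax)
    ) +
    ggplot2::theme_minimal()
}

#' Compare two Michaelis-Menten fits
#'
#' Ratios of Vmax, Km and catalytic efficiency (a / b) with standard
#' errors propagated to first order:
#' `se(r) = r * sqrt((se_a/a)^2 + (se_b/b)^2)`.
#'
#' @param fit_a,fit_b Converged `kinetic_fit` objects (e.g. wild type and
#'   mutant).
#' @return A one-row tibble: `peptide_a`, `peptide_b`, `vmax_ratio`,
#'   `vmax_ratio_se`, `km_ratio`, `km_ratio_se`, `efficiency_ratio`,
#'   `efficiency_ratio_se`.
#' @export
compare_kinetics <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "kinetic_fit") || !inherits(fit_b, "kinetic_fit")) {
    stop_usage("compare_kinetics expects two kinetic_fit objects")
  }
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop_validation("both fits must have converged")
  }
  ratio_se <- function(a, sa, b, sb) (a / b) * sqrt((sa / a)^2 + (sb / b)^2)
  eff_se <- function(f) f$efficiency * sqrt((f$se_Vmax / f$Vmax)^2 + (f$se_Km / f$Km)^2)
  tibble::tibble(
    peptide_a = fit_a$peptide, peptide_b = fit_b$peptide,
    vmax_ratio = fit_a$Vmax / fit_b$Vmax,
    vmax_ratio_se = ratio_se(fit_a$Vmax, fit_a$se_Vmax, fit_b$Vmax, fit_b$se_Vmax),
    km_ratio = fit_a$Km / fit_b$Km,
    km_ratio_se = ratio_se(fit_a$Km, fit_a$se_Km, fit_b$Km, fit_b$se_Km),
    efficiency_ratio = fit_a$efficiency / fit_b$efficiency,
    efficiency_ratio_se = ratio_se(fit_a$efficiency, eff_se(fit_a),
                                   fit_b$efficiency, eff_se(fit_b))
  )
}
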