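#' Fit a one-phase exponential decay along the AP axis
#'
#' Least-squares fit of `y(x) = P + (y0 - P) * exp(-K * x)` (the
#' plateau / Y0 / rate-constant parameterization used by common curve
#' fitting software) with constraints `K >= 0`, `P >= 0`, via
#' Levenberg-Marquardt. Initial values: `P = min(y)`, `y0 = max(y)`, `K`
#' from a log-linear fit of `y - P`; on failure the fit is restarted from
#' a fixed ladder of 5 alternative starts before being reported
#' unconverged (with the best parameters found).
#'
#' `r_squared = 1 - SS_res / SS_tot` about the mean; the degenerate
#' all-constant case (`SS_tot = 0`) is reported as `R^2 = 0` with
#' `P = y0 = const`, `K = 0`.
#'
#' @param ap_um AP positions (um), length >= 4
#' @param y intensities (>= 0)
#' @param weights optional per-point weights
#' @return a `decay_fit`: list with `plateau`, `y0`, `K`, `r_squared`,
#'   `n_points`, `converged`
#' @export
fit_one_phase_decay <- function(ap_um, y, weights = NULL) {
  if (length(ap_um) < 4) stopf("need at least 4 points for the decay fit")
  if (length(y) != length(ap_um)) stopf("ap_um and y lengths differ")
  if (any(y < 0)) stopf("intensities must be >= 0")
  if (is.null(weights)) weights <- rep(1, length(y))
  sst <- sum(weights * (y - stats::weighted.mean(y, weights))^2)
  if (sst == 0) {
    return(structure(list(plateau = y[1], y0 = y[1], K = 0, r_squared = 0,
                          n_points = length(y), converged = TRUE),
                     class = "decay_fit"))
  }
  p0 <- max(min(y), 0)
  y00 <- max(y)
  span0 <- max(y00 - p0, 1e-12)
  pos <- y - p0 > 1e-3 * span0
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos] - p0 + 1e-6 * span0) ~ ap_um[pos]))[2]
    max(-sl, 1e-4)
  } else 1e-2
  df <- data.frame(x = ap_um, y = y)
  best <- NULL
  # deterministic restart ladder: rate constant is the fragile parameter
  starts <- list(c(P = p0, y0 = y00, K = k0),
                 c(P = p0, y0 = y00, K = k0 * 4),
                 c(P = p0, y0 = y00, K = k0 / 4),
                 c(P = 0, y0 = y00, K = 0.1),
                 c(P = p0 * 0.5, y0 = y00 * 1.2, K = k0 * 2),
                 c(P = 0, y0 = mean(y), K = 0.01))
  converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ P + (y0 - P) * exp(-K * x), data = df,
                        start = as.list(st), weights = weights,
                        lower = c(P = 0, y0 = -Inf, K = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(weights * stats::residuals(fit)^2)
      if (is.null(best) || ssr < best$ssr)
        best <- list(coef = stats::coef(fit), ssr = ssr)
      converged <- TRUE
      break
    }
  }
  if (is.null(best)) {
    best <- list(coef = c(P = p0, y0 = y00, K = k0),
                 ssr = sum(weights * (y - (p0 + (y00 - p0) * exp(-k0 * ap_um)))^2))
  }
  co <- best$coef
  structure(list(plateau = unname(co["P"]), y0 = unname(co["y0"]),
                 K = unname(co["K"]),
                 r_squared = 1 - best$ssr / sst,
                 n_points = length(y), converged = converged),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y = %.4g + (%.4g - %.4g) exp(-%.4g x);  R^2 = %.4f (n = %d%s)\n",
              x$plateau, x$y0, x$plateau, x$K, x$r_squared, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predicted decay value at AP positions
#' @param fit a `decay_fit`
#' @param ap_um AP positions (um)
#' @return predicted intensities
#' @export
predict_decay <- function(fit, ap_um) {
  stopifnot(inherits(fit, "decay_fit"))
  fit$plateau + (fit$y0 - fit$plateau) * exp(-fit$K * ap_um)
}

#' Normalize to the one-phase-decay prediction
#'
#' Each cell's value is divided by the decay curve fitted on the internal
#' control cells, evaluated at that cell's AP position, so control cells
#' sit at ~1 and clone cells read out as local fold change along the
#' gradient. The divisor is clamped at `floor_eps` (default 5% of the
#' fitted y0) where the curve approaches zero; clamped cells are flagged.
#'
#' @param values background-subtracted intensities
#' @param ap_um AP positions (um)
#' @param fit a `decay_fit` from the control cells
#' @param floor_eps divisor floor (default `0.05 * fit$y0`)
#' @param accept_unconverged allow normalizing with an unconverged fit
#' @return list: `normalized`, `floored` (logical flags)
#' @export
normalize_to_decay_prediction <- function(values, ap_um, fit,
                                          floor_eps = NULL,
                                          accept_unconverged = FALSE) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!fit$converged && !accept_unconverged)
    stopf("decay fit did not converge; pass accept_unconverged = TRUE to override")
  if (is.null(floor_eps)) floor_eps <- 0.05 * abs(fit$y0)
  pred <- predict_decay(fit, ap_um)
  floored <- pred < floor_eps
  list(normalized = values / pmax(pred, floor_eps), floored = floored)
}
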