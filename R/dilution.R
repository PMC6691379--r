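## Limiting-dilution frequency estimation under the single-hit Poisson
## model, and the immunohistochemistry combined score.

#' Limiting-dilution frequency fit
#'
#' Under the single-hit Poisson model the fraction of sphere-negative
#' wells at dose `n` cells/well is `exp(-f n)`, so
#' `ln(fraction negative)` is linear in dose through the origin with
#' slope `-f`. The fit is weighted least squares with inverse-variance
#' weights `wells * p / (1 - p)` (the delta-method variance of
#' `ln(p-hat)`; all-negative doses use a half-count continuity
#' correction in the weight only). Dose-0 control rows and doses with
#' no negative wells (log undefined) are excluded from the fit.
#'
#' @param wells well-count table with columns `dose`, `wells`,
#'   `negative` (e.g. from [simulate_dilution()] or [read_dilution()]).
#' @return A `dilution_fit`: list with `frequency` (`= -slope`),
#'   `slope`, `se`, `df`, `ci95` (for the frequency), `n_doses`,
#'   `fitted` (the per-dose table used), `residual_ss`.
#' @export
dilution_fit <- function(wells) {
  stop_if_not_cols(wells, c("dose", "wells", "negative"), "dilution table")
  tb <- wells[wells$dose > 0, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no positive doses to fit", call. = FALSE)
  if (all(tb$negative == 0)) {
    stop("frequency too high to estimate: no negative wells at any dose",
         call. = FALSE)
  }
  tb <- tb[tb$negative > 0, , drop = FALSE]
  if (nrow(tb) < 2L) {
    stop("need at least two doses with a positive negative-well fraction",
         call. = FALSE)
  }
  p <- tb$negative / tb$wells
  y <- log(p)
  ## continuity-corrected p for the weight when p = 1 (zero variance)
  pw <- pmin(p, (tb$wells - 0.5) / tb$wells)
  w <- tb$wells * pw / (1 - pw)
  fit <- stats::lm(y ~ 0 + dose, data = data.frame(y = y, dose = tb$dose),
                   weights = w)
  slope <- unname(coef(fit)[1])
  ## noiseless input yields a perfect fit; summary()'s warning about it
  ## is expected there, not a defect
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[1, 2]
  df <- fit$df.residual
  tcrit <- if (df > 0) stats::qt(0.975, df) else Inf
  structure(list(frequency = -slope, slope = slope, se = se, df = df,
                 ci95 = -slope + c(-1, 1) * tcrit * se,
                 n_doses = nrow(tb),
                 fitted = data.frame(dose = tb$dose, wells = tb$wells,
                                     negative = tb$negative,
                                     fraction_negative = p,
                                     log_fraction = y, weight = w),
                 residual_ss = sum(w * stats::residuals(fit)^2)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(paste0("dilution_fit: frequency 1/%.1f (f = %.5g), ",
                     "95%% CI [%.5g, %.5g], %d doses\n"),
              1 / x$frequency, x$frequency, x$ci95[1], x$ci95[2],
              x$n_doses))
  invisible(x)
}

#' Compare the slopes of two limiting-dilution fits
#'
#' Two-slope contrast `(b1 - b2) / sqrt(se1^2 + se2^2)` with
#' Welch-Satterthwaite degrees of freedom — the regression-slope
#' comparison used to test whether two conditions differ in
#' initiating-cell frequency.
#'
#' @param fit_a,fit_b `dilution_fit` objects.
#' @return List with `statistic` (t), `df`, `p`, and the frequency
#'   difference.
#' @export
compare_dilution_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dilution_fit"), inherits(fit_b, "dilution_fit"))
  delta <- fit_a$slope - fit_b$slope
  se <- sqrt(fit_a$se^2 + fit_b$se^2)
  df <- se^4 / (fit_a$se^4 / fit_a$df + fit_b$se^4 / fit_b$df)
  tstat <- delta / se
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       frequency_difference = fit_b$frequency - fit_a$frequency)
}

#' Immunohistochemistry combined score
#'
#' The combined score is the product of the positive-cell percentage
#' bin (0-6) and the staining intensity (0-3), giving a 0-18 range.
#'
#' @param positivity_bin integer(s) in 0..6.
#' @param intensity integer(s) in 0..3.
#' @return Integer score(s) in 0..18.
#' @export
#' @examples
#' ihc_combined_score(6, 3)  # 18
ihc_combined_score <- function(positivity_bin, intensity) {
  if (any(positivity_bin != as.integer(positivity_bin)) ||
      any(intensity != as.integer(intensity))) {
    stop("scores must be integers", call. = FALSE)
  }
  if (any(positivity_bin < 0 | positivity_bin > 6)) {
    stop("positivity_bin must be in 0..6", call. = FALSE)
  }
  if (any(intensity < 0 | intensity > 3)) {
    stop("intensity must be in 0..3", call. = FALSE)
  }
  as.integer(positivity_bin) * as.integer(intensity)
}
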