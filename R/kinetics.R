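# Enzyme-kinetics analysis: standard curves, initial rates from coupled
# assay traces, Michaelis-Menten and substrate-inhibition fits with
# first-order error propagation into kcat/KM, mutant-activity
# normalization, and the Pi -> PPi stoichiometric conversion for
# pyrophosphatase-coupled readouts.

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `absorbance = slope * conc + intercept`,
#' as used for NADH (kinase assay, 340 nm) and inorganic-phosphate
#' (malachite green, 635 nm) calibration.
#'
#' @param conc analyte concentrations (uM), at least two distinct
#'   levels.
#' @param absorbance matching absorbances (AU).
#' @param incubation_time optional tag (e.g. minutes of colour
#'   development) carried along for bookkeeping.
#' @return an object of class `standard_curve` with elements `slope`
#'   (AU/uM), `intercept` (AU), `r_squared` and the underlying `lm` fit.
#' @examples
#' sc <- fit_standard_curve(c(0, 100), c(0, 0.622))
#' sc$slope  # 0.00622 AU/uM, i.e. the NADH extinction 6220 / M / cm
#' @export
fit_standard_curve <- function(conc, absorbance, incubation_time = NA) {
  stopifnot(is.numeric(conc), is.numeric(absorbance),
            length(conc) == length(absorbance), length(conc) >= 2)
  if (length(unique(conc)) < 2)
    stop("singular design: need at least two distinct concentrations")
  fit <- stats::lm(absorbance ~ conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("standard curve slope is zero")
  r2 <- if (stats::var(absorbance) > 0)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, incubation_time = incubation_time,
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve: absorbance =", signif(x$slope, 4), "* conc +",
      signif(x$intercept, 4), "\n")
  if (!is.na(x$r_squared)) cat("R-squared:", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' @export
predict.standard_curve <- function(object, conc, ...) {
  object$slope * conc + object$intercept
}

#' Invert a standard curve
#'
#' @param curve a [fit_standard_curve()] result.
#' @param absorbance absorbances (AU).
#' @return concentrations (uM).
#' @export
conc_from_abs <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Initial rate from an absorbance trace
#'
#' Least-squares slope of the absorbance over a time window, converted
#' to a concentration rate via the standard curve. Sign convention: for
#' the 340 nm tag the readout is NADH consumption (one NADH oxidized per
#' ADP formed in the pyruvate kinase / lactate dehydrogenase coupling),
#' so a falling trace yields a positive rate; for the 635 nm tag the
#' readout is product (Pi) appearance and a rising trace is positive.
#'
#' @param trace data.frame with `time_s` and `absorbance` columns, time
#'   strictly increasing.
#' @param curve the matching [fit_standard_curve()].
#' @param window `c(t0, t1)` in seconds; at least 3 points must fall in
#'   it.
#' @param wavelength `"340"` (consumption) or `"635"` (production).
#' @param r2_floor linearity floor; a window R-squared below it triggers
#'   a warning (the rate is still returned).
#' @return rate in uM/s with attribute `r_squared`.
#' @export
initial_rate <- function(trace, curve, window = c(0, 60),
                         wavelength = c("340", "635"), r2_floor = 0.9) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "absorbance") %in% names(trace)),
            inherits(curve, "standard_curve"),
            is.numeric(window), length(window) == 2)
  wavelength <- match.arg(wavelength)
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("trace time must be strictly increasing")
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(sel) < 3)
    stop("window must contain at least 3 trace points")
  d <- trace[sel, ]
  fit <- stats::lm(absorbance ~ time_s, data = d)
  r2 <- if (stats::var(d$absorbance) > 0)
    suppressWarnings(summary(fit)$r.squared) else 1
  if (r2 < r2_floor)
    warning("trace window is nonlinear (R-squared = ",
            signif(r2, 3), ")")
  abs_slope <- unname(stats::coef(fit)[2])       # AU/s
  conc_slope <- abs_slope / curve$slope          # uM/s
  rate <- if (wavelength == "340") -conc_slope else conc_slope
  structure(rate, r_squared = r2)
}

# coerce a rate dataset into (S, v) with an enzyme concentration
as_rate_data <- function(data, e0_uM) {
  stopifnot(is.data.frame(data))
  scol <- intersect(c("substrate_conc_uM", "S"), names(data))[1]
  vcol <- intersect(c("rate_uM_per_s", "rate", "v"), names(data))[1]
  if (is.na(scol) || is.na(vcol))
    stop("rate data needs substrate_conc_uM and rate_uM_per_s columns")
  if (missing(e0_uM) || is.null(e0_uM)) e0_uM <- attr(data, "E0_uM")
  if (is.null(e0_uM) || !is_number(e0_uM) || e0_uM <= 0)
    stop("a positive enzyme concentration e0_uM is required")
  S <- data[[scol]]; v <- data[[vcol]]
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  list(S = S, v = v, E0 = e0_uM)
}

new_kinetic_fit <- function(model, KM, KM_sd, kcat, kcat_sd,
                            Ki = NULL, Ki_sd = NULL, E0, fit, S, v,
                            extra = list()) {
  eff <- efficiency(kcat, kcat_sd, KM, KM_sd)
  structure(c(list(model = model, KM = KM, KM_sd = KM_sd,
                   kcat = kcat, kcat_sd = kcat_sd,
                   Ki = Ki, Ki_sd = Ki_sd,
                   eff = eff$eff, eff_sd = eff$eff_sd,
                   E0 = E0, fit = fit, S = S, v = v,
                   fitted = stats::fitted(fit),
                   residuals = stats::residuals(fit)),
              extra),
            class = "kinetic_fit")
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of `v = kcat * E0 * S / (KM + S)` with KM and
#' kcat log-parameterized (so the parameter path stays positive),
#' initialized at `KM = median(S)` and `kcat = max(v)/E0`. Parameter
#' standard errors come from the fit covariance by the delta method, and
#' the catalytic efficiency kcat/KM (per molar, per second) is
#' propagated with [efficiency()]. A coefficient of variation above 10
#' on either parameter triggers an identifiability warning.
#'
#' @param data data.frame with `substrate_conc_uM` and `rate_uM_per_s`
#'   columns (e.g. from [gen_rate_data()]); at least 3 distinct
#'   substrate levels.
#' @param e0_uM enzyme concentration (uM); defaults to the data's
#'   `E0_uM` attribute.
#' @return an object of class `kinetic_fit`.
#' @examples
#' tr <- kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0)
#' d <- gen_rate_data(tr, c(10, 25, 77, 250, 1000), n_reps = 1)
#' fit_mm(d)
#' @export
fit_mm <- function(data, e0_uM = NULL) {
  rd <- as_rate_data(data, e0_uM)
  if (length(unique(rd$S)) < 3)
    stop("need at least 3 distinct substrate levels")
  df <- data.frame(S = rd$S, v = rd$v)
  E0 <- rd$E0
  start <- list(lkcat = log(max(rd$v) / E0), lKM = log(stats::median(rd$S)))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ exp(lkcat) * E0 * S / (exp(lKM) + S),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  lsd <- if (is.null(vc)) c(lkcat = NA_real_, lKM = NA_real_) else
    sqrt(pmax(diag(vc), 0))
  kcat <- exp(est[["lkcat"]]); KM <- exp(est[["lKM"]])
  kcat_sd <- kcat * lsd[["lkcat"]]; KM_sd <- KM * lsd[["lKM"]]
  if (isTRUE(KM_sd / KM > 10) || isTRUE(kcat_sd / kcat > 10))
    warning("parameters are poorly identified ",
            "(standard error exceeds 10x the estimate)")
  new_kinetic_fit("mm", KM, KM_sd, kcat, kcat_sd, E0 = E0, fit = fit,
                  S = rd$S, v = rd$v)
}

# corrected Akaike information criterion from an nls fit
aicc <- function(fit) {
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) + 1  # + residual variance
  rss <- sum(stats::residuals(fit)^2)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Fit substrate-inhibition kinetics
#'
#' Nonlinear least squares of the standard uncompetitive
#' substrate-inhibition form `v = kcat * E0 * S / (KM + S + S^2/Ki)`
#' (log-parameterized), with the peak-rate substrate concentration
#' `sqrt(KM * Ki)` reported and a corrected-AIC comparison against the
#' plain Michaelis-Menten fit. When the data show no supported rate
#' decline (the corrected AIC prefers the plain hyperbola, or the Ki
#' estimate exceeds 100x the largest substrate concentration) the
#' inhibition constant is reported as unbounded (`Inf`), the fit is
#' flagged MM-preferred, and the Michaelis-Menten parameters are
#' returned.
#'
#' @param data data.frame with `substrate_conc_uM` and `rate_uM_per_s`
#'   columns; at least 5 distinct substrate levels spanning the peak.
#' @param e0_uM enzyme concentration (uM); defaults to the data's
#'   `E0_uM` attribute.
#' @return an object of class `kinetic_fit` with extra fields `Ki`,
#'   `Ki_sd`, `peak_uM`, `aicc_si`, `aicc_mm` and `mm_preferred`.
#' @export
fit_substrate_inhibition <- function(data, e0_uM = NULL) {
  rd <- as_rate_data(data, e0_uM)
  if (length(unique(rd$S)) < 5)
    stop("need at least 5 distinct substrate levels spanning the peak")
  df <- data.frame(S = rd$S, v = rd$v)
  E0 <- rd$E0
  mm <- fit_mm(data, E0)
  # nested-model initialization: start from the Michaelis-Menten
  # solution with a weak inhibition term, so the S^2/Ki term only
  # leaves the near-MM basin when the data actually decline; walk the
  # Ki start inward if the flat basin makes the gradient degenerate
  fit <- NULL
  for (ki0 in max(rd$S) * c(100, 10, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ exp(lkcat) * E0 * S / (exp(lKM) + S + S^2 / exp(lKi)),
        data = df,
        start = list(lkcat = log(mm$kcat), lKM = log(mm$KM),
                     lKi = log(ki0)),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new_kinetic_fit(
      "substrate_inhibition", mm$KM, mm$KM_sd, mm$kcat, mm$kcat_sd,
      Ki = Inf, Ki_sd = NA_real_, E0 = E0, fit = mm$fit,
      S = rd$S, v = rd$v,
      extra = list(peak_uM = Inf, aicc_si = NA_real_,
                   aicc_mm = aicc(mm$fit), mm_preferred = TRUE)))
  }
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  lsd <- if (is.null(vc))
    c(lkcat = NA_real_, lKM = NA_real_, lKi = NA_real_) else
    sqrt(pmax(diag(vc), 0))
  kcat <- exp(est[["lkcat"]]); KM <- exp(est[["lKM"]])
  Ki <- exp(est[["lKi"]])
  a_si <- aicc(fit); a_mm <- aicc(mm$fit)
  mm_preferred <- a_mm <= a_si || Ki > 100 * max(rd$S)
  if (mm_preferred) {
    # the inhibition term is statistically unsupported: its point
    # estimate only reflects noise, so report the boundary (no
    # inhibition) and the parameters of the preferred plain hyperbola
    return(new_kinetic_fit(
      "substrate_inhibition", mm$KM, mm$KM_sd, mm$kcat, mm$kcat_sd,
      Ki = Inf, Ki_sd = NA_real_, E0 = E0, fit = mm$fit,
      S = rd$S, v = rd$v,
      extra = list(peak_uM = Inf, aicc_si = a_si, aicc_mm = a_mm,
                   mm_preferred = TRUE)))
  }
  new_kinetic_fit("substrate_inhibition", KM, KM * lsd[["lKM"]],
                  kcat, kcat * lsd[["lkcat"]],
                  Ki = Ki, Ki_sd = Ki * lsd[["lKi"]],
                  E0 = E0, fit = fit, S = rd$S, v = rd$v,
                  extra = list(peak_uM = sqrt(KM * Ki),
                               aicc_si = a_si, aicc_mm = a_mm,
                               mm_preferred = FALSE))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit (", x$model, "), E0 = ", x$E0, " uM\n", sep = "")
  cat("  KM   = ", signif(x$KM, 3), " +/- ", signif(x$KM_sd, 2),
      " uM\n", sep = "")
  cat("  kcat = ", signif(x$kcat, 3), " +/- ", signif(x$kcat_sd, 2),
      " /s\n", sep = "")
  if (!is.null(x$Ki))
    cat("  Ki   = ", signif(x$Ki, 3), " +/- ", signif(x$Ki_sd, 2),
        " uM (peak at ", signif(x$peak_uM, 3), " uM)\n", sep = "")
  cat("  kcat/KM = ", signif(x$eff, 2), " +/- ", signif(x$eff_sd, 2),
      " /M/s\n", sep = "")
  if (isTRUE(x$mm_preferred))
    cat("  note: AICc/Ki diagnostics prefer plain Michaelis-Menten\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  out <- c(KM = object$KM, kcat = object$kcat)
  if (!is.null(object$Ki)) out <- c(out, Ki = object$Ki)
  out
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  data.frame(model = object$model,
             KM_uM = object$KM, KM_sd = object$KM_sd,
             kcat_per_s = object$kcat, kcat_sd = object$kcat_sd,
             Ki_uM = object$Ki %||% NA_real_,
             Ki_sd = object$Ki_sd %||% NA_real_,
             eff_per_M_s = object$eff, eff_sd = object$eff_sd,
             stringsAsFactors = FALSE)
}

#' @export
predict.kinetic_fit <- function(object, S, ...) {
  if (missing(S)) S <- object$S
  if (object$model == "mm") {
    object$kcat * object$E0 * S / (object$KM + S)
  } else {
    object$kcat * object$E0 * S /
      (object$KM + S + S^2 / object$Ki)
  }
}

#' @export
residuals.kinetic_fit <- function(object, ...) object$residuals

#' @export
plot.kinetic_fit <- function(x, ...) {
  S_grid <- seq(min(x$S) / 2, max(x$S) * 1.05, length.out = 200)
  graphics::plot(x$S, x$v, xlab = "substrate (uM)",
                 ylab = "rate (uM/s)",
                 main = sprintf("%s fit: KM = %s uM, kcat = %s /s",
                                x$model, signif(x$KM, 3),
                                signif(x$kcat, 3)), ...)
  graphics::lines(S_grid, predict(x, S_grid), col = "steelblue",
                  lwd = 2)
  invisible(x)
}

#' Catalytic efficiency with first-order error propagation
#'
#' `kcat/KM` in per-molar per-second (KM given in uM), with the relative
#' uncertainty combined in quadrature:
#' `(sd_eff/eff)^2 = (sd_kcat/kcat)^2 + (sd_KM/KM)^2`.
#'
#' @param kcat turnover number (per second), positive.
#' @param kcat_sd its standard deviation.
#' @param KM_uM Michaelis constant (uM), positive.
#' @param KM_sd its standard deviation.
#' @return a list with `eff` and `eff_sd` (per molar, per second).
#' @examples
#' efficiency(0.90, 0.07, 77, 19)  # about (1.2 +/- 0.3) x 10^4
#' @export
efficiency <- function(kcat, kcat_sd = 0, KM_uM, KM_sd = 0) {
  stopifnot(is_number(kcat), kcat > 0)
  if (!is_number(KM_uM) || KM_uM <= 0)
    stop("KM must be positive")
  kcat_sd <- if (is.na(kcat_sd)) 0 else kcat_sd
  KM_sd <- if (is.na(KM_sd)) 0 else KM_sd
  eff <- kcat / (KM_uM * 1e-6)
  rel <- sqrt((kcat_sd / kcat)^2 + (KM_sd / KM_uM)^2)
  list(eff = eff, eff_sd = eff * rel)
}

#' Normalize mutant activity to wildtype
#'
#' Percent activity `100 * mean(mut)/mean(wt)` with the mutant replicate
#' standard deviation scaled proportionally
#' (`sd = sd(mut) * 100 / mean(wt)`); a mutant mean below the detection
#' floor is flagged not-detected (N.D.).
#'
#' @param wt_reps wildtype replicate rates (at least 3).
#' @param mut_reps mutant replicate rates (at least 3).
#' @param detection_floor rate below which activity counts as not
#'   detected (same units as the rates).
#' @return a list with `percent`, `sd` and `nd` (logical); `percent` and
#'   `sd` are `NA` when `nd` is TRUE.
#' @examples
#' normalize_mutant(c(1.9, 2.0, 2.1), c(0.9, 1.0, 1.1))
#' @export
normalize_mutant <- function(wt_reps, mut_reps, detection_floor = 0) {
  stopifnot(is.numeric(wt_reps), is.numeric(mut_reps))
  if (length(wt_reps) < 3 || length(mut_reps) < 3)
    stop("need at least three replicates per protein")
  mw <- mean(wt_reps)
  if (mw <= 0) stop("wildtype mean activity must be positive")
  mm <- mean(mut_reps)
  if (mm < detection_floor)
    return(list(percent = NA_real_, sd = NA_real_, nd = TRUE))
  list(percent = 100 * mm / mw,
       sd = stats::sd(mut_reps) * 100 / mw,
       nd = FALSE)
}

#' Convert a phosphate rate to a pyrophosphate rate
#'
#' The pyrophosphorylase readout measures inorganic phosphate after
#' pyrophosphatase hydrolysis of the released PPi; one PPi hydrolyzes to
#' two Pi, so the enzymatic rate is the Pi rate divided by the
#' stoichiometry factor (default 2, configurable).
#'
#' @param pi_rate phosphate appearance rate (uM/s), non-negative.
#' @param stoichiometry_factor Pi produced per PPi, positive.
#' @return pyrophosphorylase rate (uM/s).
#' @export
pi_to_ppi_rate <- function(pi_rate, stoichiometry_factor = 2) {
  stopifnot(is.numeric(pi_rate), all(pi_rate >= 0))
  if (!is_number(stoichiometry_factor) || stoichiometry_factor <= 0)
    stop("stoichiometry_factor must be positive")
  pi_rate / stoichiometry_factor
}
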