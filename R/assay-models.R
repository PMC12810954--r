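# 1:1 Langmuir SPR kinetics, Boltzmann thermal-shift fitting, and the caliper
# tumor-volume formula.

# Closed-form 1:1 Langmuir response at times t (s) for analyte concentration
# conc (M): association to t_assoc, then exponential dissociation.
langmuir_response <- function(t, ka, kd, rmax, conc, t_assoc) {
  kobs <- ka * conc + kd
  req <- rmax * ka * conc / kobs
  r_assoc_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-kobs * t)),
         r_assoc_end * exp(-kd * (t - t_assoc)))
}

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Association follows `R(t) = Req (1 - exp(-(ka C + kd) t))` with
#' `Req = Rmax ka C / (ka C + kd)`; dissociation decays exponentially with
#' rate `kd` from the association endpoint. I.i.d. Gaussian noise of standard
#' deviation `noise_sd` RU is added; deterministic under `seed`.
#'
#' @param ka Association rate (1/M/s), > 0.
#' @param kd Dissociation rate (1/s), > 0.
#' @param rmax Analyte-saturated response (RU), > 0.
#' @param conc Analyte concentration (M), > 0.
#' @param t_assoc,t_dissoc Association / dissociation durations (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise sd (RU).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble: `time`, `response`, `conc`, `t_assoc`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, t_assoc = 180, t_dissoc = 600,
                                dt = 1, noise_sd = 0, seed = NULL) {
  if (any(c(ka, kd, rmax, conc, dt) <= 0)) {
    stop("ka, kd, rmax, conc and dt must all be positive", call. = FALSE)
  }
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- langmuir_response(t, ka, kd, rmax, conc, t_assoc)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
    r <- r + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  tibble::tibble(time = t, response = r, conc = conc, t_assoc = t_assoc)
}

#' Global 1:1 kinetic fit over a dilution series
#'
#' Fits shared (`ka`, `kd`, `Rmax`) to all sensorgrams simultaneously by
#' Levenberg-Marquardt least squares on the closed-form 1:1 Langmuir model,
#' with multi-start initialization over a log grid (`ka` in 1e4..1e8,
#' `kd` in 1e-4..1). `KD` is reported as `kd / ka`, never fitted
#' independently.
#'
#' @param sensorgrams Tibble with columns `time`, `response`, `conc`,
#'   `t_assoc` (as produced by [simulate_sensorgram()]; stack curves with
#'   `dplyr::bind_rows()`).
#' @return A `kinetic_fit`: list with `ka`, `kd`, `rmax`, `KD` (molar),
#'   `residual_rms` (RU), `n_curves`, `n_points`, and `data`.
#' @export
fit_kinetics <- function(sensorgrams) {
  d <- sensorgrams
  concs <- sort(unique(d$conc))
  if (length(concs) < 3L) stop("need at least 3 analyte concentrations", call. = FALSE)
  if (stats::sd(d$response) < 1e-8) {
    stop("kinetic fit failed: flat response, nothing to fit", call. = FALSE)
  }
  resid_fn <- function(par) {
    ka <- 10^par[1]; kd <- 10^par[2]; rmax <- 10^par[3]
    d$response - langmuir_response(d$time, ka, kd, rmax, d$conc, d$t_assoc)
  }
  lrmax0 <- log10(max(abs(d$response)) / 0.8)
  best <- NULL
  for (lka in 4:8) {
    for (lkd in -4:0) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(lka, lkd, lrmax0), fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop("kinetic fit failed to converge from any start", call. = FALSE)
  par <- best$fit$par
  ka <- 10^par[1]; kd <- 10^par[2]; rmax <- 10^par[3]
  rms <- sqrt(best$sse / nrow(d))
  if (rms > max(abs(d$response)) * 0.5) {
    stop("kinetic fit failed: best residual RMS ", signif(rms, 3),
         " RU is not a usable fit", call. = FALSE)
  }
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = kd / ka,
                 residual_rms = rms, n_curves = length(concs),
                 n_points = nrow(d), data = d), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> ka %.3g 1/M/s, kd %.3g 1/s, KD %.3g nM, Rmax %.3g RU (rms %.3g RU, %d curves)\n",
              x$ka, x$kd, x$KD * 1e9, x$rmax, x$residual_rms, x$n_curves))
  invisible(x)
}

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = c("ka", "kd", "KD", "Rmax"),
                 estimate = c(x$ka, x$kd, x$KD, x$rmax),
                 unit = c("1/M/s", "1/s", "M", "RU"))
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(ka = x$ka, kd = x$kd, KD_nM = x$KD * 1e9, rmax = x$rmax,
                 residual_rms = x$residual_rms, n_curves = x$n_curves,
                 n_points = x$n_points)
}

#' Autoplot methods for fitted assay and validation objects
#'
#' @param object A fitted object.
#' @param ... Ignored.
#' @return A ggplot.
#' @name autoplot_helpers
NULL

#' @rdname autoplot_helpers
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  fitted <- dplyr::mutate(d, fitted = langmuir_response(
    .data$time, object$ka, object$kd, object$rmax, .data$conc, .data$t_assoc))
  ggplot2::ggplot(fitted, ggplot2::aes(x = .data$time, group = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response), size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  title = sprintf("1:1 Langmuir global fit: KD = %.3g nM", object$KD * 1e9))
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate (1/M/s), > 0.
#' @param kd Dissociation rate (1/s), >= 0.
#' @return `kd / ka` in molar.
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0)) stop("ka must be positive", call. = FALSE)
  if (any(kd < 0)) stop("kd must be nonnegative", call. = FALSE)
  kd / ka
}

#' Check a reported KD against the rate-constant ratio
#'
#' Instrument software sometimes reports an equilibrium KD that differs from
#' `kd/ka` of the same fit; this flags a relative disagreement above
#' `tolerance` (default 5%).
#'
#' @param ka,kd Rate constants.
#' @param reported_kd Reported equilibrium KD (molar).
#' @param tolerance Relative disagreement triggering the flag.
#' @return Tibble with both values, the relative difference, and `consistent`.
#' @export
kd_consistency <- function(ka, kd, reported_kd, tolerance = 0.05) {
  ratio <- kd_from_rates(ka, kd)
  rel <- abs(ratio - reported_kd) / reported_kd
  tibble::tibble(kd_over_ka = ratio, reported_kd = reported_kd,
                 relative_difference = rel, consistent = rel <= tolerance)
}

# Boltzmann sigmoid used by the thermal-shift model.
boltzmann_sigmoid <- function(temp, f_low, f_high, tm, slope) {
  f_low + (f_high - f_low) / (1 + exp((tm - temp) / slope))
}

#' Simulate a thermal-shift melt curve
#'
#' @param tm Melting temperature (deg C), the sigmoid inflection.
#' @param slope Transition width parameter (deg C).
#' @param f_low,f_high Pre-/post-transition fluorescence baselines (AU).
#' @param temperatures Temperature grid (deg C, ascending).
#' @param noise_sd Gaussian noise sd in AU (use a fraction of the amplitude
#'   for relative noise).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble: `temperature`, `fluorescence`.
#' @export
simulate_melt_curve <- function(tm, slope = 2, f_low = 0, f_high = 1,
                                temperatures = seq(25, 95, by = 0.5),
                                noise_sd = 0, seed = NULL) {
  stopifnot(slope > 0, !is.unsorted(temperatures))
  f <- boltzmann_sigmoid(temperatures, f_low, f_high, tm, slope)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  }
  tibble::tibble(temperature = temperatures, fluorescence = f)
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Fits `F(T) = F_low + (F_high - F_low) / (1 + exp((Tm - T)/s))` by
#' Levenberg-Marquardt least squares; `Tm` is the inflection.
#'
#' @param curve Tibble with `temperature` and `fluorescence` columns
#'   (>= 10 points spanning the transition).
#' @return A `tm_fit`: list with `tm` (deg C), `slope`, `f_low`, `f_high`,
#'   `residual_rms`, and `data`.
#' @export
fit_melt_curve <- function(curve) {
  d <- curve
  if (nrow(d) < 10L) stop("need at least 10 points", call. = FALSE)
  amp0 <- max(d$fluorescence) - min(d$fluorescence)
  if (amp0 < 1e-12) stop("no transition in range: flat curve", call. = FALSE)
  half <- min(d$fluorescence) + amp0 / 2
  tm0 <- d$temperature[which.min(abs(d$fluorescence - half))]
  resid_fn <- function(par) {
    d$fluorescence - boltzmann_sigmoid(d$temperature, par[1], par[2], par[3], exp(par[4]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(min(d$fluorescence), max(d$fluorescence), tm0, log(2)),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("melt-curve fit failed: ", conditionMessage(e), call. = FALSE))
  par <- fit$par
  tm <- par[3]
  rms <- sqrt(mean(fit$fvec^2))
  amp <- abs(par[2] - par[1])
  if (tm < min(d$temperature) || tm > max(d$temperature)) {
    stop("no transition in range: fitted Tm ", round(tm, 2),
         " outside the temperature grid", call. = FALSE)
  }
  if (amp < 5 * rms) {
    stop("no transition in range: fitted amplitude indistinguishable from noise",
         call. = FALSE)
  }
  structure(list(tm = tm, slope = exp(par[4]), f_low = par[1], f_high = par[2],
                 residual_rms = rms, data = d), class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> Tm %.2f degC (slope %.2f, rms %.3g AU)\n",
              x$tm, x$slope, x$residual_rms))
  invisible(x)
}

#' @method tidy tm_fit
#' @export
tidy.tm_fit <- function(x, ...) {
  tibble::tibble(term = c("tm", "slope", "f_low", "f_high"),
                 estimate = c(x$tm, x$slope, x$f_low, x$f_high))
}

#' @method glance tm_fit
#' @export
glance.tm_fit <- function(x, ...) {
  tibble::tibble(tm = x$tm, slope = x$slope, residual_rms = x$residual_rms,
                 n_points = nrow(x$data))
}

#' @rdname autoplot_helpers
#' @method autoplot tm_fit
#' @export
autoplot.tm_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- boltzmann_sigmoid(d$temperature, object$f_low, object$f_high,
                                object$tm, object$slope)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fluorescence), size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed") +
    ggplot2::labs(x = "temperature (°C)", y = "fluorescence (AU)",
                  title = sprintf("Boltzmann melt fit: Tm = %.2f °C", object$tm))
}

#' Caliper tumor volume with humane endpoint
#'
#' Volume is `((length + width)/2)^3 * 0.52` in cubic millimetres; the
#' endpoint flag is set when the volume exceeds `endpoint_mm3`. The printed
#' caliper formula's second dimension is interpreted as tumor width.
#'
#' @param length_mm,width_mm Caliper measurements (mm), nonnegative;
#'   vectorized.
#' @param endpoint_mm3 Humane endpoint volume (mm^3).
#' @return Tibble: `length`, `width`, `volume`, `endpoint_reached`.
#' @export
tumor_volume <- function(length_mm, width_mm, endpoint_mm3 = 1500) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("tumor dimensions must be nonnegative", call. = FALSE)
  }
  v <- ((length_mm + width_mm) / 2)^3 * 0.52
  tibble::tibble(length = length_mm, width = width_mm, volume = v,
                 endpoint_reached = v > endpoint_mm3)
}
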