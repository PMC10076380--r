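# Impedimetric degradation-rate pipeline: simplified Randles circuit fit
# of each spectrum -> film capacitance -> apparent thickness -> linear
# thinning rate -> group statistics; plus gravimetric weight-loss
# normalization.

eps0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Simplified Randles circuit parameters
#'
#' Series (solution) resistance in series with a parallel RC element. The
#' PET film is a blocking dielectric, so no Warburg diffusion element is
#' included; the quantity of interest is the film capacitance.
#'
#' @param R_s series resistance, Ohm.
#' @param R_ct parallel (charge-transfer/leak) resistance, Ohm.
#' @param C film capacitance, F.
#' @return list of class `randles_params`.
#' @export
randles_params <- function(R_s, R_ct, C) {
  if (any(c(R_s, R_ct, C) <= 0) || !all(is.finite(c(R_s, R_ct, C))))
    stopf("Randles parameters must be positive and finite")
  structure(list(R_s = R_s, R_ct = R_ct, C = C), class = "randles_params")
}

#' Impedance of the simplified Randles circuit
#'
#' `Z(w) = R_s + R_ct / (1 + i w R_ct C)`, `w = 2 pi f`. The real part
#' runs from `R_s + R_ct` (DC) down to `R_s` (high frequency); the
#' imaginary part is capacitive (non-positive) at all frequencies.
#'
#' @param p a [randles_params()].
#' @param freq_hz frequencies in Hz (> 0).
#' @return complex impedance vector, Ohm.
#' @export
randles_impedance <- function(p, freq_hz) {
  if (any(freq_hz <= 0)) stopf("frequencies must be positive")
  w <- 2 * pi * freq_hz
  p$R_s + p$R_ct / (1 + 1i * w * p$R_ct * p$C)
}

#' Fit the simplified Randles circuit to one spectrum
#'
#' Levenberg-Marquardt least squares over real and imaginary parts
#' jointly, each residual weighted by `1/|Z|` (modulus weighting, i.e.
#' squared weight `1/|Z|^2`): spectra span several decades of modulus and
#' unweighted fits would be dominated by the low-frequency points.
#' Positivity is enforced by fitting log-parameters. Initial values, when
#' not supplied, come from the circuit's limiting behavior: `R_s` from the
#' high-frequency real part, `C` from the high-frequency imaginary branch
#' (`-Im Z ~ 1/(wC)`), and `R_ct` from the low-frequency modulus. `R_ct`
#' is capped (default `1e6 * max|Z|`); a fit at the cap is flagged
#' `at_bound` and arises for effectively pure capacitors.
#'
#' @param freq_hz frequencies in Hz (>= 6 points spanning >= 2 decades).
#' @param Z complex impedance at those frequencies.
#' @param init optional [randles_params()] starting point.
#' @param R_ct_max upper cap on `R_ct` (Ohm).
#' @return object of class `randles_fit`: `params`, `residual_norm`,
#'   `at_bound`, `converged`, `info`.
#' @export
fit_randles <- function(freq_hz, Z, init = NULL, R_ct_max = NULL) {
  if (length(freq_hz) < 6) stopf("need >= 6 frequency points")
  if (log10(max(freq_hz) / min(freq_hz)) < 2)
    stopf("frequency range must span >= 2 decades")
  ord <- order(freq_hz)
  f <- freq_hz[ord]; z <- Z[ord]
  absz <- Mod(z)
  R_ct_max <- R_ct_max %||% (1e6 * max(absz))
  if (is.null(init)) {
    nf <- length(f)
    R_s0 <- max(Re(z[nf]), 1e-3 * max(absz))
    w_hi <- 2 * pi * f[nf]
    C0 <- max(1 / (w_hi * max(-Im(z[nf]), 1e-12 * max(absz))), 1e-18)
    m <- max(Mod(z[1] - R_s0), 1e-9)
    w_lo <- 2 * pi * f[1]
    denom <- 1 - (m * w_lo * C0)^2
    R_ct0 <- if (denom > 1e-6) m / sqrt(denom) else min(1e3 * m, R_ct_max)
    R_ct0 <- min(max(R_ct0, 1e-3), R_ct_max)
    init <- randles_params(R_s0, R_ct0, C0)
  }
  wts <- 1 / absz
  resid_fn <- function(theta) {
    p <- list(R_s = exp(theta[1]), R_ct = exp(theta[2]), C = exp(theta[3]))
    zm <- p$R_s + p$R_ct / (1 + 1i * 2 * pi * f * p$R_ct * p$C)
    c(Re(zm - z) * wts, Im(zm - z) * wts)
  }
  theta0 <- log(c(init$R_s, init$R_ct, init$C))
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    lower = c(-60, -60, -80),
    upper = c(60, log(R_ct_max), 10),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  if (!fit$info %in% 1:4)
    stopf("Randles fit did not converge (info %d, residual %.3g)",
          fit$info, sqrt(sum(fit$fvec^2)))
  th <- fit$par
  params <- randles_params(exp(th[1]), exp(th[2]), exp(th[3]))
  structure(list(params = params,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 at_bound = th[2] > log(R_ct_max) - 1e-3,
                 converged = TRUE, info = fit$info),
            class = "randles_fit")
}

#' PET film geometry constants
#'
#' @param epsilon_r relative permittivity of PET (default 3.3).
#' @param d0_um starting film thickness, micrometers (default 225,
#'   measured mechanically).
#' @param area_mm2 film area, mm^2 (default 4.3 x 9.1 = 39.13).
#' @return list of class `film_geometry`.
#' @export
film_geometry <- function(epsilon_r = 3.3, d0_um = 225, area_mm2 = 4.3 * 9.1) {
  if (any(c(epsilon_r, d0_um, area_mm2) <= 0))
    stopf("film geometry constants must be positive")
  structure(list(epsilon_r = epsilon_r, d0_um = d0_um, area_mm2 = area_mm2),
            class = "film_geometry")
}

# parallel-plate capacitance (F) of the film at thickness d_um
plate_capacitance <- function(geom, d_um) {
  eps0 * geom$epsilon_r * (geom$area_mm2 * 1e-6) / (d_um * 1e-6)
}

#' Fit capacitance for every spectrum of a series
#'
#' @param series an [impedance_series()].
#' @param ... passed to [fit_randles()].
#' @return data.frame with `time_h`, `C_F`, `at_bound`.
#' @export
fit_capacitance_series <- function(series, ...) {
  fits <- lapply(seq_along(series$time_h), function(i)
    fit_randles(series$freq_hz, series$Z[i, ], ...))
  data.frame(time_h = series$time_h,
             C_F = vapply(fits, function(f) f$params$C, 0),
             at_bound = vapply(fits, function(f) f$at_bound, TRUE))
}

#' Translate capacitance into apparent film thickness
#'
#' Calibrated mode (default) anchors to the mechanically measured starting
#' thickness: `d(t) = d0 * C(t0)/C(t)`, so the electrode area cancels and
#' a uniform scaling of all capacitances leaves the thickness unchanged.
#' Absolute mode uses the parallel-plate formula
#' `d(t) = eps0 * eps_r * area / C(t)` and is sensitive to the uncertain
#' exposed area; treat it as approximate.
#'
#' @param C_series data.frame with `time_h`, `C_F` (from
#'   [fit_capacitance_series()]).
#' @param geom a [film_geometry()].
#' @param mode `"calibrated"` or `"absolute"`.
#' @return data.frame of class `thickness_series` with `time_h`,
#'   `thickness_um`.
#' @export
capacitance_to_thickness <- function(C_series, geom = film_geometry(),
                                     mode = c("calibrated", "absolute")) {
  mode <- match.arg(mode)
  C <- C_series$C_F
  if (any(C <= 0)) stopf("non-positive capacitance")
  d <- if (mode == "calibrated") geom$d0_um * C[1] / C
       else eps0 * geom$epsilon_r * (geom$area_mm2 * 1e-6) / C * 1e6
  out <- data.frame(time_h = C_series$time_h, thickness_um = d)
  class(out) <- c("thickness_series", "data.frame")
  out
}

#' Enzymatic degradation rate from a thickness series
#'
#' Ordinary least-squares regression of apparent thickness on time over a
#' stated window; the rate is reported as positive micrometers per hour of
#' thinning (the negated slope). The regression window is deliberately a
#' required, logged argument: published analyses of the same measurement
#' have used both 5-10 h and 10-15 h windows, so reports must state which
#' was applied.
#'
#' @param series a [capacitance_to_thickness()] result (columns `time_h`,
#'   `thickness_um`).
#' @param window `c(t_start, t_end)` in hours; >= 3 points must fall
#'   inside (inclusive).
#' @return object of class `rate_estimate`: `rate_um_h`, `se`, `window`,
#'   `r_squared`, `n`, `flag`.
#' @export
degradation_rate <- function(series, window) {
  if (length(window) != 2 || window[1] >= window[2])
    stopf("window must be c(start, end) with start < end")
  d <- series[series$time_h >= window[1] & series$time_h <= window[2], ]
  if (nrow(d) < 3) stopf("fewer than 3 points inside window [%g, %g] h",
                         window[1], window[2])
  fit <- stats::lm(thickness_um ~ time_h, data = d)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit exactly
  slope <- stats::coef(fit)[["time_h"]]
  se <- sm$coefficients["time_h", "Std. Error"]
  r2 <- sm$r.squared
  flag <- NULL
  if (stats::var(d$thickness_um) < .Machine$double.eps) {
    r2 <- 0; flag <- "constant thickness: R^2 undefined, reported 0"
  }
  structure(list(rate_um_h = -slope, se = se, window = window,
                 r_squared = r2, n = nrow(d), flag = flag),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3f +/- %.3f um/h over [%g, %g] h (n=%d, R^2=%.4f)\n",
              x$rate_um_h, x$se, x$window[1], x$window[2], x$n, x$r_squared))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Full impedance-to-rate pipeline
#'
#' Convenience chain: per-spectrum Randles fit, capacitance to thickness
#' (calibrated), linear thinning rate over the window.
#'
#' @param series an [impedance_series()].
#' @param geom a [film_geometry()]; defaults to the series' own, else
#'   package defaults.
#' @param window regression window in hours.
#' @param mode thickness mode, see [capacitance_to_thickness()].
#' @return a [degradation_rate()] result with the thickness series
#'   attached as attribute `"thickness"`.
#' @export
impedance_pipeline <- function(series, geom = NULL, window = c(5, 10),
                               mode = "calibrated") {
  geom <- geom %||% series$geom %||% film_geometry()
  Cs <- fit_capacitance_series(series)
  th <- capacitance_to_thickness(Cs, geom, mode)
  rate <- degradation_rate(th, window)
  attr(rate, "thickness") <- th
  rate
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Standard one-way analysis of variance across groups of rates followed
#' by Tukey honest significant differences (studentized-range
#' distribution), with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param groups named list, one numeric vector of rates per group
#'   (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`, `tukey` (data.frame: pair, diff,
#'   lwr, upr, p_adj, stars), `flag`.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stopf("each group needs n >= 2")
  d <- data.frame(rate = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), vapply(groups, length, 0L))))
  flag <- NULL
  within_var <- vapply(groups, stats::var, 0)
  if (all(within_var < .Machine$double.eps) &&
      stats::var(vapply(groups, mean, 0)) < .Machine$double.eps) {
    flag <- "all groups identical and constant: F undefined"
    return(list(F = NaN, p = NaN, df = NULL, tukey = NULL, flag = flag))
  }
  fit <- stats::aov(rate ~ group, data = d)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stars = significance_stars(tk[, "p adj"]),
                      row.names = NULL)
  list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       df = sm[["Df"]], tukey = tukey, flag = flag)
}

#' Normalize weight loss to the wild-type mean
#'
#' Gravimetric weight losses of a variant expressed as percent of the
#' wild-type mean, `100 * mean(variant)/mean(WT)`, with the spread from
#' first-order error propagation of the two replicate SDs:
#' `pct * sqrt((sd_v/mean_v)^2 + (sd_wt/mean_wt)^2)` (the variant term is
#' `100 * sd_v / mean_wt` when the variant mean is zero).
#'
#' @param variant,wildtype replicate weight losses (mg), n >= 1 each.
#' @return list with `percent`, `sd`, `n_variant`, `n_wildtype`.
#' @export
normalize_weight_loss <- function(variant, wildtype) {
  if (!length(variant) || !length(wildtype)) stopf("need >= 1 replicate each")
  mw <- mean(wildtype)
  if (mw <= 0) stopf("wild-type mean weight loss must be positive")
  mv <- mean(variant)
  pct <- 100 * mv / mw
  sv <- if (length(variant) > 1) stats::sd(variant) else 0
  sw <- if (length(wildtype) > 1) stats::sd(wildtype) else 0
  sd_pct <- if (mv == 0) 100 * sv / mw
            else abs(pct) * sqrt((sv / mv)^2 + (sw / mw)^2)
  list(percent = pct, sd = sd_pct,
       n_variant = length(variant), n_wildtype = length(wildtype))
}
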