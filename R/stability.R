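#' Fraction unfolded from a denaturation curve
#'
#' Two-state reduction of a fluorescence-vs-urea curve. The native plateau
#' is the mean signal inside `native_window` (low urea) and the unfolded
#' plateau the mean inside `unfolded_window` (high urea); the fraction
#' unfolded at each point is `(F - F_N)/(F_U - F_N)`, clipped to [0, 1]
#' with out-of-range points flagged. If windows are not given, the first
#' and last 15\% of the urea grid are used.
#'
#' @param curve data.frame with columns `urea_M` and `signal` (e.g. from
#'   [gen_unfolding()] or `read.csv`).
#' @param native_window,unfolded_window numeric `c(min, max)` urea ranges
#'   (M) over the native and unfolded baselines; each must contain at
#'   least 2 points.
#' @return data.frame of class `unfolded_fractions`: `urea_M`, `signal`,
#'   `f_unfolded`, `clipped`; plateau values in attributes `f_native`,
#'   `f_unfolded_plateau`.
#' @export
fraction_unfolded <- function(curve, native_window = NULL,
                              unfolded_window = NULL) {
  u <- curve$urea_M
  f <- curve$signal
  if (is.null(u) || is.null(f)) stop("curve must have urea_M and signal columns")
  ord <- order(u)
  u <- u[ord]; f <- f[ord]
  span <- range(u)
  if (is.null(native_window))
    native_window <- c(span[1], span[1] + 0.15 * diff(span))
  if (is.null(unfolded_window))
    unfolded_window <- c(span[2] - 0.15 * diff(span), span[2])
  in_n <- u >= native_window[1] & u <= native_window[2]
  in_u <- u >= unfolded_window[1] & u <= unfolded_window[2]
  if (sum(in_n) < 2L || sum(in_u) < 2L)
    stop("each plateau window must contain at least 2 points")
  f_n <- mean(f[in_n])
  f_u <- mean(f[in_u])
  if (f_n == f_u) stop("native and unfolded plateaus are identical")
  frac <- (f - f_n) / (f_u - f_n)
  clipped <- frac < 0 | frac > 1
  frac <- pmin(pmax(frac, 0), 1)
  out <- data.frame(urea_M = u, signal = f, f_unfolded = frac,
                    clipped = clipped)
  attr(out, "f_native") <- f_n
  attr(out, "f_unfolded_plateau") <- f_u
  attr(out, "windows") <- list(native = native_window,
                               unfolded = unfolded_window)
  class(out) <- c("unfolded_fractions", "data.frame")
  out
}

#' Pointwise unfolding free energies from unfolded fractions
#'
#' `dG_unfold = -R T ln(U/N) = -R T ln(f_U/(1 - f_U))` in kcal/mol with
#' `R = 1.987e-3` kcal/(mol K). Only points inside the usable band
#' `eps <= f_U <= 1 - eps` are kept: the log ratio diverges at the
#' plateaus.
#'
#' @param fractions output of [fraction_unfolded()], or a data.frame with
#'   `urea_M` and `f_unfolded`.
#' @param temperature measurement temperature, K (default 295.15, room
#'   temperature).
#' @param eps usable-band margin (default 0.05).
#' @return data.frame (`urea_M`, `f_unfolded`, `dg_kcal`) of class
#'   `dg_points`, with `temperature` and `eps` attributes.
#' @export
delta_g_points <- function(fractions, temperature = 295.15, eps = 0.05) {
  u <- fractions$urea_M
  fu <- fractions$f_unfolded
  if (is.null(u) || is.null(fu))
    stop("fractions must have urea_M and f_unfolded columns")
  keep <- fu >= eps & fu <= 1 - eps
  if (!any(keep))
    stop("no points inside the usable band [", eps, ", ", 1 - eps, "]")
  u <- u[keep]; fu <- fu[keep]
  dg <- -R_KCAL * temperature * log(fu / (1 - fu))
  out <- data.frame(urea_M = u, f_unfolded = fu, dg_kcal = dg)
  attr(out, "temperature") <- temperature
  attr(out, "eps") <- eps
  class(out) <- c("dg_points", "data.frame")
  out
}

#' Linear extrapolation fit of unfolding free energies
#'
#' Least-squares line `dG_unfold = -m [urea] + dG_H2O`: the m-value is the
#' absolute slope, the water free energy of unfolding the intercept, and
#' the half-unfolding concentration their ratio `c_half = dG_H2O / m`
#' (where the line crosses zero).
#'
#' @param dg_points output of [delta_g_points()], or a data.frame with
#'   `urea_M` and `dg_kcal`.
#' @return object of class `two_state_fit`: `m` (kcal/(mol M)), `c_half`
#'   (M), `dg_h2o` (kcal/mol), standard errors `se_m` and `se_dg_h2o`,
#'   `converged`, `n`, and the underlying `fit`.
#' @export
fit_lem <- function(dg_points) {
  u <- dg_points$urea_M
  dg <- dg_points$dg_kcal
  if (is.null(u) || is.null(dg))
    stop("dg_points must have urea_M and dg_kcal columns")
  if (length(u) < 3L) stop("need at least 3 usable free-energy points")
  fit <- lm(dg ~ u)
  cf <- coef(fit)
  slope <- unname(cf["u"])
  if (slope >= 0)
    stop("fitted slope is nonnegative: data are not consistent with ",
         "two-state denaturant unfolding")
  se <- sqrt(diag(vcov(fit)))
  m <- -slope
  dg_h2o <- unname(cf["(Intercept)"])
  structure(list(m = m, c_half = dg_h2o / m, dg_h2o = dg_h2o,
                 se_m = unname(se["u"]), se_dg_h2o = unname(se["(Intercept)"]),
                 temperature = attr(dg_points, "temperature") %||% NA_real_,
                 converged = TRUE, n = length(u), fit = fit),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("two-state linear extrapolation fit:\n")
  cat(sprintf("  m      = %.3f +/- %.3f kcal/(mol M)\n", x$m, x$se_m))
  cat(sprintf("  c_half = %.2f M\n", x$c_half))
  cat(sprintf("  dG_H2O = %.3f +/- %.3f kcal/mol\n", x$dg_h2o, x$se_dg_h2o))
  invisible(x)
}

#' Two-state fit of a full denaturation curve
#'
#' Convenience wrapper: plateau windows, usable-band free energies, and the
#' linear extrapolation fit in one call.
#'
#' @inheritParams fraction_unfolded
#' @inheritParams delta_g_points
#' @return a `two_state_fit` (see [fit_lem()]).
#' @export
fit_unfolding <- function(curve, native_window = NULL, unfolded_window = NULL,
                          temperature = 295.15, eps = 0.05) {
  fr <- fraction_unfolded(curve, native_window, unfolded_window)
  fit_lem(delta_g_points(fr, temperature = temperature, eps = eps))
}

#' Global two-state fit of a denaturation curve (cross-check)
#'
#' Direct nonlinear fit of the full two-state signal model
#' `F = F_U p_U + F_N (1 - p_U)`, `p_U = 1/(1 + exp((m(c_half - [urea]))/RT))`,
#' estimating plateaus and thermodynamics simultaneously. This avoids the
#' plateau-window bias of the two-stage procedure and serves as a
#' cross-check of [fit_unfolding()]; the two-stage route remains the
#' default because it mirrors standard practice for these curves.
#'
#' @inheritParams fraction_unfolded
#' @inheritParams delta_g_points
#' @return a `two_state_fit` (see [fit_lem()]); `dg_h2o = m * c_half` by
#'   construction.
#' @export
fit_unfolding_global <- function(curve, temperature = 295.15) {
  u <- curve$urea_M
  y <- curve$signal
  if (is.null(u) || is.null(y)) stop("curve must have urea_M and signal columns")
  rt <- R_KCAL * temperature
  two_stage <- tryCatch(fit_unfolding(curve, temperature = temperature),
                        error = function(e) NULL)
  start <- list(m = two_stage$m %||% 1,
                c_half = two_stage$c_half %||% stats::median(u),
                fn = mean(head(y[order(u)], 3)),
                fu = mean(tail(y[order(u)], 3)))
  dat <- data.frame(u = u, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ fu / (1 + exp(m * (c_half - u) / rt)) +
      fn * (1 - 1 / (1 + exp(m * (c_half - u) / rt))),
    data = dat, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (cf["m"] <= 0) stop("fitted m is nonpositive: not two-state unfolding")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  structure(list(m = unname(cf["m"]), c_half = unname(cf["c_half"]),
                 dg_h2o = unname(cf["m"] * cf["c_half"]),
                 se_m = unname(se["m"]), se_dg_h2o = NA_real_,
                 f_native = unname(cf["fn"]), f_unfolded = unname(cf["fu"]),
                 temperature = temperature, converged = TRUE,
                 n = length(u), fit = fit),
            class = "two_state_fit")
}

#' Stability difference by the half-concentration method
#'
#' When two proteins have different m-values, extrapolated water free
#' energies are not comparable; the recommended comparison multiplies the
#' difference in half-unfolding concentrations by the mean of the two
#' m-values: `ddG = (c_half_b - c_half_a) * (m_a + m_b)/2`. Positive means
#' protein b is the more stable.
#'
#' @param fit_a,fit_b converged [fit_lem()] results (a is the reference).
#' @return object of class `stability_comparison`: `delta_c_half` (M),
#'   `mean_m` (kcal/(mol M)), `ddg` (kcal/mol).
#' @export
#' @examples
#' a <- list(m = 0.93, c_half = 2.9, converged = TRUE)
#' b <- list(m = 0.61, c_half = 3.8, converged = TRUE)
#' ddg_half_concentration(a, b)$ddg  # 0.693
ddg_half_concentration <- function(fit_a, fit_b) {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("both fits must have converged")
  delta <- fit_b$c_half - fit_a$c_half
  mean_m <- (fit_a$m + fit_b$m) / 2
  structure(list(delta_c_half = delta, mean_m = mean_m,
                 ddg = delta * mean_m),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("ddG = %.3f kcal/mol (dc_half %.2f M x mean m %.3f)\n",
              x$ddg, x$delta_c_half, x$mean_m))
  invisible(x)
}

#' Sigmoidal melting-temperature fit
#'
#' Fits a two-state thermal transition with linear baselines:
#' `signal = native(T) (1 - f) + unfolded(T) f`,
#' `f = 1/(1 + exp(-(T - Tm)/width))`. The apparent melting temperature is
#' the transition midpoint. A curve without a detectable transition (the
#' fitted amplitude indistinguishable from baseline drift, or the fitted
#' midpoint outside the scanned range) is an error.
#'
#' @param curve data.frame with columns `temp_C` and `signal`.
#' @param sloped_baselines fit linear baseline slopes (default) or flat
#'   baselines.
#' @return object of class `tm_fit`: `tm` (degC), `width` (degC),
#'   `se_tm`, `baselines`, `converged`, and the underlying `fit`.
#' @export
fit_melting <- function(curve, sloped_baselines = TRUE) {
  tt <- curve$temp_C
  y <- curve$signal
  if (is.null(tt) || is.null(y)) stop("curve must have temp_C and signal columns")
  ord <- order(tt)
  tt <- tt[ord]; y <- y[ord]
  if (length(tt) < 6L) stop("need at least 6 points to fit a melting curve")
  # transition guess: steepest point of a lightly smoothed derivative
  sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  dy <- diff(as.numeric(sm)) / diff(tt)
  i0 <- which.max(abs(dy))
  tm0 <- mean(tt[c(i0, i0 + 1L)], na.rm = TRUE)
  if (!is.finite(tm0)) tm0 <- stats::median(tt)
  w0 <- diff(range(tt)) / 20
  n3 <- max(3L, round(length(tt) / 6))
  start <- list(tm = tm0, lw = log(w0),
                a_n = mean(head(y, n3)), b_n = 0,
                a_u = mean(tail(y, n3)), b_u = 0)
  form <- if (sloped_baselines) {
    y ~ (a_n + b_n * tt) * (1 - 1 / (1 + exp(-(tt - tm) / exp(lw)))) +
      (a_u + b_u * tt) * (1 / (1 + exp(-(tt - tm) / exp(lw))))
  } else {
    y ~ a_n * (1 - 1 / (1 + exp(-(tt - tm) / exp(lw)))) +
      a_u * (1 / (1 + exp(-(tt - tm) / exp(lw))))
  }
  if (!sloped_baselines) start <- start[c("tm", "lw", "a_n", "a_u")]
  dat <- data.frame(tt = tt, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("no transition detected: melting fit did not converge")
  cf <- coef(fit)
  getc <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else 0
  tm <- unname(cf["tm"])
  width <- exp(unname(cf["lw"]))
  amp <- abs(getc("a_u") + getc("b_u") * tm - (getc("a_n") + getc("b_n") * tm))
  resid_sd <- sd(stats::residuals(fit))
  if (tm < min(tt) || tm > max(tt) || width > diff(range(tt)) ||
      amp < 5 * resid_sd || amp < 1e-6 * (1 + abs(mean(y))))
    stop("no transition detected within the scanned temperature range")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(tm = tm, width = width, se_tm = unname(se["tm"]),
                 baselines = list(
                   native = c(getc("a_n"), getc("b_n")),
                   unfolded = c(getc("a_u"), getc("b_u"))),
                 converged = TRUE, fit = fit),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("melting fit: Tm = %.2f degC (width %.2f degC)\n",
              x$tm, x$width))
  invisible(x)
}

#' Percent activity retained after a heat challenge
#'
#' @param heated rate after heating and cooling.
#' @param unheated rate of the unheated control; must be positive.
#' @param temperature,duration challenge conditions (degC, min; metadata).
#' @return object of class `heat_challenge` with `percent_retained`.
#' @export
residual_activity <- function(heated, unheated, temperature = NA_real_,
                              duration = NA_real_) {
  if (unheated <= 0) stop("unheated control rate must be positive")
  if (heated < 0) stop("heated rate must be nonnegative")
  structure(list(percent_retained = 100 * heated / unheated,
                 temperature = temperature, duration = duration),
            class = "heat_challenge")
}
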