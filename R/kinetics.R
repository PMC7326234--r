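#' Assay conditions for Beer-Lambert slope reduction
#'
#' @param epsilon extinction coefficient, 1/(cm M); must be positive.
#' @param path_length optical path length, cm; must be positive.
#' @param enzyme_conc enzyme concentration, uM.
#' @param blank_slope slope of the no-enzyme blank, absorbance/min.
#' @param ph assay pH (metadata only).
#' @return object of class `assay_conditions`.
#' @export
#' @examples
#' # p-nitrophenyl acetate at pH 7.0 in a 100 uL microplate well
#' assay_conditions(epsilon = 11400, path_length = 0.29)
assay_conditions <- function(epsilon, path_length, enzyme_conc = NA_real_,
                             blank_slope = 0, ph = NA_real_) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (path_length <= 0) stop("path_length must be positive")
  structure(list(epsilon = epsilon, path_length = path_length,
                 enzyme_conc = enzyme_conc, blank_slope = blank_slope,
                 ph = ph),
            class = "assay_conditions")
}

#' Convert an absorbance slope to a molar rate
#'
#' Blank-corrected Beer-Lambert reduction:
#' `rate = (slope - blank_slope) / (epsilon * path_length)` in M/min.
#' Slopes below the blank are clamped to zero and flagged (attribute
#' `clamped`) rather than propagated as negative rates.
#'
#' @param slope observed absorbance slope(s), absorbance/min.
#' @param cond an [assay_conditions()].
#' @return molar rate(s), M/min, with logical attribute `clamped`.
#' @export
slope_to_rate <- function(slope, cond) {
  stopifnot(inherits(cond, "assay_conditions"))
  rate <- (slope - cond$blank_slope) / (cond$epsilon * cond$path_length)
  clamped <- rate < 0
  if (any(clamped)) {
    warning(sum(clamped), " slope(s) below blank clamped to zero rate")
    rate[clamped] <- 0
  }
  attr(rate, "clamped") <- clamped
  rate
}

#' Rate series container
#'
#' @param substrate_mM substrate concentrations, mM (nonnegative).
#' @param rate rates; per-enzyme turnover (1/s) or molar rate (M/s),
#'   recorded by `unit`.
#' @param unit `"per_s"` (turnover) or `"M_per_s"` (molar rate).
#' @param replicate_sd optional per-point replicate standard deviations.
#' @return data.frame of class `rate_series`.
#' @export
rate_series <- function(substrate_mM, rate, unit = c("per_s", "M_per_s"),
                        replicate_sd = NULL) {
  unit <- match.arg(unit)
  if (length(substrate_mM) != length(rate))
    stop("substrate and rate lengths differ")
  if (any(substrate_mM < 0)) stop("substrate concentrations must be nonnegative")
  out <- data.frame(substrate_mM = substrate_mM, rate = rate)
  if (!is.null(replicate_sd)) out$replicate_sd <- replicate_sd
  attr(out, "unit") <- unit
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Nonlinear Michaelis-Menten fit
#'
#' Least-squares fit of `v = kcat*S/(KM + S)` to turnover rates (the v-vs-S
#' form directly, no linearization). Molar-rate input is converted to
#' per-enzyme turnover using `enzyme_conc`. Starting values are `kcat` from
#' the maximum observed rate and `KM` from the substrate concentration at
#' half-maximal rate; `stats::nls` is tried first with a
#' `minpack.lm::nlsLM` fallback. Standard errors come from the fit
#' covariance.
#'
#' @param series a [rate_series()], [gen_mm_rates()] output, or data.frame
#'   with columns `substrate_mM` and `rate_per_s` (or `rate`).
#' @param enzyme_conc enzyme concentration in uM, required only when the
#'   series carries molar rates (M/s).
#' @return object of class `michaelis_fit`: `kcat` (1/s), `km` (mM),
#'   `efficiency` (= kcat/km, 1/(s mM)), `se_kcat`, `se_km`, `converged`,
#'   and the underlying `fit`.
#' @export
fit_michaelis_menten <- function(series, enzyme_conc = NULL) {
  s <- series$substrate_mM
  v <- series$rate_per_s %||% series$rate
  if (is.null(s) || is.null(v)) stop("series must have substrate_mM and rate columns")
  unit <- attr(series, "unit") %||% "per_s"
  if (unit == "M_per_s") {
    if (is.null(enzyme_conc) || enzyme_conc <= 0)
      stop("enzyme_conc (uM) required to convert molar rates to turnover")
    v <- v / (enzyme_conc * 1e-6)  # M/s over M enzyme -> 1/s
  }
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (all(v == 0)) stop("all rates are zero; nothing to fit")
  if (length(unique(s[s > 0])) < 4L)
    warning("fewer than 4 distinct substrate concentrations; fit may be poorly determined")
  kcat0 <- max(v)
  km0 <- {
    above <- s[v >= kcat0 / 2 & s > 0]
    if (length(above)) min(above) else stats::median(s[s > 0])
  }
  dat <- data.frame(s = s, v = v)
  fit <- tryCatch(
    nls(v ~ kcat * s / (km + s), data = dat,
        start = list(kcat = kcat0, km = km0)),
    error = function(e) tryCatch(
      minpack.lm::nlsLM(v ~ kcat * s / (km + s), data = dat,
                        start = list(kcat = kcat0, km = max(km0, 1e-6)),
                        lower = c(0, 0)),
      error = function(e2) NULL)
  )
  if (is.null(fit)) stop("Michaelis-Menten fit did not converge")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  km_hat <- unname(cf["km"])
  flag_boundary <- km_hat < min(s[s > 0]) / 20
  if (flag_boundary)
    warning("fitted KM is far below the lowest substrate concentration (saturated data)")
  else if (km_hat < min(s[s > 0]) || km_hat > max(s))
    warning("substrate grid does not span the fitted KM; estimates may be extrapolated")
  structure(list(kcat = unname(cf["kcat"]), km = km_hat,
                 efficiency = unname(cf["kcat"]) / km_hat,
                 se_kcat = unname(se[1]), se_km = unname(se[2]),
                 converged = TRUE, km_at_boundary = flag_boundary,
                 n = length(s), fit = fit),
            class = "michaelis_fit")
}

#' @export
print.michaelis_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n))
  cat(sprintf("  kcat = %.4g +/- %.2g 1/s\n", x$kcat, x$se_kcat))
  cat(sprintf("  KM   = %.4g +/- %.2g mM\n", x$km, x$se_km))
  cat(sprintf("  kcat/KM = %.4g 1/(s mM)\n", x$efficiency))
  invisible(x)
}

#' Selectivity: ratio of catalytic efficiencies, fast over slow
#'
#' @param eff_fast,eff_slow catalytic efficiencies kcat/KM, 1/(s mM); both
#'   must be positive.
#' @return dimensionless selectivity.
#' @export
#' @examples
#' selectivity(8, 0.002)  # 4000: lyase reaction strongly favoured
selectivity <- function(eff_fast, eff_slow) {
  if (any(eff_fast <= 0) || any(eff_slow <= 0))
    stop("efficiencies must be positive")
  eff_fast / eff_slow
}

#' Promiscuity index: ratio of catalytic efficiencies, promiscuous over primary
#'
#' The reciprocal of [selectivity()] for the same reaction pair. A value of
#' 1 means equal catalytic efficiency for both reactions; values below 1
#' mean the promiscuous reaction is the minor one. Reported both at full
#' precision and rounded to one significant figure (the convention of
#' published promiscuity tables).
#'
#' @param eff_promiscuous,eff_primary catalytic efficiencies, 1/(s mM).
#' @return object of class `promiscuity_result`: `p`, `p_1sf`,
#'   `eff_promiscuous`, `eff_primary`.
#' @export
#' @examples
#' promiscuity(0.009, 17)$p_1sf  # 5e-04
promiscuity <- function(eff_promiscuous, eff_primary) {
  if (any(eff_promiscuous <= 0) || any(eff_primary <= 0))
    stop("efficiencies must be positive")
  p <- eff_promiscuous / eff_primary
  structure(list(p = p, p_1sf = signif(p, 1),
                 eff_promiscuous = eff_promiscuous,
                 eff_primary = eff_primary),
            class = "promiscuity_result")
}

#' @export
print.promiscuity_result <- function(x, ...) {
  cat(sprintf("promiscuity P = %.4g (reported %.1g)\n", x$p, x$p_1sf))
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' @param value_a,value_b positive quantities; `value_b` is the reference.
#' @return list: `ratio` (value_a/value_b at full precision) and `fold`
#'   (rounded-to-integer rendering).
#' @export
#' @examples
#' fold_change(0.25, 0.002)$fold  # 125
fold_change <- function(value_a, value_b) {
  if (value_b <= 0) stop("reference value must be positive")
  ratio <- value_a / value_b
  list(ratio = ratio, fold = round(ratio))
}

#' Regression of log rate ratio on substrate molecular weight
#'
#' Ordinary least squares of `ln(rate_a/rate_b)` on substrate molecular
#' weight: a positive slope means enzyme A increasingly outperforms enzyme
#' B as substrates get larger.
#'
#' @param points data.frame with columns `mw` (g/mol), `rate_a`, `rate_b`
#'   (both positive, same units).
#' @return object of class `size_rate_regression`: `slope` (per g/mol),
#'   `intercept`, `r_squared`, `se_slope`, `se_intercept`, `points`
#'   (with the `log_ratio` response), and the underlying `fit`.
#' @export
size_rate_regression <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("mw", "rate_a", "rate_b") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (any(points$rate_a <= 0 | points$rate_b <= 0))
    stop("rates must be positive (log ratio undefined)")
  points$log_ratio <- log(points$rate_a / points$rate_b)
  fit <- lm(log_ratio ~ mw, data = points)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(cf["mw"]), intercept = unname(cf["(Intercept)"]),
                 r_squared = r2, se_slope = unname(se["mw"]),
                 se_intercept = unname(se["(Intercept)"]),
                 points = points, fit = fit),
            class = "size_rate_regression")
}

#' Promiscuity comparison table for a panel of enzyme variants
#'
#' Assembles the standard variant table: catalytic efficiency for the
#' primary and the promiscuous reaction, promiscuity index (full precision
#' and 1-significant-figure rendering), and fold change in promiscuity
#' relative to a designated reference variant. Censored efficiencies
#' (detection-limit upper bounds, e.g. `<0.002`) propagate as bounds: the
#' promiscuity of a variant with a censored promiscuous-reaction efficiency
#' is itself an upper bound and is rendered as an inequality, never as a
#' point value.
#'
#' @param entries data.frame with columns `variant`, `eff_primary`,
#'   `eff_promiscuous`, and optional logical columns `primary_censored`,
#'   `promiscuous_censored` marking values that are upper bounds.
#' @param reference name of the reference variant for fold changes.
#' @return data.frame of class `promiscuity_table` with columns `variant`,
#'   `eff_primary`, `eff_promiscuous`, `p`, `p_display`, `fold_vs_ref`,
#'   `fold_display`.
#' @export
build_promiscuity_table <- function(entries, reference) {
  stopifnot(is.data.frame(entries),
            all(c("variant", "eff_primary", "eff_promiscuous") %in% names(entries)))
  n <- nrow(entries)
  pc <- entries$primary_censored %||% rep(FALSE, n)
  ec <- entries$promiscuous_censored %||% rep(FALSE, n)
  if (!reference %in% entries$variant)
    stop("reference variant '", reference, "' not among entries")
  p <- entries$eff_promiscuous / entries$eff_primary
  # censored promiscuous efficiency => upper bound on P;
  # censored primary efficiency => lower bound (not displayable as a point)
  p_upper <- ec & !pc
  p_lower <- pc & !ec
  ref_i <- match(reference, entries$variant)
  if (ec[ref_i] || pc[ref_i])
    stop("reference variant must have uncensored efficiencies")
  fold <- p / p[ref_i]
  disp <- function(x, upper, lower) {
    out <- vapply(signif(x, 1), function(v)
      format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE),
      character(1))
    out[upper] <- paste0("<", out[upper])
    out[lower] <- paste0(">", out[lower])
    out
  }
  out <- data.frame(
    variant = entries$variant,
    eff_primary = entries$eff_primary,
    eff_promiscuous = entries$eff_promiscuous,
    p = p,
    p_display = disp(p, p_upper, p_lower),
    fold_vs_ref = fold,
    fold_display = ifelse(p_upper, paste0("<", signif(fold, 2)),
                          ifelse(p_lower, paste0(">", signif(fold, 2)),
                                 as.character(round(fold)))),
    stringsAsFactors = FALSE
  )
  out$p[p_upper | p_lower] <- NA_real_  # bounds are not point values
  out$p_bound <- ifelse(p_upper, "upper", ifelse(p_lower, "lower", "point"))
  out$p_bound_value <- p
  class(out) <- c("promiscuity_table", "data.frame")
  out
}
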