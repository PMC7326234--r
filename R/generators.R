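#' Generator settings for synthetic data
#'
#' Every synthetic-data generator in the package takes a `generator_spec`
#' carrying the random seed, the noise level, and the measurement grid.
#' A fixed seed makes the output bit-identical across runs; `noise_sd = 0`
#' makes the output equal to the noiseless model exactly.
#'
#' @param seed integer random seed.
#' @param noise_sd standard deviation of additive Gaussian noise, in the
#'   units of the generated signal (rates, fluorescence counts, ...).
#' @param grid ordered numeric abscissa (substrate mM, urea M, temperature
#'   degC, or arc-length Angstrom, depending on the generator).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, noise_sd = 0, grid = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(grid)) {
    if (length(grid) == 0L) stop("grid is empty")
    if (is.unsorted(grid)) stop("grid must be ordered")
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd, grid = grid),
            class = "generator_spec")
}

# Evaluate expr with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

add_noise <- function(y, spec) {
  if (spec$noise_sd == 0) return(y)
  with_seed(spec$seed, y + rnorm(length(y), 0, spec$noise_sd))
}

#' Synthetic Michaelis-Menten rate series
#'
#' Per-enzyme turnover rates `v/E0 = kcat*S/(KM+S)` over the substrate grid,
#' with optional additive Gaussian noise. The true parameters travel with
#' the result so recovery can be checked.
#'
#' @param kcat turnover number, 1/s.
#' @param km Michaelis constant, mM.
#' @param e0 enzyme concentration, uM (metadata; rates are per enzyme).
#' @param spec a [generator_spec()]; `spec$grid` is substrate in mM.
#' @return data.frame (`substrate_mM`, `rate_per_s`) of class `mm_series`
#'   with attribute `truth = list(kcat, km, e0)`.
#' @export
#' @examples
#' s <- gen_mm_rates(0.19, 1.0, spec = generator_spec(1, 0, grid = c(0.25, 1, 4)))
#' s$rate_per_s[2]  # half-saturation: kcat/2
gen_mm_rates <- function(kcat, km, e0 = 1, spec = generator_spec()) {
  if (is.null(spec$grid)) stop("spec$grid (substrate mM) is required")
  if (kcat <= 0 || km <= 0 || e0 <= 0) stop("kcat, km, e0 must be positive")
  if (any(spec$grid < 0)) stop("substrate concentrations must be nonnegative")
  s <- spec$grid
  v <- kcat * s / (km + s)
  out <- data.frame(substrate_mM = s, rate_per_s = add_noise(v, spec))
  attr(out, "truth") <- list(kcat = kcat, km = km, e0 = e0)
  class(out) <- c("mm_series", "data.frame")
  out
}

#' Synthetic two-state urea denaturation curve
#'
#' Fluorescence over a urea grid for a protein unfolding by a two-state
#' equilibrium with free energy `dG = -m*[urea] + m*c_half` (kcal/mol).
#' The unfolded population is `p_U = 1/(1 + exp(dG/RT))` and the noiseless
#' signal is `f_unfolded*p_U + f_native*(1 - p_U)`: flat native and unfolded
#' baselines with a sigmoidal transition centred at `c_half`.
#'
#' @param m m-value, kcal/(mol M); must be positive.
#' @param c_half half-unfolding urea concentration, M.
#' @param f_native,f_unfolded plateau fluorescence signals (must differ).
#' @param temperature measurement temperature, K.
#' @param spec a [generator_spec()]; `spec$grid` is urea in M.
#' @return data.frame (`urea_M`, `signal`) of class `unfolding_curve` with
#'   attribute `truth` (parameters plus the noiseless `p_U`).
#' @export
gen_unfolding <- function(m, c_half, f_native = 1000, f_unfolded = 250,
                          temperature = 295.15, spec = generator_spec()) {
  if (is.null(spec$grid)) stop("spec$grid (urea M) is required")
  if (m <= 0) stop("m must be positive for two-state unfolding")
  if (f_native == f_unfolded) stop("f_native and f_unfolded must differ")
  urea <- spec$grid
  dg <- -m * urea + m * c_half
  p_u <- 1 / (1 + exp(dg / (R_KCAL * temperature)))
  sig <- f_unfolded * p_u + f_native * (1 - p_u)
  out <- data.frame(urea_M = urea, signal = add_noise(sig, spec))
  attr(out, "truth") <- list(m = m, c_half = c_half, f_native = f_native,
                             f_unfolded = f_unfolded,
                             temperature = temperature, p_u = p_u)
  class(out) <- c("unfolding_curve", "data.frame")
  out
}

#' Synthetic thermal melting curve
#'
#' Sigmoid transition centred at `tm` between two (optionally sloped)
#' baselines: fraction unfolded `f = 1/(1 + exp(-(T - tm)/width))`, signal
#' `= native(T)*(1 - f) + unfolded(T)*f`. At `T = tm` the signal is midway
#' between the two baselines evaluated at `tm`.
#'
#' @param tm apparent melting temperature, degC.
#' @param width transition width, degC; must be positive.
#' @param baselines list with numeric `native` and `unfolded`, each
#'   `c(intercept, slope)` (signal units, signal units per degC).
#' @param spec a [generator_spec()]; `spec$grid` is temperature in degC.
#' @return data.frame (`temp_C`, `signal`) of class `melt_curve` with
#'   attribute `truth` (parameters plus noiseless fraction unfolded).
#' @export
gen_melting <- function(tm, width, baselines = list(native = c(1000, -1),
                                                    unfolded = c(300, 0)),
                        spec = generator_spec()) {
  if (is.null(spec$grid)) stop("spec$grid (temperature degC) is required")
  if (width <= 0) stop("width must be positive")
  tt <- spec$grid
  f <- 1 / (1 + exp(-(tt - tm) / width))
  bn <- baselines$native[1] + baselines$native[2] * tt
  bu <- baselines$unfolded[1] + baselines$unfolded[2] * tt
  sig <- bn * (1 - f) + bu * f
  out <- data.frame(temp_C = tt, signal = add_noise(sig, spec))
  attr(out, "truth") <- list(tm = tm, width = width, baselines = baselines,
                             fraction_unfolded = f)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Specification of a synthetic tube-shaped channel
#'
#' The tube has a piecewise-linear clearance radius `r(s)` along its axis
#' (the z axis), described by knots `(s, r)`. Because `r(s)` is piecewise
#' linear, the exact volume `integral of pi r(s)^2 ds` is a finite sum of
#' right conical frustums and is computable in closed form.
#'
#' @param radius_knots data.frame with columns `s` (arc-length, Angstrom,
#'   strictly increasing, starting at 0) and `r` (radius, Angstrom, > 0).
#' @param length tube length in Angstrom; defaults to the last knot.
#' @param wall_atom_spacing spacing of wall atoms, Angstrom.
#' @param wall_vdw_radius van der Waals radius of the wall atoms (carbon by
#'   default; the wall is built of carbon atoms).
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(radius_knots, length = max(radius_knots$s),
                      wall_atom_spacing = 0.5, wall_vdw_radius = 1.70) {
  stopifnot(is.data.frame(radius_knots), all(c("s", "r") %in% names(radius_knots)))
  k <- radius_knots[order(radius_knots$s), , drop = FALSE]
  if (k$s[1] != 0) stop("radius knots must start at s = 0")
  if (any(diff(k$s) <= 0)) stop("knot arc-lengths must be strictly increasing")
  if (any(k$r <= 0)) stop("radius must be positive everywhere")
  if (length <= 0 || length > max(k$s))
    stop("length must be positive and covered by the radius knots")
  if (wall_atom_spacing <= 0) stop("wall_atom_spacing must be positive")
  structure(list(radius_knots = k, length = length,
                 wall_atom_spacing = wall_atom_spacing,
                 wall_vdw_radius = wall_vdw_radius),
            class = "tube_spec")
}

tube_radius_at <- function(tube, s) {
  approx(tube$radius_knots$s, tube$radius_knots$r, xout = s, rule = 2)$y
}

# Exact frustum-sum volume of a piecewise-linear radius profile over [0, length].
tube_analytic_volume <- function(tube) {
  k <- tube$radius_knots
  ss <- sort(unique(c(k$s[k$s < tube$length], tube$length)))
  rr <- tube_radius_at(tube, ss)
  sum(frustum_volume(rr[-length(rr)], rr[-1], diff(ss)))
}

#' Synthetic tube structure with analytically known channel volume
#'
#' Places carbon atoms on rings along the z axis so that the clearance
#' radius (distance to the nearest van der Waals surface) at each axial
#' station equals the requested piecewise-linear profile `r(s)`. Returns
#' the structure, the exact frustum-sum volume of the profile, and the
#' centerline path, so channel tracing and volumetrics can be validated
#' end to end. Generation fails if the realised clearance deviates from
#' the requested radius by more than 5\% anywhere (wall atoms too sparse).
#'
#' @param tube a [tube_spec()].
#' @param spec a [generator_spec()]; `noise_sd` jitters atom positions
#'   radially (Angstrom), seed fixes the ring phase jitter.
#' @return list of class `tube_structure` with elements `model`
#'   ([structure_model()]), `volume` (exact, Angstrom^3), `centerline`
#'   (data.frame x,y,z spanning the axis), `radius_knots`, and `tube`.
#' @export
gen_tube_structure <- function(tube, spec = generator_spec()) {
  stopifnot(inherits(tube, "tube_spec"))
  dz <- tube$wall_atom_spacing
  k <- tube$radius_knots
  k <- k[k$s <= tube$length, , drop = FALSE]
  if (max(k$s) < tube$length)
    k <- rbind(k, data.frame(s = tube$length,
                             r = tube_radius_at(tube, tube$length)))
  # extend the wall beyond both mouths along the end-segment slopes (keeping
  # r positive) so stations inside [0, length] see a locally complete cone
  seg_slope <- function(j) (k$r[j + 1L] - k$r[j]) / (k$s[j + 1L] - k$s[j])
  ext <- 3
  g0 <- seg_slope(1L)
  ext0 <- if (g0 > 0) min(ext, (k$r[1L] - 0.05) / g0) else ext
  g1 <- seg_slope(nrow(k) - 1L)
  ext1 <- if (g1 < 0) min(ext, (k$r[nrow(k)] - 0.05) / (-g1)) else ext
  ke <- rbind(data.frame(s = k$s[1L] - ext0, r = k$r[1L] - g0 * ext0),
              k,
              data.frame(s = k$s[nrow(k)] + ext1,
                         r = k$r[nrow(k)] + g1 * ext1))
  r_at <- function(s) approx(ke$s, ke$r, xout = s, rule = 2)$y
  # rings are laid per linear segment; on a sloped segment the wall cone is
  # inflated by sqrt(1 + slope^2) so that the inscribed-sphere clearance at
  # the axis equals r(s), not the obliquity-reduced r(s) cos(alpha)
  ring_tab <- do.call(rbind, lapply(seq_len(nrow(ke) - 1L), function(j) {
    s0 <- ke$s[j]; s1 <- ke$s[j + 1L]
    g <- (ke$r[j + 1L] - ke$r[j]) / (s1 - s0)
    zs <- unique(c(seq(s0, s1, by = dz), s1))
    data.frame(z = zs,
               ring_r = (r_at(zs) + tube$wall_vdw_radius) * sqrt(1 + g^2))
  }))
  rows <- with_seed(spec$seed, {
    lapply(seq_len(nrow(ring_tab)), function(i) {
      z <- ring_tab$z[i]
      ring_r <- ring_tab$ring_r[i]
      n <- max(8L, ceiling(2 * pi * ring_r / dz))
      # stagger alternate rings for more uniform wall coverage
      phase <- if (i %% 2L == 0L) pi / n else 0
      th <- phase + 2 * pi * (seq_len(n) - 1L) / n
      rr <- ring_r + if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
      data.frame(x = rr * cos(th), y = rr * sin(th), z = z)
    })
  })
  xyz <- do.call(rbind, rows)
  n <- nrow(xyz)
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = "CA", alt = NA_character_,
    resid = "ALA", chain = "A", resno = seq_len(n), insert = NA_character_,
    x = xyz$x, y = xyz$y, z = xyz$z, o = 1, b = 20, elesy = "C",
    stringsAsFactors = FALSE
  )
  model <- structure_model(atom, id = "synthetic-tube")
  # validate: realised clearance along the axis must track r(s) within 5%
  check_s <- seq(0, tube$length, by = min(0.25, dz / 2))
  realised <- vapply(check_s, function(s)
    clearance_radius(model, c(0, 0, s)), numeric(1))
  want <- tube_radius_at(tube, check_s)
  err <- abs(realised - want) / want
  if (max(err) > 0.05)
    stop(sprintf(paste0("wall atom spacing %.2f A too coarse: clearance ",
                        "deviates %.1f%% from the requested profile"),
                 dz, 100 * max(err)))
  structure(list(model = model,
                 volume = tube_analytic_volume(tube),
                 centerline = data.frame(x = 0, y = 0,
                                         z = c(0, tube$length)),
                 radius_knots = tube$radius_knots, tube = tube),
            class = "tube_structure")
}

#' Synthetic homolog pair with planted substitutions and flexibility hotspots
#'
#' Builds two Calpha-trace structures on a helical backbone: model B has the
#' same coordinates as model A up to Gaussian jitter, `n_subst` planted
#' amino-acid substitutions (a chosen fraction conservative under the
#' BLOSUM62-positive criterion also used by [classify_substitutions()]),
#' and B-factors elevated well above the chain standard deviation inside
#' the requested hotspot regions. The planted truth travels with the result.
#'
#' @param n_residues chain length.
#' @param n_subst number of substituted positions (`<= n_residues`).
#' @param conservative_fraction fraction of substitutions that are
#'   conservative (BLOSUM62 score > 0).
#' @param hotspot_regions list of integer ranges (e.g. `list(66:72)`) whose
#'   Calpha B-factors are elevated in model B.
#' @param coord_jitter_sd per-coordinate Gaussian jitter of model B, Angstrom.
#' @param hotspot_shift_sd hotspot B-factor elevation in units of the
#'   baseline B-factor standard deviation (default 4, comfortably above the
#'   2-SD planting guarantee).
#' @param spec a [generator_spec()]; `noise_sd` adds Gaussian noise to the
#'   B-factors of both models.
#' @return list of class `homolog_pair`: `model_a`, `model_b`
#'   ([structure_model()]s) and `truth` (substitution table, hotspot
#'   regions, identity fraction).
#' @export
gen_homolog_pair <- function(n_residues, n_subst,
                             conservative_fraction = 0.5,
                             hotspot_regions = list(),
                             coord_jitter_sd = 0.05,
                             hotspot_shift_sd = 4,
                             spec = generator_spec()) {
  if (n_subst > n_residues) stop("n_subst must not exceed n_residues")
  for (h in hotspot_regions)
    if (any(h < 1L | h > n_residues)) stop("hotspot region out of bounds")
  if (length(hotspot_regions) > 1L) {
    all_h <- unlist(hotspot_regions)
    if (anyDuplicated(all_h)) stop("hotspot regions overlap")
  }
  blosum <- blosum62_matrix()
  aas <- rownames(blosum)
  # residues with at least one positive off-diagonal BLOSUM62 partner;
  # C, G and P have none, so conservative sites cannot start from them
  cons_ok <- vapply(aas, function(a) {
    any(blosum[a, setdiff(aas, a)] > 0)
  }, logical(1))
  out <- with_seed(spec$seed, {
    seq_a <- sample(aas, n_residues, replace = TRUE)
    pos <- sort(sample.int(n_residues, n_subst))
    n_cons <- round(conservative_fraction * n_subst)
    cons_flag <- rep(FALSE, n_subst)
    if (n_cons > 0) cons_flag[seq_len(n_cons)] <- TRUE
    cons_flag <- sample(cons_flag)
    seq_b <- seq_a
    for (i in seq_along(pos)) {
      p <- pos[i]
      if (cons_flag[i] && !cons_ok[seq_a[p]])
        seq_a[p] <- sample(aas[cons_ok], 1L)
      from <- seq_a[p]
      cands <- if (cons_flag[i]) {
        setdiff(aas[blosum[from, ] > 0], from)
      } else {
        setdiff(aas[blosum[from, ] <= 0], from)
      }
      seq_b[p] <- if (length(cands) == 1L) cands else sample(cands, 1L)
    }
    # idealised alpha-helical Calpha trace: 100 deg turn, 1.5 A rise, 2.3 A radius
    i <- seq_len(n_residues)
    th <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    b_base <- rnorm(n_residues, 30, 5)
    b_a <- b_base
    b_b <- b_base
    for (h in hotspot_regions) b_b[h] <- b_b[h] + hotspot_shift_sd * 5
    if (spec$noise_sd > 0) {
      b_a <- b_a + rnorm(n_residues, 0, spec$noise_sd)
      b_b <- b_b + rnorm(n_residues, 0, spec$noise_sd)
    }
    jitter <- matrix(rnorm(3 * n_residues, 0, coord_jitter_sd), ncol = 3)
    list(seq_a = seq_a, seq_b = seq_b, pos = pos, cons = cons_flag,
         xyz = xyz, b_a = b_a, b_b = b_b, xyz_b = xyz + jitter)
  })
  mk <- function(seq1, xyz, b, id) {
    atom <- data.frame(
      type = "ATOM", eleno = seq_len(n_residues), elety = "CA",
      alt = NA_character_, resid = bio3d::aa123(seq1), chain = "A",
      resno = seq_len(n_residues), insert = NA_character_,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = b, elesy = "C",
      stringsAsFactors = FALSE
    )
    structure_model(atom, id = id)
  }
  truth_sub <- data.frame(position = out$pos,
                          aa_from = out$seq_a[out$pos],
                          aa_to = out$seq_b[out$pos],
                          conservative = out$cons)
  structure(list(
    model_a = mk(out$seq_a, out$xyz, out$b_a, "synthetic-ancestor"),
    model_b = mk(out$seq_b, out$xyz_b, out$b_b, "synthetic-descendant"),
    truth = list(substitutions = truth_sub,
                 hotspot_regions = hotspot_regions,
                 identity = 1 - n_subst / n_residues)
  ), class = "homolog_pair")
}
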