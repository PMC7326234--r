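test_that("clearance radius equals the nearest van der Waals surface", {
  one <- toy_structure(rbind(c(5, 0, 0)))  # carbon, vdW 1.70
  expect_equal(clearance_radius(one, c(0, 0, 0)), 5 - 1.7)
  # a probe at an atom centre reports minus the vdW radius
  expect_equal(clearance_radius(one, c(5, 0, 0)), -1.7)
  # random clouds agree with exhaustive enumeration
  set.seed(7)
  for (trial in 1:25) {
    xyz <- matrix(runif(150, -10, 10), ncol = 3)
    ele <- sample(c("C", "N", "O", "S"), 50, replace = TRUE)
    m <- toy_structure(xyz, elesy = ele)
    p <- runif(3, -10, 10)
    expect_equal(clearance_radius(m, p), bf_clearance(m, p))
  }
})

test_that("profile tracing samples the tube geometry at fixed steps", {
  tube <- gen_tube_structure(tube_spec(data.frame(s = c(0, 12), r = c(2, 2))),
                             generator_spec(1))
  prof <- trace_profile(tube$model, tube$centerline, step = 0.5)
  expect_equal(prof$s, seq(0, 12, by = 0.5))
  expect_true(all(abs(prof$r - 2) / 2 < 0.05))
  # a step longer than the path leaves only the endpoints
  two <- trace_profile(tube$model, tube$centerline, step = 50)
  expect_equal(two$s, c(0, 12))
  expect_error(trace_profile(tube$model, rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero-length")
  # a blocked path truncates with a warning
  expect_warning(
    blocked <- trace_profile(tube$model,
                             rbind(c(0, 0, 0), c(0, 10, 0)), step = 0.25),
    "blocked")
  expect_lt(max(blocked$s), 10)
})

test_that("frustum volume matches its closed forms and symmetries", {
  expect_equal(frustum_volume(1, 1, 3), 3 * pi)          # cylinder
  expect_equal(frustum_volume(1, 0, 3), pi)              # cone
  expect_equal(frustum_volume(2, 1, 1.5), 3.5 * pi)      # hand evaluation
  expect_equal(frustum_volume(2, 1, 1.5), frustum_volume(1, 2, 1.5))
  expect_equal(frustum_volume(1.3, 1.3, 2), pi * 1.3^2 * 2)
  expect_error(frustum_volume(-1, 1, 1), "nonnegative")
  expect_error(frustum_volume(1, 1, 0), "positive")
})

test_that("profile volume is exact, additive and monotone", {
  s <- seq(0, 10, by = 0.5)
  prof <- import_profile(data.frame(s = s, x = 0, y = 0, z = s, r = 2))
  expect_equal(profile_volume(prof), 40 * pi, tolerance = 1e-12)
  # additivity to machine precision
  v <- profile_volume(prof, 0, 10)
  expect_equal(profile_volume(prof, 0, 3.2) + profile_volume(prof, 3.2, 10),
               v, tolerance = 1e-12)
  # partial frustums interpolate radii at cut bounds
  tapered <- import_profile(data.frame(s = s, x = 0, y = 0, z = s,
                                       r = 2 - 0.1 * s))
  expect_equal(profile_volume(tapered, 0.25, 9.75),
               riemann_volume(function(q) 2 - 0.1 * q, 0.25, 9.75),
               tolerance = 1e-6)
  # enlarging every radius strictly increases the volume
  bigger <- import_profile(data.frame(s = s, x = 0, y = 0, z = s,
                                      r = (2 - 0.1 * s) + 0.2))
  expect_gt(profile_volume(bigger), profile_volume(tapered))
  expect_error(profile_volume(prof, 5, 2), "exceed")
  expect_error(profile_volume(prof, -1, 5), "outside")
})

test_that("frustum sums converge to the Riemann integral on smooth profiles", {
  rfun <- function(s) 2 + 0.6 * sin(s / 2)
  mk <- function(step) {
    s <- seq(0, 12, by = step)
    import_profile(data.frame(s = s, x = 0, y = 0, z = s, r = rfun(s)))
  }
  oracle <- riemann_volume(rfun, 0, 12, n = 200000)
  e1 <- abs(profile_volume(mk(0.5)) - oracle)
  e2 <- abs(profile_volume(mk(0.25)) - oracle)
  expect_lt(e1 / oracle, 0.005)
  # halving the step changes the volume by well under 0.1%
  expect_lt(abs(profile_volume(mk(0.25)) - profile_volume(mk(0.5))) / oracle,
            0.001)
  # observed convergence order of at least ~2
  expect_lt(e2, e1 / 3)
})

test_that("pinch points require prominence and mirror under reversal", {
  s <- seq(0, 20, by = 0.1)
  r <- 2.5 - 1.2 * exp(-((s - 10.3) / 1.5)^2)
  prof <- import_profile(data.frame(s = s, x = 0, y = 0, z = s, r = r))
  pp <- find_pinch_points(prof, min_prominence = 0.2)
  expect_equal(pp, 10.3, tolerance = 1e-9)
  # monotone profile: no pinch points
  mono <- import_profile(data.frame(s = s, x = 0, y = 0, z = s,
                                    r = 1 + 0.1 * s))
  expect_length(find_pinch_points(mono), 0L)
  # dips shallower than the prominence are not reported
  shallow <- import_profile(data.frame(s = s, x = 0, y = 0, z = s,
                                       r = 2.5 - 0.1 * exp(-((s - 8) / 1)^2)))
  expect_length(find_pinch_points(shallow, min_prominence = 0.2), 0L)
  # reversed profile mirrors the pinch position
  rev_prof <- import_profile(data.frame(s = max(s) - rev(s), x = 0, y = 0,
                                        z = s, r = rev(r)))
  expect_equal(find_pinch_points(rev_prof, 0.2), 20 - 10.3,
               tolerance = 1e-9)
})

test_that("active-site segments cut, integrate and annotate the profile", {
  s <- seq(0, 16, by = 0.25)
  cyl <- import_profile(data.frame(s = s, x = 0, y = 0, z = s, r = 1.8))
  seg <- active_site_volume(cyl, s_start = 0, length = 10.5)
  expect_equal(seg$volume, pi * 1.8^2 * 10.5, tolerance = 1e-9)
  # translation invariance on a constant profile
  seg2 <- active_site_volume(cyl, s_start = 2.25, length = 10.5)
  expect_equal(seg2$volume, seg$volume, tolerance = 1e-9)
  # profile too short is reported with the achievable length
  expect_error(active_site_volume(cyl, s_start = 10, length = 10.5),
               "achievable")
  # narrowing-then-widening profile: volume matches the integral oracle
  rfun <- function(q) 2.4 - 0.9 * exp(-((q - 6) / 2)^2)
  wav <- import_profile(data.frame(s = s, x = 0, y = 0, z = s, r = rfun(s)))
  segw <- active_site_volume(wav, 0, 10.5)
  expect_lt(abs(segw$volume - riemann_volume(rfun, 0, 10.5)) /
              segw$volume, 0.005)
  expect_equal(segw$pinch_points, 6, tolerance = 0.2)
})

test_that("profile import validates and round-trips traced profiles", {
  tube <- gen_tube_structure(tube_spec(data.frame(s = c(0, 8), r = c(2, 2))),
                             generator_spec(1))
  prof <- trace_profile(tube$model, tube$centerline, step = 0.5)
  f <- tempfile(fileext = ".csv")
  export_profile(prof, f)
  back <- import_profile(f)
  expect_equal(back$s, prof$s)
  expect_equal(back$r, prof$r)
  expect_equal(profile_volume(back), profile_volume(prof))
  # shuffled rows are sorted on import
  tab <- read.csv(f)
  shuf <- import_profile(tab[sample(nrow(tab)), ])
  expect_equal(shuf$s, prof$s)
  # malformed inputs are rejected
  tab2 <- tab; tab2$s_A[2] <- tab2$s_A[1]
  expect_error(import_profile(tab2), "duplicate")
  tab3 <- tab; tab3$r_A[3] <- 0
  expect_error(import_profile(tab3), "positive")
})
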