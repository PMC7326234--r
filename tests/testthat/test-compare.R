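test_that("PDB round trip preserves coordinates and layout", {
  tube <- gen_tube_structure(tube_spec(data.frame(s = c(0, 6), r = c(2, 2))),
                             generator_spec(1))
  f1 <- tempfile(fileext = ".pdb")
  f2 <- tempfile(fileext = ".pdb")
  write_structure(tube$model, f1)
  m2 <- read_structure(f1)
  expect_equal(m2$atom$x, round(tube$model$atom$x, 3))
  expect_equal(m2$atom$b, tube$model$atom$b)
  # write -> read -> write is byte-stable
  write_structure(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(read_structure(tempfile()), "not found")
})

test_that("altloc records resolve to the highest occupancy, ties alphabetical", {
  atom <- data.frame(
    type = "ATOM", eleno = 1:4,
    elety = c("CA", "CA", "CB", "CB"),
    alt = c("A", "B", "B", "A"),
    resid = "ALA", chain = "A", resno = c(1, 1, 1, 1),
    insert = NA_character_,
    x = c(0, 5, 1, 2), y = 0, z = 0, o = c(0.4, 0.6, 0.5, 0.5),
    elesy = "C", b = 10, stringsAsFactors = FALSE
  )
  res <- paleoenz:::resolve_altloc(atom)
  expect_equal(nrow(res), 2L)
  expect_equal(res$x[res$elety == "CA"], 5)  # occupancy 0.6 wins
  expect_equal(res$alt[res$elety == "CB"], "A")  # tie -> alphabetical
})

test_that("B-factor Z-scores standardise each chain exactly", {
  pair <- gen_homolog_pair(120, 0, spec = generator_spec(9))
  z <- normalize_bfactors(pair$model_a)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(z$z), 1, tolerance = 1e-9)
  # translation invariance: shifting all B by +10 A^2 leaves z unchanged
  shifted <- pair$model_a
  shifted$atom$b <- shifted$atom$b + 10
  expect_equal(normalize_bfactors(shifted)$z, z$z, tolerance = 1e-9)
  # uniform B-factors are an error, as is a too-short chain
  flat <- shifted
  flat$atom$b <- 30
  expect_error(normalize_bfactors(flat), "uniform|deviation")
  expect_error(normalize_bfactors(toy_structure(cbind(0:1, 0, 0))), "fewer")
})

test_that("chain alignment recovers identity on planted homolog pairs", {
  pair <- gen_homolog_pair(257, 49, conservative_fraction = 0.55,
                           spec = generator_spec(21))
  aln <- align_chains(pair$model_a, pair$model_b)
  expect_equal(aln$n_aligned, 257)
  expect_equal(aln$identity, 1 - 49 / 257, tolerance = 1e-12)
  expect_equal(round(100 * aln$identity, 1), 80.9)
  # identical chains align gap-free at identity 1
  self <- align_chains(pair$model_a, pair$model_a)
  expect_equal(self$identity, 1)
  expect_true(all(!is.na(self$positions$resno_a)))
  # C-terminal trim rule excludes tag/linker residues
  trimmed <- align_chains(pair$model_a, pair$model_b, trim_after = 200)
  expect_equal(trimmed$n_aligned, 200)
})

test_that("z-score differencing flags exactly the planted hotspot", {
  pair <- gen_homolog_pair(257, 0, hotspot_regions = list(66:72),
                           spec = generator_spec(13))
  aln <- align_chains(pair$model_a, pair$model_b)
  za <- normalize_bfactors(pair$model_a)
  zb <- normalize_bfactors(pair$model_b)
  dz <- zscore_difference(za, zb, aln, threshold = 1)
  expect_equal(nrow(dz$regions), 1L)
  expect_equal(dz$regions$start_res, 66)
  expect_equal(dz$regions$end_res, 72)
  # hotspot is elevated in model B, so dz = z_a - z_b is negative there
  expect_lt(dz$regions$mean_dz, -1)
  # identical z lists: no differences anywhere
  dz0 <- zscore_difference(za, za, aln, threshold = 1)
  expect_equal(nrow(dz0$regions), 0L)
  expect_true(all(dz0$points$dz == 0))
  # zero threshold flags every position
  dz_all <- zscore_difference(za, zb, aln, threshold = 0)
  expect_true(all(dz_all$points$flagged))
})

test_that("minimum residue distance matches exhaustive enumeration", {
  set.seed(17)
  for (trial in 1:25) {
    xyz <- matrix(runif(3 * 12, 0, 12), ncol = 3)
    m <- toy_structure(xyz, resno = rep(1:3, each = 4),
                       elety = rep(c("CA", "CB", "CG", "CD"), 3))
    expect_equal(min_residue_distance(m, 1, 3), bf_min_dist(m, 1, 3))
    expect_equal(min_residue_distance(m, 2, 3), bf_min_dist(m, 2, 3))
  }
  m <- toy_structure(matrix(runif(12), ncol = 3), resno = rep(1:2, 2))
  expect_equal(min_residue_distance(m, 1, 1), 0)
  expect_error(min_residue_distance(m, 1, 99), "not found")
  # hydrogens are excluded by default
  hm <- toy_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0)),
                      elesy = c("C", "H", "C"), resno = c(1, 1, 2),
                      elety = c("CA", "H", "CA"))
  expect_equal(min_residue_distance(hm, 1, 2), 4)
  expect_equal(min_residue_distance(hm, 1, 2, include_hydrogens = TRUE), 3)
})

test_that("Kabsch superposition is exact under rigid motion and checked against bio3d", {
  pair <- gen_homolog_pair(80, 0, spec = generator_spec(31))
  m <- pair$model_a
  # self superposition: zero RMSD, identity transform
  s0 <- superpose(m, m)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # rotated + translated copy superposes to zero
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- m
  xyz <- as.matrix(m$atom[, c("x", "y", "z")]) %*% rot
  moved$atom$x <- xyz[, 1] + 3; moved$atom$y <- xyz[, 2] - 7
  moved$atom$z <- xyz[, 3] + 11
  expect_lt(superpose(m, moved)$rmsd, 1e-6)
  # jittered copy: RMSD agrees with bio3d::fit.xyz on the same pairs
  jit <- gen_homolog_pair(80, 0, coord_jitter_sd = 0.3,
                          spec = generator_spec(32))
  sp <- superpose(jit$model_a, jit$model_b)
  xa <- as.numeric(t(as.matrix(jit$model_a$atom[, c("x", "y", "z")])))
  xb <- as.numeric(t(as.matrix(jit$model_b$atom[, c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(fixed = xa, mobile = xb,
                           fixed.inds = 1:length(xa),
                           mobile.inds = 1:length(xb))
  expect_equal(sp$rmsd, bio3d::rmsd(xa, fitted), tolerance = 1e-3)
  # per-atom Gaussian jitter sd sigma gives RMSD near sigma * sqrt(3)
  expect_equal(sp$rmsd, 0.3 * sqrt(3), tolerance = 0.15)
  # degenerate collinear sets are refused
  lin <- toy_structure(cbind(1:5, 0, 0))
  expect_error(superpose(lin, lin), "collinear|degenerate")
})

test_that("substitution classification round-trips the planted plan", {
  pair <- gen_homolog_pair(200, 30, conservative_fraction = 0.6,
                           hotspot_regions = list(),
                           spec = generator_spec(41))
  aln <- align_chains(pair$model_a, pair$model_b)
  subs <- classify_substitutions(aln, pair$model_a, pair$model_b,
                                 cap_range = c(108, 179), n_points = 60)
  truth <- pair$truth$substitutions
  expect_equal(subs$summary$n_substitutions, 30)
  got <- subs$records[order(subs$records$resno_a), ]
  expect_equal(got$resno_a, truth$position)
  expect_equal(got$aa_from, truth$aa_from)
  expect_equal(got$aa_to, truth$aa_to)
  expect_equal(got$conservative, truth$conservative)
  expect_equal(subs$summary$n_conservative, round(0.6 * 30))
  expect_equal(got$domain, ifelse(truth$position >= 108 &
                                    truth$position <= 179,
                                  "cap", "catalytic"))
  # no mismatches -> empty record set
  none <- classify_substitutions(align_chains(pair$model_a, pair$model_a),
                                 pair$model_a, pair$model_a, n_points = 60)
  expect_equal(none$summary$n_substitutions, 0)
})

test_that("Shrake-Rupley SASA matches closed forms", {
  # isolated atom: full inflated sphere
  one <- toy_structure(rbind(c(0, 0, 0)), elesy = "O", elety = "O")
  s1 <- compute_sasa(one, n_points = 960)
  expect_equal(s1$total, 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-6)
  # two equal overlapping spheres: analytic lens formula within 2%
  two <- toy_structure(rbind(c(0, 0, 0), c(2, 0, 0)), elesy = "O",
                       elety = c("O", "OXT"), resno = c(1, 1))
  s2 <- compute_sasa(two, n_points = 960)
  rr <- 1.52 + 1.4
  h <- rr - 1
  analytic <- 2 * (4 * pi * rr^2 - 2 * pi * rr * h)
  expect_lt(abs(s2$total - analytic) / analytic, 0.02)
  # atom buried inside a dense shell is inaccessible
  dirs <- paleoenz:::fibonacci_sphere(200)
  shell <- toy_structure(rbind(c(0, 0, 0), dirs * 2.2),
                         resno = c(1, rep(2, 200)))
  sb <- compute_sasa(shell, n_points = 240)
  expect_lt(sb$atom$sasa[1], 1e-6)
  # convergence: doubling the sampling changes the total by < 0.5%
  pair <- gen_homolog_pair(60, 0, spec = generator_spec(51))
  t1 <- compute_sasa(pair$model_a, n_points = 480)$total
  t2 <- compute_sasa(pair$model_a, n_points = 960)$total
  expect_lt(abs(t1 - t2) / t2, 0.005)
})

test_that("interaction census counts match brute force and are monotone", {
  toy <- asp_lys_toy(5)
  # only OD1 is within 5 A of NZ at this geometry
  expect_equal(interaction_census(toy, salt_cutoff = 5)$salt_pair_count, 1L)
  expect_equal(interaction_census(toy, salt_cutoff = 5)$salt_pair_count,
               bf_salt_pairs(toy, 5))
  # widening the cutoff can only add pairs
  c7 <- interaction_census(toy, salt_cutoff = 7)$salt_pair_count
  expect_gte(c7, 1L)
  expect_equal(c7, bf_salt_pairs(toy, 7))
  # randomized charged toys agree with exhaustive enumeration
  set.seed(99)
  resids <- c("ASP", "GLU", "LYS", "ARG", "HIS", "ALA")
  ats <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
              ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
              ALA = "CB")
  for (trial in 1:20) {
    rs <- sample(resids, 15, replace = TRUE)
    rows <- do.call(rbind, lapply(seq_along(rs), function(i) {
      nm <- ats[[rs[i]]]
      data.frame(resid = rs[i], resno = i, elety = nm,
                 x = runif(length(nm), 0, 20), y = runif(length(nm), 0, 20),
                 z = runif(length(nm), 0, 20))
    }))
    m <- structure_model(data.frame(
      type = "ATOM", eleno = seq_len(nrow(rows)), elety = rows$elety,
      alt = NA, resid = rows$resid, chain = "A", resno = rows$resno,
      insert = NA, x = rows$x, y = rows$y, z = rows$z, o = 1, b = 10,
      elesy = substr(rows$elety, 1, 1), stringsAsFactors = FALSE))
    expect_equal(interaction_census(m, salt_cutoff = 7)$salt_pair_count,
                 bf_salt_pairs(m, 7))
  }
  # a structure with no charged residues has no salt pairs
  ala <- toy_structure(matrix(runif(30), ncol = 3))
  expect_equal(interaction_census(ala)$salt_pair_count, 0L)
})

test_that("hydrogen bond census finds a planted backbone pair", {
  atoms <- data.frame(
    type = "ATOM", eleno = 1:4,
    elety = c("N", "O", "N", "O"), alt = NA,
    resid = "ALA", chain = "A", resno = c(1, 1, 5, 5), insert = NA,
    x = c(0, 1.2, 4.0, 9), y = 0, z = 0, o = 1, b = 10,
    elesy = c("N", "O", "N", "O"), stringsAsFactors = FALSE
  )
  m <- structure_model(atoms)
  cen <- interaction_census(m)
  # res1 O -- res5 N at 2.8 A is the only inter-residue donor-acceptor pair
  # inside the 2.4-3.5 A window
  expect_equal(cen$hbond_count, 1L)
  expect_equal(interaction_census(m, hbond_max = 2.0)$hbond_count, 0L)
})

test_that("residue type counts are exact and order-invariant", {
  pair <- gen_homolog_pair(100, 0, spec = generator_spec(61))
  m <- pair$model_a
  counts <- count_residue_types(m, c("GLY", "PRO"))
  seqs <- bio3d::aa321(m$atom$resid)
  expect_equal(counts$count[counts$resid == "GLY"], sum(seqs == "G"))
  expect_equal(counts$count[counts$resid == "PRO"], sum(seqs == "P"))
  # shuffling atom order does not change the census
  shuf <- m
  perm <- sample(nrow(shuf$atom))
  shuf$atom <- shuf$atom[perm, ]
  expect_equal(count_residue_types(shuf, c("GLY", "PRO"))$count,
               counts$count)
  # the tag/linker exclusion rule drops high-numbered residues
  trimmed <- count_residue_types(m, c("GLY", "PRO"), exclude_after = 50)
  expect_lte(sum(trimmed$count), sum(counts$count))
})
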