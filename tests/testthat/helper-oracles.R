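# Independent brute-force oracles and toy-structure builders used across
# the suite. These never call the implementation paths they check.

# Structure from a bare coordinate table (element defaults to carbon).
toy_structure <- function(xyz, elesy = "C", resid = "ALA", resno = NULL,
                          elety = NULL, chain = "A", b = 20) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  structure_model(data.frame(
    type = "ATOM", eleno = seq_len(n),
    elety = elety %||% rep("CA", n), alt = NA_character_,
    resid = rep_len(resid, n), chain = rep_len(chain, n),
    resno = resno %||% seq_len(n), insert = NA_character_,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = rep_len(b, n), elesy = rep_len(elesy, n),
    stringsAsFactors = FALSE
  ), id = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive clearance radius: loop over every atom, no vectorized path.
bf_clearance <- function(model, point) {
  a <- model$atom
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - point)^2))
    r <- d - vdw_radius(a$elesy[i])
    if (r < best) best <- r
  }
  best
}

# Exhaustive minimum inter-residue atom distance.
bf_min_dist <- function(model, resno_a, resno_b, chain = "A") {
  a <- model$atom
  sa <- a[a$chain == chain & a$resno == resno_a & a$elesy != "H", ]
  sb <- a[a$chain == chain & a$resno == resno_b & a$elesy != "H", ]
  best <- Inf
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    d <- sqrt((sa$x[i] - sb$x[j])^2 + (sa$y[i] - sb$y[j])^2 +
                (sa$z[i] - sb$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# Exhaustive count of opposite-charge atom pairs within a cutoff, using
# the same charge assignment table as the implementation but a plain
# double loop over all pairs.
bf_salt_pairs <- function(model, cutoff = 7) {
  a <- model$atom[!model$atom$het, ]
  chg <- integer(nrow(a))
  neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  pos <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
              HIS = c("ND1", "NE2"))
  for (i in seq_len(nrow(a))) {
    if (a$resid[i] %in% names(neg) && a$elety[i] %in% neg[[a$resid[i]]])
      chg[i] <- -1L
    if (a$resid[i] %in% names(pos) && a$elety[i] %in% pos[[a$resid[i]]])
      chg[i] <- 1L
  }
  count <- 0L
  for (i in seq_len(nrow(a) - 1L)) for (j in (i + 1L):nrow(a)) {
    if (chg[i] * chg[j] == -1L) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= cutoff) count <- count + 1L
    }
  }
  count
}

# Fine-step Riemann integral of pi r(s)^2 ds for a radius function.
riemann_volume <- function(radius_fn, s_start, s_end, n = 20000) {
  s <- seq(s_start, s_end, length.out = n + 1)
  r <- radius_fn(s)
  mid <- (r[-1]^2 + r[-(n + 1)]^2) / 2
  sum(pi * mid * diff(s))
}

# Minimal two-residue toy with full sidechain-like atom names, used for
# interaction censuses: one Asp carboxylate and one Lys amine at a set
# nitrogen-oxygen distance.
asp_lys_toy <- function(no_dist = 5) {
  atoms <- data.frame(
    type = "ATOM", eleno = 1:6,
    elety = c("CA", "OD1", "OD2", "CA", "NZ", "CB"),
    alt = NA_character_,
    resid = c("ASP", "ASP", "ASP", "LYS", "LYS", "LYS"),
    chain = "A", resno = c(1, 1, 1, 2, 2, 2), insert = NA_character_,
    x = c(0, 0.5, -0.5, no_dist + 1, no_dist, no_dist + 2),
    y = c(0, 1, 1, 0, 1, 0), z = 0,
    o = 1, b = 20, elesy = c("C", "O", "O", "C", "N", "C"),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, id = "asp-lys-toy")
}
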