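#' Minimum interatomic distance between two residues
#'
#' Smallest pairwise Euclidean distance between the atom sets of two
#' residues, by default over non-hydrogen atoms only (the convention of
#' published closest-contact tables).
#'
#' @param model a [structure_model()].
#' @param resno_a,resno_b residue numbers (author numbering).
#' @param chain chain identifier (default `"A"`).
#' @param include_hydrogens include hydrogen atoms (default FALSE).
#' @return minimum distance in Angstrom.
#' @export
min_residue_distance <- function(model, resno_a, resno_b, chain = "A",
                                 include_hydrogens = FALSE) {
  ra <- residue_atoms(model, chain, resno_a, include_hydrogens)
  rb <- residue_atoms(model, chain, resno_b, include_hydrogens)
  if (nrow(ra) == 0L) stop("residue ", resno_a, " not found in chain ", chain)
  if (nrow(rb) == 0L) stop("residue ", resno_b, " not found in chain ", chain)
  xa <- coords_matrix(ra)
  xb <- coords_matrix(rb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

# Formal-charge and hydrogen-bond heuristics by residue/atom name.
# Protonation-free: side-chain carboxylate oxygens negative; Lys NZ,
# Arg guanidinium nitrogens and His ring nitrogens positive.
CHARGED_ATOMS <- list(
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  positive = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))
)

HBOND_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)

HBOND_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH", MET = "SD"
)

match_atom_set <- function(atom, spec) {
  hit <- rep(FALSE, nrow(atom))
  for (res in names(spec)) {
    if (res == "backbone") {
      hit <- hit | atom$elety %in% spec[[res]]
    } else {
      hit <- hit | (atom$resid == res & atom$elety %in% spec[[res]])
    }
  }
  hit
}

count_pairs_within <- function(xa, xb, cutoff, same_set = FALSE,
                               min_dist = 0, exclude = NULL) {
  if (nrow(xa) == 0L || nrow(xb) == 0L) return(0L)
  d2 <- outer(rowSums(xa[, 1:3, drop = FALSE]^2),
              rowSums(xb[, 1:3, drop = FALSE]^2), `+`) -
    2 * xa[, 1:3, drop = FALSE] %*% t(xb[, 1:3, drop = FALSE])
  ok <- d2 <= cutoff^2 & d2 >= min_dist^2
  if (!is.null(exclude)) ok <- ok & !exclude
  if (same_set) sum(ok[upper.tri(ok)]) else sum(ok)
}

#' Census of stabilizing interactions in a structure
#'
#' Geometric counts under explicit, echoed criteria: salt pairs
#' (oppositely charged atoms within `salt_cutoff`), hydrogen bonds
#' (donor-acceptor heavy-atom pairs between `hbond_min` and `hbond_max`,
#' different residues; hydrogens need not be present), nonpolar contacts
#' (carbon-carbon pairs of different residues within `nonpolar_cutoff`),
#' and total and nonpolar solvent-accessible surface area. All criteria
#' are returned with the counts because such censuses are
#' criterion-dependent.
#'
#' @param model a [structure_model()].
#' @param chain optional chain restriction.
#' @param salt_cutoff distance limit for opposite formal charges, Angstrom.
#' @param hbond_max,hbond_min donor-acceptor heavy-atom distance window,
#'   Angstrom.
#' @param nonpolar_cutoff carbon-carbon contact limit, Angstrom.
#' @param include_sasa also run [compute_sasa()] (slower).
#' @param n_points SASA sampling density when `include_sasa = TRUE`.
#' @return object of class `interaction_census`: `salt_pair_count`,
#'   `hbond_count`, `nonpolar_contact_count`, `sasa_total`,
#'   `sasa_nonpolar` (NA unless requested), `criteria`.
#' @export
interaction_census <- function(model, chain = NULL, salt_cutoff = 7.0,
                               hbond_max = 3.5, hbond_min = 2.4,
                               nonpolar_cutoff = 4.5,
                               include_sasa = FALSE, n_points = 120) {
  a <- model$atom
  a <- a[!a$het & a$elesy != "H", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms selected")
  xyz <- coords_matrix(a)
  neg <- match_atom_set(a, CHARGED_ATOMS$negative)
  pos <- match_atom_set(a, CHARGED_ATOMS$positive)
  salt <- count_pairs_within(xyz[neg, , drop = FALSE],
                             xyz[pos, , drop = FALSE], salt_cutoff)
  don <- match_atom_set(a, HBOND_DONORS)
  acc <- match_atom_set(a, HBOND_ACCEPTORS)
  xd <- xyz[don, , drop = FALSE]
  xc <- xyz[acc, , drop = FALSE]
  same_res <- outer(paste(a$chain, a$resno)[don],
                    paste(a$chain, a$resno)[acc], `==`)
  hb <- count_pairs_within(xd, xc, hbond_max, min_dist = hbond_min,
                           exclude = same_res)
  cc <- a$elesy == "C"
  xcc <- xyz[cc, , drop = FALSE]
  res_cc <- paste(a$chain, a$resno)[cc]
  same_cc <- outer(res_cc, res_cc, `==`)
  np <- {
    d2 <- outer(rowSums(xcc^2), rowSums(xcc^2), `+`) - 2 * xcc %*% t(xcc)
    ok <- d2 <= nonpolar_cutoff^2 & !same_cc
    sum(ok[upper.tri(ok)])
  }
  sasa_total <- sasa_nonpolar <- NA_real_
  if (include_sasa) {
    s <- compute_sasa(model, chain = chain, n_points = n_points)
    sasa_total <- s$total
    sasa_nonpolar <- s$total_nonpolar
  }
  structure(list(
    salt_pair_count = salt, hbond_count = hb,
    nonpolar_contact_count = np,
    sasa_total = sasa_total, sasa_nonpolar = sasa_nonpolar,
    criteria = list(salt_cutoff = salt_cutoff, hbond_max = hbond_max,
                    hbond_min = hbond_min,
                    nonpolar_cutoff = nonpolar_cutoff,
                    charge_model = "Asp/Glu carboxylate O negative; Lys NZ, Arg NE/NH1/NH2, His ND1/NE2 positive")
  ), class = "interaction_census")
}

#' @export
print.interaction_census <- function(x, ...) {
  cat(sprintf("interactions: %d salt pairs, %d H-bonds, %d nonpolar contacts\n",
              x$salt_pair_count, x$hbond_count, x$nonpolar_contact_count))
  invisible(x)
}

#' Count residues of given types in a chain
#'
#' Exact per-chain counts of residues by 3-letter name, one per residue
#' (insertion codes respected), with an optional exclusion of
#' purification-tag/linker residues by residue-number cutoff.
#'
#' @param model a [structure_model()].
#' @param residue_names 3-letter names to count (default Gly and Pro, the
#'   unfolded-state flexibility census).
#' @param chain optional chain restriction (default all chains, reported
#'   per chain).
#' @param exclude_after optional residue number; residues with
#'   `resno > exclude_after` are ignored (tag/linker exclusion).
#' @return data.frame `chain`, `resid`, `count`.
#' @export
count_residue_types <- function(model, residue_names = c("GLY", "PRO"),
                                chain = NULL, exclude_after = NULL) {
  a <- model$atom[!model$atom$het, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(exclude_after)) a <- a[a$resno <= exclude_after, , drop = FALSE]
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert))
  res <- a[!duplicated(key), c("chain", "resid"), drop = FALSE]
  chains <- unique(res$chain)
  out <- expand.grid(chain = chains, resid = residue_names,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(ch, rn) sum(res$chain == ch & res$resid == rn),
                      out$chain, out$resid)
  out[order(out$chain, out$resid), , drop = FALSE]
}
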