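# BLOSUM62 restricted to the 20 standard residues plus X, via Biostrings.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      aas <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
      cache <<- e$BLOSUM62[aas, aas]
    }
    cache
  }
})

# One-letter sequence of a chain from its Calpha records; non-standard
# residues map to X.
chain_sequence <- function(model, chain) {
  ca <- ca_atoms(model, chain)
  if (nrow(ca) == 0L) stop("chain ", chain, " has no Calpha atoms")
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | !aa %in% rownames(blosum62_matrix())] <- "X"
  list(seq = aa, resno = ca$resno)
}

#' Global alignment of two chains
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) of the
#' Calpha sequences of one chain from each model, through
#' `Biostrings::pairwiseAlignment`. Identity is computed over aligned
#' non-gap columns. Purification-tag and linker residues can be excluded
#' with a C-terminal trim: residues numbered above `trim_after` are
#' dropped before aligning.
#'
#' @param model_a,model_b [structure_model()]s.
#' @param chain_a,chain_b chain identifiers (default `"A"`).
#' @param trim_after optional residue number; residues with
#'   `resno > trim_after` are excluded from both chains (His-tag/linker
#'   trim rule).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return object of class `chain_alignment`: `positions` (data.frame
#'   `resno_a`, `aa_a`, `resno_b`, `aa_b`, `match`; `NA` resno marks a
#'   gap), `identity` (fraction over aligned non-gap columns),
#'   `n_aligned`.
#' @export
align_chains <- function(model_a, model_b, chain_a = "A", chain_b = "A",
                         trim_after = NULL, gap_opening = 10,
                         gap_extension = 0.5) {
  sa <- chain_sequence(model_a, chain_a)
  sb <- chain_sequence(model_b, chain_b)
  if (!is.null(trim_after)) {
    ka <- sa$resno <= trim_after
    kb <- sb$resno <= trim_after
    sa <- list(seq = sa$seq[ka], resno = sa$resno[ka])
    sb <- list(seq = sb$seq[kb], resno = sb$resno[kb])
  }
  if (!length(sa$seq) || !length(sb$seq))
    stop("cannot align an empty chain")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(sa$seq, collapse = "")),
    Biostrings::AAString(paste(sb$seq, collapse = "")),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  n <- length(pa)
  resno_a <- resno_b <- integer(n)
  for (k in seq_len(n)) {
    if (pa[k] != "-") { ia <- ia + 1L; resno_a[k] <- sa$resno[ia] }
    else resno_a[k] <- NA_integer_
    if (pb[k] != "-") { ib <- ib + 1L; resno_b[k] <- sb$resno[ib] }
    else resno_b[k] <- NA_integer_
  }
  pos <- data.frame(resno_a = resno_a, aa_a = pa, resno_b = resno_b,
                    aa_b = pb, stringsAsFactors = FALSE)
  pos$match <- !is.na(pos$resno_a) & !is.na(pos$resno_b) & pos$aa_a == pos$aa_b
  aligned <- !is.na(pos$resno_a) & !is.na(pos$resno_b)
  structure(list(positions = pos,
                 identity = sum(pos$match) / sum(aligned),
                 n_aligned = sum(aligned)),
            class = "chain_alignment")
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf("chain alignment: %d aligned positions, %.1f%% identity\n",
              x$n_aligned, 100 * x$identity))
  invisible(x)
}

# Kabsch: rotation R minimising ||b_centred %*% R - a_centred|| (row vectors).
kabsch_rotation <- function(a, b) {
  h <- crossprod(b, a)
  svd_h <- svd(h)
  d <- sign(det(svd_h$u %*% t(svd_h$v)))
  svd_h$u %*% diag(c(1, 1, d)) %*% t(svd_h$v)
}

#' Rigid superposition of two structures (Kabsch)
#'
#' Least-squares rigid-body superposition of the matched Calpha atoms of
#' chain B onto chain A via the Kabsch singular-value-decomposition
#' algorithm, with the RMSD over the matched Calphas after the transform.
#' Optional iterative outlier rejection (residues beyond `trim_cutoff`
#' times the current RMSD dropped, refit) reports a core RMSD separately
#' from the all-position value.
#'
#' @param model_a,model_b [structure_model()]s.
#' @param alignment optional [align_chains()] result; if omitted, residues
#'   are matched by number.
#' @param chain_a,chain_b chains used (default `"A"`).
#' @param trim_cycles iterations of outlier rejection (0 = none).
#' @param trim_cutoff rejection threshold in multiples of the RMSD.
#' @return object of class `superposition`: `rmsd` (Angstrom, all matched
#'   positions), `rotation` (3x3), `translation` (length 3; transform maps
#'   B coordinates onto A as `x R + t`), `n_matched`, and if trimmed,
#'   `rmsd_core`/`n_core`.
#' @export
superpose <- function(model_a, model_b, alignment = NULL,
                      chain_a = "A", chain_b = "A",
                      trim_cycles = 0, trim_cutoff = 2) {
  ca_a <- ca_atoms(model_a, chain_a)
  ca_b <- ca_atoms(model_b, chain_b)
  if (is.null(alignment)) {
    common <- intersect(ca_a$resno, ca_b$resno)
    map <- data.frame(resno_a = common, resno_b = common)
  } else {
    pos <- alignment$positions
    map <- pos[!is.na(pos$resno_a) & !is.na(pos$resno_b),
               c("resno_a", "resno_b"), drop = FALSE]
  }
  ia <- match(map$resno_a, ca_a$resno)
  ib <- match(map$resno_b, ca_b$resno)
  keep <- !is.na(ia) & !is.na(ib)
  xa <- coords_matrix(ca_a)[ia[keep], , drop = FALSE]
  xb <- coords_matrix(ca_b)[ib[keep], , drop = FALSE]
  n <- nrow(xa)
  if (n < 3L) stop("need at least 3 matched Calpha pairs")
  if (qr(sweep(xa, 2, colMeans(xa)))$rank < 2L)
    stop("degenerate (collinear) point set")
  fit_pair <- function(xa, xb) {
    ca <- colMeans(xa); cb <- colMeans(xb)
    rot <- kabsch_rotation(sweep(xa, 2, ca), sweep(xb, 2, cb))
    moved <- sweep(sweep(xb, 2, cb) %*% rot, 2, ca, `+`)
    list(rot = rot, trans = ca - drop(cb %*% rot),
         dev = sqrt(rowSums((moved - xa)^2)))
  }
  f <- fit_pair(xa, xb)
  rmsd_all <- sqrt(mean(f$dev^2))
  out <- list(rmsd = rmsd_all, rotation = f$rot, translation = f$trans,
              n_matched = n)
  if (trim_cycles > 0) {
    keep_i <- seq_len(n)
    fc <- f
    for (cyc in seq_len(trim_cycles)) {
      rms <- sqrt(mean(fc$dev^2))
      inl <- which(fc$dev <= trim_cutoff * rms)
      if (length(inl) == length(keep_i) || length(inl) < 3L) break
      keep_i <- keep_i[inl]
      fc <- fit_pair(xa[keep_i, , drop = FALSE], xb[keep_i, , drop = FALSE])
    }
    out$rmsd_core <- sqrt(mean(fc$dev^2))
    out$n_core <- length(keep_i)
  }
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d Calpha pairs: RMSD %.3f A\n",
              x$n_matched, x$rmsd))
  if (!is.null(x$rmsd_core))
    cat(sprintf("  trimmed core: %d pairs, RMSD %.3f A\n",
                x$n_core, x$rmsd_core))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' Maps points from the mobile (B) frame into the reference (A) frame,
#' e.g. to transfer a tunnel start point marked in a reference structure.
#'
#' @param sup a [superpose()] result.
#' @param xyz numeric matrix (n x 3) or length-3 vector.
#' @return transformed coordinates, same shape as the input.
#' @export
transfer_points <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition"))
  v <- is.null(dim(xyz))
  m <- if (v) matrix(xyz, ncol = 3) else as.matrix(xyz)
  out <- sweep(m %*% sup$rotation, 2, sup$translation, `+`)
  if (v) drop(out) else out
}

#' Classify substitutions between two aligned chains
#'
#' Every aligned mismatch becomes a substitution record with three
#' annotations: conservative or not (default criterion: positive BLOSUM62
#' score, a named, swappable policy), surface exposure (relative
#' per-residue solvent accessibility of the first model at or above
#' `sasa_threshold`), and domain assignment (cap/lid versus catalytic,
#' from the residue interval `cap_range`).
#'
#' @param alignment a [align_chains()] result.
#' @param model_a,model_b the two [structure_model()]s.
#' @param chain_a,chain_b chains used.
#' @param cap_range inclusive residue interval of the cap (lid) domain,
#'   default `c(108, 179)`.
#' @param sasa_threshold relative SASA at or above which a residue counts
#'   as surface exposed (default 0.01: "at least some surface exposed").
#' @param sasa optional precomputed [compute_sasa()] result for
#'   `model_a`; computed on demand otherwise.
#' @param criterion `"blosum62"` (score > 0 is conservative) or a
#'   function `(aa_from, aa_to) -> logical`.
#' @param n_points sphere sampling density for on-demand SASA.
#' @return list of class `substitution_set`: `records` (data.frame
#'   `resno_a`, `resno_b`, `aa_from`, `aa_to`, `score`, `conservative`,
#'   `surface_exposed`, `domain`) and `summary` (counts and fractions).
#' @export
classify_substitutions <- function(alignment, model_a, model_b,
                                   chain_a = "A", chain_b = "A",
                                   cap_range = c(108, 179),
                                   sasa_threshold = 0.01, sasa = NULL,
                                   criterion = "blosum62",
                                   n_points = 240) {
  stopifnot(inherits(alignment, "chain_alignment"))
  pos <- alignment$positions
  mm <- !is.na(pos$resno_a) & !is.na(pos$resno_b) & pos$aa_a != pos$aa_b
  rec <- pos[mm, , drop = FALSE]
  blosum <- blosum62_matrix()
  if (nrow(rec)) {
    score <- blosum[cbind(rec$aa_a, rec$aa_b)]
    conservative <- if (is.function(criterion)) {
      mapply(criterion, rec$aa_a, rec$aa_b)
    } else if (identical(criterion, "blosum62")) {
      score > 0
    } else stop("unknown conservative-substitution criterion: ", criterion)
    if (is.null(sasa))
      sasa <- compute_sasa(model_a, chain = chain_a, n_points = n_points)
    rel <- sasa$residue$rel_sasa[match(rec$resno_a, sasa$residue$resno)]
    records <- data.frame(
      resno_a = rec$resno_a, resno_b = rec$resno_b,
      aa_from = rec$aa_a, aa_to = rec$aa_b, score = score,
      conservative = conservative,
      surface_exposed = !is.na(rel) & rel >= sasa_threshold,
      domain = ifelse(rec$resno_a >= cap_range[1] &
                        rec$resno_a <= cap_range[2], "cap", "catalytic"),
      stringsAsFactors = FALSE
    )
  } else {
    records <- data.frame(resno_a = integer(0), resno_b = integer(0),
                          aa_from = character(0), aa_to = character(0),
                          score = numeric(0), conservative = logical(0),
                          surface_exposed = logical(0),
                          domain = character(0))
  }
  summary <- list(
    n_substitutions = nrow(records),
    n_conservative = sum(records$conservative),
    fraction_conservative = if (nrow(records)) mean(records$conservative)
      else NA_real_,
    n_surface = sum(records$surface_exposed),
    n_cap = sum(records$domain == "cap"),
    n_catalytic = sum(records$domain == "catalytic"),
    criterion = if (is.function(criterion)) "custom" else criterion,
    sasa_threshold = sasa_threshold, cap_range = cap_range
  )
  structure(list(records = records, summary = summary),
            class = "substitution_set")
}

#' @export
print.substitution_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("substitutions: %d (%d conservative, %d on surface; %d cap / %d catalytic)\n",
              s$n_substitutions, s$n_conservative, s$n_surface,
              s$n_cap, s$n_catalytic))
  invisible(x)
}
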