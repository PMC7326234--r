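#' Z-score normalization of Calpha B-factors
#'
#' Per-chain standardization of the crystallographic B-factors of the
#' Calpha atoms: subtract the chain mean and divide by the chain standard
#' deviation. The resulting Z-scores have mean 0 and SD 1 within the chain
#' and are comparable across structures solved at different resolutions.
#'
#' @param model a [structure_model()].
#' @param chain chain identifier (default `"A"`).
#' @return data.frame of class `residue_zscore`: `chain`, `resno`,
#'   `resid`, `b` (raw, Angstrom^2), `z`.
#' @export
normalize_bfactors <- function(model, chain = "A") {
  ca <- ca_atoms(model, chain)
  if (nrow(ca) < 3L)
    stop("chain ", chain, " has fewer than 3 Calpha atoms")
  mu <- mean(ca$b)
  sigma <- sd(ca$b)
  if (sigma == 0) stop("uniform B-factors: standard deviation is zero")
  out <- data.frame(chain = chain, resno = ca$resno, resid = ca$resid,
                    b = ca$b, z = (ca$b - mu) / sigma)
  attr(out, "mean_b") <- mu
  attr(out, "sd_b") <- sigma
  class(out) <- c("residue_zscore", "data.frame")
  out
}

#' Difference of normalized flexibility between two aligned chains
#'
#' At every aligned position, `dz = z_a - z_b`: positive values mark
#' residues more mobile in structure A than in B. Contiguous runs with
#' `|dz| >= threshold` are reported as flexibility-difference regions.
#' Alignment gap positions are excluded.
#'
#' @param za,zb [normalize_bfactors()] outputs for the two chains.
#' @param alignment a [align_chains()] result mapping residues of A to B.
#' @param threshold flag limit in SD units (default 1).
#' @return list of class `zscore_difference`: `points` (per matched
#'   position: `resno_a`, `resno_b`, `z_a`, `z_b`, `dz`, `flagged`) and
#'   `regions` (`start_res`, `end_res`, `n`, `mean_dz`, in A numbering).
#' @export
zscore_difference <- function(za, zb, alignment, threshold = 1) {
  stopifnot(inherits(alignment, "chain_alignment"))
  pos <- alignment$positions
  pos <- pos[!is.na(pos$resno_a) & !is.na(pos$resno_b), , drop = FALSE]
  ia <- match(pos$resno_a, za$resno)
  ib <- match(pos$resno_b, zb$resno)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no matched positions with Z-scores on both chains")
  pts <- data.frame(resno_a = pos$resno_a[keep], resno_b = pos$resno_b[keep],
                    z_a = za$z[ia[keep]], z_b = zb$z[ib[keep]])
  pts$dz <- pts$z_a - pts$z_b
  pts$flagged <- abs(pts$dz) >= threshold
  pts <- pts[order(pts$resno_a), , drop = FALSE]
  regions <- flag_runs(pts$resno_a, pts$flagged, pts$dz)
  structure(list(points = pts, regions = regions, threshold = threshold),
            class = "zscore_difference")
}

# Contiguous runs (in residue numbering) of flagged positions.
flag_runs <- function(resno, flagged, dz) {
  if (!any(flagged)) {
    return(data.frame(start_res = integer(0), end_res = integer(0),
                      n = integer(0), mean_dz = numeric(0)))
  }
  idx <- which(flagged)
  brk <- c(0L, which(diff(resno[idx]) > 1L), length(idx))
  out <- lapply(seq_len(length(brk) - 1L), function(k) {
    run <- idx[(brk[k] + 1L):brk[k + 1L]]
    data.frame(start_res = resno[run[1L]], end_res = resno[run[length(run)]],
               n = length(run), mean_dz = mean(dz[run]))
  })
  do.call(rbind, out)
}

#' @export
print.zscore_difference <- function(x, ...) {
  cat(sprintf("z-score difference over %d matched positions (threshold %g):\n",
              nrow(x$points), x$threshold))
  if (nrow(x$regions)) print(x$regions) else cat("  no flagged regions\n")
  invisible(x)
}
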