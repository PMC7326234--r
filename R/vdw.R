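#' Van der Waals radii used for clearance and surface calculations
#'
#' Bondi (1964) element radii, the set commonly used for protein cavity and
#' surface work. Unknown elements fall back to 1.70 Angstrom (carbon) with a
#' warning.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"N"`).
#' @return numeric vector of radii in Angstrom, one per input element.
#' @export
#' @examples
#' vdw_radius(c("C", "N", "O", "S"))
vdw_radius <- function(elements) {
  tab <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    ZN = 1.39, FE = 1.40, MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75
  )
  key <- toupper(trimws(elements))
  r <- unname(tab[key])
  if (anyNA(r)) {
    missing <- unique(key[is.na(r)])
    warning("no van der Waals radius for element(s) ",
            paste(missing, collapse = ", "), "; using 1.70 A")
    r[is.na(r)] <- 1.70
  }
  r
}

# Theoretical maximum accessible surface areas (A^2) of residue X in a
# Gly-X-Gly tripeptide (Tien et al. 2013), used to express per-residue SASA
# as a relative exposure.
GXG_MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)
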