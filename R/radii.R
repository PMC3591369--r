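#' Van der Waals radii table
#'
#' Standard van der Waals radii (Angstrom) used for solvent-accessibility,
#' protrusion and steric-collision calculations.  Elements not listed fall
#' back to the carbon value of 1.70 A.
#'
#' @param ... Named overrides, e.g. `vdw_radii(SE = 1.90)`.
#' @return Named numeric vector of radii keyed by element symbol, with a
#'   `default` entry used for unknown elements.
#' @examples
#' vdw_radii()[["C"]]
#' @export
vdw_radii <- function(...) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
         default = 1.70)
  over <- c(...)
  if (length(over)) r[toupper(names(over))] <- as.numeric(over)
  r
}

# radius lookup for a vector of element symbols
radius_for_element <- function(elesy, radii = vdw_radii()) {
  key <- toupper(trimws(elesy))
  out <- unname(radii[key])
  out[is.na(out)] <- radii[["default"]]
  out
}

# heavy side-chain atom counts for the 20 standard amino acids
.side_chain_atoms <- c(
  ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5, GLU = 5,
  GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5, MET = 4, PHE = 7,
  PRO = 3, SER = 2, THR = 3, TRP = 10, TYR = 8, VAL = 3)

# three-letter -> one-letter with X fallback (warns once per call)
aa_one_letter <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  bad <- is.na(out) | out == "X"
  if (any(bad & !(resid %in% names(.side_chain_atoms)))) {
    warn(paste0("non-standard residue code(s) mapped to X: ",
                paste(unique(resid[bad]), collapse = ", ")))
  }
  out[is.na(out)] <- "X"
  out
}
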