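#' Build a surface patch around a central residue
#'
#' Implements the centre-of-mass / solvent-vector construction: (a) a
#' pre-patch of the central residue and its n-1 nearest surface residues
#' (Calpha distance); (b) the pre-patch centre of mass (unweighted mean of
#' Calpha coordinates), from which every surface residue gets a solvent
#' vector Calpha - COM; (c) the final patch keeps the central residue plus
#' the closest n-1 surface residues whose solvent vector makes an angle of
#' at most 110 degrees (closed bound) with the central residue's.
#' Candidates for step (c) are drawn from the whole surface set.  Distance
#' ties are broken by (chain, resno, insert) order.
#'
#' @param atoms Atom tibble (must contain Calpha atoms for the residues
#'   involved).
#' @param central Residue key (`chain:resno:insert`) of the patch centre;
#'   must be in `surface_set`.
#' @param surface_set Character vector of surface residue keys.
#' @param n Requested patch size, between 5 and 8.
#' @param max_angle Angular bound in degrees (default 110).
#' @return A list of class `surface_patch`: `central`, `members` (central
#'   first, then by Calpha distance), `n_requested`, `complete`,
#'   `degenerate`, `com`, and `solvent_vectors` (matrix, one row per
#'   surface residue).  A patch whose central solvent vector has zero
#'   length is returned degenerate with only the central member, with a
#'   warning.
#' @export
build_patch <- function(atoms, central, surface_set, n = 5, max_angle = 110) {
  if (!n %in% 5:8) abort("patch size n must be in 5..8")
  surface_set <- unique(surface_set)
  if (!central %in% surface_set) abort("central residue not in surface set")
  prot <- atoms[atoms$record == "ATOM", , drop = FALSE]
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  ca <- ca[atom_keys(ca) %in% surface_set, , drop = FALSE]
  ca <- ca[!duplicated(atom_keys(ca)), , drop = FALSE]
  ca_keys <- atom_keys(ca)
  if (!central %in% ca_keys) abort("central residue lacks a Calpha atom")
  miss <- setdiff(surface_set, ca_keys)
  if (length(miss)) {
    warn(paste0(length(miss), " surface residue(s) without Calpha dropped"))
    surface_set <- intersect(surface_set, ca_keys)
  }
  ord0 <- order(ca$chain, ca$resno, ca$insert)
  ca <- ca[ord0, , drop = FALSE]
  ca_keys <- atom_keys(ca)
  xyz <- coords(ca)
  ic <- match(central, ca_keys)

  d <- sqrt(rowSums(sweep(xyz, 2, xyz[ic, ])^2))
  ord <- order(d)                     # ca already in tie-break order
  pre <- ord[seq_len(min(n, length(ord)))]
  com <- colMeans(xyz[pre, , drop = FALSE])

  sv <- sweep(xyz, 2, com)
  rownames(sv) <- ca_keys
  norms <- sqrt(rowSums(sv^2))
  vc <- sv[ic, ]
  if (norms[ic] < 1e-9) {
    warn(paste0("degenerate patch at ", central,
                ": central Calpha coincides with the pre-patch COM"))
    out <- list(central = central, members = central, n_requested = n,
                complete = FALSE, degenerate = TRUE, com = com,
                solvent_vectors = sv)
    class(out) <- "surface_patch"
    return(out)
  }
  cosang <- as.numeric(sv %*% vc) / (norms * norms[ic])
  cosang[norms < 1e-9] <- NA          # zero-length vectors excluded
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- which(!is.na(ang) & ang <= max_angle + 1e-9)
  ok <- setdiff(ok, ic)
  ok <- ok[order(d[ok])]
  members <- c(central, ca_keys[ok[seq_len(min(n - 1, length(ok)))]])
  out <- list(central = central, members = members, n_requested = n,
              complete = length(members) == n, degenerate = FALSE,
              com = com, solvent_vectors = sv)
  class(out) <- "surface_patch"
  out
}

#' Build patches for many central residues
#'
#' @param atoms Atom tibble.
#' @param centrals Character vector of central residue keys.
#' @param surface_set Surface residue keys.
#' @param n Patch size in 5..8.
#' @param max_angle Angular bound in degrees.
#' @return Tibble with columns `central`, `members` (list-column),
#'   `size`, `complete`, `degenerate`.
#' @export
build_patches <- function(atoms, centrals, surface_set, n = 7,
                          max_angle = 110) {
  ps <- purrr::map(centrals, build_patch, atoms = atoms,
                   surface_set = surface_set, n = n, max_angle = max_angle)
  tibble(central = centrals,
         members = purrr::map(ps, "members"),
         size = vapply(ps, function(p) length(p$members), integer(1)),
         complete = vapply(ps, function(p) p$complete, logical(1)),
         degenerate = vapply(ps, function(p) p$degenerate, logical(1)))
}

#' Fraction of overlap-labelled residues in a patch
#'
#' @param patch A `surface_patch` (or a character vector of member keys).
#' @param labels Labels for the members: a tibble (`res`, `label`) or a
#'   named character vector with values `"O"`/`"N"`.
#' @return `#O / #members` as a fraction in \[0, 1\].
#' @export
patch_label_ratio <- function(patch, labels) {
  members <- if (inherits(patch, "surface_patch")) patch$members else patch
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$res)
  lab <- unname(labels[members])
  if (anyNA(lab)) {
    abort(paste0("unlabeled patch member(s): ",
                 paste(members[is.na(lab)], collapse = ", ")))
  }
  mean(lab == "O")
}
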