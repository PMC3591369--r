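#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD when
#' mapping `mobile` onto `target`, with the SVD determinant correction so a
#' reflection is never returned.
#'
#' @param mobile,target n x 3 coordinate matrices of paired atoms (n >= 3,
#'   not collinear).
#' @return A list of class `rigid_transform`: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (A over the fitted pairs).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' tr <- superpose(a, a)
#' tr$rmsd
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) abort("coordinate sets differ in size")
  if (nrow(mobile) < 3) abort("need at least 3 paired atoms to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  if (min(svd(A)$d) < 1e-8 * max(svd(A)$d)) {
    abort("degenerate (collinear) coordinate set")
  }
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ct - R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tr, "+")
  out <- list(rotation = R, translation = tr,
              rmsd = sqrt(mean(rowSums((fitted - target)^2))))
  class(out) <- "rigid_transform"
  out
}

#' Apply a rigid transform to coordinates or an atom table
#'
#' @param x An n x 3 matrix, or an atom tibble with `x`,`y`,`z` columns.
#' @param transform A `rigid_transform` from [superpose()].
#' @return Object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (is.data.frame(x)) {
    m <- apply_transform(coords(x), transform)
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Steric collision test
#'
#' True iff any heavy-atom pair between the two sets is closer than the sum
#' of the two van der Waals radii (strict inequality, so a pair at exactly
#' the contact distance is not a collision).
#'
#' @param ligand_atoms,partner_atoms Atom tibbles (with `radius` columns).
#' @return Logical scalar.
#' @export
detect_collision <- function(ligand_atoms, partner_atoms) {
  if (nrow(ligand_atoms) == 0L || nrow(partner_atoms) == 0L) return(FALSE)
  any_vdw_clash(coords(ligand_atoms), ligand_atoms$radius,
                coords(partner_atoms), partner_atoms$radius)
}

# min heavy-atom distance matrix between residues (rows) given an atom table
residue_min_dist <- function(atoms, keys) {
  k <- atom_keys(atoms)
  n <- length(keys)
  m <- matrix(0, n, n, dimnames = list(keys, keys))
  xyz <- lapply(keys, function(key) coords(atoms[k == key, , drop = FALSE]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- m[j, i] <- min_pair_distance(xyz[[i]], xyz[[j]])
    }
  }
  m
}

#' Cluster a residue set into spatially connected regions
#'
#' Single-linkage connected components: two residues are linked when their
#' minimum heavy-atom distance is at most the cutoff.  Used to measure the
#' coherence of overlap regions on an interface.
#'
#' @param atoms Atom tibble containing (at least) the listed residues.
#' @param residues Character vector of residue keys (`chain:resno:insert`).
#' @param linkage_cutoff Linkage distance in Angstrom (default 5).
#' @return A list of character vectors, one per cluster, partitioning
#'   `residues`; ordered by decreasing size.
#' @export
cluster_overlap_region <- function(atoms, residues, linkage_cutoff = 5.0) {
  residues <- unique(residues)
  if (length(residues) == 0L) return(list())
  present <- atom_keys(atoms)
  missing <- setdiff(residues, present)
  if (length(missing)) {
    abort(paste0("residues not in structure: ", paste(missing, collapse = ", ")))
  }
  if (length(residues) == 1L) return(list(residues))
  dm <- residue_min_dist(atoms[present %in% residues, , drop = FALSE], residues)
  adj <- (dm <= linkage_cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  cl <- split(residues, comp$membership)
  unname(cl[order(-vapply(cl, length, integer(1)))])
}
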