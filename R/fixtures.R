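# Deterministic toy structures and feature tables with known ground truth.
# Pseudo-proteins are poly-alanine-like chains (CA + one CB-like atom per
# residue); realism is not a goal, geometric validity is.

atom_row <- function(serial, elety, resid, chain, resno, x, y, z,
                     record = "ATOM", elesy = "C") {
  tibble(record = record, serial = serial, elety = elety, resid = resid,
         chain = chain, resno = resno, insert = "", x = x, y = y, z = z,
         elesy = elesy, radius = radius_for_element(elesy))
}

#' Single-atom-per-residue ring structure
#'
#' `n_residues` Calpha atoms evenly spaced on a circle in the z = 0 plane.
#' The centre of mass of any symmetric subset is the circle centre, so all
#' solvent vectors are exactly radial and patch angles are known in closed
#' form (adjacent residues are separated by 360/n degrees).
#'
#' @param seed Integer seed (kept for API uniformity; the ring is
#'   deterministic).
#' @param n_residues Number of residues (>= 5).
#' @param radius Circle radius in Angstrom.
#' @return Atom tibble (chain `R`, residues 1..n).
#' @export
make_ring <- function(seed = 1L, n_residues = 12L, radius = 10) {
  if (n_residues < 5) abort("need at least 5 residues")
  th <- 2 * pi * (seq_len(n_residues) - 1) / n_residues
  bind_rows(purrr::map(seq_len(n_residues), function(i) {
    atom_row(i, "CA", "ALA", "R", i,
             radius * cos(th[i]), radius * sin(th[i]), 0)
  }))
}

#' Residues on a sphere with contiguous overlap caps
#'
#' Places one-Calpha residues on a Fibonacci sphere and labels residues
#' inside `n_blobs` spherical caps as overlap (`O`).  Because the caps are
#' spatially contiguous, surface patches built on this structure have
#' label-coherent members, which is what patch voting exploits.
#'
#' @param seed Integer seed (cap placement).
#' @param n_residues Number of residues.
#' @param radius Sphere radius in Angstrom.
#' @param n_blobs Number of overlap caps.
#' @param cap_angle Angular cap radius in degrees.
#' @param effects Effect sizes for the per-residue feature draw
#'   ([effect_sizes()]).
#' @return List: `atoms`, `truth` (tibble `res`, `label`) and `features`
#'   (labelled feature tibble, one row per residue, drawn conditional on
#'   the residue's true label).
#' @export
make_sphere_cloud <- function(seed = 1L, n_residues = 400L, radius = NULL,
                              n_blobs = 8L, cap_angle = 16,
                              effects = effect_sizes()) {
  set.seed(seed)
  # default radius keeps the inter-residue spacing near 3.8 A
  radius <- radius %||% 3.8 * sqrt(n_residues / (4 * pi))
  k <- seq_len(n_residues)
  ga <- pi * (3 - sqrt(5))
  zf <- 1 - (2 * k - 1) / n_residues
  rf <- sqrt(pmax(0, 1 - zf^2))
  u <- cbind(rf * cos(ga * k), rf * sin(ga * k), zf)
  atoms <- bind_rows(purrr::map(k, function(i) {
    atom_row(i, "CA", "ALA", "S", i,
             radius * u[i, 1], radius * u[i, 2], radius * u[i, 3])
  }))
  centres <- u[sample(n_residues, n_blobs), , drop = FALSE]
  cosmax <- cos(cap_angle * pi / 180)
  is_o <- apply(u %*% t(centres) >= cosmax, 1, any)
  labels <- ifelse(is_o, "O", "N")
  features <- bind_cols(
    tibble(res = atom_keys(atoms), chain = "S", resno = seq_len(n_residues),
           insert = "", aa = "ALA", label = labels),
    draw_features(labels, effects))
  list(atoms = atoms,
       truth = tibble(res = atom_keys(atoms), label = labels),
       features = features)
}

#' Class-conditional effect sizes for synthetic feature tables
#'
#' Mean shifts applied to the overlap class relative to the non-overlap
#' baseline, in the directions observed on real interfaces: overlap
#' residues are more conserved (negative shift), less protruding, less
#' solvent exposed, more densely packed (default +0.97 contacts/atom) and
#' more often hot spots (48% vs 37%).
#'
#' @param density Contact-density shift for class O.
#' @param protrusion,conservation,surface Shifts for class O (applied with
#'   a decaying profile over the five neighbour features).
#' @param hotspot_o,hotspot_n Per-residue hot-spot probabilities used for
#'   the patch hot-spot frequency feature.
#' @return Named list of effect sizes.
#' @export
effect_sizes <- function(density = 0.97, protrusion = -0.8,
                         conservation = -0.6, surface = -0.15,
                         hotspot_o = 0.48, hotspot_n = 0.37) {
  list(density = density, protrusion = protrusion,
       conservation = conservation, surface = surface,
       hotspot_o = hotspot_o, hotspot_n = hotspot_n)
}

#' @rdname effect_sizes
#' @export
null_effect_sizes <- function() {
  effect_sizes(density = 0, protrusion = 0, conservation = 0, surface = 0,
               hotspot_o = 0.37, hotspot_n = 0.37)
}

# draw the 13 features for a given label vector
draw_features <- function(labels, effects) {
  n <- length(labels)
  is_o <- labels == "O"
  decay <- c(1, 0.8, 0.6, 0.5, 0.4)
  out <- tibble(
    surfaceFraction = pmin(1, pmax(0, rnorm(n, 0.55, 0.18) +
                                     is_o * effects$surface)),
    density = pmax(0, rnorm(n, 3.0, 1.2) + is_o * effects$density))
  for (j in 1:5) {
    out[[paste0("protru", j)]] <-
      pmax(0, rnorm(n, 2.2, 1.0) + is_o * effects$protrusion * decay[j])
  }
  for (j in 1:5) {
    out[[paste0("cons", j)]] <-
      rnorm(n, 0, 1) + is_o * effects$conservation * decay[j]
  }
  p <- ifelse(is_o, effects$hotspot_o, effects$hotspot_n)
  out$hsfPatch8 <- rbinom(n, 8, p) / 8
  out
}

#' Synthetic labelled feature table
#'
#' Draws the 13 classifier features from class-conditional Gaussians whose
#' mean shifts follow the directions observed on real interfaces (see
#' [effect_sizes()]).  The default class sizes mimic the roughly 1:4.3
#' overlap to non-overlap imbalance of residue-level interface data at a
#' total of 2000 residues.
#'
#' @param seed Integer seed.
#' @param n_overlap,n_nonoverlap Class sizes.
#' @param effects Effect-size list from [effect_sizes()].
#' @return Tibble with identifier columns (`res`, `chain`, `resno`,
#'   `insert`, `aa`), a `label` column and the 13 features, in random row
#'   order.
#' @examples
#' ft <- make_feature_table(seed = 1, n_overlap = 50, n_nonoverlap = 200)
#' table(ft$label)
#' @export
make_feature_table <- function(seed = 1L, n_overlap = 377L,
                               n_nonoverlap = 1623L,
                               effects = effect_sizes()) {
  if (n_overlap < 1 || n_nonoverlap < 1) abort("class counts must be >= 1")
  set.seed(seed)
  labels <- sample(c(rep("O", n_overlap), rep("N", n_nonoverlap)))
  n <- length(labels)
  bind_cols(
    tibble(res = res_key("S", seq_len(n)), chain = "S", resno = seq_len(n),
           insert = "", aa = "ALA", label = labels),
    draw_features(labels, effects))
}

#' Synthetic PP/PL complex pair with a ligand-binding pocket
#'
#' Builds a protein-protein complex whose reference chain `A` (a two-layer
#' pseudo-protein slab) binds partner chain `B` across a flat interface
#' with a concave pocket at its centre, plus the matching protein-ligand
#' structure: a copy of chain `A` (under a seeded rigid transform, so the
#' superposition step is exercised) with a small ligand placed at
#' `ligand_site`.
#'
#' Sites: `"pocket"` puts the ligand in the interface pocket where it
#' contacts the pocket-lining ring (competitive: after superposition it
#' clashes with chain `B`); `"rim"` puts it beside the interface where it
#' touches two or more interface residues but cannot clash with `B`
#' (non-competitive); `"back"` puts it on the opposite face (no interface
#' overlap).  With `pocket_depth = 0` the interface is flat and a
#' `"pocket"` request is placed outside the pocket mouth (rim), yielding a
#' non-competitive pair.
#'
#' @param seed Integer seed (rigid transform of the PL structure and
#'   coordinate jitter).
#' @param pocket_depth Pocket depth in Angstrom (default 2).
#' @param n_interface Approximate number of partner residues facing the
#'   interface (controls the partner slab size; default 25).
#' @param ligand_site One of `"pocket"`, `"rim"`, `"back"`.
#' @param noise Gaussian coordinate jitter (sd, Angstrom) applied to the
#'   protein atoms so repeated fixtures are not identical (default 0.08).
#' @return List: `pp` (atom tibble, chains A and B), `pl` (atom tibble,
#'   chain A copy + HETATM ligand `LIG`), `truth` (tibble `res`, `label`
#'   over the true PP interface of chain A), `o_set` (overlap residue
#'   keys), `ligand_site`, `pocket_depth`.
#' @export
make_pocket_complex <- function(seed = 1L, pocket_depth = 2.0,
                                n_interface = 25L,
                                ligand_site = c("pocket", "rim", "back"),
                                noise = 0.08) {
  ligand_site <- match.arg(ligand_site)
  if (pocket_depth < 0 || n_interface < 9) {
    abort("infeasible geometry: pocket_depth must be >= 0, n_interface >= 9")
  }
  if (pocket_depth < 1 && ligand_site == "pocket") ligand_site <- "rim"
  set.seed(seed)
  s <- 3.8
  nx <- 7L
  pocket_ij <- expand.grid(i = 2:3, j = 2:3)

  # chain A: front layer (z = 0, faces the partner) + back layer (z = -s)
  rows <- list(); serial <- 0L; resno <- 0L
  add_res <- function(x, y, z, chain, dz_cb = -1.4) {
    serial <<- serial + 2L; resno <<- resno + 1L
    rows[[length(rows) + 1L]] <<- bind_rows(
      atom_row(serial - 1L, "CA", "ALA", chain, resno, x, y, z),
      atom_row(serial, "CB", "ALA", chain, resno, x + 0.4, y + 0.4,
               z + dz_cb))
  }
  front_key <- matrix("", nx, nx)
  for (i in 0:(nx - 1)) for (j in 0:(nx - 1)) {
    depth <- if (any(pocket_ij$i == i & pocket_ij$j == j)) pocket_depth else 0
    add_res(i * s, j * s, -depth, "A")
    front_key[i + 1, j + 1] <- res_key("A", resno)
  }
  for (i in 0:(nx - 1)) for (j in 0:(nx - 1)) add_res(i * s, j * s, -2 * s, "A")
  chain_a <- bind_rows(rows)

  # chain B: partner slab centred over chain A at z = 4.3; when there is a
  # pocket, a plug residue of the partner protrudes into it (the partner
  # loop the ligand competes with), putting the pocket lining into the PP
  # interface
  nb <- max(3L, as.integer(ceiling(sqrt(n_interface))))
  centre <- (nx - 1) * s / 2
  pocket_centre <- mean(range(pocket_ij$i)) * s
  rows <- list(); resno <- 0L
  for (i in 0:(nb - 1)) for (j in 0:(nb - 1)) {
    add_res(centre + (i - (nb - 1) / 2) * s,
            centre + (j - (nb - 1) / 2) * s, 4.3, "B", dz_cb = 1.4)
  }
  if (pocket_depth >= 1) {
    add_res(pocket_centre, pocket_centre, -pocket_depth + 3.5, "B",
            dz_cb = 1.4)
  }
  chain_b <- bind_rows(rows)

  # ligand geometry (ideal frame of chain A); pc = pocket centre
  pc <- pocket_centre
  edge <- 5 * s  # outermost front-layer column still facing the partner
  lig_xyz <- switch(ligand_site,
    pocket = rbind(
      c(pc, pc, -2.0), c(pc, pc, -0.5), c(pc, pc, 1.0), c(pc, pc, 2.6),
      c(pc - 2.2, pc, 0.5), c(pc + 2.2, pc, 0.5),
      c(pc, pc - 2.2, 0.5), c(pc, pc + 2.2, 0.5),
      c(centre, centre, 1.6)),
    rim = rbind(
      c(edge + 4.0, centre - 1.9, 0.0),
      c(edge + 4.0, centre, 0.0),
      c(edge + 4.0, centre + 1.9, 0.0),
      c(edge + 5.4, centre, 0.0)),
    back = rbind(
      c(s - 1.9, s, -12.2), c(s, s, -12.2), c(s + 1.9, s, -12.2),
      c(s, s, -13.6)))
  ligand <- bind_rows(purrr::map(seq_len(nrow(lig_xyz)), function(k) {
    atom_row(1000L + k, paste0("C", k), "LIG", "L", 1L,
             lig_xyz[k, 1], lig_xyz[k, 2], lig_xyz[k, 3],
             record = "HETATM")
  }))

  jitter_atoms <- function(a) {
    a$x <- a$x + rnorm(nrow(a), 0, noise)
    a$y <- a$y + rnorm(nrow(a), 0, noise)
    a$z <- a$z + rnorm(nrow(a), 0, noise)
    a
  }
  pp <- bind_rows(jitter_atoms(chain_a), jitter_atoms(chain_b))
  pl_chain <- jitter_atoms(chain_a)

  # ground truth from the realised PP geometry and the ideal ligand pose
  a_res <- residue_table(pp[pp$chain == "A", ])
  keys <- atom_keys(pp[pp$chain == "A", ])
  bmat <- coords(pp[pp$chain == "B", ])
  lmat <- lig_xyz
  pl_ref <- coords(pl_chain)  # pre-transform == chain A frame
  dist_to <- function(key, m, ref_atoms, ref_keys) {
    min_pair_distance(coords(ref_atoms[ref_keys == key, , drop = FALSE]), m)
  }
  a_atoms_pp <- pp[pp$chain == "A", ]
  a_atoms_pl <- pl_chain
  d_b <- vapply(a_res$res, dist_to, numeric(1), m = bmat,
                ref_atoms = a_atoms_pp, ref_keys = atom_keys(a_atoms_pp))
  d_l <- vapply(a_res$res, dist_to, numeric(1), m = lmat,
                ref_atoms = a_atoms_pl, ref_keys = atom_keys(a_atoms_pl))
  pp_if <- a_res$res[d_b <= 5]
  pl_if <- a_res$res[d_l <= 5]
  o_set <- intersect(pp_if, pl_if)
  truth <- tibble(res = pp_if,
                  label = ifelse(pp_if %in% o_set, "O", "N"))

  # PL structure gets a seeded rigid transform (rotation + translation)
  ang <- stats::runif(3, -pi, pi)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  rot <- Rz(ang[1]) %*% Rx(ang[2]) %*% Rz(ang[3])
  shift <- stats::runif(3, -20, 20)
  tr <- structure(list(rotation = rot, translation = shift, rmsd = 0),
                  class = "rigid_transform")
  pl <- bind_rows(apply_transform(pl_chain, tr), apply_transform(ligand, tr))

  list(pp = pp, pl = pl, truth = truth, o_set = o_set,
       ligand_site = ligand_site, pocket_depth = pocket_depth)
}

#' Synthetic conservation scores for a pocket-complex fixture
#'
#' Emulates the empirical association between ligand-overlap residues and
#' evolutionary conservation: residues in the fixture's true overlap set
#' get negative (conserved) scores, the rest mildly positive, plus noise.
#'
#' @param pc A fixture from [make_pocket_complex()].
#' @param seed Integer seed.
#' @param effect Mean score gap between overlap and other residues.
#' @param sd Score noise.
#' @return Tibble (`res`, `score`) covering every chain-A residue.
#' @export
make_fixture_conservation <- function(pc, seed = 1L, effect = 1.2, sd = 0.4) {
  set.seed(seed)
  res <- unique(atom_keys(pc$pp[pc$pp$chain == "A", ]))
  tibble(res = res,
         score = rnorm(length(res), 0, sd) +
           ifelse(res %in% pc$o_set, -effect, 0.2))
}
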