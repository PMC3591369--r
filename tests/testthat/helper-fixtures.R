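# in-code fixtures and brute-force oracles shared across the suite

atoms_tbl <- function(x, y, z, elety = "CA", resid = "ALA", chain = "A",
                      resno = seq_along(x), elesy = "C",
                      record = "ATOM") {
  tibble::tibble(record = record, serial = seq_along(x), elety = elety,
                 resid = resid, chain = chain, resno = resno, insert = "",
                 x = x, y = y, z = z, elesy = elesy,
                 radius = bindpatch:::radius_for_element(elesy))
}

one_carbon <- function(x = 0, y = 0, z = 0) atoms_tbl(x, y, z)

# hand-written 3-residue PDB text (chain A)
mini_pdb <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CB  ALA A   1       0.000   1.530   0.000  1.00  0.00           C",
  "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      4  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
  "ATOM      5  OG  SER A   3       7.600   1.410   0.000  1.00  0.00           O",
  "END")

# PDB with a water, a sodium ion and a 9-heavy-atom benzamidine-like group
het_pdb <- function() {
  ring <- t(sapply(0:5, function(k) {
    c(20 + 1.4 * cos(k * pi / 3), 1.4 * sin(k * pi / 3), 0)
  }))
  lig <- rbind(ring, c(22.8, 0, 0), c(23.5, 1.1, 0), c(23.5, -1.1, 0))
  c(mini_pdb()[1:5],
    "HETATM   10  O   HOH A 101      12.000   0.000   0.000  1.00  0.00           O",
    "HETATM   11 NA    NA A 102      15.000   0.000   0.000  1.00  0.00          NA",
    sprintf("HETATM  %3d  C%d  BEN A 103    %8.3f%8.3f%8.3f  1.00  0.00           C",
            11 + seq_len(nrow(lig)), seq_len(nrow(lig)),
            lig[, 1], lig[, 2], lig[, 3]),
    "END")
}

# two parallel strands of one-atom residues, facing pairs `gap` apart in z
two_strands <- function(gap, n = 6, chain_b = "B") {
  a <- atoms_tbl(x = 3.8 * seq_len(n), y = rep(0, n), z = rep(0, n))
  b <- atoms_tbl(x = 3.8 * seq_len(n), y = rep(0, n), z = rep(gap, n),
                 chain = chain_b)
  b$serial <- b$serial + n
  dplyr::bind_rows(a, b)
}

# brute-force oracles -------------------------------------------------------

bf_min_res_dist <- function(atoms, key_a, key_b) {
  k <- bindpatch:::atom_keys(atoms)
  a <- atoms[k == key_a, c("x", "y", "z")]
  b <- atoms[k == key_b, c("x", "y", "z")]
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
             2 * as.matrix(a) %*% t(as.matrix(b))))
}

# all-pairs interface scan: residues of chain q with any atom within cutoff
# of any atom of chain p
bf_interface <- function(atoms, q, p, cutoff = 5) {
  qa <- atoms[atoms$chain == q, ]
  pa <- atoms[atoms$chain == p, ]
  keys <- unique(bindpatch:::atom_keys(qa))
  keep <- vapply(keys, function(key) {
    sel <- bindpatch:::atom_keys(qa) == key
    m <- as.matrix(qa[sel, c("x", "y", "z")])
    pm <- as.matrix(pa[, c("x", "y", "z")])
    d2 <- outer(rowSums(m^2), rowSums(pm^2), "+") - 2 * m %*% t(pm)
    sqrt(max(0, min(d2))) <= cutoff
  }, logical(1))
  keys[keep]
}

# brute-force double loop contact density for one residue
bf_density <- function(atoms, chain, key, cutoff = 5) {
  q <- atoms[atoms$chain == chain & atoms$record == "ATOM", ]
  k <- bindpatch:::atom_keys(q)
  mine <- q[k == key, ]
  others <- q[k != key, ]
  acc <- mine[mine$atom_sasa > 0, ]
  total <- 0
  for (i in seq_len(nrow(acc))) {
    for (j in seq_len(nrow(others))) {
      d <- sqrt((acc$x[i] - others$x[j])^2 + (acc$y[i] - others$y[j])^2 +
                  (acc$z[i] - others$z[j])^2)
      if (d <= cutoff) total <- total + 1
    }
  }
  total / nrow(mine)
}

# transitive closure clustering from an adjacency matrix
bf_clusters <- function(adj) {
  n <- nrow(adj)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && lab[j] != lab[i]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), lab)
}

# analytic union volume of two spheres
two_sphere_union <- function(r1, r2, d) {
  v <- function(r) 4 / 3 * pi * r^3
  if (d >= r1 + r2) return(v(r1) + v(r2))
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v(r1) + v(r2) - lens
}

# deterministic pocket-pair feature set used by classifier/dataset tests
fixture_training_features <- function(seeds = 1:4) {
  purrr::map_dfr(seeds, function(sd) {
    pc <- make_pocket_complex(seed = sd)
    p <- make_pair(pc$pp, "A", "B", pc$pl, "A", pair_id = paste0("fx", sd))
    cons <- make_fixture_conservation(pc, seed = sd)
    fv <- suppressWarnings(
      build_feature_vectors(pc$pp, "A", p$labeling, conservation = cons))
    fv$label <- p$labeling$label[match(fv$res, p$labeling$res)]
    fv
  })
}
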