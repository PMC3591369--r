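test_that("interface detection honours the distance cutoff", {
  near <- two_strands(gap = 4)
  i4 <- detect_interface(near, "A", partner_chain = "B",
                         surface = unique(bindpatch:::atom_keys(near)))
  expect_equal(nrow(i4), 6)  # every facing residue
  far <- two_strands(gap = 8)
  i8 <- detect_interface(far, "A", partner_chain = "B",
                         surface = unique(bindpatch:::atom_keys(far)))
  expect_equal(nrow(i8), 0)
  expect_error(detect_interface(near, "A", partner_chain = "C"))
})

test_that("interface equals the all-pairs brute-force scan and is symmetric", {
  set.seed(7)
  a <- atoms_tbl(x = runif(15, 0, 20), y = runif(15, 0, 12),
                 z = runif(15, 0, 4), resno = 1:15)
  b <- atoms_tbl(x = runif(12, 0, 20), y = runif(12, 0, 12),
                 z = runif(12, 5, 9), resno = 1:12, chain = "B")
  s <- dplyr::bind_rows(a, b)
  all_a <- unique(bindpatch:::atom_keys(a))
  all_b <- unique(bindpatch:::atom_keys(b))
  got <- detect_interface(s, "A", partner_chain = "B", surface = all_a)
  expect_setequal(got$res, bf_interface(s, "A", "B"))
  # symmetry: r in iface(A|B) iff some residue of B within cutoff of r
  got_b <- detect_interface(s, "B", partner_chain = "A", surface = all_b)
  expect_setequal(got_b$res, bf_interface(s, "B", "A"))
  expect_equal(nrow(got) > 0, nrow(got_b) > 0)
})

test_that("global alignment identity behaves on the canonical cases", {
  id <- align_sequences("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(alignment_identity(id), 1.0)
  expect_equal(id$pos_a, id$pos_b)
  sub <- align_sequences("ACDEFGHIKL", "ACDEFGHIKV")
  expect_equal(alignment_identity(sub), 0.9)
  junk <- align_sequences("AAAAAAAAAA", "WWWWWWWWWW")
  expect_lt(alignment_identity(junk), 0.4)
  expect_warning(align_sequences("ACDB", "ACDE"), "X")
})

test_that("overlap labelling partitions the PP interface", {
  pc <- make_pocket_complex(seed = 2)
  ref <- chain_residues(pc$pp, "A")
  amap <- align_sequences(ref$seq, ref$seq)
  surface <- unique(bindpatch:::atom_keys(pc$pp[pc$pp$chain == "A", ]))
  pp_if <- detect_interface(pc$pp, "A", partner_chain = "B",
                            surface = surface)
  lig <- extract_ligands(pc$pl)
  # use untransformed ligand frame: labels via identical chain copy
  pl_ref <- chain_residues(pc$pl, "A")
  pl_if <- detect_interface(pc$pl, "A", partner_atoms = lig,
                            surface = pl_ref$residues$res)
  lab <- label_overlap(pp_if, pl_if, amap, ref$residues, pl_ref$residues)
  expect_setequal(lab$res, pp_if$res)                   # covers interface
  expect_true(all(lab$label %in% c("O", "N")))
  expect_equal(attr(lab, "n_overlap") + attr(lab, "n_nonoverlap"), nrow(lab))
  # PL interface contained in PP interface => O equals the PL interface
  expect_setequal(lab$res[lab$label == "O"],
                  intersect(pp_if$res, pl_if$res))
  # disjoint interfaces are an invalid pair
  fake_pl <- pl_if[0, ]
  expect_error(label_overlap(pp_if, fake_pl, amap, ref$residues,
                             pl_ref$residues),
               class = "bindpatch_insufficient_overlap")
})

test_that("Kabsch superposition recovers a known transform", {
  set.seed(11)
  a <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identity case
  tr0 <- superpose(a, a)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(sqrt(sum(tr0$translation^2)), 1e-9)
  expect_lt(tr0$rmsd, 1e-9)
  # known rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  b <- sweep(a %*% t(R), 2, c(3, -2, 7), "+")
  tr <- superpose(b, a)
  expect_lt(tr$rmsd, 1e-6)
  expect_equal(apply_transform(b, tr), a, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  # re-fitting superposed coordinates is the identity within 1e-9
  tr2 <- superpose(apply_transform(b, tr), a)
  expect_equal(tr2$rotation, diag(3), tolerance = 1e-9)
})

test_that("reflection-requiring sets still give a proper rotation", {
  set.seed(3)
  a <- matrix(rnorm(24, sd = 4), ncol = 3)
  b <- a %*% diag(c(-1, 1, 1))  # mirrored
  tr <- superpose(b, a)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_gt(tr$rmsd, 0)
})

test_that("superposition input validation", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("collision uses the strict sum-of-radii bound", {
  lig <- one_carbon(0, 0, 0)
  near <- one_carbon(2.0, 0, 0)
  expect_true(detect_collision(lig, near))          # 2.0 < 3.4
  far <- one_carbon(3.6, 0, 0)
  expect_false(detect_collision(lig, far))          # 3.6 > 3.4
  boundary <- one_carbon(3.4, 0, 0)
  expect_false(detect_collision(lig, boundary))     # exactly r_i + r_j
})

test_that("overlap-region clustering matches transitive closure", {
  # one contiguous stretch
  a <- atoms_tbl(x = 3.8 * (1:5), y = rep(0, 5), z = rep(0, 5))
  keys <- unique(bindpatch:::atom_keys(a))
  expect_length(cluster_overlap_region(a, keys), 1)
  # two stretches 12 A apart
  b <- atoms_tbl(x = c(3.8 * (1:3), 3.8 * (1:3) + 23.4), y = rep(0, 6),
                 z = rep(0, 6), resno = 1:6)
  cl <- cluster_overlap_region(b, unique(bindpatch:::atom_keys(b)))
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, length, integer(1))), c(3, 3))
  # random geometry vs brute-force transitive closure
  set.seed(5)
  r <- atoms_tbl(x = runif(14, 0, 30), y = runif(14, 0, 30),
                 z = rep(0, 14), resno = 1:14)
  rk <- unique(bindpatch:::atom_keys(r))
  got <- cluster_overlap_region(r, rk)
  d <- as.matrix(dist(r[, c("x", "y", "z")]))
  want <- bf_clusters(d <= 5)
  expect_equal(unname(sort(vapply(got, length, integer(1)))),
               unname(sort(vapply(want, length, integer(1)))))
  expect_length(got, length(want))
  # permutation invariance of the cluster count
  got_perm <- cluster_overlap_region(r, sample(rk))
  expect_length(got_perm, length(got))
  expect_length(cluster_overlap_region(r, character(0)), 0)
})
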