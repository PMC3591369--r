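test_that("protrusion matches the one- and two-sphere closed forms", {
  v <- function(r) 4 / 3 * pi * r^3
  a <- one_carbon()
  cx1 <- protrusion(a)$atom_cx
  want1 <- (v(10) - v(1.7)) / v(1.7)
  expect_lt(abs(cx1 - want1) / want1, 0.02)
  # two overlapping carbons: union volume by inclusion-exclusion
  b <- dplyr::bind_rows(one_carbon(), one_carbon(2.0)) |>
    dplyr::mutate(serial = 1:2, resno = 1:2)
  cx2 <- protrusion(b)$atom_cx[1]
  vu <- two_sphere_union(1.7, 1.7, 2.0)
  want2 <- (v(10) - vu) / vu
  expect_lt(abs(cx2 - want2) / want2, 0.02)
})

test_that("grid refinement shrinks the protrusion error", {
  v <- function(r) 4 / 3 * pi * r^3
  want <- (v(10) - v(1.7)) / v(1.7)
  err <- function(h) abs(protrusion(one_carbon(), grid_spacing = h)$atom_cx -
                           want) / want
  expect_lt(err(0.25), err(0.5) / 2)
})

test_that("an atom inside a close-packed block is (near) fully buried", {
  g <- expand.grid(x = seq(-6, 6, by = 1.5), y = seq(-6, 6, by = 1.5),
                   z = seq(-6, 6, by = 1.5))
  block <- atoms_tbl(x = g$x, y = g$y, z = g$z, resno = seq_len(nrow(g)))
  centre <- which(g$x == 0 & g$y == 0 & g$z == 0)
  cx <- protrusion(block, sphere_radius = 5)$atom_cx[centre]
  expect_lt(cx, 0.05)
})

test_that("contact density follows the printed formula", {
  # isolated residue: no contacts
  iso <- compute_sasa(one_carbon())
  expect_equal(contact_density(iso, "A")$density, 0)
  # 1-atom residue with 3 foreign heavy atoms at 4 A -> 3 contacts / 1 atom
  s <- atoms_tbl(x = c(0, 4, -4, 0), y = c(0, 0, 0, 4), z = rep(0, 4),
                 resno = 1:4) |> compute_sasa()
  expect_equal(contact_density(s, "A")$density[1], 3)
})

test_that("contact density equals brute force on random fixtures", {
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    s <- atoms_tbl(x = runif(n, 0, 10), y = runif(n, 0, 10),
                   z = runif(n, 0, 10),
                   resno = sort(sample(1:5, n, replace = TRUE))) |>
      compute_sasa()
    got <- contact_density(s, "A")
    for (key in got$res) {
      expect_equal(got$density[got$res == key], bf_density(s, "A", key),
                   tolerance = 1e-12)
    }
  }
})

test_that("surface fraction is bounded and decreases under occlusion", {
  # free Ala-X-Ala tripeptide: central residue's fraction is ~1
  tp <- bindpatch:::build_tripeptide("LEU") |> compute_sasa()
  fr <- surface_fraction(tp, "A")
  expect_equal(fr$surface_fraction[fr$resno == 2], 1, tolerance = 1e-6)
  # adding occluders never increases the fraction
  occ1 <- dplyr::bind_rows(tp, atoms_tbl(x = 3.8, y = 3, z = 0, resno = 10,
                                         chain = "Z")) |> compute_sasa()
  f1 <- surface_fraction(occ1, "A")$surface_fraction[fr$resno == 2]
  occ2 <- dplyr::bind_rows(occ1[, names(tp)],
                           atoms_tbl(x = 3.8, y = -3, z = 1, resno = 11,
                                     chain = "Z")) |> compute_sasa()
  f2 <- surface_fraction(occ2, "A")$surface_fraction[fr$resno == 2]
  expect_lte(f1, 1)
  expect_lte(f2, f1 + 1e-9)
  expect_true(all(fr$surface_fraction >= 0 & fr$surface_fraction <= 1))
  # unknown residue type is a named error
  bad <- tp |> dplyr::mutate(resid = ifelse(resno == 2, "XXX", resid))
  expect_error(surface_fraction(bad, "A"), "XXX")
})

test_that("fully buried residues score zero surface fraction", {
  shell <- expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5),
                       z = c(-2.5, 0, 2.5))
  cl <- atoms_tbl(x = shell$x, y = shell$y, z = shell$z, resno = 1:27) |>
    compute_sasa()
  fr <- surface_fraction(cl, "A")
  expect_equal(fr$surface_fraction[fr$resno == 14], 0, tolerance = 1e-6)
})

test_that("conservation loads from TSV and grade-file dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tresno\tscore", "A\t1\t-0.75", "A\t2\t0.10",
               "A\t3\t1.30"), tsv)
  tab <- load_conservation(tsv, "tsv", chain = "A")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$score[tab$res == "A:1:"], -0.75)

  grades <- tempfile(fileext = ".grades")
  writeLines(c(
    "\tAmino Acid Conservation Scores",
    "\t===============================",
    " POS\t SEQ\t    3LATOM\tSCORE\t\tCOLOR",
    "   1\t   M\t   MET1:A\t-0.750\t\t  9",
    "   2\t   A\t   ALA2:A\t 0.100\t\t  5",
    "   3\t   S\t   SER3:A\t 1.300\t\t  1",
    ""), grades)
  tab2 <- load_conservation(grades, "consurf_grades", chain = "A")
  expect_equal(nrow(tab2), 3)
  expect_equal(sort(tab2$score), sort(tab$score))

  # wrong chain is a hard error
  expect_error(load_conservation(grades, "consurf_grades", chain = "B"),
               "chain B")
  # numbering mismatch beyond 20% unmatched is a hard error
  expect_error(load_conservation(tsv, "tsv", chain = "A",
                                 residues = paste0("A:", 10:20, ":")),
               "mismatch")
})

test_that("hot-spot surrogate flags buried, densely packed residues", {
  pc <- make_pocket_complex(seed = 6)
  atoms <- compute_sasa(pc$pp)
  iface <- detect_interface(atoms, "A", partner_chain = "B",
                            surface = unique(bindpatch:::atom_keys(
                              atoms[atoms$chain == "A", ])))
  hs <- predict_hotspots(atoms, "A", iface)
  expect_setequal(hs$res, iface$res)
  expect_true(is.logical(hs$hotspot))
  # the pocket core (deepest, most occluded and packed residues) is
  # enriched in hot spots relative to the rest of the interface
  a_rt <- bindpatch:::residue_table(atoms[atoms$chain == "A", ])
  a_rt <- a_rt[a_rt$res %in% hs$res, ]
  core <- a_rt$res[order(a_rt$ca_z)][1:4]
  expect_gte(mean(hs$hotspot[hs$res %in% core]),
             mean(hs$hotspot[!hs$res %in% core]))
  # user-supplied labels override the surrogate exactly
  user <- tibble::tibble(res = iface$res,
                         hotspot = rep(c(TRUE, FALSE),
                                       length.out = nrow(iface)))
  hs2 <- predict_hotspots(atoms, "A", iface, labels = user)
  expect_equal(hs2$hotspot, user$hotspot)
  expect_equal(unique(hs2$source), "user-supplied")
})

test_that("feature vectors have the documented layout and are deterministic", {
  pc <- make_pocket_complex(seed = 8)
  iface <- detect_interface(pc$pp, "A", partner_chain = "B")
  cons <- make_fixture_conservation(pc, seed = 8)
  fv <- build_feature_vectors(pc$pp, "A", iface, conservation = cons)
  expect_setequal(fv$res, iface$res)
  expect_true(all(feature_names() %in% names(fv)))
  # protru1 is the central residue's own protrusion value
  cx <- protrusion(compute_sasa(pc$pp)) |> residue_protrusion()
  expect_equal(fv$protru1, cx$cx[match(fv$res, cx$res)], tolerance = 1e-9)
  # cons1 is the central residue's own conservation score
  expect_equal(fv$cons1, cons$score[match(fv$res, cons$res)])
  # permuting the atom row order changes nothing
  set.seed(1)
  fv2 <- build_feature_vectors(pc$pp[sample(nrow(pc$pp)), ], "A", iface,
                               conservation = cons)
  fv2 <- fv2[match(fv$res, fv2$res), ]
  expect_equal(as.data.frame(fv2), as.data.frame(fv), tolerance = 1e-9)
})

test_that("hot-spot patch frequency is the member fraction", {
  # 8 hot spots out of 8 vs none: ratio arithmetic via patch_label_ratio
  members <- paste0("A:", 1:8, ":")
  labels <- tibble::tibble(res = members,
                           label = c("O", "O", rep("N", 6)))
  expect_equal(patch_label_ratio(members, labels), 0.25)
})

test_that("feature table TSV round-trips through the documented contract", {
  ft <- make_feature_table(seed = 5, n_overlap = 10, n_nonoverlap = 20)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr[1:5], c("chain", "resnum", "icode", "aa", "label"))
  expect_equal(hdr[6:18], feature_names())
  back <- read_feature_table(path)
  expect_equal(nrow(back), 30)
  expect_equal(back$surfaceFraction, ft$surfaceFraction)
  # a table missing a feature column is refused by name
  broken <- ft |> dplyr::select(-"density")
  p2 <- tempfile(fileext = ".tsv")
  write.table(broken, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(p2), "density")
})
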