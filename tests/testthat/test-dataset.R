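test_that("the three fixture variants yield the documented outcomes", {
  pocket <- make_pocket_complex(seed = 14, ligand_site = "pocket")
  acc <- make_pair(pocket$pp, "A", "B", pocket$pl, "A", pair_id = "pocket")
  expect_s3_class(acc, "pppl_pair")
  expect_gte(acc$n_overlap, 2)
  expect_setequal(acc$labeling$res[acc$labeling$label == "O"], pocket$o_set)

  back <- make_pocket_complex(seed = 15, ligand_site = "back")
  rej1 <- make_pair(back$pp, "A", "B", back$pl, "A")
  expect_true(is_rejected(rej1))
  expect_equal(rej1$reason, "insufficient_overlap")

  rim <- make_pocket_complex(seed = 16, ligand_site = "rim")
  rej2 <- make_pair(rim$pp, "A", "B", rim$pl, "A")
  expect_true(is_rejected(rej2))
  expect_equal(rej2$reason, "collision_free")
})

test_that("a flat interface cannot host a competitive ligand", {
  flat <- make_pocket_complex(seed = 17, pocket_depth = 0)
  expect_equal(flat$ligand_site, "rim")
  res <- make_pair(flat$pp, "A", "B", flat$pl, "A")
  expect_true(is_rejected(res))
  expect_equal(res$reason, "collision_free")
})

test_that("low-identity reference chains are rejected as such", {
  pc <- make_pocket_complex(seed = 18)
  res <- make_pair(pc$pp, "A", "B", pc$pl, "A", min_identity = 1.01)
  expect_true(is_rejected(res))
  expect_equal(res$reason, "low_identity")
})

fake_pair <- function(id, seq1, p2_len = 20, iface_id = 0.5) {
  structure(list(pair_id = id, seq_p1 = seq1, p2_len = p2_len,
                 iface_identity = iface_id),
            class = "pppl_pair")
}

test_that("redundancy reduction clusters, drops peptides, picks the best", {
  s1 <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  s2 <- paste(rep("WWGGWWGGWW", 6), collapse = "")  # unrelated (< 40% identity)
  pairs <- list(
    fake_pair("a1", s1, iface_id = 0.6),
    fake_pair("a2", s1, iface_id = 0.9),   # same reference -> same cluster
    fake_pair("b1", s2, iface_id = 0.4))
  kept <- reduce_redundancy(pairs)
  ids <- vapply(kept, function(p) p$pair_id, character(1))
  expect_true("a2" %in% ids)     # higher interface identity wins
  expect_false("a1" %in% ids)
  expect_true("b1" %in% ids)     # distinct cluster survives
  # a peptide-only cluster disappears entirely
  pairs2 <- list(fake_pair("pep1", s1, p2_len = 3),
                 fake_pair("pep2", s1, p2_len = 4),
                 fake_pair("b1", s2, p2_len = 30))
  kept2 <- reduce_redundancy(pairs2)
  expect_equal(vapply(kept2, function(p) p$pair_id, character(1)), "b1")
  # idempotence and monotonicity
  expect_length(reduce_redundancy(kept2), 1)
  expect_lte(length(kept), length(pairs))
})

test_that("rejection reasons are mutually exclusive and exhaustive", {
  reasons <- c()
  for (st in c("pocket", "rim", "back")) {
    pc <- make_pocket_complex(seed = 19, ligand_site = st)
    r <- make_pair(pc$pp, "A", "B", pc$pl, "A")
    reasons <- c(reasons, if (is_rejected(r)) r$reason else "accepted")
  }
  expect_equal(sort(reasons),
               sort(c("accepted", "collision_free", "insufficient_overlap")))
})

test_that("the manifest pipeline accepts one pair and explains the rest", {
  dir <- withr::local_tempdir()
  rows <- list()
  for (st in c("pocket", "rim", "back")) {
    pc <- make_pocket_complex(seed = 21, ligand_site = st)
    ppf <- file.path(dir, paste0(st, "_pp.pdb"))
    plf <- file.path(dir, paste0(st, "_pl.pdb"))
    write_structure_pdb(pc$pp, ppf)
    write_structure_pdb(pc$pl, plf)
    consf <- file.path(dir, paste0(st, "_cons.tsv"))
    cons <- make_fixture_conservation(pc, seed = 21)
    parts <- do.call(rbind, strsplit(cons$res, ":"))
    write.table(data.frame(chain = parts[, 1], resno = parts[, 2],
                           score = cons$score),
                consf, sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[st]] <- data.frame(pp_file = ppf, pp_chain1 = "A",
                             pp_chain2 = "B", pl_file = plf, pl_chain = "A",
                             ligand_code = "LIG",
                             conservation_file = consf,
                             conservation_dialect = "tsv")
  }
  manifest <- file.path(dir, "pairs.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- suppressWarnings(run_pair_manifest(manifest))
  expect_equal(sum(out$report$status == "accepted"), 1)
  expect_setequal(out$report$reason[out$report$status == "rejected"],
                  c("collision_free", "insufficient_overlap"))
  expect_length(out$pairs, 1)
  expect_true(all(feature_names() %in% names(out$features)))
  expect_true(all(out$features$label %in% c("O", "N")))
  expect_gte(sum(out$features$label == "O"), 2)
  expect_error(run_pair_manifest(data.frame()), "empty")
})
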