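#' Assemble and validate one PP:PL training pair
#'
#' Runs the full pairing pipeline for one protein-protein complex and one
#' protein-ligand complex sharing a homologous reference protein: sequence
#' alignment of the two reference chains, interface detection on both
#' sides, overlap labelling through the alignment, Kabsch superposition of
#' the PL reference onto the PP reference, and the steric collision test
#' that keeps only competitive pairs (ligand and partner protein cannot
#' bind simultaneously).
#'
#' @param pp_atoms Atom tibble of the PP complex.
#' @param pp_chain1 Reference chain of the PP complex (P1).
#' @param pp_chain2 Partner protein chain (P2).
#' @param pl_atoms Atom tibble of the PL complex.
#' @param pl_chain Reference chain of the PL complex (P3).
#' @param ligand_id Ligand identifier (`het:chain:resno`) as produced by
#'   [extract_ligands()], or a bare HET code (first copy taken); `NULL`
#'   picks the first ligand.
#' @param min_identity Minimum sequence identity between the reference
#'   chains (default 0.40).
#' @param min_overlap Minimum shared interface residues (default 2).
#' @param cutoff Interface distance cutoff in Angstrom.
#' @param pair_id Identifier for reports; autogenerated when `NULL`.
#' @return A `pppl_pair` (list with the labelling, identity, transform and
#'   metadata) or a `pppl_rejection` with `reason` in `low_identity`,
#'   `insufficient_overlap`, `collision_free`.
#' @export
make_pair <- function(pp_atoms, pp_chain1, pp_chain2, pl_atoms, pl_chain,
                      ligand_id = NULL, min_identity = 0.40,
                      min_overlap = 2L, cutoff = 5.0, pair_id = NULL) {
  pair_id <- pair_id %||%
    paste0(attr(pp_atoms, "structure_id") %||% "pp", ":", pp_chain1,
           pp_chain2, "~", attr(pl_atoms, "structure_id") %||% "pl", ":",
           pl_chain)
  reject <- function(reason, detail = NULL) {
    structure(list(pair_id = pair_id, reason = reason, detail = detail),
              class = "pppl_rejection")
  }

  ligs <- extract_ligands(pl_atoms)
  if (nrow(ligs) == 0L) abort("PL structure contains no ligand")
  if (is.null(ligand_id)) {
    ligand_id <- ligs$ligand_id[1]
  } else if (!ligand_id %in% ligs$ligand_id) {
    hit <- ligs$ligand_id[sub(":.*", "", ligs$ligand_id) == ligand_id]
    if (length(hit) == 0L) {
      abort(paste0("ligand ", ligand_id, " not found in PL structure"))
    }
    ligand_id <- hit[1]
  }
  lig <- ligs[ligs$ligand_id == ligand_id, , drop = FALSE]

  ref_pp <- chain_residues(pp_atoms, pp_chain1)
  ref_pl <- chain_residues(pl_atoms, pl_chain)
  amap <- align_sequences(ref_pp$seq, ref_pl$seq)
  identity <- alignment_identity(amap)
  if (identity < min_identity) {
    return(reject("low_identity", sprintf("identity %.2f", identity)))
  }

  pp_iface <- detect_interface(pp_atoms, pp_chain1,
                               partner_chain = pp_chain2, cutoff = cutoff)
  pl_iface <- detect_interface(pl_atoms, pl_chain, partner_atoms = lig,
                               cutoff = cutoff)
  labeling <- tryCatch(
    label_overlap(pp_iface, pl_iface, amap, ref_pp$residues,
                  ref_pl$residues, min_overlap = min_overlap),
    bindpatch_insufficient_overlap = function(e) NULL)
  if (is.null(labeling) || nrow(pp_iface) == 0L || nrow(pl_iface) == 0L) {
    return(reject("insufficient_overlap"))
  }

  # superpose the PL reference onto the PP reference on aligned CA pairs
  ca_of <- function(atoms, chain, residues, pos) {
    ca <- atoms[atoms$chain == chain & atoms$elety == "CA" &
                  atoms$record == "ATOM", , drop = FALSE]
    keys <- residues$res[pos]
    ca <- ca[match(keys, atom_keys(ca)), , drop = FALSE]
    ca
  }
  ca_pp <- ca_of(pp_atoms, pp_chain1, ref_pp$residues, amap$pos_a)
  ca_pl <- ca_of(pl_atoms, pl_chain, ref_pl$residues, amap$pos_b)
  ok <- stats::complete.cases(ca_pp$x, ca_pl$x)
  tr <- superpose(coords(ca_pl[ok, , drop = FALSE]),
                  coords(ca_pp[ok, , drop = FALSE]))
  lig_mapped <- apply_transform(lig, tr)

  partner <- pp_atoms[pp_atoms$chain == pp_chain2, , drop = FALSE]
  if (!detect_collision(lig_mapped, partner)) {
    return(reject("collision_free"))
  }

  # identity over the union of aligned PP- and PL-interface positions,
  # used later to pick cluster representatives
  if_pos_a <- match(pp_iface$res, ref_pp$residues$res)
  if_pos_b <- amap$pos_a[amap$pos_b %in% match(pl_iface$res, ref_pl$residues$res)]
  if_cols <- amap[amap$pos_a %in% union(if_pos_a, if_pos_b), , drop = FALSE]
  iface_identity <- if (nrow(if_cols)) mean(if_cols$match) else 0

  out <- list(
    pair_id = pair_id,
    pp = list(id = attr(pp_atoms, "structure_id"), chain1 = pp_chain1,
              chain2 = pp_chain2),
    pl = list(id = attr(pl_atoms, "structure_id"), chain = pl_chain,
              ligand_id = ligand_id),
    identity = identity, iface_identity = iface_identity,
    seq_p1 = ref_pp$seq,
    p2_len = nrow(chain_residues(pp_atoms, pp_chain2)$residues),
    labeling = labeling,
    n_overlap = attr(labeling, "n_overlap"),
    n_nonoverlap = attr(labeling, "n_nonoverlap"),
    transform = tr, competitive = TRUE)
  class(out) <- "pppl_pair"
  out
}

#' @export
print.pppl_pair <- function(x, ...) {
  cat("PP:PL pair", x$pair_id, "\n")
  cat(sprintf("  identity %.2f | overlap %d | non-overlap %d | rmsd %.2f A\n",
              x$identity, x$n_overlap, x$n_nonoverlap, x$transform$rmsd))
  invisible(x)
}

#' Is a pairing result a rejection?
#' @param x Result of [make_pair()].
#' @return Logical scalar.
#' @export
is_rejected <- function(x) inherits(x, "pppl_rejection")

#' Remove sequence redundancy among accepted pairs
#'
#' Clusters the PP reference sequences greedily (longest sequence seeds a
#' cluster; a sequence joins the first seed it matches at or above the
#' identity cutoff).  Clusters whose every partner protein is a peptide
#' shorter than 5 residues are dropped entirely; each remaining cluster is
#' represented by the pair with the highest interface-residue identity
#' (ties: first by pair id).
#'
#' @param pairs List of `pppl_pair` objects.
#' @param identity_cutoff Clustering identity cutoff (default 0.40).
#' @return Sub-list of `pairs`, one representative per retained cluster.
#' @export
reduce_redundancy <- function(pairs, identity_cutoff = 0.40) {
  pairs <- Filter(Negate(is_rejected), pairs)
  if (length(pairs) == 0L) return(pairs)
  seqs <- vapply(pairs, function(p) p$seq_p1, character(1))
  ord <- order(-nchar(seqs), vapply(pairs, function(p) p$pair_id, character(1)))
  cluster <- integer(length(pairs))
  seeds <- integer(0)
  for (i in ord) {
    placed <- FALSE
    for (s in seeds) {
      idn <- alignment_identity(align_sequences(seqs[i], seqs[s]))
      if (idn >= identity_cutoff) {
        cluster[i] <- cluster[s]; placed <- TRUE; break
      }
    }
    if (!placed) {
      seeds <- c(seeds, i)
      cluster[i] <- length(seeds)
    }
  }
  keep <- list()
  for (cl in sort(unique(cluster))) {
    members <- pairs[cluster == cl]
    p2 <- vapply(members, function(p) p$p2_len, numeric(1))
    if (all(p2 < 5)) next  # peptide-only cluster
    ii <- vapply(members, function(p) p$iface_identity, numeric(1))
    ids <- vapply(members, function(p) p$pair_id, character(1))
    keep[[length(keep) + 1L]] <- members[[order(-ii, ids)[1]]]
  }
  keep
}

#' Run a pair manifest end to end
#'
#' Reads a TSV manifest (`pp_file`, `pp_chain1`, `pp_chain2`, `pl_file`,
#' `pl_chain`, `ligand_code`; optional `conservation_file`,
#' `conservation_dialect`), builds every candidate pair (each copy of a
#' ligand HET code is a separate candidate), reduces redundancy among the
#' accepted pairs, and assembles the labelled residue feature table for
#' training.
#'
#' @param manifest Path to the manifest TSV, or an equivalent data frame.
#' @param identity_cutoff Redundancy-reduction cutoff (default 0.40).
#' @param ... Passed on to [make_pair()].
#' @return List: `pairs` (accepted, redundancy-reduced), `report` (tibble
#'   of every candidate with `status`/`reason`), `features` (labelled
#'   feature tibble across accepted pairs, with a `pair_id` column).
#' @export
run_pair_manifest <- function(manifest, identity_cutoff = 0.40, ...) {
  mf <- if (is.character(manifest)) {
    read.table(manifest, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else as.data.frame(manifest)
  if (nrow(mf) == 0L) abort("empty pair manifest")
  need <- c("pp_file", "pp_chain1", "pp_chain2", "pl_file", "pl_chain",
            "ligand_code")
  missing <- setdiff(need, names(mf))
  if (length(missing)) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }

  results <- list(); report <- list(); cons <- list()
  for (r in seq_len(nrow(mf))) {
    pp <- read_structure(mf$pp_file[r])
    pl <- read_structure(mf$pl_file[r])
    ligs <- extract_ligands(pl)
    cand <- ligs$ligand_id[sub(":.*", "", ligs$ligand_id) == mf$ligand_code[r]]
    cand <- unique(cand)
    if (length(cand) == 0L) {
      report[[length(report) + 1L]] <- tibble(
        pair_id = paste0("row", r), status = "rejected",
        reason = "ligand_not_found", n_overlap = NA_integer_)
      next
    }
    for (lg in cand) {
      res <- make_pair(pp, mf$pp_chain1[r], mf$pp_chain2[r], pl,
                       mf$pl_chain[r], ligand_id = lg, ...)
      results[[length(results) + 1L]] <- res
      if (is_rejected(res)) {
        report[[length(report) + 1L]] <- tibble(
          pair_id = res$pair_id, status = "rejected", reason = res$reason,
          n_overlap = NA_integer_)
      } else {
        report[[length(report) + 1L]] <- tibble(
          pair_id = res$pair_id, status = "accepted", reason = NA_character_,
          n_overlap = res$n_overlap)
        has_cons <- !is.null(mf$conservation_file) &&
          !is.na(mf$conservation_file[r]) && nzchar(mf$conservation_file[r])
        dial <- if (!is.null(mf$conservation_dialect) &&
                      !is.na(mf$conservation_dialect[r])) {
          mf$conservation_dialect[r]
        } else "tsv"
        cons[[res$pair_id]] <- list(
          atoms = pp, chain = mf$pp_chain1[r],
          conservation = if (has_cons) {
            load_conservation(mf$conservation_file[r], dialect = dial,
                              chain = mf$pp_chain1[r])
          } else NULL)
      }
    }
  }

  kept <- reduce_redundancy(results, identity_cutoff = identity_cutoff)
  feats <- purrr::map(kept, function(p) {
    ctx <- cons[[p$pair_id]]
    fv <- build_feature_vectors(ctx$atoms, ctx$chain, p$labeling,
                                conservation = ctx$conservation)
    fv$label <- p$labeling$label[match(fv$res, p$labeling$res)]
    fv$pair_id <- p$pair_id
    fv
  })
  features <- if (length(feats)) bind_rows(feats) else tibble()
  list(pairs = kept, report = bind_rows(report), features = features)
}
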