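#' Detect the binding interface of a chain
#'
#' A surface residue of the query chain belongs to the interface when at
#' least one of its heavy atoms lies within `cutoff` of any heavy atom of
#' the binding partner (a protein chain or a ligand).  The surface filter
#' is applied to the query side only.
#'
#' @param atoms Atom tibble holding the query chain (and the partner chain,
#'   when `partner_chain` is used).
#' @param query_chain Chain identifier of the query protein.
#' @param partner_chain Chain identifier of the partner protein, or `NULL`
#'   when `partner_atoms` is given.
#' @param partner_atoms Atom tibble of the partner (e.g. one ligand from
#'   [extract_ligands()]); overrides `partner_chain`.
#' @param cutoff Distance cutoff in Angstrom (default 5; the bound is
#'   inclusive).
#' @param surface Optional character vector of surface residue keys for the
#'   query chain; when `NULL` it is computed from the isolated query chain
#'   with [compute_sasa()] + [surface_residues()].
#' @param rel_sasa_threshold Surface threshold forwarded to
#'   [surface_residues()] when `surface` is computed here.
#' @return Tibble of interface residues (`res`, `chain`, `resno`, `insert`,
#'   `resid`, `min_dist`), with attributes `query_chain`, `partner` and
#'   `cutoff`.
#' @export
detect_interface <- function(atoms, query_chain, partner_chain = NULL,
                             partner_atoms = NULL, cutoff = 5.0,
                             surface = NULL, rel_sasa_threshold = 0.05) {
  q <- atoms[atoms$chain == query_chain & atoms$record == "ATOM", , drop = FALSE]
  if (nrow(q) == 0L) abort(paste0("query chain ", query_chain, " has no atoms"))
  if (is.null(partner_atoms)) {
    if (is.null(partner_chain)) abort("give partner_chain or partner_atoms")
    partner_atoms <- atoms[atoms$chain == partner_chain, , drop = FALSE]
    partner_label <- partner_chain
  } else {
    partner_label <- partner_atoms$ligand_id[1] %||% "ligand"
  }
  if (nrow(partner_atoms) == 0L) abort("binding partner has no atoms")

  if (is.null(surface)) {
    surf <- q |> compute_sasa() |> surface_residues(rel_sasa_threshold)
    surface <- surf$res[surf$is_surface]
  }
  rt <- residue_table(q)
  rt <- rt[rt$res %in% surface, , drop = FALSE]
  keys <- atom_keys(q)
  pm <- coords(partner_atoms)
  rt$min_dist <- unname(vapply(rt$res, function(key) {
    min_pair_distance(coords(q[keys == key, , drop = FALSE]), pm)
  }, numeric(1)))
  out <- rt |>
    filter(.data$min_dist <= cutoff) |>
    select("res", "chain", "resno", "insert", "resid", "min_dist")
  attr(out, "query_chain") <- query_chain
  attr(out, "partner") <- partner_label
  attr(out, "cutoff") <- cutoff
  out
}

#' Global sequence alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 (gap open 10, gap extend
#' 0.5) via Biostrings.  Characters outside the 20-letter alphabet are
#' mapped to X with a warning.
#'
#' @param seq_a,seq_b One-letter amino-acid strings.
#' @return Tibble of aligned non-gap columns (`pos_a`, `pos_b`, `aa_a`,
#'   `aa_b`, `match`) with an `identity` attribute (matches over alignment
#'   columns).
#' @examples
#' align_sequences("ACDEFGHIK", "ACDEFGHIK")
#' @export
align_sequences <- function(seq_a, seq_b) {
  clean <- function(s) {
    s <- toupper(s)
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWY]", "", s)
    if (nchar(bad)) {
      warn(paste0("non-standard residue code(s) mapped to X: ",
                  paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
      s <- chartr(bad, strrep("X", nchar(bad)), s)
    }
    s
  }
  seq_a <- clean(seq_a); seq_b <- clean(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) abort("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  al_a <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  pos_a <- cumsum(al_a != "-"); pos_b <- cumsum(al_b != "-")
  keep <- al_a != "-" & al_b != "-"
  out <- tibble(pos_a = pos_a[keep], pos_b = pos_b[keep],
                aa_a = al_a[keep], aa_b = al_b[keep],
                match = al_a[keep] == al_b[keep])
  attr(out, "identity") <- sum(out$match) / length(al_a)
  out
}

#' Alignment identity
#' @param amap Alignment tibble from [align_sequences()].
#' @return Fraction of identical columns over the alignment length.
#' @export
alignment_identity <- function(amap) attr(amap, "identity")

#' Label overlap and non-overlap residues of a PP interface
#'
#' Maps the protein-ligand (PL) interface of the homologous reference
#' protein onto the protein-protein (PP) interface through a sequence
#' alignment.  A PP-interface residue is labelled `O` (overlap) when its
#' aligned position belongs to the PL interface, `N` otherwise.  PL
#' positions that are unaligned (gapped) in the PP reference are ignored.
#'
#' @param pp_iface Interface tibble of the PP reference chain
#'   (from [detect_interface()]).
#' @param pl_iface Interface tibble of the PL reference chain vs the ligand.
#' @param amap Alignment of the PP reference sequence (`a`) to the PL
#'   reference sequence (`b`), from [align_sequences()].
#' @param pp_residues,pl_residues Ordered residue tables of the two
#'   reference chains (`chain_residues()`), defining sequence positions.
#' @param min_overlap Minimum number of overlap residues for a valid pair
#'   (default 2); fewer raises a classed error
#'   (`bindpatch_insufficient_overlap`).
#' @return Tibble (`res`, `chain`, `resno`, `insert`, `resid`, `label`)
#'   covering exactly the PP interface, with attributes `n_overlap` and
#'   `n_nonoverlap`.
#' @export
label_overlap <- function(pp_iface, pl_iface, amap, pp_residues, pl_residues,
                          min_overlap = 2L) {
  pos_of <- function(residues, keys) match(keys, residues$res)
  map_b <- setNames(amap$pos_b, amap$pos_a)
  pp_pos <- pos_of(pp_residues, pp_iface$res)
  if (anyNA(pp_pos)) abort("PP interface residue missing from residue table")
  pl_pos <- unname(map_b[as.character(pp_pos)])
  pl_key <- ifelse(is.na(pl_pos), NA_character_, pl_residues$res[pl_pos])
  lab <- ifelse(!is.na(pl_key) & pl_key %in% pl_iface$res, "O", "N")
  out <- pp_iface |>
    select("res", "chain", "resno", "insert", "resid") |>
    mutate(label = lab)
  n_o <- sum(lab == "O"); n_n <- sum(lab == "N")
  if (n_o < min_overlap) {
    abort(paste0("insufficient overlap: ", n_o, " < ", min_overlap),
          class = "bindpatch_insufficient_overlap")
  }
  attr(out, "n_overlap") <- n_o
  attr(out, "n_nonoverlap") <- n_n
  out
}

#' Ordered residue table and sequence of a protein chain
#'
#' @param atoms Atom tibble.
#' @param chain Chain identifier.
#' @return List with `seq` (one-letter string) and `residues` (ordered
#'   residue tibble whose row number is the sequence position).
#' @export
chain_residues <- function(atoms, chain) chain_sequence(atoms, chain)
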