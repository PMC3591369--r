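#' Read a PDB-format structure into an atom table
#'
#' Parses ATOM/HETATM records (first model only) into a tibble with one row
#' per heavy atom.  Hydrogens are dropped, alternate locations are resolved
#' to the highest-occupancy conformer (ties: first in file), and van der
#' Waals radii are assigned from a configurable element table.
#'
#' @param file Path to a PDB file.  Exactly one of `file`/`text` is given.
#' @param text Character scalar (or vector of lines) of PDB-format text.
#' @param chains Optional character vector of chain identifiers to retain;
#'   an error names any requested chain that is absent.
#' @param radii Radii table from [vdw_radii()].
#' @param id Structure identifier stored in the `structure_id` attribute.
#' @return A tibble of heavy atoms with columns `record`, `serial`, `elety`
#'   (atom name), `resid` (3-letter residue code), `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `elesy` (element) and `radius`.
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
#'   "END")
#' read_structure(text = pdb)
#' @export
read_structure <- function(file = NULL, text = NULL, chains = NULL,
                           radii = vdw_radii(), id = NULL) {
  if (is.null(file) == is.null(text)) {
    abort("supply exactly one of `file` or `text`")
  }
  if (!is.null(text)) {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(lines, file)
  } else {
    if (!file.exists(file)) abort(paste0("no such file: ", file))
    lines <- readLines(file, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  }
  validate_pdb_lines(lines)

  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy <- infer_element(at$elesy, at$elety)

  # heavy atoms only
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]

  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing)) {
      abort(paste0("chain(s) not present in structure: ",
                   paste(missing, collapse = ", ")))
    }
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (nrow(at) == 0L) abort("structure contains no heavy atoms")

  # resolve altlocs: highest occupancy per (chain, resno, insert, elety),
  # tie broken by file order
  at$alt[is.na(at$alt)] <- ""
  at <- at |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.ord)

  out <- tibble(
    record = at$type, serial = at$eleno, elety = at$elety,
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = at$insert, x = at$x, y = at$y, z = at$z,
    elesy = toupper(at$elesy),
    radius = radius_for_element(at$elesy, radii))
  attr(out, "structure_id") <- id %||% "structure"
  out
}

# reject ATOM/HETATM records whose fixed-width coordinate fields do not parse
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    co <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                        substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(co)) {
      abort(paste0("unparseable PDB record at line ", i, ": ",
                   substr(ln, 1, 30), "..."))
    }
  }
  invisible(TRUE)
}

# derive element symbol from atom name when columns 77-78 are blank
infer_element <- function(elesy, elety) {
  elesy <- trimws(as.character(elesy))
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety[blank])))
    # 4-char names starting in column 13 can begin with the element; strip
    # common remoteness letters for standard protein atoms
    guess <- substr(guess, 1, 1)
    elesy[blank] <- guess
  }
  elesy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residue key used throughout: chain + resno + insertion code
res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = ":")
}

atom_keys <- function(atoms) res_key(atoms$chain, atoms$resno, atoms$insert)

coords <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Summarise an atom table to one row per residue
#'
#' @param atoms An atom tibble from [read_structure()] (optionally filtered).
#' @return A tibble with `chain`, `resno`, `insert`, `resid`, `record`,
#'   `n_atoms`, `res` (the residue key) and Calpha coordinates
#'   (`ca_x`,`ca_y`,`ca_z`; the residue centroid when no CA atom exists).
#' @export
residue_table <- function(atoms) {
  atoms |>
    mutate(res = atom_keys(atoms)) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$res) |>
    summarise(
      resid = .data$resid[1], record = .data$record[1], n_atoms = n(),
      ca_x = if (any(.data$elety == "CA")) .data$x[.data$elety == "CA"][1] else mean(.data$x),
      ca_y = if (any(.data$elety == "CA")) .data$y[.data$elety == "CA"][1] else mean(.data$y),
      ca_z = if (any(.data$elety == "CA")) .data$z[.data$elety == "CA"][1] else mean(.data$z),
      .groups = "drop") |>
    arrange(.data$chain, .data$resno, .data$insert)
}

# ordered one-letter sequence and residue keys of a (protein) chain
chain_sequence <- function(atoms, chain) {
  rt <- residue_table(atoms[atoms$chain == chain & atoms$record == "ATOM", ])
  if (nrow(rt) == 0L) abort(paste0("no ATOM residues in chain ", chain))
  list(seq = paste(aa_one_letter(rt$resid), collapse = ""), residues = rt)
}

#' Extract small-molecule ligands from a structure
#'
#' A ligand is a HETATM residue group that is not a water or a monoatomic
#' ion: groups whose code is in the exclusion set, or that have fewer than
#' two heavy atoms, are dropped.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param excluded_het_codes HET codes never treated as ligands (waters and
#'   common ions by default).
#' @return A tibble of ligand atoms with an extra `ligand_id` column
#'   (`het_code:chain:resno`); zero rows when the structure has no ligand.
#' @export
extract_ligands <- function(atoms,
                            excluded_het_codes = c("HOH", "WAT", "DOD",
                                                   "NA", "K", "CL", "MG", "CA",
                                                   "ZN", "MN", "FE", "CU", "NI",
                                                   "CO", "CD", "IOD", "BR")) {
  het <- atoms[atoms$record == "HETATM" &
                 !(atoms$resid %in% excluded_het_codes), , drop = FALSE]
  if (nrow(het) == 0L) return(het |> mutate(ligand_id = character(0)))
  het <- het |>
    mutate(ligand_id = paste(.data$resid, .data$chain, .data$resno, sep = ":")) |>
    group_by(.data$ligand_id) |>
    filter(n() >= 2) |>
    ungroup()
  het
}

#' Write an atom table back to PDB format
#'
#' @param atoms Atom tibble.
#' @param file Output path; when `NULL` the lines are returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_structure_pdb <- function(atoms, file = NULL) {
  fmt <- function(i) {
    a <- atoms[i, ]
    name <- a$elety
    name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, a$serial %% 100000L, name, a$resid, a$chain,
            a$resno %% 10000L, ifelse(a$insert == "", " ", a$insert),
            a$x, a$y, a$z, 1, 0, a$elesy)
  }
  lines <- c(vapply(seq_len(nrow(atoms)), fmt, character(1)), "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
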