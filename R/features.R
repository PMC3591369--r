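#' Names of the 13 classifier features
#'
#' Surface fraction and contact density of the central residue, protrusion
#' index and conservation of the five nearest surface residues (index 1 is
#' the central residue itself), and the hot-spot frequency in its size-8
#' surface patch.
#'
#' @return Character vector of length 13, in the fixed column order of the
#'   feature-table contract.
#' @export
feature_names <- function() {
  c("surfaceFraction", "density", paste0("protru", 1:5),
    paste0("cons", 1:5), "hsfPatch8")
}

#' Protrusion index (cx)
#'
#' For every heavy atom, the ratio of empty to occupied volume inside a
#' sphere of radius `sphere_radius` centred on the atom:
#' `cx = V_empty / V_atoms`, where `V_atoms` is the union volume of all
#' heavy-atom spheres intersecting the neighbourhood (the central atom
#' included) and `V_empty` the remainder of the sphere.  Volumes are
#' estimated on a uniform voxel grid.  0 means fully buried; large values
#' mean protruding, solvent-exposed atoms.
#'
#' @param atoms Atom tibble.
#' @param sphere_radius Neighbourhood radius in Angstrom (default 10).
#' @param grid_spacing Voxel edge in Angstrom (default 0.25; halving the
#'   spacing roughly halves the discretisation error).
#' @return `atoms` with an `atom_cx` column.
#' @export
protrusion <- function(atoms, sphere_radius = 10.0, grid_spacing = 0.25) {
  if (nrow(atoms) == 0L) abort("empty atom table")
  atoms$atom_cx <- cx_protrusion(coords(atoms), atoms$radius,
                                 sphere_radius, grid_spacing)
  atoms
}

#' Per-residue protrusion values
#'
#' @param atoms Atom tibble with `atom_cx` (see [protrusion()]).
#' @return Tibble (`res`, `chain`, `resno`, `insert`, `resid`, `cx`) where
#'   `cx` is the mean over the residue's heavy atoms.
#' @export
residue_protrusion <- function(atoms) {
  if (is.null(atoms$atom_cx)) abort("run protrusion() first")
  atoms |>
    mutate(res = atom_keys(atoms)) |>
    group_by(.data$res, .data$chain, .data$resno, .data$insert) |>
    summarise(resid = .data$resid[1], cx = mean(.data$atom_cx),
              .groups = "drop") |>
    arrange(.data$chain, .data$resno, .data$insert)
}

#' Intra-chain contact density
#'
#' For each residue of the chain, counts the heavy-atom contacts of its
#' surface-accessible atoms (atom SASA > 0 in the supplied context) with
#' heavy atoms of *other* residues of the same chain within the cutoff,
#' normalised by the residue's total heavy-atom count:
#' `density_i = sum_j contacts(atom_ij) / totalAtoms_i`, the sum running
#' over surface-accessible atoms j only.
#'
#' @param atoms Atom tibble carrying `atom_sasa` (see [compute_sasa()];
#'   compute it in the context - chain or complex - you want accessibility
#'   judged in).
#' @param chain Chain identifier.
#' @param contact_cutoff Contact distance in Angstrom (default 5,
#'   inclusive).
#' @return Tibble (`res`, `chain`, `resno`, `insert`, `resid`, `density`).
#' @export
contact_density <- function(atoms, chain, contact_cutoff = 5.0) {
  if (is.null(atoms$atom_sasa)) abort("run compute_sasa() first")
  q <- atoms[atoms$chain == chain & atoms$record == "ATOM", , drop = FALSE]
  if (nrow(q) == 0L) abort(paste0("chain ", chain, " not found"))
  keys <- atom_keys(q)
  xyz <- coords(q)
  rt <- residue_table(q)
  rt$density <- unname(vapply(rt$res, function(key) {
    mine <- keys == key
    acc <- mine & q$atom_sasa > 0
    if (!any(acc)) return(0)
    others <- xyz[!mine, , drop = FALSE]
    if (nrow(others) == 0L) return(0)
    sum(count_within(xyz[acc, , drop = FALSE], others, contact_cutoff)) /
      sum(mine)
  }, numeric(1)))
  rt |> select("res", "chain", "resno", "insert", "resid", "density")
}

#' Relative surface fraction
#'
#' SASA of each residue of the chain in the supplied (complex) context,
#' divided by the total surface of that residue type at the centre of an
#' extended Ala-X-Ala tripeptide ([tripeptide_reference_sasa()]); clipped
#' to \[0, 1\].
#'
#' @param atoms Atom tibble of the complex, carrying `atom_sasa` computed
#'   in the complex.
#' @param chain Chain identifier.
#' @return Tibble (`res`, `chain`, `resno`, `insert`, `resid`,
#'   `surface_fraction`).
#' @export
surface_fraction <- function(atoms, chain) {
  if (is.null(atoms$atom_sasa)) abort("run compute_sasa() first")
  q <- atoms[atoms$chain == chain & atoms$record == "ATOM", , drop = FALSE]
  if (nrow(q) == 0L) abort(paste0("chain ", chain, " not found"))
  unknown <- setdiff(unique(q$resid), names(.side_chain_atoms))
  if (length(unknown)) {
    abort(paste0("unknown amino-acid code(s): ", paste(unknown, collapse = ", ")))
  }
  ref <- tripeptide_reference_sasa(unique(q$resid))
  rs <- residue_sasa(q, reference = ref)
  rs |>
    mutate(surface_fraction = pmin(1, pmax(0, .data$rel_sasa))) |>
    select("res", "chain", "resno", "insert", "resid", "surface_fraction")
}

#' Load per-residue conservation scores
#'
#' Reads normalized evolutionary conservation scores (negative = conserved,
#' positive = variable) either from a plain TSV (`chain`, `resno`, `score`
#' columns, optional `insert`) or from the ConSurf-DB grade-file dialect
#' (header junk tolerated; residue identity taken from the `3LATOM` field,
#' e.g. `MET1:A`, and the normalized `SCORE` column).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"consurf_grades"`.
#' @param chain Chain the scores belong to (used for matching and for the
#'   grade-file chain check).
#' @param residues Optional character vector of residue keys expected to be
#'   covered; if more than `max_unmatched` of them have no score the load
#'   fails with a numbering-mismatch error.
#' @param max_unmatched Tolerated unmatched fraction (default 0.2).
#' @return Tibble (`res`, `score`).
#' @export
load_conservation <- function(path, dialect = c("tsv", "consurf_grades"),
                              chain = NULL, residues = NULL,
                              max_unmatched = 0.2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("chain", "resno", "score") %in% names(df))) {
      abort("TSV must have columns chain, resno, score (optional insert)")
    }
    if (is.null(df$insert)) df$insert <- ""
    df$insert[is.na(df$insert)] <- ""
    if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
    tab <- tibble(res = res_key(df$chain, df$resno, df$insert),
                  score = as.numeric(df$score))
  } else {
    lines <- readLines(path, warn = FALSE)
    rows <- list()
    for (ln in lines) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 4 || !grepl("^[0-9]+$", f[1])) next
      m <- regmatches(f[3], regexec("^([A-Z]{3})([0-9]+)([A-Z]?):([A-Za-z0-9])$",
                                    f[3]))[[1]]
      if (length(m) == 0L) next   # unresolved position ("-")
      sc <- suppressWarnings(as.numeric(f[4]))
      if (is.na(sc)) next
      rows[[length(rows) + 1L]] <- tibble(
        chain = m[5], resno = as.integer(m[3]), insert = m[4], score = sc)
    }
    df <- bind_rows(rows)
    if (nrow(df) == 0L) abort("no parseable grade rows found")
    if (!is.null(chain)) {
      if (!any(df$chain == chain)) {
        abort(paste0("conservation file contains no residues for chain ",
                     chain, " (found: ",
                     paste(unique(df$chain), collapse = ", "), ")"))
      }
      df <- df[df$chain == chain, , drop = FALSE]
    }
    tab <- tibble(res = res_key(df$chain, df$resno, df$insert),
                  score = df$score)
  }
  tab <- distinct(tab, .data$res, .keep_all = TRUE)
  if (!is.null(residues)) {
    unmatched <- setdiff(residues, tab$res)
    frac <- length(unmatched) / length(residues)
    if (frac > max_unmatched) {
      abort(paste0("conservation numbering mismatch: ",
                   length(unmatched), "/", length(residues),
                   " residues without a score"))
    }
    if (length(unmatched)) {
      warn(paste0(length(unmatched),
                  " residue(s) without a conservation score"))
    }
  }
  tab
}

#' Predict hot-spot residues (empirical surrogate)
#'
#' Flags an interface residue as a hot spot when it is strongly occluded
#' from solvent in the complex (relative SASA at most `rel_sasa_max`) and
#' densely packed (contact density at least the chain median plus
#' `density_k` times the IQR).  This is a configurable knowledge-based
#' surrogate in the accessibility-plus-packing family; supply `labels` to
#' override it with externally computed hot spots.
#'
#' @param atoms Atom tibble of the full complex.
#' @param query_chain Chain the interface belongs to.
#' @param interface Interface tibble from [detect_interface()].
#' @param rel_sasa_max Maximum in-complex relative SASA (default 0.20).
#' @param density_k IQR multiplier for the density threshold (default 0.5).
#' @param labels Optional tibble (`res`, `hotspot` logical) of user labels;
#'   returned as-is for the interface residues (missing ones = FALSE).
#' @return Tibble (`res`, `hotspot`, `source`), one row per interface
#'   residue.
#' @export
predict_hotspots <- function(atoms, query_chain, interface,
                             rel_sasa_max = 0.20, density_k = 0.5,
                             labels = NULL) {
  if (!is.null(labels)) {
    hs <- interface |>
      select("res") |>
      left_join(labels, by = "res") |>
      mutate(hotspot = !is.na(.data$hotspot) & .data$hotspot,
             source = "user-supplied")
    return(hs)
  }
  cx_atoms <- if (is.null(atoms$atom_sasa)) compute_sasa(atoms) else atoms
  rs <- residue_sasa(cx_atoms[cx_atoms$chain == query_chain &
                                cx_atoms$record == "ATOM", , drop = FALSE])
  dens <- contact_density(cx_atoms, query_chain)
  thr <- median(dens$density) +
    density_k * (quantile(dens$density, 0.75) - quantile(dens$density, 0.25))
  interface |>
    select("res") |>
    left_join(rs |> select("res", "rel_sasa"), by = "res") |>
    left_join(dens |> select("res", "density"), by = "res") |>
    mutate(hotspot = .data$rel_sasa <= rel_sasa_max & .data$density >= thr,
           source = "predicted") |>
    select("res", "hotspot", "source")
}

#' Build the 13-feature vectors for every interface residue
#'
#' Assembles, per interface residue: the surface fraction and contact
#' density of the residue itself, the protrusion index and conservation
#' score of the residue and its four nearest surface residues (Calpha
#' distance, ties broken by residue order), and the hot-spot frequency in
#' its size-8 surface patch.
#'
#' @param atoms Atom tibble of the PP complex.
#' @param query_chain Reference chain carrying the interface.
#' @param interface Interface tibble from [detect_interface()].
#' @param conservation Tibble (`res`, `score`) from [load_conservation()],
#'   or `NULL` (all scores imputed as 0 with a warning).
#' @param hotspots Tibble from [predict_hotspots()], or `NULL` to run the
#'   surrogate predictor here.
#' @param surface Character vector of surface residue keys of the isolated
#'   query chain, or `NULL` to compute it.
#' @param rel_sasa_threshold Surface threshold when `surface` is computed.
#' @param probe_radius,n_points SASA parameters.
#' @param sphere_radius,grid_spacing Protrusion parameters.
#' @param contact_cutoff Contact-density cutoff.
#' @return Tibble with identifier columns (`res`, `chain`, `resno`,
#'   `insert`, `aa`) and the 13 numeric feature columns of
#'   [feature_names()].
#' @export
build_feature_vectors <- function(atoms, query_chain, interface,
                                  conservation = NULL, hotspots = NULL,
                                  surface = NULL, rel_sasa_threshold = 0.05,
                                  probe_radius = 1.4, n_points = 960L,
                                  sphere_radius = 10.0, grid_spacing = 0.25,
                                  contact_cutoff = 5.0) {
  if (nrow(interface) == 0L) abort("empty interface")
  cx_atoms <- compute_sasa(atoms, probe_radius, n_points)
  q_iso <- atoms[atoms$chain == query_chain & atoms$record == "ATOM", , drop = FALSE]
  if (is.null(surface)) {
    surf <- q_iso |> compute_sasa(probe_radius, n_points) |>
      surface_residues(rel_sasa_threshold)
    surface <- surf$res[surf$is_surface]
  }
  sf <- surface_fraction(cx_atoms, query_chain)
  dens <- contact_density(cx_atoms, query_chain, contact_cutoff)
  cx <- protrusion(cx_atoms[cx_atoms$record == "ATOM" |
                              cx_atoms$record == "HETATM", , drop = FALSE],
                   sphere_radius, grid_spacing) |>
    residue_protrusion()
  if (is.null(hotspots)) {
    hotspots <- predict_hotspots(cx_atoms, query_chain, interface)
  }
  if (is.null(conservation)) {
    warn("no conservation table supplied; all scores imputed as 0")
    conservation <- tibble(res = character(0), score = numeric(0))
  }

  rt <- residue_table(q_iso)
  surf_rt <- rt[rt$res %in% surface, , drop = FALSE]
  if (nrow(surf_rt) < 5) abort("fewer than 5 surface residues")
  lookup <- function(tab, col, keys, default = NA_real_) {
    v <- tab[[col]][match(keys, tab$res)]
    v[is.na(v)] <- default
    v
  }
  cons_of <- function(keys) {
    v <- conservation$score[match(keys, conservation$res)]
    if (anyNA(v)) {
      warn(paste0(sum(is.na(v)), " residue(s) missing a conservation score; ",
                  "imputed as 0"))
      v[is.na(v)] <- 0
    }
    v
  }
  hs_set <- hotspots$res[hotspots$hotspot]

  rows <- purrr::map(seq_len(nrow(interface)), function(i) {
    key <- interface$res[i]
    me <- surf_rt[surf_rt$res == key, , drop = FALSE]
    if (nrow(me) == 0L) me <- rt[rt$res == key, , drop = FALSE]
    d <- sqrt((surf_rt$ca_x - me$ca_x)^2 + (surf_rt$ca_y - me$ca_y)^2 +
                (surf_rt$ca_z - me$ca_z)^2)
    ord <- order(d, surf_rt$chain, surf_rt$resno, surf_rt$insert)
    near <- surf_rt$res[ord]
    near <- unique(c(key, near))[1:5]
    p8 <- build_patch(atoms, key, surface, n = 8)
    hsf <- mean(p8$members %in% hs_set)
    tibble(
      res = key, chain = interface$chain[i], resno = interface$resno[i],
      insert = interface$insert[i], aa = interface$resid[i],
      surfaceFraction = lookup(sf, "surface_fraction", key, 0),
      density = lookup(dens, "density", key, 0),
      !!!setNames(as.list(lookup(cx, "cx", near, 0)), paste0("protru", 1:5)),
      !!!setNames(as.list(cons_of(near)), paste0("cons", 1:5)),
      hsfPatch8 = hsf)
  })
  bind_rows(rows)
}

#' Write / read the feature-table TSV contract
#'
#' Fixed column order: `chain`, `resnum`, `icode`, `aa`, optional `label`,
#' then the 13 features of [feature_names()].
#'
#' @param features Feature tibble (from [build_feature_vectors()],
#'   optionally with a `label` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  nm <- c(chain = "chain", resno = "resnum", insert = "icode", aa = "aa")
  for (i in seq_along(nm)) {
    if (names(nm)[i] %in% names(out)) {
      names(out)[names(out) == names(nm)[i]] <- nm[i]
    }
  }
  keep <- c("chain", "resnum", "icode", "aa",
            if ("label" %in% names(out)) "label", feature_names())
  keep <- intersect(keep, names(out))
  write.table(out[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing)) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}
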