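#' Predict the ligand-binding sub-region of a PP interface
#'
#' End-to-end prediction for one protein-protein complex: detects the
#' interface of the reference chain, computes the 13-feature vectors,
#' scores every interface residue with a trained balanced ensemble, and
#' aggregates the predictions into high-confidence binding patches
#' (size-`patch_size` patches whose central residue is predicted overlap
#' and that contain at least `min_votes` predicted overlap residues).
#'
#' @param model A `balanced_rf` model from [brf_train()].
#' @param atoms Atom tibble of the PP complex.
#' @param query_chain Reference chain carrying the interface.
#' @param partner_chain Partner protein chain.
#' @param conservation Optional conservation tibble
#'   ([load_conservation()]).
#' @param hotspots Optional hot-spot labels ([predict_hotspots()]).
#' @param cutoff Interface cutoff in Angstrom (default 5).
#' @param patch_size Patch size for the vote (default 7).
#' @param min_votes Minimum predicted-O members per reported patch
#'   (default 5).
#' @return List: `residues` (per-residue prediction tibble with
#'   `vote_fraction` and `pred_label`), `patches` (reported binding
#'   patches, possibly empty), `features` (the feature table used).  When
#'   the interface is empty, all three are empty with a warning.
#' @export
predict_interface_overlap <- function(model, atoms, query_chain,
                                      partner_chain, conservation = NULL,
                                      hotspots = NULL, cutoff = 5.0,
                                      patch_size = 7L, min_votes = 5L) {
  q_iso <- atoms[atoms$chain == query_chain & atoms$record == "ATOM", , drop = FALSE]
  surf <- q_iso |> compute_sasa() |> surface_residues()
  surface <- surf$res[surf$is_surface]
  iface <- detect_interface(atoms, query_chain,
                            partner_chain = partner_chain,
                            cutoff = cutoff, surface = surface)
  if (nrow(iface) == 0L) {
    warn("empty interface; nothing to predict")
    return(list(residues = tibble(), patches = tibble(), features = tibble()))
  }
  fv <- build_feature_vectors(atoms, query_chain, iface,
                              conservation = conservation,
                              hotspots = hotspots, surface = surface)
  pred <- predict(model, fv)
  patches <- build_patches(atoms, centrals = iface$res,
                           surface_set = surface, n = patch_size)
  bp <- predict_binding_patches(pred, patches, min_votes = min_votes,
                                expected_size = patch_size)
  list(residues = pred, patches = bp, features = fv)
}

#' Write residue predictions as TSV
#'
#' @param prediction Prediction tibble from [predict.balanced_rf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(prediction, path) {
  out <- prediction
  names(out)[names(out) == "resno"] <- "resnum"
  names(out)[names(out) == "insert"] <- "icode"
  keep <- intersect(c("chain", "resnum", "icode", "aa", "vote_fraction",
                      "pred_label"), names(out))
  write.table(out[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write binding-patch predictions as TSV
#'
#' @param patches Patch tibble from [predict_binding_patches()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patch_tsv <- function(patches, path) {
  out <- tibble(central = patches$central,
                members = vapply(patches$members, paste, character(1),
                                 collapse = ","),
                n_overlap = patches$n_overlap, ratio = patches$ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export overlap labels as TSV
#'
#' Two-way bridge so labels can come from other tools: columns `chain`,
#' `resnum`, `icode`, `aa`, `label`.
#'
#' @param labeling Labelling tibble from [label_overlap()].
#' @param path Output path.
#' @return `path` (write) or the labelling tibble (read).
#' @export
write_labeling_tsv <- function(labeling, path) {
  out <- labeling
  names(out)[names(out) == "resno"] <- "resnum"
  names(out)[names(out) == "insert"] <- "icode"
  names(out)[names(out) == "resid"] <- "aa"
  keep <- intersect(c("chain", "resnum", "icode", "aa", "label"), names(out))
  write.table(out[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeling_tsv
#' @export
read_labeling_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  tibble(res = res_key(df$chain, df$resnum, df$icode),
         chain = df$chain, resno = df$resnum, insert = df$icode,
         resid = df$aa, label = df$label)
}
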