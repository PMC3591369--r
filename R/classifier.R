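#' Train a class-balanced random-forest ensemble
#'
#' Interface residue classes are heavily imbalanced (far more non-overlap
#' than overlap residues), which skews a single forest towards the majority
#' class.  The ensemble therefore fits `K` random forests, each on a
#' balanced sample that keeps every minority-class row and draws, without
#' replacement, the same number of rows from the majority class.  The
#' final label is a majority vote over the `K` members.
#'
#' @param features Tibble with a `label` column (`"O"`/`"N"`, character or
#'   factor) and the 13 feature columns of [feature_names()].
#' @param K Number of balanced draws / forest members (the method default
#'   is 1000; use small values for interactive work).
#' @param ntree Trees per member (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(13))` = 3).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param keep_draws Keep the row indices of every balanced draw in the
#'   returned object (`draws`); off by default to keep models small.
#' @return Object of class `balanced_rf`: list with `members`, `K`,
#'   `ntree`, `mtry`, `feature_names`, `seed`, `class_order`,
#'   `member_class_counts` (K x 2 matrix of per-draw class sizes).
#' @examples
#' ft <- make_feature_table(seed = 1, n_overlap = 40, n_nonoverlap = 160)
#' fit <- brf_train(ft, K = 3, ntree = 50, seed = 1)
#' @export
brf_train <- function(features, K = 1000L, ntree = 500L,
                      mtry = floor(sqrt(13)), seed = 1L,
                      keep_draws = FALSE) {
  if (K < 1) abort("K must be >= 1")
  if (!"label" %in% names(features)) abort("features need a `label` column")
  missing <- setdiff(feature_names(), names(features))
  if (length(missing)) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  y <- factor(as.character(features$label), levels = c("O", "N"))
  if (anyNA(y)) abort("labels must be O or N")
  if (length(unique(y)) < 2) abort("both classes must be present for training")
  x <- as.data.frame(features[, feature_names()])

  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  n_min <- min(counts)
  idx_min <- which(y == minority)
  idx_maj <- which(y == majority)

  set.seed(seed)
  draws <- vector("list", K)
  counts <- matrix(0L, K, 2, dimnames = list(NULL, c("O", "N")))
  members <- purrr::map(seq_len(K), function(k) {
    take <- c(idx_min, sample(idx_maj, n_min, replace = FALSE))
    draws[[k]] <<- take
    counts[k, ] <<- c(sum(y[take] == "O"), sum(y[take] == "N"))
    randomForest::randomForest(x = x[take, , drop = FALSE],
                               y = droplevels(y[take]),
                               ntree = ntree, mtry = mtry)
  })
  out <- list(members = members, K = as.integer(K), ntree = as.integer(ntree),
              mtry = as.integer(mtry), feature_names = feature_names(),
              seed = as.integer(seed), class_order = c("O", "N"),
              n_train = length(y), n_balanced = 2L * n_min,
              member_class_counts = counts,
              draws = if (keep_draws) draws else NULL)
  class(out) <- "balanced_rf"
  out
}

#' @export
print.balanced_rf <- function(x, ...) {
  cat("Balanced random-forest ensemble\n")
  cat("  members:", x$K, " trees/member:", x$ntree, " mtry:", x$mtry, "\n")
  cat("  balanced training rows per member:", x$n_balanced,
      "(of", x$n_train, "total)\n")
  invisible(x)
}

#' Predict overlap labels with a balanced ensemble
#'
#' Each member forest casts one vote; the vote fraction is the share of
#' members voting overlap (`O`) and the label is `O` when the fraction
#' exceeds 0.5 (an exact tie goes to the conservative class `N`).
#'
#' @param object A `balanced_rf` model.
#' @param newdata Tibble with the 13 feature columns (identifier columns
#'   and a `label` column are carried through / used for the confusion
#'   matrix).
#' @param ... Unused.
#' @return `newdata`'s identifier columns plus `vote_fraction` and
#'   `pred_label`; when `newdata` has a `label` column the returned tibble
#'   carries a `confusion` attribute (named TP/FP/FN/TN counts).
#' @export
predict.balanced_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(newdata[, object$feature_names])
  # member vote from the raw tree-vote matrix: a member votes O when more
  # of its trees vote O than N (a tie goes to N), which keeps prediction
  # deterministic (randomForest's own label output breaks ties randomly)
  votes <- vapply(object$members, function(m) {
    v <- predict(m, x, type = "vote", norm_votes = FALSE)
    v[, "O"] > v[, "N"]
  }, logical(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  frac <- rowMeans(votes)
  out <- newdata[, setdiff(names(newdata), object$feature_names), drop = FALSE]
  out <- as_tibble(out)
  out$vote_fraction <- frac
  out$pred_label <- ifelse(frac > 0.5, "O", "N")
  if ("label" %in% names(newdata)) {
    attr(out, "confusion") <- confusion_counts(out$pred_label,
                                               as.character(newdata$label))
  }
  out
}

confusion_counts <- function(pred, truth) {
  c(TP = sum(pred == "O" & truth == "O"),
    FP = sum(pred == "O" & truth == "N"),
    FN = sum(pred == "N" & truth == "O"),
    TN = sum(pred == "N" & truth == "N"))
}

#' Evaluate overlap predictions against known labels
#'
#' @param prediction Tibble from [predict.balanced_rf()] (needs
#'   `pred_label`).
#' @param truth Tibble with `label` (and `res` when row order may differ),
#'   or a character vector aligned with `prediction`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`, `error_o`
#'   (fraction of true O predicted N), `error_n`, `n`.
#' @export
evaluate_overlap_prediction <- function(prediction, truth) {
  tl <- if (is.data.frame(truth)) {
    if (!is.null(truth$res) && !is.null(prediction$res)) {
      as.character(truth$label[match(prediction$res, truth$res)])
    } else as.character(truth$label)
  } else as.character(truth)
  if (length(tl) != nrow(prediction) || anyNA(tl)) {
    abort("truth labels do not cover the scored residues")
  }
  cc <- confusion_counts(prediction$pred_label, tl)
  tibble(tp = cc[["TP"]], fp = cc[["FP"]], fn = cc[["FN"]], tn = cc[["TN"]],
         accuracy = (cc[["TP"]] + cc[["TN"]]) / sum(cc),
         error_o = ifelse(cc[["TP"]] + cc[["FN"]] > 0,
                          cc[["FN"]] / (cc[["TP"]] + cc[["FN"]]), NA_real_),
         error_n = ifelse(cc[["TN"]] + cc[["FP"]] > 0,
                          cc[["FP"]] / (cc[["TN"]] + cc[["FP"]]), NA_real_),
         n = sum(cc))
}

#' Permutation feature importance
#'
#' Mean decrease in accuracy on a labelled evaluation set when one feature
#' column at a time is randomly shuffled.
#'
#' @param object A `balanced_rf` model.
#' @param features Labelled evaluation tibble (held out from training).
#' @param n_shuffles Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @return Tibble (`feature`, `importance`) sorted by decreasing
#'   importance; `importance` is accuracy(original) minus the mean shuffled
#'   accuracy.
#' @export
brf_importance <- function(object, features, n_shuffles = 5L, seed = 1L) {
  base <- evaluate_overlap_prediction(predict(object, features),
                                      as.character(features$label))$accuracy
  set.seed(seed)
  imp <- vapply(object$feature_names, function(f) {
    accs <- vapply(seq_len(n_shuffles), function(s) {
      shuf <- features
      shuf[[f]] <- sample(shuf[[f]])
      evaluate_overlap_prediction(predict(object, shuf),
                                  as.character(features$label))$accuracy
    }, numeric(1))
    base - mean(accs)
  }, numeric(1))
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' Report high-confidence small-molecule binding patches
#'
#' Filters size-n surface patches to those whose central residue is
#' predicted overlap and that contain at least `min_votes` predicted
#' overlap residues in total; the survivors are the predicted
#' small-molecule binding patches, sorted by their O ratio.
#'
#' @param prediction Tibble from [predict.balanced_rf()] with `res` and
#'   `pred_label` columns.
#' @param patches Patch tibble from [build_patches()] (size 7 in the
#'   standard protocol).
#' @param min_votes Minimum number of predicted-O members (default 5).
#' @param expected_size Patch size the vote threshold is calibrated for
#'   (default 7); patches of another size trigger a warning but are still
#'   evaluated against `min_votes`.
#' @return Patch tibble filtered and augmented with `n_overlap` and
#'   `ratio` (`#O / size`), sorted by decreasing ratio.
#' @export
predict_binding_patches <- function(prediction, patches, min_votes = 5L,
                                    expected_size = 7L) {
  lab <- setNames(prediction$pred_label, prediction$res)
  if (any(patches$size != expected_size)) {
    warn(paste0(sum(patches$size != expected_size), " patch(es) are not of ",
                "size ", expected_size, "; evaluated against min_votes anyway"))
  }
  n_o <- vapply(patches$members, function(m) {
    l <- lab[m]
    sum(!is.na(l) & l == "O")
  }, integer(1))
  covered <- vapply(patches$members, function(m) all(m %in% names(lab)),
                    logical(1))
  if (!all(covered)) {
    warn(paste0(sum(!covered),
                " patch(es) contain members without a prediction; ",
                "those members count as non-overlap"))
  }
  out <- patches |>
    mutate(n_overlap = n_o,
           ratio = n_o / .data$size,
           central_pred = unname(lab[.data$central])) |>
    filter(!is.na(.data$central_pred), .data$central_pred == "O",
           .data$n_overlap >= min_votes) |>
    arrange(dplyr::desc(.data$ratio)) |>
    select(-"central_pred")
  out
}

#' Patch precision by O-ratio bin
#'
#' For patches whose central residue is predicted overlap, bins them by the
#' fraction of predicted-O members (k/n) and reports, per bin, how often
#' the central residue is truly an overlap residue.  On real interfaces
#' this precision rises with the ratio, which is what makes patch voting
#' useful.
#'
#' @param prediction Prediction tibble (`res`, `pred_label`).
#' @param patches Patch tibble from [build_patches()].
#' @param truth Tibble (`res`, `label`) of true labels for the central
#'   residues.
#' @return Tibble (`ratio`, `n_patches`, `precision`).
#' @export
patch_precision_by_ratio <- function(prediction, patches, truth) {
  lab <- setNames(prediction$pred_label, prediction$res)
  tl <- setNames(as.character(truth$label), truth$res)
  df <- patches |>
    mutate(
      n_overlap = vapply(.data$members,
                         function(m) sum(lab[m] == "O", na.rm = TRUE),
                         integer(1)),
      ratio = .data$n_overlap / .data$size,
      central_pred = unname(lab[.data$central]),
      central_true = unname(tl[.data$central])) |>
    filter(.data$central_pred == "O", !is.na(.data$central_true))
  df |>
    group_by(.data$ratio) |>
    summarise(n_patches = n(),
              precision = mean(.data$central_true == "O"),
              .groups = "drop") |>
    arrange(.data$ratio)
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a balanced ensemble (out-of-ensemble view of its members)
#'
#' @param x A `balanced_rf` model.
#' @param ... Unused.
#' @return Tibble with one row per member: `member`, `ntree`, `oob_error`
#'   (the member forest's out-of-bag error on its balanced sample).
#' @export
tidy.balanced_rf <- function(x, ...) {
  tibble(member = seq_len(x$K),
         ntree = x$ntree,
         oob_error = vapply(x$members, function(m) {
           unname(m$err.rate[m$ntree, "OOB"])
         }, numeric(1)))
}

#' Glance at a balanced ensemble
#'
#' @param x A `balanced_rf` model.
#' @param ... Unused.
#' @return One-row tibble: `K`, `ntree`, `mtry`, `n_train`, `n_balanced`,
#'   `mean_oob_error`, `seed`.
#' @export
glance.balanced_rf <- function(x, ...) {
  tibble(K = x$K, ntree = x$ntree, mtry = x$mtry, n_train = x$n_train,
         n_balanced = x$n_balanced,
         mean_oob_error = mean(tidy(x)$oob_error), seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- serialization ---------------------------------------------------------

#' Save / load a balanced ensemble
#'
#' The archive is a single RDS file embedding the member forests, feature
#' names, `K`, seed and a format version.
#'
#' @param object A `balanced_rf` model.
#' @param path Archive path.
#' @return `path` (save) or the restored `balanced_rf` (load).
#' @export
brf_save <- function(object, path) {
  stopifnot(inherits(object, "balanced_rf"))
  object$format_version <- 1L
  saveRDS(object, path)
  invisible(path)
}

#' @rdname brf_save
#' @export
brf_load <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- readRDS(path)
  if (!inherits(obj, "balanced_rf")) abort("not a balanced_rf archive")
  obj
}
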