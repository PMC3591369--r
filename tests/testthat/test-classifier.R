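small_table <- function(seed = 1, n_o = 40, n_n = 160,
                        effects = effect_sizes()) {
  make_feature_table(seed = seed, n_overlap = n_o, n_nonoverlap = n_n,
                     effects = effects)
}

test_that("every ensemble member trains on exactly balanced classes", {
  ft <- small_table(seed = 2, n_o = 100, n_n = 400)
  fit <- brf_train(ft, K = 10, ntree = 30, seed = 4)
  expect_equal(fit$K, 10)
  expect_true(all(fit$member_class_counts[, "O"] == 100))
  expect_true(all(fit$member_class_counts[, "N"] == 100))
})

test_that("majority-class points are all used across many draws", {
  ft <- small_table(seed = 3, n_o = 12, n_n = 50)
  fit <- brf_train(ft, K = 200, ntree = 5, seed = 9, keep_draws = TRUE)
  maj <- which(ft$label == "N")
  used <- unique(unlist(fit$draws))
  # each draw takes 12 of 50 majority rows; P(any row never drawn in 200
  # draws) = 50 * (1 - 12/50)^200 ~ 1e-22
  expect_true(all(maj %in% used))
  # draws are without replacement within a draw
  expect_true(all(vapply(fit$draws, anyDuplicated, integer(1)) == 0))
})

test_that("training is deterministic given the seed", {
  ft <- small_table(seed = 5)
  te <- small_table(seed = 6)
  p1 <- predict(brf_train(ft, K = 5, ntree = 50, seed = 7), te)
  p2 <- predict(brf_train(ft, K = 5, ntree = 50, seed = 7), te)
  expect_identical(p1$vote_fraction, p2$vote_fraction)
  p3 <- predict(brf_train(ft, K = 5, ntree = 50, seed = 8), te)
  expect_false(identical(p1$vote_fraction, p3$vote_fraction))
})

test_that("perfectly separable features are learnt outright", {
  ft <- small_table(seed = 10)
  ft$density <- ifelse(ft$label == "O", 10, 0)  # one feature decides
  fit <- brf_train(ft, K = 3, ntree = 50, seed = 1)
  ev <- evaluate_overlap_prediction(predict(fit, ft), ft$label)
  expect_gte(ev$accuracy, 0.99)
})

test_that("training input is validated", {
  ft <- small_table(seed = 11)
  expect_error(brf_train(ft[ft$label == "N", ], K = 2), "both classes")
  expect_error(brf_train(ft, K = 0), "K")
  expect_error(brf_train(dplyr::select(ft, -"cons3"), K = 2), "cons3")
})

test_that("votes, labels and the confusion matrix are consistent", {
  ft <- small_table(seed = 12)
  te <- small_table(seed = 13)
  fit1 <- brf_train(ft, K = 1, ntree = 40, seed = 2)
  p1 <- predict(fit1, te)
  expect_true(all(p1$vote_fraction %in% c(0, 1)))  # K = 1
  fit <- brf_train(ft, K = 5, ntree = 40, seed = 2)
  p <- predict(fit, te)
  expect_true(all(p$vote_fraction >= 0 & p$vote_fraction <= 1))
  expect_equal(p$pred_label, ifelse(p$vote_fraction > 0.5, "O", "N"))
  cc <- attr(p, "confusion")
  expect_equal(sum(cc), nrow(te))
  ev <- evaluate_overlap_prediction(p, te$label)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, nrow(te))
  # oracle tabulation
  expect_equal(ev$tp, sum(p$pred_label == "O" & te$label == "O"))
  expect_error(predict(fit, dplyr::select(te, -"protru2")), "protru2")
})

test_that("evaluation handles the degenerate prediction patterns", {
  truth <- c(rep("O", 10), rep("N", 10))
  perfect <- tibble::tibble(pred_label = truth)
  ev <- evaluate_overlap_prediction(perfect, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$fp + ev$fn, 0)
  all_o <- tibble::tibble(pred_label = rep("O", 20))
  ev2 <- evaluate_overlap_prediction(all_o, truth)
  expect_equal(ev2$accuracy, 0.5)
})

test_that("permutation importance isolates informative features", {
  ft <- small_table(seed = 20, n_o = 120, n_n = 240,
                    effects = null_effect_sizes())
  # density alone decides the label; cons5 stays pure noise
  ft$density <- ifelse(ft$label == "O", 6, 1) + rnorm(nrow(ft), 0, 0.3)
  te <- ft[sample(nrow(ft)), ]
  fit <- brf_train(ft, K = 3, ntree = 60, seed = 3)
  imp <- brf_importance(fit, te, n_shuffles = 5, seed = 5)
  expect_equal(imp$feature[1], "density")
  expect_lt(abs(imp$importance[imp$feature == "cons5"]), 0.05)
  imp2 <- brf_importance(fit, te, n_shuffles = 5, seed = 5)
  expect_identical(imp, imp2)
})

test_that("binding patches require an O centre and enough O votes", {
  res <- paste0("A:", 1:9, ":")
  pred <- tibble::tibble(res = res,
                         pred_label = c(rep("O", 6), rep("N", 3)),
                         vote_fraction = c(rep(0.9, 6), rep(0.1, 3)))
  patches <- tibble::tibble(
    central = c("A:1:", "A:7:", "A:2:"),
    members = list(res[1:7], res[c(7, 1:6)], res[c(2, 5:9, 1)]),
    size = c(7L, 7L, 7L), complete = TRUE, degenerate = FALSE)
  out <- predict_binding_patches(pred, patches, min_votes = 5)
  # patch 1: central O, 6 O members -> in; patch 2: central N -> out;
  # patch 3: central O but 4 O -> out
  expect_equal(out$central, "A:1:")
  expect_equal(out$ratio, 6 / 7)
  # all-O patch comes first and a wrong-size patch warns but is evaluated
  patches$members[[2]] <- res[1:6]
  patches$size[2] <- 6L
  patches$central[2] <- "A:1:"
  expect_warning(out2 <- predict_binding_patches(pred, patches,
                                                 min_votes = 5), "size")
  expect_equal(out2$ratio[1], 1)  # 6/6 all-O patch sorted first
})

test_that("tidy and glance summarise the ensemble", {
  ft <- small_table(seed = 30)
  fit <- brf_train(ft, K = 4, ntree = 30, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(td$oob_error >= 0 & td$oob_error <= 1))
  gl <- glance(fit)
  expect_equal(gl$K, 4)
  expect_equal(gl$n_balanced, 2 * min(table(ft$label)))
})

test_that("model archives round-trip", {
  ft <- small_table(seed = 31)
  te <- small_table(seed = 32)
  fit <- brf_train(ft, K = 2, ntree = 30, seed = 6)
  path <- tempfile(fileext = ".rds")
  brf_save(fit, path)
  back <- brf_load(path)
  expect_identical(predict(back, te)$vote_fraction,
                   predict(fit, te)$vote_fraction)
  expect_error(brf_load(tempfile()), "no such file")
})
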