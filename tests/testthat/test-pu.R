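# smaller tables than the headline study conditions keep the unit tests
# fast; the full-scale properties live in the acceptance suite
small_table <- function(seed = 1, ...) {
  make_pu_table(n_pos_labeled = 60L, n_unlabeled = 340L, pi_u = 0.15,
                n_features = 6L, n_informative = 3L, effect_size = 2,
                seed = seed, ...)
}

test_that("the labeling frequency is recovered on separable data", {
  tab <- small_table(2)
  m <- fit_pu(tab, num_trees = 200L, seed = 9L)
  expect_gt(m$c_hat, 0)
  expect_lte(m$c_hat, 1)
  truth <- attr(tab, "pu_truth")
  # n = 400 leaves a visible shrinkage bias in g; tight recovery is
  # asserted at full scale in the acceptance suite
  expect_lt(abs(m$c_hat - truth$c_true), 0.2)
  expect_true(all(m$stage1$w >= 0 & m$stage1$w <= 1))
  # certain negatives get weight ~ 0
  far_neg <- which(tab$y == 0 & tab$f01 < -1 & tab$f02 < -1)
  expect_lt(mean(m$stage1$w[far_neg]), 0.1)
})

test_that("full labeling reduces the scheme to a supervised forest", {
  tab <- make_pu_table(n_pos_labeled = 80L, n_unlabeled = 320L, pi_u = 0,
                       n_features = 6L, n_informative = 3L,
                       effect_size = 2, seed = 5)
  m <- fit_pu(tab, num_trees = 200L, seed = 3L)
  pu_pred <- predict(m, tab)$.pred_positive
  sup <- ranger::ranger(
    x = as.data.frame(tab[, sprintf("f%02d", 1:6)]),
    y = factor(tab$y, levels = c(0L, 1L)), probability = TRUE,
    num.trees = 200L, min.node.size = 1L, seed = 3L, num.threads = 1L)
  sup_pred <- predict(sup, as.data.frame(
    tab[, sprintf("f%02d", 1:6)]))$predictions[, "1"] >= 0.5
  expect_gte(mean(pu_pred == sup_pred), 0.99)
})

test_that("training-set fall-out is tiny when all unlabeled are true negatives", {
  tab <- make_pu_table(n_pos_labeled = 80L, n_unlabeled = 320L, pi_u = 0,
                       n_features = 6L, n_informative = 3L,
                       effect_size = 3, seed = 8)
  m <- fit_pu(tab, num_trees = 200L, seed = 2L)
  pr <- predict(m, tab)
  expect_lte(100 * mean(pr$.pred_positive[tab$s == 0]), 2)
  expect_gt(median(pr$.prob_positive[tab$s == 1]), 0.9)
})

test_that("prediction is deterministic and name-aligned", {
  tab <- small_table(4)
  m <- fit_pu(tab, num_trees = 150L, seed = 7L)
  p1 <- predict(m, tab)
  # duplicated rows give identical probabilities
  dup <- dplyr::bind_rows(tab[5, ], tab[5, ])
  pd <- predict(m, dup)
  expect_equal(pd$.prob_positive[1], pd$.prob_positive[2])
  # shuffling feature columns changes nothing
  shuffled <- tab[, c(1:4, rev(5:10))]
  expect_equal(predict(m, shuffled), p1)
  expect_error(predict(m, tab[, 1:6]), "Missing feature")
})

test_that("degenerate inputs are rejected", {
  tab <- small_table(1)
  expect_error(fit_pu(tab[tab$s == 1, ]), "at least 2")
  const <- tab
  const[sprintf("f%02d", 1:6)] <- 0
  expect_error(fit_pu(const, num_trees = 50L, seed = 1L), "identical")
  na_tab <- tab
  na_tab$f01[3] <- NA
  expect_error(fit_pu(na_tab), "Missing values")
})

test_that("stratified folds preserve the class ratio exactly", {
  tab <- make_pu_table(n_pos_labeled = 100L, n_unlabeled = 900L, pi_u = 0.1,
                       n_features = 4L, seed = 6)
  cv <- pu_crossval(tab, k = 10L, num_trees = 60L, stage1_folds = 3L,
                    seed = 12L)
  expect_equal(cv$folds$n_pos, rep(10L, 10L))
  expect_equal(cv$folds$n_unlabeled, rep(90L, 10L))
  expect_true(all(cv$folds$recall >= 0 & cv$folds$recall <= 100))
  expect_true(all(cv$folds$fallout >= 0 & cv$folds$fallout <= 100))
  expect_error(pu_crossval(tab[c(which(tab$s == 1)[1:5],
                                 which(tab$s == 0)), ], k = 10L),
               "fewer than k")
})

test_that("cross-validation is reproducible and row-order invariant", {
  tab <- small_table(9)
  cv1 <- pu_crossval(tab, k = 5L, num_trees = 100L, seed = 21L)
  cv2 <- pu_crossval(tab, k = 5L, num_trees = 100L, seed = 21L)
  expect_equal(glance(cv1), glance(cv2))
  expect_equal(cv1$importance, cv2$importance)
  # permute the rows: fold assignment is keyed on segment_id
  perm <- withr::with_seed(1, sample(nrow(tab)))
  cv3 <- pu_crossval(tab[perm, ], k = 5L, num_trees = 100L, seed = 21L)
  expect_equal(glance(cv3), glance(cv1))
})

test_that("separable data yields high recall and fall-out near the hidden rate", {
  tab <- make_pu_table(n_pos_labeled = 60L, n_unlabeled = 340L, pi_u = 0.15,
                       n_features = 6L, n_informative = 3L, effect_size = 3,
                       seed = 14)
  cv <- pu_crossval(tab, k = 5L, num_trees = 200L, seed = 2L)
  expect_gte(cv$recall_mean, 90)
  expect_lt(abs(cv$fallout_mean / 100 - 0.15), 0.08)
})

test_that("impurity importances are normalized and concentrate on signal", {
  # single informative feature carries > half the importance
  tab <- make_pu_table(n_pos_labeled = 60L, n_unlabeled = 340L, pi_u = 0.15,
                       n_features = 6L, n_informative = 1L,
                       effect_size = 3, seed = 17)
  const_tab <- tab
  const_tab$f06 <- 0   # a constant feature cannot be split on
  m <- fit_pu(const_tab, num_trees = 200L, seed = 4L)
  imp <- feature_importances(m, n_groups = 5L)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-8)
  expect_gt(imp$importance[imp$feature == "f01"], 0.5)
  expect_lte(imp$importance[imp$feature == "f06"], 0.01)
  expect_true(all(imp$sd >= 0))
  expect_identical(tidy(m)$feature, imp$feature)
})

test_that("group importances form a percentage partition", {
  tab <- make_pu_table(n_pos_labeled = 60L, n_unlabeled = 240L, pi_u = 0.1,
                       n_features = 6L, n_informative = 2L,
                       effect_size = 4, seed = 19)
  cv <- pu_crossval(tab, k = 5L, num_trees = 100L, seed = 6L)
  groups <- list(signal = c("f01", "f02"),
                 noise = sprintf("f%02d", 3:6))
  gi <- group_importance(cv, groups)
  expect_equal(sum(gi$percent), 100, tolerance = 1e-6)
  expect_gte(gi$percent[gi$group == "signal"], 90)
  expect_equal(group_importance(cv, list(all = sprintf("f%02d", 1:6)))
               $percent, 100, tolerance = 1e-9)
  expect_error(group_importance(cv, list(a = "f01", b = c("f01", "f02"))),
               "more than one")
  expect_error(group_importance(cv, list(a = "f01")), "not assigned")
})
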