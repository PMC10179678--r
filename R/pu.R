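RESERVED_COLS <- c("segment_id", "label", "s", "y", "region", "source_id",
                   "chain", "ins", "first_res", "last_res", "n_AA", "fold")

sub_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 7919 + a * 104729 + b * 1299709) %% 2147483629)
}

pu_feature_cols <- function(data, feature_cols, label_col) {
  if (!is.null(feature_cols)) {
    miss <- setdiff(feature_cols, names(data))
    if (length(miss))
      abort(paste0("Feature column(s) not in data: ",
                   paste(miss, collapse = ", ")))
    return(feature_cols)
  }
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, c(RESERVED_COLS, label_col))
}

pu_labels <- function(data, label_col) {
  v <- data[[label_col]]
  if (is.null(v)) abort(paste0("Label column '", label_col, "' not found."))
  if (is.character(v) || is.factor(v)) {
    v <- as.character(v)
    if (!all(v %in% c("positive", "unlabeled")))
      abort("Character labels must be 'positive' or 'unlabeled'.")
    v <- as.integer(v == "positive")
  }
  if (!all(v %in% c(0, 1))) abort("Labels must be 0/1 (unlabeled/positive).")
  as.integer(v)
}

# stratified fold assignment keyed on a stable identifier so the result is
# invariant to row order of the input table
assign_folds <- function(ids, strata, k, seed) {
  fold <- integer(length(ids))
  groups <- sort(unique(strata))   # sorted: invariant to row order
  for (g in groups) {
    in_g <- which(strata == g)
    if (length(in_g) < k)
      abort(paste0("Stratum '", g, "' has ", length(in_g),
                   " members, fewer than k = ", k, " folds."))
    ord <- in_g[order(ids[in_g])]
    perm <- local_seed(sub_seed(seed, match(g, groups)),
                       sample(length(ord)))
    fold[ord[perm]] <- rep_len(seq_len(k), length(ord))
  }
  fold
}

# evaluate `code` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# min_node: stage 1 needs calibrated probabilities, so its leaves are
# regularized (ranger's probability-forest default of 10); stage 2 is a
# classifier, so its trees are grown out fully (leaf size 1).
ranger_fit <- function(x, y, weights = NULL, num_trees, mtry, seed,
                       min_node = 1L) {
  ranger::ranger(
    x = x, y = factor(y, levels = c(0L, 1L)),
    probability = TRUE, num.trees = num_trees,
    min.node.size = min_node,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(x)))),
    importance = "impurity", case.weights = weights,
    seed = seed, num.threads = 1L, verbose = FALSE
  )
}

ranger_prob <- function(fit, x) {
  predict(fit, data = x, num.threads = 1L,
          verbose = FALSE)$predictions[, "1"]
}

#' Fit a two-stage positive-unlabeled random-forest classifier
#'
#' Implements the Elkan-Noto scheme with two random forests. Stage 1 is a
#' probability forest trained to separate the labeled positives from the
#' unlabeled pool; its out-of-fold probabilities `g(x)` (internal stratified
#' cross-fitting, never in-sample, to avoid the forests' optimistic bias)
#' estimate `P(s = 1 | x)`. Averaging `g` over the labeled positives gives
#' the labeling-frequency estimate `c_hat = P(s = 1 | y = 1)`. Stage 2 is
#' trained on the positives (weight 1) plus each unlabeled example entered
#' twice: once as a positive with weight
#' `w(x) = ((1 - c_hat) / c_hat) * g(x) / (1 - g(x))` (clipped to `[0, 1]`)
#' and once as a negative with weight `1 - w(x)`. The fit is deterministic
#' given `seed`.
#'
#' @param data Data frame with one row per segment: a label column, a stable
#'   `segment_id` (recommended) and numeric feature columns. Use dplyr to
#'   restrict the table to a region scope (loop / non-loop / all) before
#'   fitting.
#' @param feature_cols Feature column names. Default: every numeric column
#'   that is not a reserved metadata column (`segment_id`, `label`, `s`,
#'   `y`, `region`, `chain`, `first_res`, `last_res`, `n_AA`, ...).
#' @param label_col Column holding 1/0 or `"positive"`/`"unlabeled"`.
#' @param num_trees,mtry Forest size and features per split (default 500
#'   trees, sqrt of the feature count).
#' @param stage1_folds Internal folds for the out-of-fold `g(x)`.
#' @param threshold Stage-2 probability threshold for class calls.
#' @param seed Integer seed driving all randomness.
#' @return A `pu_model` object.
#' @export
fit_pu <- function(data, feature_cols = NULL, label_col = "s",
                   num_trees = 500L, mtry = NULL, stage1_folds = 5L,
                   threshold = 0.5, seed = 1L) {
  data <- as_tibble(data)
  feats <- pu_feature_cols(data, feature_cols, label_col)
  if (!length(feats)) abort("No feature columns found.")
  s <- pu_labels(data, label_col)
  if (sum(s == 1L) < 2L || sum(s == 0L) < 2L)
    abort("Need at least 2 positive and 2 unlabeled examples.")
  x <- as.data.frame(data[, feats, drop = FALSE])
  if (anyNA(x)) abort("Missing values in the feature matrix.")
  if (all(vapply(x, function(col) stats::var(col) == 0, logical(1))))
    abort(paste0("All features are constant; stage-1 probabilities would ",
                 "be identical (degenerate classifier)."))
  ids <- if ("segment_id" %in% names(data)) data$segment_id else
    sprintf("row%08d", seq_len(nrow(data)))
  # train on id-sorted rows so the fit is invariant to input row order
  ord <- order(ids)
  x <- x[ord, , drop = FALSE]
  s <- s[ord]
  ids <- ids[ord]

  k1 <- min(stage1_folds, sum(s == 1L), sum(s == 0L))
  fold <- assign_folds(ids, s, k1, sub_seed(seed, 1L))
  g <- numeric(nrow(x))
  for (f in seq_len(k1)) {
    tr <- fold != f
    fit1 <- ranger_fit(x[tr, , drop = FALSE], s[tr], NULL,
                       num_trees, mtry, sub_seed(seed, 2L, f),
                       min_node = 10L)
    g[!tr] <- ranger_prob(fit1, x[!tr, , drop = FALSE])
  }
  if (sd(g) == 0)
    abort("Stage-1 probabilities are all identical; classifier is degenerate.")
  c_hat <- mean(g[s == 1L])
  if (c_hat <= 0) abort("Estimated labeling frequency is not positive.")

  gc <- pmin(pmax(g, 1e-6), 1 - 1e-6)
  w_pos <- pmin(pmax(((1 - c_hat) / c_hat) * gc / (1 - gc), 0), 1)
  unl <- which(s == 0L)
  pos <- which(s == 1L)
  x2 <- rbind(x[pos, , drop = FALSE], x[unl, , drop = FALSE],
              x[unl, , drop = FALSE])
  y2 <- c(rep(1L, length(pos)), rep(1L, length(unl)), rep(0L, length(unl)))
  w2 <- c(rep(1, length(pos)), w_pos[unl], 1 - w_pos[unl])
  stage2 <- ranger_fit(x2, y2, w2, num_trees, mtry, sub_seed(seed, 3L))

  structure(
    list(
      stage2 = stage2, c_hat = c_hat, feature_names = feats,
      threshold = threshold, seed = seed, num_trees = num_trees,
      mtry = mtry %||% max(1L, floor(sqrt(length(feats)))),
      stage1_folds = k1,
      stage1 = tibble(segment_id = ids, s = s, g = g,
                      w = ifelse(s == 1L, 1, w_pos)),
      train = list(x = x2, y = y2, w = w2)
    ),
    class = "pu_model"
  )
}

#' @export
print.pu_model <- function(x, ...) {
  cat("<pu_model> Elkan-Noto two-stage random forest\n")
  cat("  features:", length(x$feature_names),
      "| trees:", x$num_trees, "| mtry:", x$mtry, "\n")
  cat("  labeled positives:", sum(x$stage1$s == 1L),
      "| unlabeled:", sum(x$stage1$s == 0L), "\n")
  cat("  estimated labeling frequency c_hat:", round(x$c_hat, 4), "\n")
  invisible(x)
}

#' Predict positive-class probabilities from a PU model
#'
#' @param object A `pu_model`.
#' @param newdata Data frame containing (at least) the training feature
#'   columns; they are aligned by name, so column order is irrelevant.
#'   Missing features are an error that names them.
#' @param ... Unused.
#' @return Tibble with `.prob_positive` and logical `.pred_positive`
#'   (probability thresholded at the model's `threshold`).
#' @export
predict.pu_model <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    abort(paste0("Missing feature column(s): ", paste(miss, collapse = ", ")))
  x <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  p <- ranger_prob(object$stage2, x)
  tibble(.prob_positive = p, .pred_positive = p >= object$threshold)
}

#' @method glance pu_model
#' @export
glance.pu_model <- function(x, ...) {
  tibble(
    c_hat = x$c_hat, n_pos = sum(x$stage1$s == 1L),
    n_unlabeled = sum(x$stage1$s == 0L),
    n_features = length(x$feature_names),
    num_trees = x$num_trees, mtry = x$mtry, seed = x$seed
  )
}

#' @method tidy pu_model
#' @export
tidy.pu_model <- function(x, ...) {
  feature_importances(x, n_groups = 0L)
}

#' Impurity-based feature importances of the final forest
#'
#' Mean decrease in impurity per feature, normalized to sum to 1. The
#' between-tree spread is estimated by refitting `n_groups` independent
#' sub-forests of `num_trees / n_groups` trees on the same weighted
#' training expansion and taking the standard deviation of their
#' normalized importances (`n_groups = 0` skips this and reports `NA`).
#'
#' @param model A fitted `pu_model`.
#' @param n_groups Number of sub-forests for the spread estimate.
#' @return Tibble with `feature`, `importance` (sums to 1), `sd`.
#' @export
feature_importances <- function(model, n_groups = 10L) {
  stopifnot(inherits(model, "pu_model"))
  imp <- ranger::importance(model$stage2)
  imp <- imp / sum(imp)
  sds <- rep(NA_real_, length(imp))
  if (n_groups > 0L) {
    per_tree <- max(1L, model$num_trees %/% n_groups)
    reps <- vapply(seq_len(n_groups), function(gidx) {
      f <- ranger_fit(model$train$x, model$train$y, model$train$w,
                      per_tree, model$mtry, sub_seed(model$seed, 4L, gidx))
      v <- ranger::importance(f)
      v / sum(v)
    }, numeric(length(imp)))
    sds <- apply(reps, 1L, sd)
  }
  tibble(feature = names(imp), importance = unname(imp), sd = unname(sds))
}

#' Stratified k-fold cross-validation of the PU classifier
#'
#' Splits the table into k folds preserving the positive:unlabeled ratio
#' (fold assignment is keyed on `segment_id`, so it is invariant to row
#' order), fits the two-stage model on each training split and scores the
#' held-out fold. Recall is the percentage of held-out positives predicted
#' positive; fall-out is the percentage of held-out unlabeled examples
#' predicted positive -- under the positive-unlabeled regime the latter
#' bounds, rather than measures, the false-positive rate, and also
#' estimates the fraction of viable deletions hiding in the unlabeled pool.
#'
#' @inheritParams fit_pu
#' @param k Number of folds (5 or 10 in the reference protocol).
#' @param importance_sd Also estimate per-fold importance spreads? (Slower;
#'   the across-fold sd is always reported.)
#' @return A `pu_cv` object; see [tidy.pu_cv()] and [glance.pu_cv()].
#' @export
pu_crossval <- function(data, k = 10L, feature_cols = NULL, label_col = "s",
                        num_trees = 500L, mtry = NULL, stage1_folds = 5L,
                        threshold = 0.5, seed = 1L, importance_sd = FALSE) {
  data <- as_tibble(data)
  s <- pu_labels(data, label_col)
  ids <- if ("segment_id" %in% names(data)) data$segment_id else
    sprintf("row%08d", seq_len(nrow(data)))
  fold <- assign_folds(ids, s, k, sub_seed(seed, 10L))
  per_fold <- vector("list", k)
  imps <- vector("list", k)
  c_hats <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_pu(data[tr, , drop = FALSE], feature_cols = feature_cols,
                label_col = label_col, num_trees = num_trees, mtry = mtry,
                stage1_folds = stage1_folds, threshold = threshold,
                seed = sub_seed(seed, 11L, f))
    pr <- predict(m, data[!tr, , drop = FALSE])
    s_te <- s[!tr]
    per_fold[[f]] <- tibble(
      fold = f,
      n_pos = sum(s_te == 1L), n_unlabeled = sum(s_te == 0L),
      recall = 100 * mean(pr$.pred_positive[s_te == 1L]),
      fallout = 100 * mean(pr$.pred_positive[s_te == 0L])
    )
    fi <- feature_importances(m, n_groups = if (importance_sd) 10L else 0L)
    imps[[f]] <- fi$importance
    c_hats[f] <- m$c_hat
    names(imps)[f] <- f
    if (f == 1L) imp_features <- fi$feature
  }
  imp_mat <- do.call(cbind, imps)
  folds <- dplyr::bind_rows(per_fold)
  structure(
    list(
      folds = folds,
      recall_mean = mean(folds$recall), recall_sd = sd(folds$recall),
      fallout_mean = mean(folds$fallout), fallout_sd = sd(folds$fallout),
      c_hat_mean = mean(c_hats),
      importance = tibble(
        feature = imp_features,
        importance = rowMeans(imp_mat),
        sd = apply(imp_mat, 1L, sd)
      ),
      k = k, seed = seed,
      fold_assignment = tibble(segment_id = ids, s = s, fold = fold)
    ),
    class = "pu_cv"
  )
}

#' @export
print.pu_cv <- function(x, ...) {
  cat("<pu_cv> stratified ", x$k, "-fold cross-validation (seed ", x$seed,
      ")\n", sep = "")
  cat(sprintf("  recall:   %.1f +/- %.1f %%\n", x$recall_mean, x$recall_sd))
  cat(sprintf("  fall-out: %.1f +/- %.1f %%\n", x$fallout_mean, x$fallout_sd))
  cat(sprintf("  mean c_hat: %.3f\n", x$c_hat_mean))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `pu_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy pu_cv
#' @export
tidy.pu_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A `pu_cv` object.
#' @param ... Unused.
#' @return Tibble with recall / fall-out means and sds (percent).
#' @method glance pu_cv
#' @export
glance.pu_cv <- function(x, ...) {
  tibble(
    k = x$k, recall_mean = x$recall_mean, recall_sd = x$recall_sd,
    fallout_mean = x$fallout_mean, fallout_sd = x$fallout_sd,
    c_hat_mean = x$c_hat_mean, seed = x$seed
  )
}

#' Summed importance of named feature groups
#'
#' Collapses per-feature importances into percent contributions of disjoint
#' feature groups (e.g. dynamics-derived vs externally supplied features).
#' The groups must partition the feature set.
#'
#' @param importance A tibble with `feature` and `importance` columns (from
#'   [feature_importances()] or a `pu_cv` object's `importance` element).
#' @param groups Named list of character vectors of feature names.
#' @return Tibble with `group` and `percent` (sums to 100).
#' @export
group_importance <- function(importance, groups) {
  if (inherits(importance, "pu_cv")) importance <- importance$importance
  all_named <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_named))
    abort(paste0("Feature(s) assigned to more than one group: ",
                 paste(unique(all_named[duplicated(all_named)]),
                       collapse = ", ")))
  uncovered <- setdiff(importance$feature, all_named)
  if (length(uncovered))
    abort(paste0("Feature(s) not assigned to any group: ",
                 paste(uncovered, collapse = ", ")))
  pct <- vapply(groups, function(g)
    100 * sum(importance$importance[importance$feature %in% g]) /
      sum(importance$importance), numeric(1))
  tibble(group = names(groups), percent = unname(pct))
}
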