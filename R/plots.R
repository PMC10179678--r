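#' Plot per-residue dynamics profiles
#'
#' One panel per Z-scored track along the sequence, with hinge residues
#' marked; the standardized scale makes the six profiles comparable.
#'
#' @param object A `residue_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residue_profiles
#' @export
autoplot.residue_profiles <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("resno", paste0("z_", DYNAMICS_TRACKS))],
    cols = -"resno", names_to = "track", values_to = "zscore",
    names_prefix = "z_"
  )
  hinge <- as_tibble(object)[as_tibble(object)$is_hinge, "resno"]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resno, y = .data$zscore)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(data = hinge, ggplot2::aes(xintercept = .data$resno),
                        colour = "tomato", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~track, scales = "free_y") +
    ggplot2::labs(x = "residue", y = "Z-score",
                  title = "Intrinsic-dynamics profiles (hinges in red)")
}

#' Plot cross-validated recall and fall-out
#'
#' @param object A `pu_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pu_cv
#' @export
autoplot.pu_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("recall", "fallout"),
                              names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold),
                                     y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = "%",
                  title = sprintf("Stratified %d-fold cross-validation",
                                  object$k))
}

#' Plot feature importances
#'
#' @param importance Tibble from [feature_importances()] or a `pu_cv`
#'   object.
#' @param top_n Show only the `top_n` largest contributors.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 20L) {
  if (inherits(importance, "pu_cv")) importance <- importance$importance
  imp <- dplyr::slice_max(importance, .data$importance, n = top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = pmax(.data$importance - .data$sd, 0),
      xmax = .data$importance + .data$sd), height = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "mean decrease in impurity (normalized)", y = NULL)
}
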