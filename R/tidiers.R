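#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted scoring model into one row per feature weight
#'
#' @param x A `cc_model`.
#' @param ... Unused.
#' @return Tibble with `key`, `category`, `type`, `weight`, sorted by
#'   decreasing `abs(weight)`.
#' @export
tidy.cc_model <- function(x, ...) {
  types <- vapply(CC_CATEGORIES, `[[`, character(1), "type")
  out <- tibble(key = names(x$w),
                category = key_category(names(x$w)),
                weight = unname(x$w))
  out$type <- unname(types[out$category])
  dplyr::arrange(out[, c("key", "category", "type", "weight")],
                 dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.cc_model
#' @export
glance.cc_model <- function(x, ...) {
  tibble(n_features = length(x$w), C1 = x$C1, C2 = x$C2, epsilon = x$epsilon,
         E_cutoff = x$E_cutoff, intercept = x$intercept,
         objective = attr(x, "objective") %||% NA_real_,
         duality_gap = attr(x, "duality_gap") %||% NA_real_)
}

#' Tidy nested cross-validation results
#'
#' @param x A `cc_cv` from [nested_cv()].
#' @param ... Unused.
#' @return `tidy()`: the pooled held-out predictions, one row per record;
#'   `glance()`: a one-row summary with `r` and `auc`.
#' @export
tidy.cc_cv <- function(x, ...) x$predictions

#' @rdname tidy.cc_cv
#' @export
glance.cc_cv <- function(x, ...) {
  dplyr::mutate(x$metrics, outer_k = x$outer_k, inner_k = x$inner_k,
                binders_only = x$binders_only)
}

#' Tidy a design solution into one row per block
#'
#' @param x A `cc_design`.
#' @param ... Unused.
#' @export
tidy.cc_design <- function(x, ...) x$heptads

#' @rdname tidy.cc_design
#' @export
glance.cc_design <- function(x, ...) {
  tibble(status = x$status, S_target = x$S_target,
         min_gap = if (length(x$S_off) > 0) min(x$S_off) - x$S_target else NA_real_,
         n_off_targets = length(x$S_off), nodes = x$nodes)
}

#' Plot held-out predictions against measured affinities
#'
#' Binders are shown as points on the log10 K_d scale with the identity
#' line; censored non-binders are collapsed at the ceiling.
#'
#' @param object A `cc_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_cv <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_kd, y = .data$pred,
                                   colour = .data$is_binder)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "measured log10 K_d (nM)", y = "predicted score (log10 nM)",
      colour = "binder",
      title = sprintf("Nested CV: R = %.2f, AUC = %.2f",
                      object$metrics$r, object$metrics$auc)
    )
}

#' Plot a learning curve
#'
#' @param curve Tibble from [learning_curve()].
#' @return A ggplot of R and AUC against the training fraction.
#' @export
plot_learning_curve <- function(curve) {
  df <- tidyr::pivot_longer(curve, c("r", "auc"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of interactions used", y = "cross-validated value")
}

#' Plot a recursive-feature-elimination curve
#'
#' @param curve Tibble from [rfe()]`$curve`.
#' @return A ggplot of validation R against the retained feature count.
#' @export
plot_rfe_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_features, y = .data$r_val)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "features retained", y = "validation Pearson R (binders)")
}
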