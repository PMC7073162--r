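#' Tidy a prediction fit into a per-pair tibble
#'
#' @param x An `lda_fit` from [lda_predict()].
#' @param ... Unused.
#' @return Tibble with columns `lncrna`, `disease`, `score` and `known`
#'   (whether the pair is a known association), sorted by descending
#'   score with lexicographic tie-break.
#' @method tidy lda_fit
#' @export
tidy.lda_fit <- function(x, ...) {
  tidyr::expand_grid(lncrna = rownames(x$scores),
                     disease = colnames(x$scores)) |>
    dplyr::mutate(score = x$scores[cbind(.data$lncrna, .data$disease)],
                  known = x$ld[cbind(.data$lncrna, .data$disease)] != 0) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lncrna, .data$disease)
}

#' One-row summary of a prediction fit
#'
#' @inheritParams tidy.lda_fit
#' @return One-row tibble: dimensions, number of known associations and
#'   the model parameters.
#' @method glance lda_fit
#' @export
glance.lda_fit <- function(x, ...) {
  tibble(n_lncrna = nrow(x$scores), n_disease = ncol(x$scores),
         n_known = sum(x$ld), alpha = x$params$alpha,
         beta = x$params$beta, omega = x$params$omega,
         delta = x$params$delta)
}

#' Tidy a cross-validation result into the per-fold table
#'
#' @param x An `lda_cv` from [lda_loocv()].
#' @param ... Unused.
#' @return Tibble with one row per held-out association: ids, score,
#'   midrank among candidates, candidate count and per-fold AUC.
#' @method tidy lda_cv
#' @export
tidy.lda_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.lda_cv
#' @return One-row tibble: protocol, fold count, both AUC estimators and
#'   which one `auc` reports.
#' @method glance lda_cv
#' @export
glance.lda_cv <- function(x, ...) {
  tibble(protocol = x$protocol, n_folds = nrow(x$folds),
         auc = x$auc, auc_per_fold = x$auc_per_fold,
         auc_pooled = x$auc_pooled, estimator = x$estimator)
}

#' Heatmap of prediction scores
#'
#' @param object An `lda_fit`.
#' @param ... Unused.
#' @return A ggplot: disease-by-lncRNA score heatmap with known
#'   associations outlined.
#' @method autoplot lda_fit
#' @export
autoplot.lda_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$lncrna)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$known),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "disease", y = "lncRNA", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' ROC curve of a cross-validation result
#'
#' @param object An `lda_cv`.
#' @param ... Unused.
#' @return A ggplot of the pooled ROC curve, annotated with both AUC
#'   estimators.
#' @method autoplot lda_cv
#' @export
autoplot.lda_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s LOOCV", object$protocol),
      subtitle = sprintf("AUC: %.4f (per-fold), %.4f (pooled)",
                         object$auc_per_fold, object$auc_pooled)) +
    ggplot2::theme_minimal()
}
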