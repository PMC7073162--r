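#' Area under the ROC curve from score vectors
#'
#' Rank-sum (Mann-Whitney) estimator of the AUC: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, with
#' ties counted half. Equivalent to a threshold sweep over the pooled
#' score set with trapezoidal integration.
#'
#' @param positive,negative Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(positive, negative) {
  if (length(positive) == 0L || length(negative) == 0L) {
    abort("`positive` and `negative` must be non-empty.")
  }
  r <- rank(c(positive, negative))
  np <- length(positive)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(negative))
}

#' ROC points from score vectors
#'
#' Threshold sweep over the pooled scores: tied scores are grouped so the
#' curve cuts diagonally through ties and its trapezoidal area equals the
#' rank-sum AUC of [auc_from_scores()].
#'
#' @inheritParams auc_from_scores
#' @return Tibble with columns `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing.
#' @export
roc_points <- function(positive, negative) {
  if (length(positive) == 0L || length(negative) == 0L) {
    abort("`positive` and `negative` must be non-empty.")
  }
  scores <- c(positive, negative)
  is_pos <- rep(c(1, 0), c(length(positive), length(negative)))
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[o])
  fp <- cumsum(1 - is_pos[o])
  # one point per distinct threshold: keep the last index of each tie group
  last <- which(diff(scores[o]) != 0)
  keep <- c(last, length(scores))
  tibble(fpr = c(0, fp[keep] / length(negative)),
         tpr = c(0, tp[keep] / length(positive)))
}

# Trapezoidal area under a (fpr, tpr) polyline.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# Default scorer: full re-prediction from a (possibly masked) Boolean
# matrix. `frozen` optionally carries integrated similarities computed
# once from the full matrix, skipping per-fold recomputation.
default_scorer <- function(ld, dd, params, frozen = NULL) {
  if (is.null(frozen)) {
    lda_predict(ld, dd, params = params)$scores
  } else {
    score_stages(ld, frozen$dd_is, frozen$ll_is, params)
  }
}

# Weighted networks + projections + combination on given integrated
# similarities.
score_stages <- function(ld, dd_is, ll_is, params) {
  w_d <- disease_weighted_network(ld, dd_is, params$alpha)
  w_l <- lncrna_weighted_network(ld, ll_is, params$beta)
  combine_scores(project_disease_space(w_l, dd_is),
                 project_lncrna_space(w_d, ll_is),
                 params$omega)
}

#' Leave-one-out cross-validation of association predictions
#'
#' Evaluates the scoring pipeline with three leave-one-out protocols:
#'
#' * `"associations"`: each known association is masked in turn (its
#'   matrix entry set to 0), all association-derived quantities are
#'   recomputed, and the held-out pair is ranked against every pair that
#'   is 0 in the full matrix (the candidate negatives).
#' * `"new_lncrna"`: each lncRNA with at least one association has its
#'   entire row zeroed (simulating a newly discovered lncRNA); each of
#'   its removed associations is ranked against the zero-pairs of that
#'   same row.
#' * `"isolated_disease"`: the column-wise analogue, zeroing one
#'   disease's column at a time.
#'
#' The default AUC estimator averages the per-fold normalized rank of the
#' held-out positive (insensitive to score-scale drift between folds,
#' since the Gaussian kernels are recomputed on each masked matrix);
#' `pooled = TRUE` instead pools all positive and candidate scores into a
#' single rank-sum AUC. Both are reported in `glance()`, together with a
#' pooled ROC curve whose trapezoidal area equals the pooled AUC.
#'
#' @inheritParams lda_predict
#' @param protocol One of `"associations"`, `"new_lncrna"`,
#'   `"isolated_disease"`.
#' @param pooled Report the pooled estimator as `auc`? Default `FALSE`
#'   (per-fold estimator).
#' @param frozen_similarity Compute functional and Gaussian-kernel
#'   similarities once from the full matrix instead of per fold? Default
#'   `FALSE`; freezing is faster but lets the held-out signal linger in
#'   the similarity layers.
#' @param scorer Scoring function `function(ld, dd, params, frozen)`
#'   returning a score matrix; the default runs the package pipeline.
#'   Replaceable for instrumentation and testing.
#' @return An object of class `lda_cv` with elements `protocol`, `folds`
#'   (per held-out pair: ids, score, midrank among candidates, number of
#'   candidates, per-fold AUC), `roc` (pooled ROC points), `auc`
#'   (selected estimator), `auc_per_fold`, `auc_pooled`, `estimator` and
#'   `params`.
#' @examples
#' sim <- simulate_lda(nl = 10, nd = 12, seed = 1)
#' dd <- disease_semantic_similarity(sim$dag, sim$disease_ids)
#' cv <- lda_loocv(sim$associations, dd,
#'                 lncrna_ids = sim$lncrna_ids,
#'                 disease_ids = sim$disease_ids)
#' glance(cv)
#' @export
lda_loocv <- function(associations, dd,
                      protocol = c("associations", "new_lncrna",
                                   "isolated_disease"),
                      params = lda_params(), pooled = FALSE,
                      frozen_similarity = FALSE,
                      lncrna_ids = NULL, disease_ids = NULL,
                      scorer = default_scorer) {
  protocol <- match.arg(protocol)
  ld <- if (is.matrix(associations)) associations else
    association_matrix(associations, lncrna_ids, disease_ids)
  if (sum(ld) < 2) abort("Need at least 2 known associations for LOOCV.")
  dd <- expand_similarity(dd, colnames(ld))
  frozen <- NULL
  if (frozen_similarity) {
    fit0 <- lda_predict(ld, dd, params = params)
    frozen <- list(dd_is = fit0$dd_is, ll_is = fit0$ll_is)
  }
  run <- switch(protocol,
    associations     = loocv_pairs(ld, dd, params, scorer, frozen),
    new_lncrna       = loocv_entity(ld, dd, params, scorer, frozen,
                                    margin = 1L),
    isolated_disease = loocv_entity(ld, dd, params, scorer, frozen,
                                    margin = 2L))
  roc <- roc_points(run$pos_scores, run$neg_scores)
  auc_pooled <- auc_from_scores(run$pos_scores, run$neg_scores)
  auc_per_fold <- mean(run$folds$fold_auc)
  structure(
    list(protocol = protocol, folds = run$folds, roc = roc,
         auc = if (pooled) auc_pooled else auc_per_fold,
         auc_per_fold = auc_per_fold, auc_pooled = auc_pooled,
         estimator = if (pooled) "pooled" else "per_fold",
         params = params),
    class = "lda_cv")
}

# Standard protocol: mask one 1-entry at a time; candidates are the
# 0-entries of the FULL matrix (never pairs held out in other folds).
loocv_pairs <- function(ld, dd, params, scorer, frozen) {
  ones <- which(ld == 1, arr.ind = TRUE)
  zeros <- ld == 0
  n_cand <- sum(zeros)
  folds <- vector("list", nrow(ones))
  neg_scores <- vector("list", nrow(ones))
  for (f in seq_len(nrow(ones))) {
    i <- ones[f, 1L]; j <- ones[f, 2L]
    masked <- ld
    masked[i, j] <- 0
    s <- scorer(masked, dd, params, frozen)
    pos <- s[i, j]
    neg <- s[zeros]
    folds[[f]] <- fold_record(rownames(ld)[i], colnames(ld)[j], pos, neg)
    neg_scores[[f]] <- neg
  }
  folds <- dplyr::bind_rows(folds)
  list(folds = folds, pos_scores = folds$score,
       neg_scores = unlist(neg_scores, use.names = FALSE))
}

# Entity protocols: zero a full row (margin 1, new lncRNA) or column
# (margin 2, isolated disease); each removed association is ranked
# locally against the zero-pairs of its own row/column in the full
# matrix.
loocv_entity <- function(ld, dd, params, scorer, frozen, margin) {
  n_ent <- dim(ld)[margin]
  folds <- list()
  neg_scores <- list()
  for (e in seq_len(n_ent)) {
    line <- if (margin == 1L) ld[e, ] else ld[, e]
    pos_idx <- which(line == 1)
    if (length(pos_idx) == 0L) next
    neg_idx <- which(line == 0)
    if (length(neg_idx) == 0L) next
    masked <- ld
    if (margin == 1L) masked[e, ] <- 0 else masked[, e] <- 0
    s <- scorer(masked, dd, params, frozen)
    s_line <- if (margin == 1L) s[e, ] else s[, e]
    neg <- s_line[neg_idx]
    for (j in pos_idx) {
      lnc <- if (margin == 1L) rownames(ld)[e] else rownames(ld)[j]
      dis <- if (margin == 1L) colnames(ld)[j] else colnames(ld)[e]
      folds[[length(folds) + 1L]] <- fold_record(lnc, dis, s_line[j], neg)
    }
    neg_scores[[length(neg_scores) + 1L]] <- neg
  }
  if (length(folds) == 0L) {
    abort("Protocol has no evaluable fold (no entity with both known and candidate pairs).")
  }
  folds <- dplyr::bind_rows(folds)
  list(folds = folds, pos_scores = folds$score,
       neg_scores = unlist(neg_scores, use.names = FALSE))
}

fold_record <- function(lncrna, disease, score, neg) {
  below <- sum(neg < score)
  ties <- sum(neg == score)
  tibble(
    lncrna = lncrna, disease = disease, score = score,
    rank = 1 + sum(neg > score) + 0.5 * ties,
    candidates = length(neg),
    fold_auc = (below + 0.5 * ties) / length(neg))
}

#' Parameter sweep over leave-one-out AUC
#'
#' Runs [lda_loocv()] for every row of a parameter grid and returns the
#' grid augmented with the resulting AUC, mirroring the grid search used
#' to pick the default `alpha`, `beta` and `omega`.
#'
#' @inheritParams lda_loocv
#' @param grid Data frame whose columns are a subset of the [lda_params()]
#'   arguments; unspecified parameters keep their defaults.
#' @return The grid as a tibble with an added `auc` column.
#' @export
lda_sweep <- function(associations, dd, grid,
                      protocol = "associations", pooled = FALSE,
                      frozen_similarity = FALSE,
                      lncrna_ids = NULL, disease_ids = NULL) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0L) abort("`grid` must have at least one row.")
  bad <- setdiff(names(grid), names(formals(lda_params)))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown parameter column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  grid$auc <- purrr::pmap_dbl(grid, function(...) {
    p <- do.call(lda_params, list(...))
    lda_loocv(associations, dd, protocol = protocol, params = p,
              pooled = pooled, frozen_similarity = frozen_similarity,
              lncrna_ids = lncrna_ids, disease_ids = disease_ids)$auc
  })
  grid
}

#' @export
print.lda_cv <- function(x, ...) {
  cat(sprintf("<lda_cv> protocol: %s | %d folds | AUC (%s) = %.4f\n",
              x$protocol, nrow(x$folds), x$estimator, x$auc))
  invisible(x)
}
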