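#' Model parameters
#'
#' Bundles the tunable parameters of the projection model. `alpha` and
#' `beta` weight the similarity-smoothing terms of the two weighted
#' networks, `omega` weights the lncRNA-space projection against the
#' disease-space projection in the final score, `delta` is the semantic
#' decay factor, and `gamma_prime_l` / `gamma_prime_d` are the raw GIP
#' bandwidths for lncRNAs and diseases. Defaults are the values at which
#' leave-one-out AUC peaks on the reference association catalogue.
#'
#' @param alpha,beta Smoothing weights in \[0, 1\]. Default 0.1.
#' @param omega Projection mixing weight in \[0, 1\]. Default 0.8.
#' @param delta Semantic decay factor in \[0, 1\]. Default 0.5.
#' @param gamma_prime_l,gamma_prime_d Raw GIP bandwidths, positive.
#'   Default 1.
#' @return A list of class `lda_params`.
#' @export
lda_params <- function(alpha = 0.1, beta = 0.1, omega = 0.8, delta = 0.5,
                       gamma_prime_l = 1, gamma_prime_d = 1) {
  check_scalar_prob(alpha, "alpha")
  check_scalar_prob(beta, "beta")
  check_scalar_prob(omega, "omega")
  check_scalar_prob(delta, "delta")
  if (gamma_prime_l <= 0 || gamma_prime_d <= 0) {
    abort("`gamma_prime_l` and `gamma_prime_d` must be positive.")
  }
  structure(list(alpha = alpha, beta = beta, omega = omega, delta = delta,
                 gamma_prime_l = gamma_prime_l,
                 gamma_prime_d = gamma_prime_d),
            class = "lda_params")
}

#' Disease-similarity weighted association network
#'
#' Smooths the Boolean association matrix with disease similarities:
#' each entry gains `alpha` times the average disease similarity between
#' disease j and the diseases the lncRNA is already associated with
#' (the diagonal self-similarity term is excluded). Rows with no known
#' association are left untouched (the smoothing term is 0), which keeps
#' the new-lncRNA protocol well defined.
#'
#' @param ld Boolean association matrix (lncRNA rows, disease columns).
#' @param dd_is Integrated disease similarity matrix, labels matching the
#'   columns of `ld`.
#' @param alpha Smoothing weight in \[0, 1\].
#' @return Weighted network matrix, same shape and labels as `ld`.
#' @export
disease_weighted_network <- function(ld, dd_is, alpha) {
  check_scalar_prob(alpha, "alpha")
  if (!identical(colnames(ld), rownames(dd_is))) {
    abort("Disease labels of `ld` and `dd_is` do not match.")
  }
  rs <- rowSums(ld)
  # sum_{k != j} dd[k, j] * ld[i, k] = (LD %*% DD)[i, j] - ld[i, j] * dd[j, j]
  num <- ld %*% dd_is - ld * rep(diag(dd_is), each = nrow(ld))
  scale <- ifelse(rs > 0, 1 / rs, 0)
  ld + alpha * num * scale
}

#' LncRNA-similarity weighted association network
#'
#' Column-wise analogue of [disease_weighted_network()]: each entry gains
#' `beta` times the average lncRNA similarity between lncRNA l and the
#' lncRNAs already associated with disease d, normalized by the number of
#' known associations of that disease. Columns with no association are
#' left untouched (isolated-disease guard).
#'
#' @inheritParams disease_weighted_network
#' @param ll_is Integrated lncRNA similarity matrix, labels matching the
#'   rows of `ld`.
#' @param beta Smoothing weight in \[0, 1\].
#' @return Weighted network matrix, same shape and labels as `ld`.
#' @export
lncrna_weighted_network <- function(ld, ll_is, beta) {
  check_scalar_prob(beta, "beta")
  if (!identical(rownames(ld), rownames(ll_is))) {
    abort("LncRNA labels of `ld` and `ll_is` do not match.")
  }
  cs <- colSums(ld)
  num <- ll_is %*% ld - ld * rep(diag(ll_is), times = ncol(ld))
  scale <- ifelse(cs > 0, 1 / cs, 0)
  ld + beta * sweep(num, 2L, scale, `*`)
}

#' Space projection scores through the disease similarity space
#'
#' Projects each disease's integrated-similarity column onto each
#' lncRNA's weighted association profile: the score for pair (l, d) is
#' the scalar projection of the similarity vector of d onto the row of l
#' in the lncRNA-similarity weighted network (dot product over the row's
#' Euclidean norm). A zero-norm row yields score 0.
#'
#' @param w_l LncRNA-similarity weighted network
#'   (see [lncrna_weighted_network()]).
#' @param dd_is Integrated disease similarity matrix.
#' @return Score matrix, lncRNA rows and disease columns.
#' @export
project_disease_space <- function(w_l, dd_is) {
  if (!identical(colnames(w_l), rownames(dd_is))) {
    abort("Disease labels of `w_l` and `dd_is` do not match.")
  }
  norms <- sqrt(rowSums(w_l^2))
  inv <- ifelse(norms > 0, 1 / norms, 0)
  (w_l %*% dd_is) * inv
}

#' Space projection scores through the lncRNA similarity space
#'
#' Mirror of [project_disease_space()]: the score for pair (l, d) is the
#' scalar projection of the integrated-similarity row of l onto the
#' column of d in the disease-similarity weighted network. A zero-norm
#' column yields score 0.
#'
#' @param w_d Disease-similarity weighted network
#'   (see [disease_weighted_network()]).
#' @param ll_is Integrated lncRNA similarity matrix.
#' @return Score matrix, lncRNA rows and disease columns.
#' @export
project_lncrna_space <- function(w_d, ll_is) {
  if (!identical(rownames(w_d), rownames(ll_is))) {
    abort("LncRNA labels of `w_d` and `ll_is` do not match.")
  }
  norms <- sqrt(colSums(w_d^2))
  inv <- ifelse(norms > 0, 1 / norms, 0)
  sweep(ll_is %*% w_d, 2L, inv, `*`)
}

#' Combine the two projection scores
#'
#' Convex combination of the disease-space and lncRNA-space projection
#' scores: `(1 - omega) * p_d + omega * p_l`. Larger `omega` gives the
#' lncRNA-space projection more weight.
#'
#' @param p_d,p_l Score matrices with identical labels.
#' @param omega Mixing weight in \[0, 1\].
#' @return Combined score matrix.
#' @export
combine_scores <- function(p_d, p_l, omega) {
  check_scalar_prob(omega, "omega")
  if (!identical(dim(p_d), dim(p_l)) ||
      !identical(dimnames(p_d), dimnames(p_l))) {
    abort("`p_d` and `p_l` must have identical shape and labels.")
  }
  (1 - omega) * p_d + omega * p_l
}

#' Predict lncRNA-disease association scores
#'
#' Runs the full scoring pipeline on an association table: lncRNA
#' functional similarity (unless supplied), Gaussian interaction profile
#' kernels on the current association matrix, integration of the primary
#' similarities with the kernels, similarity-weighted network
#' reconstruction, the two space projections, and their convex
#' combination. The function is deterministic: identical inputs give
#' identical scores.
#'
#' @param associations Tibble with columns `lncrna`, `disease`
#'   (see [read_associations()]), or a Boolean association matrix.
#' @param dd Disease similarity matrix (semantic similarity from
#'   [disease_semantic_similarity()] or a precomputed matrix). Must cover
#'   all diseases; diseases missing from its labels are added with zero
#'   off-diagonal similarity.
#' @param ll Optional precomputed lncRNA functional similarity matrix;
#'   computed from `associations` and `dd` when `NULL`.
#' @param params Model parameters from [lda_params()].
#' @param lncrna_ids,disease_ids Optional id universes passed to
#'   [association_matrix()] when `associations` is a tibble.
#' @return An object of class `lda_fit`: a list with the final `scores`
#'   matrix, the Boolean matrix `ld`, all intermediate matrices
#'   (`ll`, `gl`, `gd`, `dd_is`, `ll_is`, `w_d`, `w_l`, `p_d`, `p_l`) and
#'   the `params`. Use [tidy.lda_fit()] for a per-pair tibble.
#' @examples
#' toy <- worked_toy()
#' fit <- lda_predict(toy$associations, dd = toy$dd)
#' tidy(fit)
#' @export
lda_predict <- function(associations, dd, ll = NULL, params = lda_params(),
                        lncrna_ids = NULL, disease_ids = NULL) {
  ld <- if (is.matrix(associations)) associations else
    association_matrix(associations, lncrna_ids, disease_ids)
  dd <- expand_similarity(dd, colnames(ld))
  if (is.null(ll)) {
    ll <- lncrna_functional_similarity(ld, dd)
  } else {
    ll <- expand_similarity(ll, rownames(ld))
  }
  gl <- gip_similarity(ld, gip_bandwidth(ld, params$gamma_prime_l))
  gd <- gip_similarity(t(ld), gip_bandwidth(t(ld), params$gamma_prime_d))
  dd_is <- integrate_similarity(dd[colnames(ld), colnames(ld)], gd)
  ll_is <- integrate_similarity(ll[rownames(ld), rownames(ld)], gl)
  w_d <- disease_weighted_network(ld, dd_is, params$alpha)
  w_l <- lncrna_weighted_network(ld, ll_is, params$beta)
  p_d <- project_disease_space(w_l, dd_is)
  p_l <- project_lncrna_space(w_d, ll_is)
  scores <- combine_scores(p_d, p_l, params$omega)
  structure(
    list(scores = scores, ld = ld, dd = dd, ll = ll, gl = gl, gd = gd,
         dd_is = dd_is, ll_is = ll_is, w_d = w_d, w_l = w_l,
         p_d = p_d, p_l = p_l, params = params),
    class = "lda_fit")
}

# Pad a similarity matrix to cover `ids`: missing ids get 0 off-diagonal
# similarity and 1 on the diagonal, so the GIP kernel substitutes for
# them at integration time.
expand_similarity <- function(sim, ids) {
  missing <- setdiff(ids, rownames(sim))
  if (length(missing) == 0L) return(sim)
  all_ids <- c(rownames(sim), missing)
  out <- matrix(0, length(all_ids), length(all_ids),
                dimnames = list(all_ids, all_ids))
  out[rownames(sim), colnames(sim)] <- sim
  diag(out) <- 1
  out
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf(
    "<lda_fit> %d lncRNAs x %d diseases, %d known associations\n",
    nrow(x$scores), ncol(x$scores), sum(x$ld)))
  cat(sprintf("params: alpha=%g beta=%g omega=%g delta=%g\n",
              x$params$alpha, x$params$beta, x$params$omega,
              x$params$delta))
  invisible(x)
}
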