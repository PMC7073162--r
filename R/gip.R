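#' Gaussian interaction profile kernel bandwidth
#'
#' Scales a raw bandwidth parameter by the mean squared Euclidean norm of
#' the interaction profiles, so the kernel adapts to the overall density
#' of known associations. If every profile is the zero vector the raw
#' bandwidth is returned unchanged with a warning (degenerate kernel on
#' pathological input).
#'
#' @param profiles Numeric matrix whose rows are interaction profiles
#'   (rows of the association matrix for lncRNAs, columns for diseases).
#' @param gamma_prime Raw bandwidth, positive. Default 1.
#' @return The effective bandwidth, a positive number.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  if (is.null(dim(profiles)) || nrow(profiles) == 0L) {
    abort("`profiles` must be a non-empty matrix of profiles (one per row).")
  }
  if (gamma_prime <= 0) abort("`gamma_prime` must be positive.")
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) {
    warn("All interaction profiles are zero; returning gamma = gamma_prime.")
    return(gamma_prime)
  }
  gamma_prime / mean_sq
}

#' Gaussian interaction profile kernel similarity
#'
#' Radial-basis similarity between interaction profiles:
#' `exp(-gamma * ||p_i - p_j||^2)`. Identical profiles score 1 and the
#' similarity decays with squared Euclidean distance.
#'
#' @inheritParams gip_bandwidth
#' @param gamma Effective bandwidth, positive (see [gip_bandwidth()]).
#' @return Labeled symmetric similarity matrix with unit diagonal,
#'   entries in (0, 1\].
#' @export
gip_similarity <- function(profiles, gamma) {
  if (gamma <= 0) abort("`gamma` must be positive.")
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical floor
  g <- exp(-gamma * d2)
  diag(g) <- 1
  g <- (g + t(g)) / 2
  dimnames(g) <- list(rownames(profiles), rownames(profiles))
  g
}

#' Integrate a primary similarity with the GIP kernel
#'
#' Fills in the zeros of a semantic or functional similarity matrix with
#' the Gaussian interaction profile kernel: where the primary similarity
#' is nonzero it is kept, where it is zero the GIP value substitutes.
#'
#' @param primary Labeled similarity matrix (semantic or functional).
#' @param gip GIP similarity matrix with identical labels.
#' @return Integrated similarity matrix, same labels.
#' @export
integrate_similarity <- function(primary, gip) {
  if (!identical(dimnames(primary), dimnames(gip))) {
    abort("`primary` and `gip` must have identical labels.")
  }
  out <- ifelse(primary != 0, primary, gip)
  diag(out) <- 1
  dimnames(out) <- dimnames(primary)
  out
}
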