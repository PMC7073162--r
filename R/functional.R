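#' Best-match similarity of a disease to a disease set
#'
#' The similarity between one disease and a set of diseases is the best
#' (maximum) pairwise similarity between the disease and any member of
#' the set.
#'
#' @param id Disease id (row of `dd`).
#' @param set Non-empty character vector of disease ids (columns of `dd`).
#' @param dd Labeled disease similarity matrix.
#' @return A single number in \[0, 1\].
#' @export
set_similarity <- function(id, set, dd) {
  if (length(set) == 0L) abort("`set` must be non-empty.")
  missing <- setdiff(c(id, set), rownames(dd))
  if (length(missing) > 0L) {
    abort(sprintf("Disease id(s) not in similarity matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  max(dd[id, set])
}

#' LncRNA functional similarity matrix
#'
#' Functional similarity of two lncRNAs measured through the diseases
#' they are associated with: each disease of one lncRNA is matched to its
#' most similar disease of the other lncRNA (in both directions), and the
#' best-match similarities are averaged over all m + n diseases. An
#' lncRNA with no known diseases has functional similarity 0 to every
#' other lncRNA (diagonal stays 1); the Gaussian interaction profile
#' kernel fills in for such lncRNAs during integration.
#'
#' @param ld Boolean association matrix (lncRNA rows, disease columns),
#'   e.g. from [association_matrix()].
#' @param dd Labeled disease similarity matrix covering the columns of
#'   `ld`.
#' @return Labeled symmetric lncRNA similarity matrix with unit diagonal.
#' @export
lncrna_functional_similarity <- function(ld, dd) {
  if (!all(colnames(ld) %in% rownames(dd))) {
    abort("Disease similarity matrix does not cover all diseases in `ld`.")
  }
  nl <- nrow(ld)
  ids <- rownames(ld)
  disease_sets <- lapply(seq_len(nl), function(i) colnames(ld)[ld[i, ] != 0])
  ll <- matrix(0, nl, nl, dimnames = list(ids, ids))
  diag(ll) <- 1
  if (nl < 2L) return(ll)
  for (i in seq_len(nl - 1L)) {
    di <- disease_sets[[i]]
    for (j in seq(i + 1L, nl)) {
      dj <- disease_sets[[j]]
      if (length(di) == 0L || length(dj) == 0L) next
      sub <- dd[di, dj, drop = FALSE]
      ll[i, j] <- ll[j, i] <-
        (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(di) + length(dj))
    }
  }
  ll
}
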