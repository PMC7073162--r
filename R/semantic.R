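#' Semantic contribution profile of a disease term
#'
#' Computes, for one disease, the contribution of every node in its
#' ancestor DAG. The disease itself contributes 1; every other node `t`
#' in the closure contributes `delta` times the largest contribution
#' among t's children that lie inside the closure, so contributions decay
#' geometrically with distance from the disease term. The semantic score
#' `ss` is the sum of all contributions.
#'
#' @param dag DAG edge tibble with columns `child`, `parent`
#'   (see [read_dag()]).
#' @param id Disease id; must resolve to a DAG node.
#' @param delta Decay factor per edge, in \[0, 1\]. Default 0.5, the value
#'   commonly used for DAG-based disease similarity.
#' @return A list with elements `id`, `contribution` (named numeric over
#'   the closure N(id)) and `ss` (their sum).
#' @export
semantic_profile <- function(dag, id, delta = 0.5) {
  check_scalar_prob(delta, "delta")
  closure <- dag_ancestors(dag, id)
  # children (within the closure) of each closure node
  in_closure <- dag$child %in% closure & dag$parent %in% closure
  kids <- split(dag$child[in_closure], dag$parent[in_closure])
  contribution <- setNames(rep(NA_real_, length(closure)), closure)
  contribution[[id]] <- 1
  # nodes become computable once all closure-children are done; the
  # closure is finite and acyclic so this terminates
  todo <- setdiff(closure, id)
  while (length(todo) > 0L) {
    progressed <- FALSE
    for (v in todo) {
      ch <- intersect(kids[[v]], closure)
      if (all(!is.na(contribution[ch]))) {
        contribution[[v]] <- delta * max(contribution[ch])
        todo <- setdiff(todo, v)
        progressed <- TRUE
      }
    }
    if (!progressed) abort("Internal error: DAG closure is not acyclic.")
  }
  list(id = id, contribution = contribution, ss = sum(contribution))
}

#' Disease semantic similarity matrix
#'
#' Pairwise semantic similarity between diseases from a disease-term DAG:
#' the shared-ancestor contributions of two diseases, summed and
#' normalized by the sum of their semantic scores. Diseases absent from
#' the DAG get similarity 0 to every other disease (diagonal 1), so that
#' the Gaussian interaction profile kernel can fill in for them during
#' integration.
#'
#' @inheritParams semantic_profile
#' @param ids Character vector of disease ids for the matrix rows/columns.
#' @return Labeled symmetric similarity matrix with unit diagonal,
#'   entries in \[0, 1\].
#' @export
disease_semantic_similarity <- function(dag, ids, delta = 0.5) {
  nodes <- unique(c(dag$child, dag$parent))
  known <- ids[ids %in% nodes]
  profiles <- setNames(
    lapply(known, function(d) semantic_profile(dag, d, delta)), known)
  n <- length(ids)
  dd <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(dd) <- 1
  if (length(known) >= 2L) {
    for (a in seq_len(length(known) - 1L)) {
      for (b in seq(a + 1L, length(known))) {
        pa <- profiles[[known[a]]]; pb <- profiles[[known[b]]]
        common <- intersect(names(pa$contribution), names(pb$contribution))
        val <- if (length(common) == 0L) 0 else
          sum(pa$contribution[common] + pb$contribution[common]) /
            (pa$ss + pb$ss)
        dd[known[a], known[b]] <- dd[known[b], known[a]] <- val
      }
    }
  }
  dd
}
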