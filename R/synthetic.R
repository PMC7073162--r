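#' Simulate an association dataset with planted block structure
#'
#' Generates a synthetic lncRNA-disease association catalogue with a
#' controllable planted signal. Diseases are partitioned round-robin into
#' `n_blocks` groups, each group forming one random rooted tree of a
#' disease-term DAG forest (every non-root term attaches to a uniformly
#' chosen earlier term of its group, up to `dag_depth` layers), so
#' within-group semantic similarity is high and between-group similarity
#' is zero. LncRNAs are assigned to the groups round-robin, and each
#' lncRNA-disease pair is associated with probability
#' `within_block_density` when lncRNA and disease share a group and
#' `background_density` otherwise. The generator is a pure function of
#' its arguments: the same seed always yields the same dataset, and the
#' caller's random-number state is left untouched.
#'
#' @param nl,nd Number of lncRNAs and diseases. Defaults 20 and 30.
#' @param n_blocks Number of planted groups; must not exceed `nl` or
#'   `nd`. Default 3.
#' @param within_block_density,background_density Association
#'   probabilities inside and outside matching groups, in \[0, 1\].
#'   Defaults 0.5 and 0.02.
#' @param dag_depth Maximum number of layers of each disease tree.
#'   Default 3.
#' @param seed Integer seed driving all randomness.
#' @return A list with `associations` (tibble `lncrna`, `disease`),
#'   `dag` (tibble `child`, `parent`), the id universes `lncrna_ids` and
#'   `disease_ids` (some entities may have no association, so the
#'   universes are reported explicitly), and the block assignments
#'   `lncrna_block`, `disease_block`.
#' @export
simulate_lda <- function(nl = 20, nd = 30, n_blocks = 3,
                         within_block_density = 0.5,
                         background_density = 0.02,
                         dag_depth = 3, seed = 1) {
  if (nl < n_blocks || nd < n_blocks) {
    abort("`nl` and `nd` must be at least `n_blocks`.")
  }
  check_scalar_prob(within_block_density, "within_block_density")
  check_scalar_prob(background_density, "background_density")
  lncrna_ids <- sprintf("l%03d", seq_len(nl))
  disease_ids <- sprintf("d%03d", seq_len(nd))
  lncrna_block <- setNames(rep_len(seq_len(n_blocks), nl), lncrna_ids)
  disease_block <- setNames(rep_len(seq_len(n_blocks), nd), disease_ids)
  with_local_seed(seed, {
    dag <- random_dag_forest(disease_ids, disease_block, dag_depth)
    p <- ifelse(outer(lncrna_block, disease_block, `==`),
                within_block_density, background_density)
    ld <- matrix(as.numeric(stats::runif(nl * nd) < p), nl, nd,
                 dimnames = list(lncrna_ids, disease_ids))
    list(associations = as_association_tibble(ld), dag = dag,
         lncrna_ids = lncrna_ids, disease_ids = disease_ids,
         lncrna_block = lncrna_block, disease_block = disease_block)
  })
}

# One random tree per block: the first disease of the block is the root
# (layer 1); each later disease picks a parent uniformly among the
# block's already-placed nodes with layer < depth.
random_dag_forest <- function(disease_ids, disease_block, depth) {
  edges <- list()
  for (b in unique(disease_block)) {
    members <- names(disease_block)[disease_block == b]
    layer <- setNames(integer(length(members)), members)
    layer[[1L]] <- 1L
    if (length(members) > 1L) {
      for (k in seq(2L, length(members))) {
        eligible <- members[seq_len(k - 1L)][layer[seq_len(k - 1L)] < depth]
        if (length(eligible) == 0L) eligible <- members[[1L]]
        parent <- eligible[[sample.int(length(eligible), 1L)]]
        layer[[k]] <- layer[[parent]] + 1L
        edges[[length(edges) + 1L]] <-
          tibble(child = members[[k]], parent = parent)
      }
    }
  }
  if (length(edges) == 0L) {
    return(tibble(child = character(0), parent = character(0)))
  }
  dplyr::bind_rows(edges)
}

#' Shuffle association labels
#'
#' Destroys the planted signal of a simulated dataset by redistributing
#' the same number of associations uniformly at random over all
#' lncRNA-disease pairs, keeping the id universes and DAG unchanged.
#' Serves as the matched negative control for planted-signal recovery
#' checks.
#'
#' @param data Output of [simulate_lda()].
#' @param seed Integer seed.
#' @return A list of the same shape as [simulate_lda()] output.
#' @export
shuffle_associations <- function(data, seed) {
  nl <- length(data$lncrna_ids)
  nd <- length(data$disease_ids)
  k <- nrow(data$associations)
  with_local_seed(seed, {
    cells <- sample.int(nl * nd, k)
    ld <- matrix(0, nl, nd,
                 dimnames = list(data$lncrna_ids, data$disease_ids))
    ld[cells] <- 1
    out <- data
    out$associations <- as_association_tibble(ld)
    out
  })
}

#' Fixed worked example with hand-derived stage values
#'
#' A 3-lncRNA by 3-disease example small enough that every pipeline
#' stage can be evaluated by hand, shipped both as code and as TSV
#' fixtures under `inst/extdata/toy/`. The DAG places d2 and d3 as
#' siblings under root d1; the association matrix has rows
#' l1 = (1, 1, 0), l2 = (1, 0, 0), l3 = (0, 0, 0). `dd_is` and `ll_is`
#' are fixed integrated-similarity matrices used to exercise the
#' weighted-network and projection stages with hand-checkable numbers.
#'
#' @return A list with `associations`, `dag`, `lncrna_ids`,
#'   `disease_ids`, the stage inputs `dd_is` and `ll_is`, and `expected`,
#'   a list of hand-derived values: the semantic similarity of the
#'   sibling diseases (`dd_23` = 1/3), root-child similarity
#'   (`dd_12` = 0.6), the weighted-network entries `w_d_l1_d3` and
#'   `w_l_l3_d1` (0.045 at alpha = beta = 0.1), the projection score
#'   `p_d_l1_d3` (0.9 / sqrt(2) at beta = 0) and the combined score
#'   `fs_l1_d3` at omega = 0.8.
#' @export
worked_toy <- function() {
  ext <- system.file("extdata", "toy", package = "lncproject",
                     mustWork = TRUE)
  associations <- read_associations(file.path(ext, "associations.tsv"))
  dag <- read_dag(file.path(ext, "dag.tsv"))
  dd_is <- read_similarity(file.path(ext, "dd_is.tsv"))
  ll_is <- read_similarity(file.path(ext, "ll_is.tsv"))
  # sibling DAG, delta = 0.5: profiles of d2/d3 are {self: 1, d1: 0.5},
  # SS = 1.5; shared ancestor d1 gives (0.5 + 0.5) / (1.5 + 1.5) = 1/3;
  # d1 vs d2 share d1: (1 + 0.5) / (1 + 1.5) = 0.6
  expected <- list(
    dd_23 = 1 / 3,
    dd_12 = 0.6,
    # row l1 = (1,1,0), rowsum 2: 0.1 * (0.5 * 1 + 0.4 * 1) / 2
    w_d_l1_d3 = 0.045,
    # column d1 = (1,1,0)', colsum 2: same arithmetic on ll_is
    w_l_l3_d1 = 0.045,
    # beta = 0 keeps w_l = LD; row (1,1,0) against dd_is column (0.5,0.4,1)
    p_d_l1_d3 = 0.9 / sqrt(2),
    # ll_is row (1,0.2,0.5) against column (0,1,1)' of a unit-weight net
    p_l_example = 0.7 / sqrt(2),
    fs_example = 0.2 * 0.9 / sqrt(2) + 0.8 * 0.7 / sqrt(2)
  )
  dd <- disease_semantic_similarity(dag, c("d1", "d2", "d3"), delta = 0.5)
  list(associations = associations, dag = dag,
       lncrna_ids = c("l1", "l2", "l3"),
       disease_ids = c("d1", "d2", "d3"),
       dd = dd, dd_is = dd_is, ll_is = ll_is, expected = expected)
}
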