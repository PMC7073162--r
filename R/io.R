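#' Read a lncRNA-disease association list
#'
#' Reads a two-column delimited file of known lncRNA-disease associations
#' (one pair per line, lncRNA id first) into a tidy tibble of unique pairs.
#' Lines starting with `#` are ignored. Identifiers are normalized by
#' trimming whitespace and case-folding so that names joined from
#' heterogeneous sources collapse to a single id; switch this off with
#' `normalize = FALSE`.
#'
#' @param path Path to the association file.
#' @param delimiter Field delimiter, default tab.
#' @param normalize Normalize ids (trim + case-fold)? Default `TRUE`.
#' @return A tibble with columns `lncrna` and `disease`, one row per
#'   distinct association, in first-appearance order. Duplicate pairs are
#'   collapsed with a warning: the Boolean association matrix cannot
#'   represent multiplicity.
#' @seealso [association_matrix()] to build the Boolean matrix.
#' @export
read_associations <- function(path, delimiter = "\t", normalize = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) abort(sprintf("Empty association file: %s", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("Line %d of %s has fewer than 2 fields.",
                  line_no[bad[1L]], path))
  }
  out <- tibble(
    lncrna  = normalize_ids(vapply(fields, `[[`, "", 1L), normalize),
    disease = normalize_ids(vapply(fields, `[[`, "", 2L), normalize)
  )
  dup <- duplicated(out)
  if (any(dup)) {
    warn(sprintf("Collapsed %d duplicate association pair(s) in %s.",
                 sum(dup), path))
    out <- out[!dup, ]
  }
  out
}

#' Build the Boolean association matrix from an association tibble
#'
#' Assembles the lncRNA-by-disease adjacency matrix of known associations:
#' entry (i, j) is 1 iff lncRNA i is associated with disease j. Row and
#' column order follow first appearance in the tibble unless explicit id
#' vectors are supplied (useful to include lncRNAs or diseases with no
#' associations).
#'
#' @param associations Tibble with columns `lncrna` and `disease`.
#' @param lncrna_ids,disease_ids Optional character vectors fixing the
#'   row/column universe and order; must cover all ids in `associations`.
#' @return Numeric 0/1 matrix with lncRNA rownames and disease colnames.
#' @export
association_matrix <- function(associations, lncrna_ids = NULL,
                               disease_ids = NULL) {
  stopifnot(all(c("lncrna", "disease") %in% names(associations)))
  lr <- lncrna_ids %||% unique(associations$lncrna)
  dr <- disease_ids %||% unique(associations$disease)
  missing_l <- setdiff(associations$lncrna, lr)
  missing_d <- setdiff(associations$disease, dr)
  if (length(missing_l) || length(missing_d)) {
    abort(sprintf("Ids missing from the supplied universe: %s",
                  paste(c(missing_l, missing_d), collapse = ", ")))
  }
  m <- matrix(0, length(lr), length(dr), dimnames = list(lr, dr))
  m[cbind(match(associations$lncrna, lr),
          match(associations$disease, dr))] <- 1
  m
}

#' Convert an association matrix back to a tidy tibble
#'
#' @param matrix Numeric 0/1 matrix with dimnames.
#' @return Tibble with columns `lncrna`, `disease`, one row per 1-entry.
#' @export
as_association_tibble <- function(matrix) {
  idx <- which(matrix != 0, arr.ind = TRUE)
  tibble(lncrna = rownames(matrix)[idx[, 1L]],
         disease = colnames(matrix)[idx[, 2L]]) |>
    dplyr::arrange(match(.data$lncrna, rownames(matrix)),
                   match(.data$disease, colnames(matrix)))
}

#' Read a labeled similarity matrix
#'
#' Reads a square labeled matrix from tab-separated text (header row of
#' labels, first column of labels, `.` decimal mark). The matrix must be
#' symmetric within `1e-8`; an asymmetric matrix is an error unless
#' `force_symmetrize = TRUE`, which averages the matrix with its
#' transpose.
#'
#' @param path Path to the TSV file.
#' @param force_symmetrize Average with the transpose instead of erroring
#'   on asymmetry? Default `FALSE`.
#' @return A labeled symmetric numeric matrix.
#' @export
read_similarity <- function(path, force_symmetrize = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()
  ), progress = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Similarity matrix in %s is not square (%d x %d).",
                  path, nrow(m), ncol(m)))
  }
  if (anyNA(m)) abort(sprintf("Similarity matrix in %s contains NA/NaN.", path))
  if (!identical(labels, colnames(m))) {
    abort(sprintf("Row labels differ from column labels in %s.", path))
  }
  rownames(m) <- labels
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    if (!force_symmetrize) {
      abort(sprintf(
        "Matrix in %s is asymmetric (max |m - t(m)| = %.3g); use force_symmetrize = TRUE to average with the transpose.",
        path, asym))
    }
    m <- (m + t(m)) / 2
  }
  m
}

#' Write a labeled matrix as TSV
#'
#' Writes any labeled numeric matrix (similarity, weighted network or
#' score matrix) in the package's matrix dialect: tab-separated, header
#' row, first column of row labels, full double precision.
#'
#' @param matrix Labeled numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a disease DAG edge list
#'
#' Reads a two-column child-parent edge list describing the disease-term
#' directed acyclic graph (one DAG forest covering all diseases). The
#' graph is checked for cycles; a cycle is an error and the message lists
#' one offending cycle.
#'
#' @param path Path to the TSV file (child, parent per line).
#' @param delimiter Field delimiter, default tab.
#' @param normalize Normalize ids (trim + case-fold)? Default `TRUE`.
#' @return Tibble with columns `child` and `parent`.
#' @export
read_dag <- function(path, delimiter = "\t", normalize = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("Line %d of %s has fewer than 2 fields.",
                  line_no[bad[1L]], path))
  }
  dag <- tibble(
    child  = normalize_ids(vapply(fields, `[[`, "", 1L), normalize),
    parent = normalize_ids(vapply(fields, `[[`, "", 2L), normalize)
  )
  dag <- dplyr::distinct(dag)
  check_acyclic(dag)
  dag
}

# Kahn's algorithm; on failure reconstruct one cycle for the error message.
check_acyclic <- function(dag) {
  nodes <- unique(c(dag$child, dag$parent))
  indeg <- table(factor(dag$parent, levels = nodes))  # edges child -> parent
  indeg <- setNames(as.integer(indeg), nodes)
  children_of <- split(dag$parent, factor(dag$child, levels = nodes))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in children_of[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    rem <- names(indeg)[indeg > 0L]
    cyc <- find_one_cycle(dag, rem)
    abort(sprintf("DAG edge list contains a cycle: %s.",
                  paste(cyc, collapse = " -> ")))
  }
  invisible(TRUE)
}

find_one_cycle <- function(dag, nodes) {
  parent_of <- split(dag$parent, dag$child)
  start <- nodes[[1L]]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(parent_of[[cur]], nodes)[1L]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' Ancestor closure of a disease term
#'
#' Returns the node set N(d) of a disease's DAG: the term itself plus all
#' of its ancestors reachable through child-to-parent edges.
#'
#' @param dag Tibble with columns `child`, `parent` (see [read_dag()]).
#' @param id Disease id present in the DAG.
#' @return Character vector of node ids; always contains `id`.
#' @export
dag_ancestors <- function(dag, id) {
  nodes <- unique(c(dag$child, dag$parent))
  if (!id %in% nodes) {
    abort(sprintf("Disease '%s' not found in the DAG; closest ids: %s",
                  id, suggest_ids(id, nodes)))
  }
  parent_of <- split(dag$parent, dag$child)
  closure <- character(0)
  frontier <- id
  while (length(frontier) > 0L) {
    closure <- union(closure, frontier)
    frontier <- setdiff(
      unique(unlist(parent_of[intersect(frontier, names(parent_of))],
                    use.names = FALSE)),
      closure)
  }
  closure
}

#' Rank candidate lncRNAs for a disease
#'
#' Orders the lncRNAs by prediction score for one target disease. Ties are
#' broken lexicographically by lncRNA id so that output is deterministic.
#' Known associations (1-entries of the input Boolean matrix) are flagged.
#'
#' @param fit An `lda_fit` from [lda_predict()], or a labeled score matrix
#'   plus `known` matrix.
#' @param disease Target disease id.
#' @param top_k Number of rows to return; values larger than the number of
#'   lncRNAs return the full list. Default 5.
#' @return Tibble with columns `rank`, `lncrna`, `score`, `known`.
#' @export
rank_candidates <- function(fit, disease, top_k = 5L) {
  scores <- if (inherits(fit, "lda_fit")) fit$scores else fit
  known <- if (inherits(fit, "lda_fit")) fit$ld else
    matrix(0, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  if (!disease %in% colnames(scores)) {
    abort(sprintf("Unknown disease '%s'; closest ids: %s",
                  disease, suggest_ids(disease, colnames(scores))))
  }
  tibble(
    lncrna = rownames(scores),
    score  = scores[, disease],
    known  = known[, disease] != 0
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$lncrna) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L) |>
    head(n = top_k)
}

#' Write a ranking table
#'
#' Writes the output of [rank_candidates()] as TSV with columns
#' `rank`, `id`, `score`, `known_flag`.
#'
#' @inheritParams rank_candidates
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(fit, disease, top_k, path) {
  rk <- rank_candidates(fit, disease, top_k) |>
    dplyr::rename(id = "lncrna", known_flag = "known")
  readr::write_tsv(rk, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
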