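# Independent brute-force oracles: plain recursion and explicit loops,
# sharing no code path with the package implementation.

oracle_contribution <- function(dag, id, node, closure, delta) {
  if (node == id) return(1)
  kids <- intersect(dag$child[dag$parent == node], closure)
  delta * max(vapply(kids, function(k)
    oracle_contribution(dag, id, k, closure, delta), 0))
}

oracle_semantic_profile <- function(dag, id, delta) {
  closure <- dag_ancestors(dag, id)
  contribution <- vapply(closure, function(t)
    oracle_contribution(dag, id, t, closure, delta), 0)
  list(contribution = contribution, ss = sum(contribution))
}

oracle_dd <- function(dag, ids, delta) {
  nodes <- unique(c(dag$child, dag$parent))
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(out) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !ids[i] %in% nodes || !ids[j] %in% nodes) next
    pi <- oracle_semantic_profile(dag, ids[i], delta)
    pj <- oracle_semantic_profile(dag, ids[j], delta)
    common <- intersect(names(pi$contribution), names(pj$contribution))
    out[i, j] <- if (length(common) == 0) 0 else
      sum(pi$contribution[common] + pj$contribution[common]) /
        (pi$ss + pj$ss)
  }
  out
}

oracle_functional <- function(ld, dd) {
  nl <- nrow(ld)
  out <- diag(nl)
  dimnames(out) <- list(rownames(ld), rownames(ld))
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    if (i == j) next
    di <- colnames(ld)[ld[i, ] == 1]
    dj <- colnames(ld)[ld[j, ] == 1]
    if (length(di) == 0 || length(dj) == 0) next
    s1 <- sum(vapply(di, function(d) max(dd[d, dj]), 0))
    s2 <- sum(vapply(dj, function(d) max(dd[d, di]), 0))
    out[i, j] <- (s1 + s2) / (length(di) + length(dj))
  }
  out
}

oracle_gip <- function(profiles, gamma) {
  n <- nrow(profiles)
  out <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                         rownames(profiles)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- sum((profiles[i, ] - profiles[j, ])^2)
    out[i, j] <- exp(-gamma * d2)
  }
  out
}

# Explicit-loop evaluation of the weighted-network / projection /
# combination stages.
oracle_w_d <- function(ld, dd_is, alpha) {
  out <- ld
  for (i in seq_len(nrow(ld))) for (j in seq_len(ncol(ld))) {
    rs <- sum(ld[i, ])
    acc <- 0
    if (rs > 0) {
      for (k in seq_len(ncol(ld))) {
        if (k != j) acc <- acc + dd_is[k, j] * ld[i, k]
      }
      acc <- acc / rs
    }
    out[i, j] <- ld[i, j] + alpha * acc
  }
  out
}

oracle_w_l <- function(ld, ll_is, beta) {
  out <- ld
  for (i in seq_len(nrow(ld))) for (j in seq_len(ncol(ld))) {
    cs <- sum(ld[, j])
    acc <- 0
    if (cs > 0) {
      for (k in seq_len(nrow(ld))) {
        if (k != i) acc <- acc + ll_is[i, k] * ld[k, j]
      }
      acc <- acc / cs
    }
    out[i, j] <- ld[i, j] + beta * acc
  }
  out
}

oracle_p_d <- function(w_l, dd_is) {
  out <- w_l * 0
  for (i in seq_len(nrow(w_l))) for (j in seq_len(ncol(w_l))) {
    nrm <- sqrt(sum(w_l[i, ]^2))
    out[i, j] <- if (nrm == 0) 0 else sum(w_l[i, ] * dd_is[, j]) / nrm
  }
  out
}

oracle_p_l <- function(w_d, ll_is) {
  out <- w_d * 0
  for (i in seq_len(nrow(w_d))) for (j in seq_len(ncol(w_d))) {
    nrm <- sqrt(sum(w_d[, j]^2))
    out[i, j] <- if (nrm == 0) 0 else sum(ll_is[i, ] * w_d[, j]) / nrm
  }
  out
}

oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Small random fixtures for property-style tests.
random_dag <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    ids <- paste0("d", seq_len(n_nodes))
    edges <- list()
    for (k in seq(2, n_nodes)) {
      parent <- ids[sample.int(k - 1, 1)]   # earlier node: acyclic
      edges[[k - 1]] <- tibble::tibble(child = ids[k], parent = parent)
    }
    dplyr::bind_rows(edges)
  })
}

random_instance <- function(nl, nd, seed, density = 0.3) {
  withr::with_seed(seed, {
    ld <- matrix(as.numeric(stats::runif(nl * nd) < density), nl, nd,
                 dimnames = list(paste0("l", seq_len(nl)),
                                 paste0("d", seq_len(nd))))
    rand_sim <- function(n, ids) {
      m <- matrix(stats::runif(n * n), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 1
      dimnames(m) <- list(ids, ids)
      m
    }
    list(ld = ld,
         dd_is = rand_sim(nd, colnames(ld)),
         ll_is = rand_sim(nl, rownames(ld)))
  })
}

expect_similarity_invariants <- function(m, tol = 1e-10) {
  testthat::expect_true(all(abs(m - t(m)) < tol))
  testthat::expect_true(all(abs(diag(m) - 1) < tol))
  testthat::expect_true(all(m >= 0 & m <= 1 + tol))
}
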