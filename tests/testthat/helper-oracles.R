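# Independent oracles and small fixture builders used across the suite.

# Build a small omic layer from a matrix (participants get P01, P02, ...).
make_layer <- function(values, layer_id = "cytokine", lod = NULL,
                       feature_prefix = "F") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(feature_prefix, seq_len(ncol(values)))
  omic_layer_table(values, layer_id, lod = lod)
}

# Enumerate every DAG on a labelled node set by filtering all edge subsets.
# On 3 nodes this yields the familiar 25 DAGs.
enumerate_all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- t(combn(p, 2))
  # each unordered pair is absent, forward, or backward: 3^(p(p-1)/2) graphs
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (i in seq_len(nrow(states))) {
    amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    for (j in seq_len(nrow(pairs))) {
      s <- states[i, j]
      if (s == 1) amat[pairs[j, 1], pairs[j, 2]] <- TRUE
      if (s == 2) amat[pairs[j, 2], pairs[j, 1]] <- TRUE
    }
    dag <- try(dag_structure(nodes, which_edges(amat, nodes)), silent = TRUE)
    if (!inherits(dag, "try-error")) out[[length(out) + 1]] <- dag
  }
  out
}

which_edges <- function(amat, nodes) {
  idx <- which(amat, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(nodes[idx[, 1]], nodes[idx[, 2]])
}

# Markov-equivalence class key: skeleton + v-structures (colliders whose
# parents are non-adjacent).
markov_class_key <- function(dag) {
  am <- dag$amat
  sk <- am | t(am)
  nodes <- dag$nodes
  vstr <- character(0)
  for (w in seq_along(nodes)) {
    pa <- which(am[, w])
    if (length(pa) < 2) next
    for (a in seq_along(pa)) for (b in seq_len(a - 1)) {
      u <- pa[a]; v <- pa[b]
      if (!sk[u, v])
        vstr <- c(vstr, paste(sort(c(nodes[u], nodes[v])), collapse = "<",
                              nodes[w]))
    }
  }
  sk_key <- paste(sort(apply(which(sk & upper.tri(sk), arr.ind = TRUE), 1,
                             function(e) paste(nodes[e[1]], nodes[e[2]]))),
                  collapse = ";")
  paste(sk_key, "|", paste(sort(vstr), collapse = ";"))
}

# Plain-R BDeu family score, kept deliberately independent of the compiled
# kernel: counts via table(), pseudo-counts via the uniform prior.
r_family_score <- function(values, node, parents, arity, ess) {
  r <- arity[node]
  if (length(parents) == 0) {
    q <- 1
    cfg <- rep(1L, nrow(values))
  } else {
    q <- prod(arity[parents])
    cfg <- 1L
    mult <- 1L
    for (p in parents) {
      cfg <- cfg + values[, p] * mult
      mult <- mult * arity[p]
    }
  }
  aij <- ess / q
  aijk <- ess / (q * r)
  total <- 0
  for (j in seq_len(q)) {
    rows <- cfg == j
    nij <- sum(rows)
    if (nij == 0) next
    njk <- tabulate(values[rows, node] + 1L, nbins = r)
    total <- total + lgamma(aij) - lgamma(aij + nij) +
      sum(lgamma(aijk + njk) - lgamma(aijk))
  }
  total
}

r_bde_score <- function(dag, data, ess) {
  sum(vapply(seq_along(dag$nodes), function(i) {
    pa <- which(dag$amat[, i])
    cols <- match(dag$nodes, data$variables)
    r_family_score(data$values, cols[i], cols[pa], data$arity, ess)
  }, numeric(1)))
}

# F1 of a consensus skeleton against a planted DAG's skeleton.
skeleton_f1 <- function(network, bn) {
  true_sk <- bn$dag$amat | t(bn$dag$amat)
  tp <- if (nrow(network$edges) == 0) 0 else
    sum(apply(network$edges, 1, function(e) true_sk[e[["from"]], e[["to"]]]))
  fp <- nrow(network$edges) - tp
  fn <- sum(true_sk) / 2 - tp
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Random discrete dataset over 3 binary variables drawn from a random joint
# distribution (Dirichlet(1) over the 8 cells).
random_3var_data <- function(n = 60) {
  pr <- rgamma(8, 1)
  pr <- pr / sum(pr)
  cells <- sample.int(8, n, replace = TRUE, prob = pr)
  x <- cbind(A = (cells - 1) %% 2,
             B = ((cells - 1) %/% 2) %% 2,
             C = (cells - 1) %/% 4)
  discrete_matrix(x)
}
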