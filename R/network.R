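#' Discrete data matrix for network learning
#'
#' Holds participants x variables state codes (0-based integers), the arity
#' (number of states) of each variable, and the source omic layer of each
#' variable. Binary variables code 0 = at or below the cohort median and
#' 1 = above it; the inflammation variable is 3-state.
#'
#' @param values integer matrix of 0-based state codes with participant row
#'   names and variable column names; no missing entries.
#' @param arity integer vector of state counts per variable (default:
#'   observed maximum + 1, at least 2).
#' @param layers character vector tagging each variable's source layer.
#' @return An object of class `discrete_matrix`.
#' @export
discrete_matrix <- function(values, arity = NULL, layers = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (anyNA(values)) stop("discrete matrix must be complete (no NA)")
  if (is.null(colnames(values))) stop("variables must be named")
  if (any(values < 0)) stop("state codes must be 0-based non-negative")
  if (is.null(arity)) arity <- pmax(apply(values, 2, max) + 1L, 2L)
  arity <- as.integer(arity)
  if (any(apply(values, 2, max) >= arity))
    stop("state code out of range for declared arity")
  if (is.null(layers)) layers <- rep(NA_character_, ncol(values))
  structure(list(values = values, arity = setNames(arity, colnames(values)),
                 layers = setNames(layers, colnames(values)),
                 variables = colnames(values)),
            class = "discrete_matrix")
}

#' @export
print.discrete_matrix <- function(x, ...) {
  cat(sprintf("<discrete_matrix> %d participants x %d variables (arities %s)\n",
              nrow(x$values), ncol(x$values),
              paste(range(x$arity), collapse = "-")))
  invisible(x)
}

#' Directed acyclic graph over network variables
#'
#' Represented as a logical adjacency matrix: `amat[u, v]` is `TRUE` for an
#' edge u -> v. Construction validates acyclicity and the absence of
#' self-loops.
#'
#' @param nodes character vector of node names.
#' @param edges optional 2-column matrix (from, to) of directed edges.
#' @return An object of class `dag_structure`.
#' @export
dag_structure <- function(nodes, edges = NULL) {
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (!all(edges %in% nodes)) stop("edge endpoint not in node set")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    amat[edges] <- TRUE
  }
  if (has_cycle(amat)) stop("edge set contains a directed cycle")
  structure(list(nodes = nodes, amat = amat), class = "dag_structure")
}

#' @rdname dag_structure
#' @export
empty_dag <- function(nodes) dag_structure(nodes)

#' @export
print.dag_structure <- function(x, ...) {
  cat(sprintf("<dag_structure> %d nodes, %d directed edges\n",
              length(x$nodes), sum(x$amat)))
  invisible(x)
}

# Transitive closure by repeated boolean squaring; reach[u, v] == TRUE means
# there is a directed path u -> ... -> v (length >= 1).
reachability <- function(amat) {
  r <- amat
  repeat {
    r2 <- r | ((r %*% amat) > 0)
    if (identical(r2, r)) return(r)
    r <- r2
  }
}

has_cycle <- function(amat) any(diag(reachability(amat)))

dag_edges <- function(dag) {
  idx <- which(dag$amat, arr.ind = TRUE)
  cbind(from = dag$nodes[idx[, 1]], to = dag$nodes[idx[, 2]])
}

# Undirected skeleton as a logical symmetric matrix.
dag_skeleton <- function(dag) dag$amat | t(dag$amat)

#' BDe (BDeu) network score
#'
#' Log marginal likelihood of a DAG for complete discrete data under the
#' likelihood-equivalent Bayesian Dirichlet score with a uniform prior over
#' parameters: pseudo-counts `ess / q_i` per parent configuration and
#' `ess / (q_i r_i)` per cell, where `r_i` is the arity of node i and `q_i`
#' the number of parent configurations. The score is decomposable into
#' per-family terms, which the hill climber exploits.
#'
#' @param dag a [dag_structure()].
#' @param data a [discrete_matrix()] whose variables include the DAG nodes.
#' @param ess imaginary (equivalent) sample size, > 0.
#' @return The log score (a single number).
#' @export
bde_score <- function(dag, data, ess = 1) {
  stopifnot(inherits(dag, "dag_structure"), inherits(data, "discrete_matrix"))
  if (ess <= 0) stop("'ess' must be > 0")
  if (!all(dag$nodes %in% data$variables))
    stop("DAG node(s) absent from the data")
  col_of <- match(dag$nodes, data$variables) - 1L
  total <- 0
  for (i in seq_along(dag$nodes)) {
    pa <- which(dag$amat[, i])
    total <- total + bde_family_score_cpp(
      data$values, col_of[i], col_of[pa], data$arity, ess)
  }
  total
}

# Family score with memoisation. cache is an environment keyed by
# "node|sorted parent columns".
family_score <- function(data, node_col, parent_cols, ess, cache = NULL) {
  if (is.null(cache))
    return(bde_family_score_cpp(data$values, node_col,
                                sort(parent_cols), data$arity, ess))
  key <- paste0(node_col, "|", paste(sort(parent_cols), collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- bde_family_score_cpp(data$values, node_col, sort(parent_cols),
                              data$arity, ess)
  cache[[key]] <- val
  val
}

#' Greedy hill-climbing structure search
#'
#' Starting from `start` (the empty DAG by default), repeatedly applies the
#' highest-scoring admissible single-edge addition, deletion, or reversal
#' while the BDeu score strictly improves, and returns the local optimum.
#' Family scores are cached so re-visited parent sets cost nothing.
#'
#' @inheritParams bde_score
#' @param max_parents cap on the number of parents per node (default 4;
#'   small discrete cohorts cannot support dense parent sets).
#' @param start optional starting [dag_structure()].
#' @param cache optional environment for family-score memoisation, shared
#'   across restarts on the same data.
#' @return list with `dag` (the local optimum) and `score`.
#' @export
hill_climb <- function(data, ess = 1, max_parents = 4, start = NULL,
                       cache = NULL) {
  stopifnot(inherits(data, "discrete_matrix"))
  nodes <- data$variables
  p <- length(nodes)
  if (is.null(start)) start <- empty_dag(nodes)
  if (!identical(sort(start$nodes), sort(nodes)))
    stop("start DAG must be over the data's variables")
  amat <- start$amat[nodes, nodes]
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cols <- seq_len(p) - 1L

  fam <- vapply(seq_len(p), function(v)
    family_score(data, cols[v], cols[which(amat[, v])], ess, cache),
    numeric(1))

  repeat {
    reach <- reachability(amat)
    n_par <- colSums(amat)
    best_delta <- 0
    best_move <- NULL
    for (v in seq_len(p)) {
      pa_v <- which(amat[, v])
      # additions u -> v
      if (n_par[v] < max_parents) {
        cand <- which(!amat[, v] & !amat[v, ] & !reach[v, ] &
                        seq_len(p) != v)
        for (u in cand) {
          d <- family_score(data, cols[v], cols[c(pa_v, u)], ess, cache) -
            fam[v]
          if (d > best_delta + 1e-12) {
            best_delta <- d
            best_move <- list(op = "add", u = u, v = v)
          }
        }
      }
      # deletions u -> v
      for (u in pa_v) {
        d <- family_score(data, cols[v], cols[setdiff(pa_v, u)], ess,
                          cache) - fam[v]
        if (d > best_delta + 1e-12) {
          best_delta <- d
          best_move <- list(op = "delete", u = u, v = v)
        }
      }
      # reversals u -> v  =>  v -> u
      for (u in pa_v) {
        if (n_par[u] >= max_parents) next
        tmp <- amat
        tmp[u, v] <- FALSE
        tmp[v, u] <- TRUE
        if (any(diag(reachability(tmp)))) next
        d <- (family_score(data, cols[v], cols[setdiff(pa_v, u)], ess,
                           cache) - fam[v]) +
          (family_score(data, cols[u], cols[c(which(amat[, u]), v)], ess,
                        cache) - fam[u])
        if (d > best_delta + 1e-12) {
          best_delta <- d
          best_move <- list(op = "reverse", u = u, v = v)
        }
      }
    }
    if (is.null(best_move)) break
    u <- best_move$u; v <- best_move$v
    if (best_move$op == "add") {
      amat[u, v] <- TRUE
    } else if (best_move$op == "delete") {
      amat[u, v] <- FALSE
    } else {
      amat[u, v] <- FALSE
      amat[v, u] <- TRUE
      fam[u] <- family_score(data, cols[u], cols[which(amat[, u])], ess,
                             cache)
    }
    fam[v] <- family_score(data, cols[v], cols[which(amat[, v])], ess, cache)
  }

  dag <- structure(list(nodes = nodes, amat = amat), class = "dag_structure")
  list(dag = dag, score = sum(fam))
}

# Apply `n_ops` random valid single-edge operations to a DAG (used to
# perturb the incumbent between restarts). The operation type is drawn
# first (add / delete / reverse, uniformly among the feasible kinds) so
# that sparse incumbents are not perturbed almost exclusively by
# additions, which would keep every restart in the same search basin.
perturb_dag <- function(dag, n_ops, max_parents = 4) {
  amat <- dag$amat
  p <- nrow(amat)
  for (i in seq_len(n_ops)) {
    for (try in 1:25) {
      edges <- which(amat, arr.ind = TRUE)
      op <- if (nrow(edges) == 0) "add" else
        sample(c("add", "delete", "reverse"), 1)
      if (op == "delete") {
        e <- edges[sample.int(nrow(edges), 1), ]
        amat[e[1], e[2]] <- FALSE
        break
      } else if (op == "reverse") {
        e <- edges[sample.int(nrow(edges), 1), ]
        tmp <- amat
        tmp[e[1], e[2]] <- FALSE
        tmp[e[2], e[1]] <- TRUE
        if (sum(tmp[, e[1]]) <= max_parents &&
            !any(diag(reachability(tmp)))) {
          amat <- tmp
          break
        }
      } else {
        u <- sample.int(p, 1)
        v <- sample.int(p, 1)
        if (u == v || amat[u, v] || amat[v, u]) next
        tmp <- amat
        tmp[u, v] <- TRUE
        if (sum(tmp[, v]) <= max_parents &&
            !any(diag(reachability(tmp)))) {
          amat <- tmp
          break
        }
      }
    }
  }
  structure(list(nodes = dag$nodes, amat = amat), class = "dag_structure")
}

#' Hill climbing with random restarts
#'
#' Restart 1 starts from the empty DAG (or `start`); each subsequent restart
#' perturbs the incumbent best with `perturb` random valid edge operations
#' and re-runs [hill_climb()], keeping the best-scoring result. The whole
#' procedure is deterministic given `seed`.
#'
#' @inheritParams hill_climb
#' @param n_restarts number of hill-climbing runs (>= 1).
#' @param perturb number of random edge operations between restarts (default 8).
#' @param seed integer seed.
#' @return list with `dag`, `score`, and `n_climbs` (hill-climb invocations).
#' @export
learn_with_restarts <- function(data, ess = 1, n_restarts = 10, perturb = 8,
                                seed = 1, max_parents = 4, start = NULL,
                                cache = NULL) {
  if (n_restarts < 1) stop("'n_restarts' must be >= 1")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    best <- hill_climb(data, ess, max_parents, start = start, cache = cache)
    climbs <- 1L
    while (climbs < n_restarts) {
      init <- perturb_dag(best$dag, perturb, max_parents)
      cand <- hill_climb(data, ess, max_parents, start = init, cache = cache)
      climbs <- climbs + 1L
      if (cand$score > best$score) best <- cand
    }
    list(dag = best$dag, score = best$score, n_climbs = climbs)
  })
}

#' Bootstrap arc strengths
#'
#' Resamples participants with replacement `B` times; each resample is
#' learned with [learn_with_restarts()] and the undirected skeleton of the
#' winning network recorded. The strength of a node pair is the fraction of
#' the `B` skeletons containing an edge between them in either direction —
#' edges carry no directional claim. Resamples in which a variable
#' degenerates to a single level are redrawn (with a capped retry count).
#'
#' @inheritParams learn_with_restarts
#' @param B number of bootstrap resamples.
#' @return An `arc_strength_table`: data.frame (`from`, `to`, `strength`)
#'   over all unordered node pairs, with attributes `nodes`, `B`,
#'   `n_restarts`, `seed`, and `n_networks` (total hill-climb invocations).
#' @export
bootstrap_arc_strengths <- function(data, ess = 1, B = 200, n_restarts = 10,
                                    perturb = 8, seed = 1, max_parents = 4) {
  stopifnot(inherits(data, "discrete_matrix"))
  if (B < 1) stop("'B' must be >= 1")
  nodes <- data$variables
  p <- length(nodes)
  n <- nrow(data$values)
  seeds <- derive_seeds(seed, 2L * B)
  acc <- matrix(0, p, p, dimnames = list(nodes, nodes))
  n_networks <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], {
      res <- NULL
      for (try in 1:100) {
        cand <- sample.int(n, n, replace = TRUE)
        lv <- apply(data$values[cand, , drop = FALSE], 2,
                    function(x) length(unique(x)))
        if (all(lv >= 2)) {
          res <- cand
          break
        }
      }
      res
    })
    if (is.null(idx))
      stop("bootstrap resample kept degenerating after 100 retries")
    boot <- discrete_matrix(data$values[idx, , drop = FALSE],
                            arity = data$arity, layers = data$layers)
    fit <- learn_with_restarts(boot, ess, n_restarts, perturb,
                               seed = seeds[B + b],
                               max_parents = max_parents)
    n_networks <- n_networks + fit$n_climbs
    acc <- acc + dag_skeleton(fit$dag)
  }
  strength <- acc / B
  pairs <- t(utils::combn(nodes, 2))
  out <- data.frame(from = pairs[, 1], to = pairs[, 2],
                    strength = strength[pairs],
                    stringsAsFactors = FALSE)
  structure(out, class = c("arc_strength_table", "data.frame"),
            nodes = nodes, B = B, n_restarts = n_restarts, seed = seed,
            n_networks = n_networks)
}

#' Significance threshold for bootstrap arc strengths
#'
#' Estimates the strength cutoff separating noise from signal by minimizing
#' the L1 distance between the empirical CDF of the observed strengths and
#' the ideal noiseless step CDF (in which every arc has strength 0 or 1) —
#' the Scutari-Nagarajan estimator behind averaged consensus networks. The
#' minimizing CDF level is the weighted median of the empirical CDF; the
#' returned threshold is the smallest observed strength strictly above the
#' corresponding strength quantile, so that edges with `strength >=
#' threshold` form the consensus network.
#'
#' @param strengths an `arc_strength_table` from
#'   [bootstrap_arc_strengths()], or a bare numeric vector of strengths.
#' @return A single threshold in `[0, 1]`.
#' @export
estimate_significance_threshold <- function(strengths) {
  s <- if (is.data.frame(strengths)) strengths$strength else as.numeric(strengths)
  if (length(s) == 0) stop("need at least one strength value")
  if (any(s < 0 | s > 1)) stop("strengths must lie in [0, 1]")
  s <- sort(s)
  if (s[1] == s[length(s)]) return(s[1])
  u <- unique(s)
  Fu <- cumsum(tabulate(match(s, u))) / length(s)
  # piecewise-constant empirical CDF on [0, 1]: value 0 before the first
  # unique strength, Fu[i] on [u[i], u[i+1]), Fu[m] up to 1
  knots <- c(0, u, 1)
  vals <- c(0, Fu)
  widths <- diff(knots)
  keep <- widths > 0
  # L1-optimal constant = weighted median of CDF levels
  ow <- order(vals[keep])
  v_sorted <- vals[keep][ow]
  w_sorted <- widths[keep][ow]
  cum <- cumsum(w_sorted) / sum(w_sorted)
  c_hat <- v_sorted[which(cum >= 0.5)[1]]
  # strength quantile at level c_hat, then keep strictly above it
  q <- u[which(Fu >= c_hat)[1]]
  above <- u[u > q]
  if (length(above) == 0) max(u) else min(above)
}

#' Threshold-averaged consensus network
#'
#' Retains every unordered node pair whose bootstrap arc strength is at
#' least `threshold` (estimated with [estimate_significance_threshold()]
#' when not supplied) and records node degrees and run provenance.
#'
#' @param strengths an `arc_strength_table`.
#' @param threshold edge-inclusion cutoff in `[0, 1]`; estimated if `NULL`.
#' @return An object of class `consensus_network` with elements `nodes`,
#'   `edges` (data.frame `from`, `to`, `strength`), `degree`, `threshold`,
#'   and `provenance`.
#' @export
build_consensus_network <- function(strengths, threshold = NULL) {
  stopifnot(inherits(strengths, "arc_strength_table"))
  if (is.null(threshold)) threshold <- estimate_significance_threshold(strengths)
  if (threshold < 0 || threshold > 1) stop("'threshold' must lie in [0, 1]")
  nodes <- attr(strengths, "nodes")
  edges <- strengths[strengths$strength >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(rep(0L, length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(
    list(nodes = nodes, edges = as.data.frame(edges), degree = degree,
         threshold = threshold,
         provenance = list(B = attr(strengths, "B"),
                           n_restarts = attr(strengths, "n_restarts"),
                           seed = attr(strengths, "seed"),
                           n_networks = attr(strengths, "n_networks"))),
    class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d edges between %d nodes (threshold %.3f; B=%s, R=%s)\n",
              nrow(x$edges), length(x$nodes), x$threshold,
              x$provenance$B, x$provenance$n_restarts))
  invisible(x)
}

#' Optimal imaginary sample size
#'
#' Maximizes the BDeu score of a fixed DAG over the equivalent sample size:
#' a log-spaced grid (2^-5 ... 2^10, 64 points by default) followed by
#' golden-section refinement between the neighbors of the best grid point.
#' Deterministic.
#'
#' @inheritParams bde_score
#' @param grid numeric vector of candidate ess values.
#' @return The ess maximizing the score.
#' @export
estimate_imaginary_sample_size <- function(data, dag = NULL,
                                           grid = 2^seq(-5, 10,
                                                        length.out = 64)) {
  stopifnot(inherits(data, "discrete_matrix"))
  if (is.null(dag)) dag <- empty_dag(data$variables)
  f <- function(e) bde_score(dag, data, e)
  sc <- vapply(grid, f, numeric(1))
  if (any(!is.finite(sc))) stop("non-finite score on the ess grid")
  i <- which.max(sc)
  lo <- log2(grid[max(1, i - 1)])
  hi <- log2(grid[min(length(grid), i + 1)])
  # golden-section search on the log2 scale
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(2^x1); f2 <- f(2^x2)
  for (it in 1:60) {
    if (b - a < 1e-6) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(2^x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(2^x1)
    }
  }
  best_ref <- if (f1 > f2) 2^x1 else 2^x2
  if (f(best_ref) >= sc[i]) best_ref else grid[i]
}
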