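#' Tie-corrected Kruskal-Wallis test
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic, degrees of freedom (groups - 1), and the upper-tail chi-square
#' p-value. A degenerate sample in which all values are identical yields
#' H = 0, p = 1 rather than an error.
#'
#' @param values numeric vector of per-participant measurements.
#' @param groups per-participant group labels (>= 2 groups, each with at
#'   least one non-missing observation).
#' @return list with elements `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop("a group is empty after NA removal")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Kruskal-Wallis across every feature of a layer
#'
#' Runs [kruskal_wallis()] feature by feature and applies Benjamini-Hochberg
#' correction across features, the standard per-layer contrast.
#'
#' @param layer an [omic_layer_table()].
#' @param groups named group labels covering the layer's participants.
#' @return data.frame with `feature`, `H`, `df`, `p`, `p_adj`, and one
#'   median column per group.
#' @export
kw_layer_test <- function(layer, groups) {
  stopifnot(inherits(layer, "omic_layer_table"))
  g <- groups[participants(layer)]
  if (any(is.na(g))) stop("group label missing for some participants")
  g <- factor(g)
  res <- lapply(colnames(layer$values), function(f) {
    r <- kruskal_wallis(layer$values[, f], g)
    med <- tapply(layer$values[, f], g, median, na.rm = TRUE)
    c(list(feature = f, H = r$H, df = r$df, p = r$p), as.list(med))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  names(out)[5:ncol(out)] <- paste0("median_", levels(g))
  out$p_adj <- benjamini_hochberg(out$p)
  out[, c("feature", "H", "df", "p", "p_adj",
          paste0("median_", levels(g)))]
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise standardized rank-mean differences with the Kruskal-Wallis tie
#' correction:
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_a + 1/n_b))`.
#' Two-sided p-values are adjusted across the `k(k-1)/2` pairs; the default
#' `"sidak"` adjustment mirrors the joint Dunn multiple-comparison behavior
#' of common statistics software.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"sidak"`, `"bonferroni"`, `"bh"`, or `"none"`.
#' @return data.frame with `group_a`, `group_b`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups,
                         adjust = c("sidak", "bonferroni", "bh", "none")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  N <- length(values)
  r <- rank(values)  # midranks
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, groups, mean)
  n_g <- table(groups)
  pairs <- utils::combn(levels(groups), 2)
  z <- apply(pairs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    se <- sqrt(var_term * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) return(0)
    (rbar[[a]] - rbar[[b]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  m <- ncol(pairs)
  p_adj <- switch(adjust,
                  none = p,
                  bonferroni = pmin(1, p * m),
                  bh = p.adjust(p, "BH"),
                  sidak = 1 - (1 - p)^m)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z = as.numeric(z), p = as.numeric(p),
             p_adj = as.numeric(pmin(1, p_adj)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies [stats::p.adjust()] with
#' `method = "BH"`: `p_adj(i) = min over j >= rank(i) of m * p(j) / j`,
#' capped at 1 and order-preserving.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Monte-Carlo Fisher's exact test for r x c tables
#'
#' Simulates tables with the observed margins by Patefield's algorithm
#' (base R's [stats::r2dtable()]) and estimates the two-sided p-value as
#' `(1 + #{simulated tables at most as probable as observed}) /
#' (iterations + 1)` — the add-one estimator, which never returns 0.
#'
#' @param table matrix of non-negative integer counts.
#' @param iterations number of simulated tables (default 2000).
#' @param seed integer seed for the simulation (required, logged in the
#'   result).
#' @return list with `p`, `iterations`, `seed`.
#' @export
fisher_monte_carlo <- function(table, iterations = 2000, seed) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (iterations < 1) stop("'iterations' must be >= 1")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margins: zero row or column sum")
  # log probability of a table under the fixed-margins hypergeometric law
  log_prob <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  obs <- log_prob(table)
  sims <- with_seed(seed, r2dtable(iterations, rs, cs))
  hits <- sum(vapply(sims, log_prob, numeric(1)) <= obs + 1e-7)
  list(p = (1 + hits) / (iterations + 1),
       iterations = iterations, seed = seed)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric p-value per pathway for the overlap
#' between a hit set and each annotation set (both intersected with the
#' universe), followed by Benjamini-Hochberg correction across pathways.
#'
#' @param hit_set character vector of significant feature IDs (subset of
#'   `universe`, non-empty).
#' @param universe character vector of all tested feature IDs.
#' @param annotation named list, pathway -> character vector of member
#'   feature IDs.
#' @return data.frame with `pathway`, `overlap`, `pathway_size`, `hits`,
#'   `universe_size`, `p`, `p_adj`.
#' @export
hypergeometric_ora <- function(hit_set, universe, annotation) {
  hit_set <- unique(hit_set)
  universe <- unique(universe)
  if (length(hit_set) == 0) stop("empty hit set")
  if (!all(hit_set %in% universe)) stop("hit set must be within the universe")
  N <- length(universe)
  n <- length(hit_set)
  res <- lapply(names(annotation), function(pw) {
    members <- intersect(annotation[[pw]], universe)
    K <- length(members)
    k <- length(intersect(members, hit_set))
    # upper tail: P(overlap >= k); k = 0 gives p = 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, pathway_size = K,
               hits = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- benjamini_hochberg(out$p)
  out[order(out$p), ]
}
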