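#' The curated 10-cytokine inflammation panel
#'
#' Canonical names of the ten pro-inflammatory cytokines and chemokines used
#' to stratify participants: IFN-a2, IL-1a, IL-1b, IL-6, IL-8, IP-10, MCP-1,
#' MIP-1a, MIP-1b, and RANTES.
#'
#' @return Character vector of the ten canonical names, in panel order.
#' @export
curated_cytokine_panel <- function() {
  c("IFN-a2", "IL-1a", "IL-1b", "IL-6", "IL-8",
    "IP-10", "MCP-1", "MIP-1a", "MIP-1b", "RANTES")
}

# Alias table: normalized synonym -> canonical panel name. Chemokine gene
# symbols (CCL/CXCL) and Greek-letter spellings all map to the same entry.
cytokine_alias_map <- function() {
  c("IFNA2" = "IFN-a2", "IFNALPHA2" = "IFN-a2",
    "IL1A" = "IL-1a", "IL1ALPHA" = "IL-1a",
    "IL1B" = "IL-1b", "IL1BETA" = "IL-1b",
    "IL6" = "IL-6", "IL8" = "IL-8", "CXCL8" = "IL-8",
    "IP10" = "IP-10", "CXCL10" = "IP-10",
    "MCP1" = "MCP-1", "CCL2" = "MCP-1",
    "MIP1A" = "MIP-1a", "MIP1ALPHA" = "MIP-1a", "CCL3" = "MIP-1a",
    "MIP1B" = "MIP-1b", "MIP1BETA" = "MIP-1b", "CCL4" = "MIP-1b",
    "RANTES" = "RANTES", "CCL5" = "RANTES")
}

normalize_cytokine_name <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  key <- sub("ALPHA$", "A", key)
  key <- sub("BETA$", "B", key)
  map <- cytokine_alias_map()
  out <- unname(map[key])
  ifelse(is.na(out), x, out)
}

#' Restrict a cytokine layer to the curated 10-cytokine panel
#'
#' Feature names are normalized through an alias table (e.g. `CCL5` maps to
#' RANTES, `CXCL10` to IP-10) before matching.
#'
#' @param table a cytokine [omic_layer_table()].
#' @return The table restricted to the ten panel cytokines, in canonical
#'   panel order and with canonical names.
#' @export
select_curated_panel <- function(table) {
  stopifnot(inherits(table, "omic_layer_table"))
  canon <- normalize_cytokine_name(colnames(table$values))
  panel <- curated_cytokine_panel()
  missing <- setdiff(panel, canon)
  if (length(missing) > 0)
    stop("curated panel cytokine(s) absent after preprocessing: ",
         paste(missing, collapse = ", "))
  idx <- match(panel, canon)
  out <- subset_layer(table, features = colnames(table$values)[idx])
  colnames(out$values) <- panel
  colnames(out$missing_mask) <- panel
  if (!is.null(out$lod)) names(out$lod) <- panel[match(names(out$lod),
    colnames(table$values)[idx])]
  out
}

#' Per-participant count of cytokines in the cohort upper quartile
#'
#' For each panel cytokine the cohort 75th percentile is computed with the
#' linear-interpolation sample quantile; a participant's count is the number
#' of cytokines for which their value lies strictly above that percentile.
#'
#' @param panel the curated 10-cytokine [omic_layer_table()].
#' @param strict count values strictly above (`TRUE`, default) or `>=` the
#'   75th percentile.
#' @param quantile_type sample quantile algorithm (see [stats::quantile()]);
#'   default 7, linear interpolation.
#' @return Named integer vector of counts, one per participant.
#' @export
count_upper_quartile <- function(panel, strict = TRUE, quantile_type = 7) {
  stopifnot(inherits(panel, "omic_layer_table"))
  v <- panel$values
  if (nrow(v) < 4) stop("need at least 4 participants for a quartile")
  if (any(panel$missing_mask)) stop("impute the panel before counting")
  q75 <- apply(v, 2, quantile, probs = 0.75, type = quantile_type,
               names = FALSE)
  above <- if (strict) sweep(v, 2, q75, ">") else sweep(v, 2, q75, ">=")
  setNames(as.integer(rowSums(above)), rownames(v))
}

#' Stratify participants into inflammation groups by hierarchical clustering
#'
#' Participants are clustered on the curated cytokine panel (log2, then
#' per-feature z-score by default) with agglomerative clustering; the tree is
#' cut into `k` clusters which are then ranked by mean upper-quartile
#' cytokine count (ties broken by mean standardized cytokine level) and
#' labeled `low` ... `high` in ascending order. The label therefore depends
#' only on the biology of the cluster, not on the dendrogram's arbitrary
#' cluster indices.
#'
#' @param panel the curated cytokine [omic_layer_table()] on the raw
#'   (abundance) scale, fully imputed.
#' @param k number of groups (default 3: low / medium / high).
#' @param log2 log2-transform before clustering (default `TRUE`; ignored if
#'   the panel is already on the log2 scale).
#' @param standardize per-feature z-score before clustering (default `TRUE`).
#' @param distance distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return A data.frame with columns `participant`, `group` (ordered factor
#'   `low < medium < high` when `k = 3`), and `uq_count`.
#' @export
cluster_inflammation_groups <- function(panel, k = 3, log2 = TRUE,
                                        standardize = TRUE,
                                        distance = "euclidean",
                                        linkage = "ward.D2") {
  stopifnot(inherits(panel, "omic_layer_table"))
  if (any(panel$missing_mask)) stop("impute the panel before clustering")
  n <- nrow(panel$values)
  if (k > n) stop("k exceeds the number of participants")
  uq <- count_upper_quartile(panel)
  group_levels <- if (k == 3) c("low", "medium", "high")
                  else if (k == 1) "low"
                  else paste0("level", seq_len(k))
  x <- panel$values
  if (log2 && identical(panel$scale, "abundance")) {
    if (any(x <= 0)) stop("non-positive values; impute before clustering")
    x <- base::log2(x)
  }
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (all(sds == 0)) stop("constant panel: cannot cluster")
    x <- scale(x[, sds > 0, drop = FALSE])
  }
  cl <- if (k == 1) {
    setNames(rep(1L, n), rownames(panel$values))
  } else {
    hc <- hclust(dist(x, method = distance), method = linkage)
    cutree(hc, k = k)
  }
  # rank clusters: ascending mean uq_count, ties by mean standardized level
  mean_uq <- tapply(uq[names(cl)], cl, mean)
  mean_lvl <- tapply(rowMeans(x)[names(cl)], cl, mean)
  ord <- order(mean_uq, mean_lvl)
  rank_of <- setNames(seq_along(ord), as.character(names(mean_uq)[ord]))
  group <- group_levels[rank_of[as.character(cl)]]
  data.frame(
    participant = rownames(panel$values),
    group = factor(group, levels = group_levels, ordered = TRUE),
    uq_count = unname(uq[rownames(panel$values)]),
    stringsAsFactors = FALSE)
}

#' Amsel-criteria bacterial vaginosis call
#'
#' A participant is BV-positive when at least 3 of the 4 Amsel criteria
#' (clue cells, positive whiff test, vaginal pH > 4.5, abnormal discharge)
#' are present. Records with a missing criterion are flagged indeterminate
#' (`NA`) and should be excluded from BV tabulations.
#'
#' @param records data.frame with logical columns `clue_cells`,
#'   `whiff_positive`, `ph_above_4_5`, `abnormal_discharge` and a
#'   `participant` column.
#' @return The input with an added logical `bv_positive` column.
#' @export
call_amsel_bv <- function(records) {
  crit <- c("clue_cells", "whiff_positive", "ph_above_4_5",
            "abnormal_discharge")
  missing_cols <- setdiff(crit, names(records))
  if (length(missing_cols) > 0)
    stop("missing Amsel criterion column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(records[, crit])
  storage.mode(m) <- "logical"
  s <- rowSums(m)  # NA when any criterion is missing
  records$bv_positive <- s >= 3
  records
}
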