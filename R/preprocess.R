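#' Remove features censored in too many samples
#'
#' Panel features (cytokines, metabolites, ...) that fall below the limit of
#' detection in a large fraction of samples carry little usable signal.
#' Following the usual Luminex-panel convention, a feature is dropped when
#' its missing fraction reaches `max_missing_fraction` — i.e. a feature
#' missing in exactly 40% of samples is removed at the default threshold.
#'
#' @param table an [omic_layer_table()] with a missing mask.
#' @param max_missing_fraction drop features whose missing fraction is
#'   `>=` this value (default 0.40).
#' @param quiet suppress the before/after count message.
#' @return The table restricted to retained features; participants unchanged.
#' @export
filter_by_detection_rate <- function(table, max_missing_fraction = 0.40,
                                     quiet = FALSE) {
  stopifnot(inherits(table, "omic_layer_table"))
  if (!(max_missing_fraction > 0 && max_missing_fraction <= 1))
    stop("'max_missing_fraction' must be in (0, 1]")
  frac <- colMeans(table$missing_mask)
  keep <- names(frac)[frac < max_missing_fraction]
  if (length(keep) == 0)
    stop("all features removed by detection-rate filter in layer '",
         table$layer_id, "'")
  if (!quiet)
    message(sprintf("detection-rate filter [%s]: %d -> %d features",
                    table$layer_id, ncol(table$values), length(keep)))
  subset_layer(table, features = keep)
}

#' Impute censored entries with half the limit of detection
#'
#' Each masked (below-LOD) entry is replaced by `lod / 2` for its feature,
#' the standard half-minimum-detectable-concentration rule for immunoassay
#' panels. Unmasked entries are untouched and the mask is cleared.
#'
#' @param table an [omic_layer_table()]; every feature with masked entries
#'   must have an LOD.
#' @return The imputed table with an empty missing mask.
#' @export
impute_half_min_lod <- function(table) {
  stopifnot(inherits(table, "omic_layer_table"))
  if (!any(table$missing_mask)) return(table)
  need <- colnames(table$values)[colSums(table$missing_mask) > 0]
  missing_lod <- setdiff(need, names(table$lod))
  if (length(missing_lod) > 0)
    stop("masked entries but no LOD for feature(s): ",
         paste(missing_lod, collapse = ", "))
  v <- table$values
  for (f in need) {
    v[table$missing_mask[, f], f] <- table$lod[[f]] / 2
  }
  cleared <- table$missing_mask
  cleared[] <- FALSE
  omic_layer_table(v, table$layer_id, lod = table$lod,
                   missing_mask = cleared)
}

#' Zero-replacement imputation for metabolite panels
#'
#' Replaces below-LOD metabolite entries. The default strategy mirrors the
#' half-minimum rule: a masked entry becomes half the minimum observed
#' positive value of its feature, which avoids literal zeros that would
#' break a subsequent log2 transform. `"zero"` inserts literal zeros and
#' `"global-half-min"` uses half the table-wide minimum positive value.
#'
#' @param table a metabolite [omic_layer_table()].
#' @param strategy `"half-min"` (default), `"zero"`, or `"global-half-min"`.
#' @return The imputed table with an empty missing mask.
#' @export
impute_zero_replacement <- function(table,
                                    strategy = c("half-min", "zero",
                                                 "global-half-min")) {
  stopifnot(inherits(table, "omic_layer_table"))
  strategy <- match.arg(strategy)
  if (table$layer_id != "metabolite")
    stop("zero-replacement imputation is defined for the metabolite layer")
  if (!any(table$missing_mask)) return(table)
  v <- table$values
  m <- table$missing_mask
  all_masked <- colnames(v)[colSums(m) == nrow(v)]
  if (length(all_masked) > 0)
    stop("feature(s) with all entries masked (run the detection-rate ",
         "filter first): ", paste(all_masked, collapse = ", "))
  fill_for <- function(f) {
    obs <- v[!m[, f], f]
    pos <- obs[obs > 0]
    switch(strategy,
           "half-min" = if (length(pos) > 0) min(pos) / 2 else 0,
           "zero" = 0,
           "global-half-min" = {
             gp <- v[!m][v[!m] > 0]
             if (length(gp) > 0) min(gp) / 2 else 0
           })
  }
  for (f in colnames(v)[colSums(m) > 0]) v[m[, f], f] <- fill_for(f)
  cleared <- m
  cleared[] <- FALSE
  omic_layer_table(v, table$layer_id, lod = table$lod,
                   missing_mask = cleared)
}

#' Elementwise log2 transform
#'
#' @param table an [omic_layer_table()] with all values strictly positive
#'   (impute first).
#' @return The transformed table. Note the result is on the log2 scale and
#'   may contain negative numbers; downstream code treats it as such.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "omic_layer_table"))
  if (any(table$missing_mask))
    stop("masked entries present; impute before log2 transform")
  bad <- which(table$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value at participant '%s', feature '%s'",
                 rownames(table$values)[bad[1, 1]],
                 colnames(table$values)[bad[1, 2]]))
  out <- table
  out$values <- log2(table$values)
  out$scale <- "log2"
  out
}

#' Inverse of [log2_transform()]
#' @param table a log2-scale `omic_layer_table`.
#' @export
log2_inverse <- function(table) {
  out <- table
  out$values <- 2^table$values
  out$scale <- "abundance"
  out
}

#' Drop features with high technical variability
#'
#' Keeps features whose coefficient of variation (replicate SD / replicate
#' mean) across repeated runs of a standard reference sample is strictly
#' below `max_cv`. Features absent from the reference runs, or with a zero
#' replicate mean, are dropped with a warning rather than an error.
#'
#' @param table an [omic_layer_table()] (typically host proteome).
#' @param refs a [reference_replicates()] object.
#' @param max_cv CV cutoff in (0, 1]; default 0.25. The boundary value 1
#'   disables the cutoff, retaining every feature with a positive replicate
#'   mean.
#' @param quiet suppress count messages.
#' @return The filtered table.
#' @export
filter_by_technical_cv <- function(table, refs, max_cv = 0.25,
                                   quiet = FALSE) {
  stopifnot(inherits(table, "omic_layer_table"),
            inherits(refs, "reference_replicates"))
  if (!(max_cv > 0 && max_cv <= 1)) stop("'max_cv' must be in (0, 1]")
  feats <- colnames(table$values)
  absent <- setdiff(feats, rownames(refs$replicate_values))
  if (length(absent) > 0 && !quiet)
    message(sprintf("technical-CV filter: %d feature(s) absent from reference runs, dropped",
                    length(absent)))
  present <- intersect(feats, rownames(refs$replicate_values))
  rv <- refs$replicate_values[present, , drop = FALSE]
  mu <- rowMeans(rv)
  zero_mean <- present[mu == 0]
  if (length(zero_mean) > 0)
    warning("zero replicate mean, feature(s) dropped: ",
            paste(zero_mean, collapse = ", "))
  cv <- rep(Inf, length(present))
  names(cv) <- present
  ok <- mu > 0
  cv[ok] <- apply(rv[ok, , drop = FALSE], 1, sd) / mu[ok]
  keep <- if (max_cv >= 1) present[ok] else present[cv < max_cv]
  if (length(keep) == 0)
    stop("all features removed by technical-CV filter in layer '",
         table$layer_id, "'")
  if (!quiet)
    message(sprintf("technical-CV filter [%s]: %d -> %d features",
                    table$layer_id, length(feats), length(keep)))
  subset_layer(table, features = keep)
}

#' Restrict all layers to participants complete everywhere
#'
#' Keeps only participants that are present, with no masked or missing
#' entries, in every supplied table, and returns all tables with rows in a
#' single consistent order.
#'
#' @param tables a list of [omic_layer_table()] objects.
#' @return A list of tables restricted to the common complete participants.
#' @export
complete_case_filter <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  complete_in <- function(t) {
    ok <- rowSums(t$missing_mask | is.na(t$values)) == 0
    rownames(t$values)[ok]
  }
  common <- Reduce(intersect, lapply(tables, complete_in))
  if (length(common) == 0) {
    counts <- vapply(tables, function(t) nrow(t$values), integer(1))
    stop("no participant is complete across all layers (per-table counts: ",
         paste(counts, collapse = ", "), ")")
  }
  # preserve the participant order of the first table
  common <- intersect(participants(tables[[1]]), common)
  lapply(tables, subset_layer, participants = common)
}
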