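#' Bacterial-protein spectral count table
#'
#' Rows are bacterial proteins with a taxon assignment (genus or species, or
#' the sentinel `"undistinguishable"` for homologous proteins matching more
#' than one genus) and an optional KEGG ko-pathway assignment; columns are
#' participants. Counts are normalized total spectral counts.
#'
#' @param counts numeric protein-by-participant matrix (>= 0) with protein
#'   row names and participant column names.
#' @param taxon character vector, one taxon per protein.
#' @param ko_pathway optional character vector of pathway IDs (`NA` for
#'   unannotated proteins).
#' @param normalized whether `counts` are already normalized to total
#'   protein detected per participant; if `FALSE` use
#'   [normalize_spectral_counts()].
#' @return An object of class `spectral_count_table`.
#' @export
spectral_count_table <- function(counts, taxon, ko_pathway = NULL,
                                 normalized = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have protein row names and participant column names")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("spectral counts must be finite and >= 0")
  if (length(taxon) != nrow(counts))
    stop("need exactly one taxon assignment per protein")
  if (!is.null(ko_pathway) && length(ko_pathway) != nrow(counts))
    stop("'ko_pathway' must have one entry (possibly NA) per protein")
  structure(
    list(counts = counts,
         taxon = setNames(as.character(taxon), rownames(counts)),
         ko_pathway = if (is.null(ko_pathway)) NULL
                      else setNames(as.character(ko_pathway), rownames(counts)),
         normalized = isTRUE(normalized)),
    class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("<spectral_count_table> %d proteins x %d participants; %d taxa%s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$taxon)),
              if (is.null(x$ko_pathway)) "" else
                sprintf("; %d ko-annotated", sum(!is.na(x$ko_pathway)))))
  invisible(x)
}

#' Normalize spectral counts to total protein detected per participant
#'
#' @param table a [spectral_count_table()] with raw counts.
#' @return The table with each participant's column divided by its total.
#' @export
normalize_spectral_counts <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stop("participant(s) with zero total spectral counts: ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  table$counts <- sweep(table$counts, 2, tot, "/")
  table$normalized <- TRUE
  table
}

#' Resolve homologous protein assignments
#'
#' Proteins whose peptides match a single genus keep that genus; proteins
#' matching more than one genus are binned into the sentinel category
#' `"undistinguishable"`.
#'
#' @param raw_assignments named list, protein ID -> character vector of
#'   candidate genera (each non-empty).
#' @return Named character vector, protein ID -> final taxon.
#' @export
bin_homologous_proteins <- function(raw_assignments) {
  stopifnot(is.list(raw_assignments))
  n_cand <- lengths(lapply(raw_assignments, unique))
  if (any(n_cand == 0))
    stop("protein(s) with empty candidate genus set: ",
         paste(names(raw_assignments)[n_cand == 0], collapse = ", "))
  out <- ifelse(n_cand == 1,
                vapply(raw_assignments, function(g) unique(g)[1], character(1)),
                "undistinguishable")
  setNames(out, names(raw_assignments))
}

#' Per-participant taxa abundance profiles
#'
#' Taxon abundance is the sum of normalized spectral counts over all
#' proteins assigned to that taxon, renormalized to proportions per
#' participant.
#'
#' @param table a normalized [spectral_count_table()].
#' @param include_undistinguishable keep the `"undistinguishable"` bin in
#'   the profile (and its mass in the denominator); default `TRUE`.
#' @return A participant-by-taxon matrix of proportions (rows sum to 1).
#' @export
compute_taxa_abundance <- function(table, include_undistinguishable = TRUE) {
  stopifnot(inherits(table, "spectral_count_table"))
  keep <- rep(TRUE, nrow(table$counts))
  if (!include_undistinguishable) keep <- table$taxon != "undistinguishable"
  cnt <- table$counts[keep, , drop = FALSE]
  tax <- table$taxon[keep]
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("participant(s) with zero total counts: ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  sums <- rowsum(cnt, group = tax)
  prop <- t(sweep(sums, 2, tot, "/"))
  prop[, order(colnames(prop)), drop = FALSE]
}

#' Is a participant's microbiome Lactobacillus dominant?
#'
#' Lactobacillus dominance (LD) means strictly more than half of the
#' microbial protein abundance is attributable to *Lactobacillus* — the sum
#' over species-level bins (*L. crispatus*, *L. iners*, ...) and any
#' genus-level *Lactobacillus* bin. A profile summing to exactly 0.5 is nLD.
#'
#' @param profile a participant-by-taxon proportion matrix from
#'   [compute_taxa_abundance()], or a single named proportion vector.
#' @param threshold dominance cutoff (strict `>`); default 0.5.
#' @return Named logical vector, one entry per participant.
#' @export
classify_lactobacillus_dominance <- function(profile, threshold = 0.5) {
  if (is.null(dim(profile))) profile <- t(as.matrix(profile))
  is_lacto <- grepl("^(Lactobacillus|L\\.?[ _])", colnames(profile))
  lsum <- rowSums(profile[, is_lacto, drop = FALSE])
  setNames(lsum > threshold, rownames(profile))
}

#' Bin bacterial proteins to KEGG ko-level pathways
#'
#' Sums counts of annotated proteins per pathway and participant; output is
#' expressed as proportions of the annotated counts (unannotated proteins
#' are excluded from the denominator).
#'
#' @param table a normalized [spectral_count_table()] with `ko_pathway`.
#' @return An [omic_layer_table()] with `layer_id = "bact_function"`.
#' @export
bin_ko_pathways <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  if (is.null(table$ko_pathway)) stop("no ko-pathway annotation present")
  ann <- !is.na(table$ko_pathway) & table$ko_pathway != ""
  if (!any(ann)) stop("no annotated proteins: cannot build function layer")
  cnt <- table$counts[ann, , drop = FALSE]
  path <- table$ko_pathway[ann]
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("participant(s) with zero annotated counts: ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  sums <- rowsum(cnt, group = path)
  prop <- t(sweep(sums, 2, tot, "/"))
  omic_layer_table(prop[, order(colnames(prop)), drop = FALSE],
                   "bact_function")
}

#' Taxonomic composition of one protein or pathway
#'
#' For a pathway, the proportion of its summed counts contributed by each
#' taxon (across all participants); for a single protein, the composition is
#' trivially its own taxon. This backs per-feature taxon pie charts.
#'
#' @param table a [spectral_count_table()].
#' @param feature a protein ID or a ko-pathway ID present in the table.
#' @return Named numeric vector of taxon proportions summing to 1.
#' @export
taxon_composition_of_feature <- function(table, feature) {
  stopifnot(inherits(table, "spectral_count_table"))
  if (feature %in% rownames(table$counts)) {
    idx <- feature
  } else if (!is.null(table$ko_pathway) &&
             feature %in% table$ko_pathway) {
    idx <- names(table$ko_pathway)[!is.na(table$ko_pathway) &
                                   table$ko_pathway == feature]
  } else {
    stop("feature '", feature, "' is neither a protein nor a pathway ID")
  }
  cnt <- table$counts[idx, , drop = FALSE]
  per_tax <- rowsum(rowSums(cnt), group = table$taxon[idx])
  tot <- sum(per_tax)
  if (tot == 0) stop("feature '", feature, "' has zero total counts")
  setNames(as.numeric(per_tax) / tot, rownames(per_tax))
}

#' Bacterial-protein abundance layer
#'
#' Exposes the normalized protein-level counts as a participant-by-protein
#' [omic_layer_table()] (`layer_id = "bact_protein"`) so the proteins can
#' enter group statistics and network screening alongside the other layers.
#'
#' @param table a normalized [spectral_count_table()].
#' @export
as_protein_layer <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  omic_layer_table(t(table$counts), "bact_protein")
}

#' Taxa abundance as an omic layer
#'
#' @param profile matrix from [compute_taxa_abundance()].
#' @export
as_taxa_layer <- function(profile) {
  omic_layer_table(profile, "taxa")
}
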