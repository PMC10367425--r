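#' Participant-by-feature abundance table for one omic layer
#'
#' The basic container used throughout the package: a numeric matrix of
#' non-negative abundances with participants as rows and features as columns,
#' tagged with the omic layer it belongs to. Entries below the limit of
#' detection (or otherwise absent) are recorded in a logical `missing_mask`
#' and held as `NA` in `values` until imputed.
#'
#' @param values numeric matrix, participants x features, with row and column
#'   names. Units are pg/mL for cytokines, percent of live cells for immune
#'   cells, and normalized relative abundance for the other layers.
#' @param layer_id one of `"cytokine"`, `"immune_cell"`, `"host_protein"`,
#'   `"metabolite"`, `"taxa"`, `"bact_function"`, `"bact_protein"`.
#' @param lod optional named numeric vector of per-feature limits of
#'   detection (must be > 0 where present).
#' @param missing_mask optional logical matrix, same shape as `values`,
#'   marking below-LOD/absent entries. Defaults to `is.na(values)`.
#' @param scale `"abundance"` (raw, non-negative; the default) or `"log2"`
#'   (transformed values, may be negative).
#' @return An object of class `omic_layer_table`.
#' @export
omic_layer_table <- function(values, layer_id,
                             lod = NULL, missing_mask = NULL,
                             scale = c("abundance", "log2")) {
  scale <- match.arg(scale)
  layer_id <- match.arg(layer_id, omic_layer_ids())
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have participant row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate participant IDs in layer '", layer_id, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature IDs in layer '", layer_id, "'")
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(values)))
      stop("'missing_mask' must have the same shape as 'values'")
    storage.mode(missing_mask) <- "logical"
  }
  observed <- values[!missing_mask]
  if (any(!is.finite(observed)))
    stop("non-finite unmasked values in layer '", layer_id, "'")
  if (scale == "abundance" && any(observed < 0))
    stop("negative abundances in layer '", layer_id, "'")
  if (!is.null(lod)) {
    if (is.null(names(lod)) || !all(names(lod) %in% colnames(values)))
      stop("'lod' must be named by feature IDs present in the table")
    if (any(!is.finite(lod)) || any(lod <= 0))
      stop("limits of detection must be finite and > 0")
  }
  structure(
    list(layer_id = layer_id, values = values,
         missing_mask = missing_mask, lod = lod, scale = scale),
    class = "omic_layer_table")
}

omic_layer_ids <- function() {
  c("cytokine", "immune_cell", "host_protein", "metabolite",
    "taxa", "bact_function", "bact_protein")
}

#' @export
print.omic_layer_table <- function(x, ...) {
  cat(sprintf("<omic_layer_table: %s> %d participants x %d features; %d masked entries\n",
              x$layer_id, nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.omic_layer_table <- function(x) dim(x$values)

#' @rdname omic_layer_table
#' @param x an `omic_layer_table`.
#' @export
participants <- function(x) rownames(x$values)

#' @rdname omic_layer_table
#' @export
features <- function(x) colnames(x$values)

# Restrict a table to a subset of features and/or participants without
# touching retained values.
subset_layer <- function(x, features = NULL, participants = NULL) {
  v <- x$values
  m <- x$missing_mask
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]
    m <- m[, features, drop = FALSE]
  }
  if (!is.null(participants)) {
    v <- v[participants, , drop = FALSE]
    m <- m[participants, , drop = FALSE]
  }
  lod <- x$lod
  if (!is.null(lod)) lod <- lod[names(lod) %in% colnames(v)]
  omic_layer_table(v, x$layer_id, lod = lod, missing_mask = m,
                   scale = if (is.null(x$scale)) "abundance" else x$scale)
}

#' Technical reference replicates for variability filtering
#'
#' Repeated measurements of a single standard sample, used to estimate each
#' feature's technical coefficient of variation.
#'
#' @param replicate_values numeric feature-by-replicate matrix with feature
#'   row names; all values must be >= 0.
#' @return An object of class `reference_replicates`.
#' @export
reference_replicates <- function(replicate_values) {
  replicate_values <- as.matrix(replicate_values)
  storage.mode(replicate_values) <- "double"
  if (is.null(rownames(replicate_values)))
    stop("'replicate_values' must have feature row names")
  if (ncol(replicate_values) < 2)
    stop("need at least 2 replicate runs")
  if (any(!is.finite(replicate_values)) || any(replicate_values < 0))
    stop("replicate values must be finite and >= 0")
  structure(list(replicate_values = replicate_values,
                 n_replicates = ncol(replicate_values)),
            class = "reference_replicates")
}

#' Read / write omic layer tables as TSV
#'
#' Tables are stored as tab-delimited text with participants as rows, a
#' mandatory header row, and the participant ID in the first column.
#' Missing entries may be encoded as empty cells or `NA`; an optional
#' sidecar TSV (`feature`, `lod`) carries per-feature limits of detection.
#'
#' @param path file path of the table.
#' @param layer_id layer tag (see [omic_layer_table()]).
#' @param lod_path optional path of the LOD sidecar TSV.
#' @param sep field delimiter, tab by default.
#' @return [read_omic_table()] returns an `omic_layer_table`;
#'   [write_omic_table()] invisibly returns `path`.
#' @export
read_omic_table <- function(path, layer_id, lod_path = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed table (need ID column + >=1 feature): ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate participant IDs in ", path)
  raw <- as.matrix(df[, -1, drop = FALSE])
  raw[which(!is.na(raw) & raw == "")] <- NA  # empty cell encodes a masked entry
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                               dimnames = dimnames(raw)))
  bad <- which(is.na(m) & !is.na(raw) & toupper(trimws(raw)) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                 bad[1, 1], colnames(raw)[bad[1, 2]], path))
  rownames(m) <- ids
  lod <- NULL
  if (!is.null(lod_path)) {
    ldf <- read.delim(lod_path, sep = sep, stringsAsFactors = FALSE)
    lod <- setNames(as.numeric(ldf[[2]]), as.character(ldf[[1]]))
  }
  omic_layer_table(m, layer_id, lod = lod)
}

#' @rdname read_omic_table
#' @param table an `omic_layer_table` to write. Masked entries are written as
#'   `NA`.
#' @export
write_omic_table <- function(table, path, sep = "\t") {
  v <- table$values
  v[table$missing_mask] <- NA_real_
  df <- data.frame(participant = rownames(v), v,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
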