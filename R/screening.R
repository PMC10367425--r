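#' Random-forest Gini screening of a layer's features
#'
#' Fits a random-forest classifier of the inflammation label on the layer's
#' features and returns the `n_top` features by mean decrease in Gini
#' impurity. Ties are broken lexicographically so the selection is
#' deterministic given the seed.
#'
#' @param layer an [omic_layer_table()], complete cases only.
#' @param labels named factor (or character) of inflammation labels covering
#'   the layer's participants.
#' @param n_top number of features to keep (default 5).
#' @param seed integer seed for the forest.
#' @param ntree number of trees (default 500).
#' @return Character vector of the selected feature IDs, most important
#'   first.
#' @export
screen_top_features <- function(layer, labels, n_top = 5, seed = 1,
                                ntree = 500) {
  stopifnot(inherits(layer, "omic_layer_table"))
  y <- labels[participants(layer)]
  if (any(is.na(y))) stop("label missing for some participants")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("label vector is constant: cannot screen")
  x <- layer$values
  if (anyNA(x) || any(layer$missing_mask))
    stop("layer must be complete-case before screening")
  if (n_top > ncol(x)) stop("'n_top' exceeds the number of features")
  fit <- with_seed(seed,
                   randomForest::randomForest(x = x, y = y, ntree = ntree))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(n_top)]
}

#' Median discretization of a layer
#'
#' Codes each feature as 1 when the value is strictly above the cohort
#' median and 0 otherwise. Features in which more than 90% of values tie at
#' the median carry almost no information at this resolution; they are
#' flagged degenerate and excluded with a message.
#'
#' @param layer an [omic_layer_table()] with complete values.
#' @param degenerate_tie_fraction exclusion cutoff for the fraction of
#'   values tied at the median (default 0.9).
#' @return Integer 0/1 matrix (participants x retained features).
#' @export
discretize_by_median <- function(layer, degenerate_tie_fraction = 0.9) {
  stopifnot(inherits(layer, "omic_layer_table"))
  x <- layer$values
  if (anyNA(x) || any(layer$missing_mask))
    stop("layer must be complete-case before discretization")
  med <- apply(x, 2, median)
  tie_frac <- colMeans(sweep(x, 2, med, "==") )
  degenerate <- tie_frac > degenerate_tie_fraction
  if (any(degenerate))
    message("excluding degenerate feature(s) (>90% tied at median): ",
            paste(colnames(x)[degenerate], collapse = ", "))
  keep <- which(!degenerate)
  if (length(keep) == 0) stop("all features degenerate at the median")
  out <- (sweep(x[, keep, drop = FALSE], 2, med[keep], ">")) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Assemble the discrete network input
#'
#' Screens each layer with [screen_top_features()], discretizes the selected
#' features by cohort median, and appends the 3-state inflammation variable,
#' producing the [discrete_matrix()] consumed by the structure-learning
#' functions.
#'
#' @param layers named list of complete-case [omic_layer_table()]s (one per
#'   omic layer), all over the same participants.
#' @param assignment data.frame from [cluster_inflammation_groups()].
#' @param n_top features to keep per layer (default 5).
#' @param seed integer seed (one sub-seed per layer is derived from it).
#' @param screen_on `"continuous"` (default) screens the raw layer values;
#'   `"discrete"` screens the median-discretized values.
#' @return A [discrete_matrix()] with `n_top * length(layers) + 1`
#'   variables.
#' @export
build_network_input <- function(layers, assignment, n_top = 5, seed = 1,
                                screen_on = c("continuous", "discrete")) {
  screen_on <- match.arg(screen_on)
  stopifnot(is.list(layers), length(layers) >= 1)
  labels <- setNames(as.character(assignment$group), assignment$participant)
  ids <- participants(layers[[1]])
  seeds <- derive_seeds(seed, length(layers))
  cols <- list()
  tags <- character(0)
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (!identical(participants(layer), ids))
      stop("layers must share one participant order (run complete_case_filter)")
    screen_layer <- layer
    if (screen_on == "discrete") {
      dm <- discretize_by_median(layer)
      screen_layer <- omic_layer_table(dm + 0.0, layer$layer_id)
    }
    top <- screen_top_features(screen_layer, labels, n_top = n_top,
                               seed = seeds[i])
    disc <- discretize_by_median(subset_layer(layer, features = top))
    cols[[i]] <- disc
    tags <- c(tags, rep(layer$layer_id, ncol(disc)))
  }
  m <- do.call(cbind, cols)
  infl <- match(labels[ids], c("low", "medium", "high")) - 1L
  if (anyNA(infl)) stop("inflammation labels must be low/medium/high")
  m <- cbind(m, inflammation = infl)
  tags <- c(tags, "inflammation")
  discrete_matrix(m, layers = tags)
}
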