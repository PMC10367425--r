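#' Ground-truth specification for a synthetic multi-omics cohort
#'
#' Bundles every parameter the generator needs: cohort size and group
#' proportions, per-layer feature counts, per-group log2 effect sizes on the
#' designated differential features, limit-of-detection censoring quantiles,
#' dispersion, the Lactobacillus-dominance mixture, and (optionally) a
#' planted dependence DAG. The defaults describe a cohort of 43 participants
#' split 6 / 25 / 12 across low / medium / high inflammation, with 10
#' curated + 20 extra cytokines, 6 immune-cell types, 200 host proteins, 82
#' metabolites, 19 taxa and 33 ko pathways, and group-wise LD probabilities
#' of 1.00 / 0.64 / 0.58.
#'
#' @param n_participants cohort size.
#' @param group_sizes named integer vector (`low`, `medium`, `high`) summing
#'   to `n_participants`.
#' @param n_cytokines_extra non-panel cytokines beyond the curated 10.
#' @param n_immune_cells,n_host_proteins,n_metabolites feature counts.
#' @param n_taxa,n_ko_pathways,n_bact_proteins metaproteome dimensions.
#' @param effect_sizes named numeric (`medium`, `high`): log2 shift added to
#'   differential features in those groups. Set both to 0 for a null cohort.
#' @param n_diff_proteins,n_diff_metabolites differential feature counts in
#'   the host-protein and metabolite layers.
#' @param lod_quantile marginal censoring quantile for LOD-censored layers.
#' @param sigma log2-scale within-group SD.
#' @param ld_prob named numeric: probability of a Lactobacillus-dominant
#'   microbiome per inflammation group.
#' @param planted_bn optional planted network from [random_planted_bn()];
#'   its variables overwrite matching generated features.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_participants = 43L,
                            group_sizes = c(low = 6L, medium = 25L,
                                            high = 12L),
                            n_cytokines_extra = 20L,
                            n_immune_cells = 6L,
                            n_host_proteins = 200L,
                            n_metabolites = 82L,
                            n_taxa = 19L,
                            n_ko_pathways = 33L,
                            n_bact_proteins = 150L,
                            effect_sizes = c(medium = 1, high = 2),
                            n_diff_proteins = 20L,
                            n_diff_metabolites = 11L,
                            lod_quantile = 0.15,
                            sigma = 1,
                            ld_prob = c(low = 1.00, medium = 0.64,
                                        high = 0.58),
                            planted_bn = NULL) {
  if (sum(group_sizes) != n_participants)
    stop("group sizes must sum to 'n_participants'")
  if (n_diff_proteins > n_host_proteins ||
      n_diff_metabolites > n_metabolites)
    stop("more differential features than features in a layer")
  if (n_bact_proteins < n_taxa)
    stop("need at least one bacterial protein per taxon")
  structure(as.list(environment()), class = "synthetic_truth")
}

# Genus pool shaping the Dirichlet taxa mixture: Lactobacillus-heavy (LD)
# versus Gardnerella/Prevotella-heavy (nLD) communities.
synthetic_taxa_pool <- function(n_taxa) {
  base <- c("L. crispatus", "L. iners", "Lactobacillus_other", "Gardnerella",
            "Prevotella", "Atopobium", "Megasphaera", "Mobiluncus",
            "Sneathia", "Ruminococcus", "Streptococcus", "Staphylococcus",
            "Bifidobacterium", "Dialister", "Anaerococcus", "Finegoldia",
            "Peptoniphilus", "Veillonella", "Escherichia", "Corynebacterium",
            "Aerococcus", "undistinguishable")
  head(base, n_taxa)
}

dirichlet_draw <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws every omic layer with the statistical structure the downstream
#' analysis assumes: log-normal positive abundances with group-specific
#' log2 mean shifts and LOD censoring (cytokines, host proteins,
#' metabolites), logistic-normal immune-cell percentages, Dirichlet taxa
#' profiles from an LD/nLD mixture, and multinomial bacterial-protein
#' spectral counts tagged with taxa and ko pathways. When the truth object
#' carries a planted DAG, ancestral samples from it overwrite the matching
#' features so that the dependence structure is known exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param seed master integer seed; the same seed reproduces the cohort
#'   byte for byte.
#' @return A list with `layers` (named list of [omic_layer_table()]s for all
#'   seven layers), `spectral_counts` (a [spectral_count_table()]),
#'   `reference_replicates`, `assignment` (ground-truth groups and
#'   uq_counts), `ld_truth`, `differential` (per-layer differential feature
#'   IDs), and `truth`.
#' @export
generate_cohort <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(seed, generate_cohort_impl(truth))
}

generate_cohort_impl <- function(truth) {
  n <- truth$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  group <- factor(rep(names(truth$group_sizes), truth$group_sizes),
                  levels = c("low", "medium", "high"), ordered = TRUE)
  names(group) <- ids
  shift <- c(low = 0, truth$effect_sizes)[as.character(group)]

  lognormal_layer <- function(n_feat, prefix, diff_idx, layer_id,
                              censor = TRUE, real_names = NULL) {
    feats <- paste0(prefix, seq_len(n_feat))
    if (!is.null(real_names))
      feats[seq_along(real_names)] <- real_names
    mu <- rnorm(n_feat, mean = 6, sd = 2)           # log2 pg/mL-scale centers
    x <- matrix(rnorm(n * n_feat, sd = truth$sigma), n, n_feat,
                dimnames = list(ids, feats))
    x <- sweep(x, 2, mu, "+")
    if (length(diff_idx) > 0)
      x[, diff_idx] <- x[, diff_idx] + shift
    v <- 2^x
    lod <- NULL
    mask <- matrix(FALSE, n, n_feat, dimnames = dimnames(v))
    if (censor && truth$lod_quantile > 0) {
      lod <- apply(v, 2, quantile, probs = truth$lod_quantile, names = FALSE)
      names(lod) <- feats
      mask <- sweep(v, 2, lod, "<")
      v[mask] <- NA_real_
    }
    omic_layer_table(v, layer_id, lod = lod, missing_mask = mask)
  }

  # cytokines: the curated 10 are the differential features
  cyto <- lognormal_layer(10L + truth$n_cytokines_extra, "CYT",
                          diff_idx = seq_len(10), layer_id = "cytokine",
                          real_names = curated_cytokine_panel())

  # immune cells: logistic-normal percentages of live cells; APC differential
  cell_names <- head(c("APC", "Neutrophils", "CD4_Tcells", "CD8_Tcells",
                       "NK_cells", "B_cells", paste0("Cell",
                       seq_len(max(0, truth$n_immune_cells - 6)))),
                     truth$n_immune_cells)
  logit <- matrix(rnorm(n * truth$n_immune_cells, sd = 1),
                  n, truth$n_immune_cells,
                  dimnames = list(ids, cell_names))
  logit <- sweep(logit, 2, c(0.5, 1.5, 1.2, 0.8, 0, -0.5)[
    seq_len(truth$n_immune_cells)], "+")
  logit[, "APC"] <- logit[, "APC"] + shift * log(2)
  pct <- t(apply(logit, 1, function(z) 100 * exp(z) / sum(exp(z))))
  immune <- omic_layer_table(pct, "immune_cell")

  # host proteome (+ technical reference replicates, 7 runs)
  prot_names <- c("SCEL", "IVL", "SERPINB3",
                  paste0("PROT", seq_len(truth$n_host_proteins - 3)))
  diff_prot <- seq_len(truth$n_diff_proteins)
  host <- lognormal_layer(truth$n_host_proteins, "PROT", diff_prot,
                          "host_protein", censor = FALSE,
                          real_names = prot_names)
  ref_mu <- 2^rnorm(truth$n_host_proteins, 6, 2)
  ref_cv <- runif(truth$n_host_proteins, 0.03, 0.45)
  refs <- matrix(rnorm(truth$n_host_proteins * 7, mean = 1,
                       sd = rep(ref_cv, 7)),
                 truth$n_host_proteins, 7)
  refs <- pmax(refs * ref_mu, 0)
  rownames(refs) <- features(host)
  refs <- reference_replicates(refs)

  # metabolites; a handful of named compounds lead the differential set
  metab_names <- c("xanthine", "lactate", "succinate", "adenosine",
                   "hexose", "hexose-phosphate", "homovanillate",
                   "phenyllactate", "inosine", "glycine", "serine",
                   paste0("MET", seq_len(truth$n_metabolites - 11)))
  metab <- lognormal_layer(truth$n_metabolites, "MET",
                           seq_len(truth$n_diff_metabolites), "metabolite",
                           real_names = metab_names)

  # microbiome: LD mixture of Dirichlet communities drives the taxa profile
  taxa <- synthetic_taxa_pool(truth$n_taxa)
  ld <- rbinom(n, 1, truth$ld_prob[as.character(group)]) == 1
  names(ld) <- ids
  alpha_ld <- setNames(rep(0.2, length(taxa)), taxa)
  alpha_ld[c("L. crispatus", "L. iners", "Lactobacillus_other")] <-
    c(20, 8, 4)
  alpha_ld["Gardnerella"] <- 1
  alpha_nld <- setNames(rep(0.3, length(taxa)), taxa)
  alpha_nld[c("Gardnerella", "Prevotella", "Atopobium", "L. iners")] <-
    c(10, 5, 3, 3)
  alpha_nld["L. crispatus"] <- 0.5
  taxa_prob <- t(vapply(ids, function(i)
    dirichlet_draw(if (ld[[i]]) alpha_ld else alpha_nld),
    numeric(length(taxa))))
  colnames(taxa_prob) <- taxa

  # bacterial proteins: each belongs to one taxon; within-taxon weights are
  # fixed; counts are multinomial and then normalized per participant
  # every taxon in the pool gets at least one protein; the rest are drawn
  # in proportion to the mixture's expected abundance
  prot_tax <- c(taxa,
                sample(taxa, truth$n_bact_proteins - length(taxa),
                       replace = TRUE,
                       prob = (alpha_ld + alpha_nld) /
                         sum(alpha_ld + alpha_nld)))
  bp_names <- sprintf("BP%03d", seq_len(truth$n_bact_proteins))
  w <- rgamma(truth$n_bact_proteins, shape = 1.5, rate = 1) + 0.05
  pathways <- sprintf("ko_path%02d", seq_len(truth$n_ko_pathways))
  ko <- rep(NA_character_, truth$n_bact_proteins)
  annotated <- runif(truth$n_bact_proteins) < 0.55
  ko[annotated] <- sample(pathways, sum(annotated), replace = TRUE)
  counts <- matrix(0, truth$n_bact_proteins, n,
                   dimnames = list(bp_names, ids))
  for (i in seq_len(n)) {
    pr <- taxa_prob[i, prot_tax] * w
    counts[, i] <- as.numeric(stats::rmultinom(1, size = 2000,
                                               prob = pr / sum(pr)))
  }
  # guard against empty columns in tiny configurations
  zero <- colSums(counts) == 0
  if (any(zero)) counts[1, zero] <- 1
  sct <- normalize_spectral_counts(
    spectral_count_table(counts, prot_tax, ko_pathway = ko,
                         normalized = FALSE))

  taxa_profile <- compute_taxa_abundance(sct)
  layers <- list(
    cytokine = cyto,
    immune_cell = immune,
    host_protein = host,
    metabolite = metab,
    taxa = as_taxa_layer(taxa_profile),
    bact_function = bin_ko_pathways(sct),
    bact_protein = as_protein_layer(sct))

  # optionally overwrite designated features with samples from a planted DAG
  if (!is.null(truth$planted_bn)) {
    dm <- sample_discrete_from_dag(truth$planted_bn, n)
    for (v in colnames(dm$values)) {
      for (ln in names(layers)) {
        if (v %in% features(layers[[ln]])) {
          base_v <- layers[[ln]]$values[, v]
          layers[[ln]]$values[, v] <-
            2^(6 + 2 * dm$values[, v] + rnorm(n, sd = 0.25))
        }
      }
    }
  }

  assignment <- data.frame(participant = ids, group = group,
                           uq_count = NA_integer_,
                           stringsAsFactors = FALSE)
  list(layers = layers, spectral_counts = sct,
       reference_replicates = refs,
       assignment = assignment, ld_truth = ld,
       differential = list(
         cytokine = curated_cytokine_panel(),
         immune_cell = "APC",
         host_protein = features(host)[diff_prot],
         metabolite = features(metab)[seq_len(truth$n_diff_metabolites)]),
       truth = truth)
}

#' Random planted Bayesian network
#'
#' Builds a random DAG over `p` binary variables (each node draws up to
#' `max_parents` parents from its predecessors in a random topological
#' order) with strong conditional probability tables: roots are fair coins
#' and children follow the parity of their parents with probability
#' `strength`. Used as ground truth for structure-recovery simulations.
#'
#' @param p number of variables.
#' @param max_parents cap on parents per node (default 2).
#' @param edge_prob probability of wiring each candidate parent.
#' @param strength CPT determinism in (0.5, 1); default 0.9.
#' @param seed integer seed.
#' @return list with `nodes`, `dag` (a [dag_structure()]), `parents`, and
#'   `cpt` (per node, P(X = 1) for each parent configuration, parents in
#'   column order).
#' @export
random_planted_bn <- function(p = 10, max_parents = 2, edge_prob = 0.4,
                              strength = 0.9, seed = 1) {
  with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(p))
    ord <- sample(nodes)
    parents <- setNames(vector("list", p), nodes)
    for (i in seq_along(ord)) {
      if (i == 1) next
      pool <- ord[seq_len(i - 1)]
      cand <- pool[runif(length(pool)) < edge_prob]
      if (length(cand) > max_parents)
        cand <- sample(cand, max_parents)
      parents[[ord[i]]] <- sort(cand)
    }
    cpt <- lapply(nodes, function(v) {
      np <- length(parents[[v]])
      if (np == 0) return(0.5)
      # noisy-OR: each active parent independently pushes the child on,
      # so every parent-child pair carries strong marginal dependence
      cfg <- expand.grid(rep(list(0:1), np))
      leak <- 1 - strength
      pmin(1 - (1 - leak) * (1 - strength)^rowSums(cfg), strength)
    })
    names(cpt) <- nodes
    edges <- do.call(rbind, lapply(nodes, function(v) {
      if (length(parents[[v]]) == 0) return(NULL)
      cbind(from = parents[[v]], to = v)
    }))
    list(nodes = nodes, dag = dag_structure(nodes, edges),
         parents = parents, cpt = cpt)
  })
}

#' Ancestral sampling from a planted network
#'
#' Samples `n` complete rows from a [random_planted_bn()]-style object by
#' drawing each node given its parents in topological order.
#'
#' @param bn a planted network (`nodes`, `parents`, `cpt`).
#' @param n number of rows.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so the generator can embed the draw in a seeded run).
#' @return A [discrete_matrix()] of 0/1 states.
#' @export
sample_discrete_from_dag <- function(bn, n, seed = NULL) {
  draw <- function() {
    if (is.null(bn$cpt)) stop("planted network is missing its CPTs")
    nodes <- bn$nodes
    x <- matrix(NA_integer_, n, length(nodes),
                dimnames = list(sprintf("S%04d", seq_len(n)), nodes))
    remaining <- nodes
    while (length(remaining) > 0) {
      ready <- remaining[vapply(remaining, function(v)
        all(bn$parents[[v]] %in% setdiff(nodes, remaining)), logical(1))]
      if (length(ready) == 0) stop("planted graph is not acyclic")
      for (v in ready) {
        pa <- bn$parents[[v]]
        pr <- if (length(pa) == 0) rep(bn$cpt[[v]][1], n) else {
          idx <- 1 + as.vector(x[, pa, drop = FALSE] %*%
                                 2^(seq_along(pa) - 1))
          bn$cpt[[v]][idx]
        }
        x[, v] <- rbinom(n, 1, pr)
      }
      remaining <- setdiff(remaining, ready)
    }
    discrete_matrix(x, arity = rep(2L, length(nodes)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
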