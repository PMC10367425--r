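test_that("the same master seed reproduces the cohort exactly", {
  tr <- synthetic_truth()
  a <- generate_cohort(tr, seed = 101)
  b <- generate_cohort(tr, seed = 101)
  expect_identical(a$layers$cytokine$values, b$layers$cytokine$values)
  expect_identical(a$spectral_counts$counts, b$spectral_counts$counts)
  expect_identical(a$ld_truth, b$ld_truth)
  c <- generate_cohort(tr, seed = 102)
  expect_false(identical(a$layers$cytokine$values,
                         c$layers$cytokine$values))
})

test_that("cohort dimensions and layer tags follow the truth object", {
  tr <- synthetic_truth()
  co <- generate_cohort(tr, seed = 7)
  expect_identical(names(co$layers),
                   c("cytokine", "immune_cell", "host_protein", "metabolite",
                     "taxa", "bact_function", "bact_protein"))
  expect_identical(dim(co$layers$cytokine$values), c(43L, 30L))
  expect_identical(dim(co$layers$host_protein$values), c(43L, 200L))
  expect_identical(dim(co$layers$metabolite$values), c(43L, 82L))
  expect_identical(ncol(co$layers$taxa$values), 19L)
  expect_lte(ncol(co$layers$bact_function$values), 33L)
  expect_identical(co$reference_replicates$n_replicates, 7L)
  expect_true(all(curated_cytokine_panel() %in%
                    features(co$layers$cytokine)))
  expect_identical(as.vector(table(co$assignment$group)), c(6L, 25L, 12L))
  expect_error(synthetic_truth(n_diff_metabolites = 200L),
               "more differential")
})

test_that("LOD censoring hits the configured marginal quantile", {
  co <- generate_cohort(synthetic_truth(), seed = 19)
  frac <- mean(co$layers$cytokine$missing_mask)
  expect_lt(abs(frac - 0.15), 0.05)
  # taxa proportions are compositional
  expect_equal(unname(rowSums(co$layers$taxa$values)), rep(1, 43),
               tolerance = 1e-9)
})

test_that("the LD mixture reproduces the target dominance fraction", {
  fracs <- vapply(1:30, function(s) {
    co <- generate_cohort(synthetic_truth(n_host_proteins = 5L,
                                          n_metabolites = 12L,
                                          n_diff_proteins = 0L,
                                          n_diff_metabolites = 0L), seed = s)
    mean(classify_lactobacillus_dominance(
      compute_taxa_abundance(co$spectral_counts)))
  }, numeric(1))
  # expected fraction (6*1.00 + 25*0.64 + 12*0.58)/43 ~ 0.673
  expect_lt(abs(mean(fracs) - 29 / 43), 3 * sqrt(0.673 * 0.327 / (30 * 43)))
})

test_that("planted group effects give the rank test its expected power", {
  # a 2-SD log2 shift on a cytokine at n = 43: KW should reject
  rejections <- vapply(1:100, function(s) {
    co <- generate_cohort(synthetic_truth(n_cytokines_extra = 0L,
                                          n_host_proteins = 5L,
                                          n_metabolites = 12L,
                                          n_diff_proteins = 0L,
                                          n_diff_metabolites = 0L,
                                          effect_sizes = c(medium = 2,
                                                           high = 2),
                                          lod_quantile = 0),
                          seed = 500 + s)
    g <- setNames(as.character(co$assignment$group),
                  co$assignment$participant)
    kruskal_wallis(co$layers$cytokine$values[, "IL-6"],
                   g[participants(co$layers$cytokine)])$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("ancestral sampling honors the planted CPTs", {
  # root with P(1) = 1 gives a constant column
  bn1 <- list(nodes = "X", parents = list(X = character(0)),
              cpt = list(X = 1))
  d1 <- sample_discrete_from_dag(bn1, 50, seed = 1)
  expect_true(all(d1$values[, "X"] == 1))
  # deterministic chain X -> Y copies the column
  bn2 <- list(nodes = c("X", "Y"),
              parents = list(X = character(0), Y = "X"),
              cpt = list(X = 0.5, Y = c(0, 1)))
  d2 <- sample_discrete_from_dag(bn2, 300, seed = 2)
  expect_identical(d2$values[, "X"], d2$values[, "Y"])
  # empirical joint matches the CPT-implied joint at n = 10,000
  bn3 <- random_planted_bn(3, seed = 3)
  d3 <- sample_discrete_from_dag(bn3, 10000, seed = 4)
  # implied joint by enumeration over the 8 states
  states <- expand.grid(rep(list(0:1), 3))
  names(states) <- bn3$nodes
  p_state <- vapply(seq_len(nrow(states)), function(i) {
    prod(vapply(bn3$nodes, function(v) {
      pa <- bn3$parents[[v]]
      pr1 <- if (length(pa) == 0) bn3$cpt[[v]][1] else
        bn3$cpt[[v]][1 + sum(unlist(states[i, pa]) * 2^(seq_along(pa) - 1))]
      if (states[i, v] == 1) pr1 else 1 - pr1
    }, numeric(1)))
  }, numeric(1))
  emp <- as.vector(table(factor(
    d3$values[, 1] + 2 * d3$values[, 2] + 4 * d3$values[, 3],
    levels = 0:7))) / 10000
  key <- states[[bn3$nodes[1]]] + 2 * states[[bn3$nodes[2]]] +
    4 * states[[bn3$nodes[3]]]
  expect_true(all(abs(emp[order(key)] - p_state[order(key)]) <
                    3 * sqrt(p_state[order(key)] *
                               (1 - p_state[order(key)]) / 10000) + 0.005))
  # missing CPT errors
  bn_bad <- list(nodes = "X", parents = list(X = character(0)), cpt = NULL)
  expect_error(sample_discrete_from_dag(bn_bad, 10, seed = 1), "CPT")
})

test_that("planted differential features dominate screening", {
  hits <- 0
  for (s in 1:20) {
    co <- generate_cohort(synthetic_truth(n_host_proteins = 5L,
                                          n_metabolites = 12L,
                                          n_diff_metabolites = 0L,
                                          n_diff_proteins = 0L,
                                          lod_quantile = 0), seed = 700 + s)
    g <- setNames(as.character(co$assignment$group),
                  co$assignment$participant)
    top <- screen_top_features(co$layers$cytokine, g, n_top = 5,
                               seed = s, ntree = 300)
    hits <- hits + (mean(top %in% curated_cytokine_panel()) >= 0.6)
  }
  expect_gte(hits / 20, 0.9)
})
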