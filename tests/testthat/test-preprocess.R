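censored_layer <- function(n_missing_per_feature, n = 10, lod = NULL,
                           layer_id = "cytokine") {
  k <- length(n_missing_per_feature)
  v <- matrix(runif(n * k, 1, 10), n, k,
              dimnames = list(sprintf("P%02d", 1:n), paste0("F", 1:k)))
  for (j in seq_len(k)) if (n_missing_per_feature[j] > 0)
    v[seq_len(n_missing_per_feature[j]), j] <- NA
  omic_layer_table(v, layer_id, lod = lod)
}

test_that("detection-rate filter removes features at or above the cutoff", {
  set.seed(1)
  # features missing in 3, 4, 5 of 10 samples: only the first survives 0.40
  t1 <- censored_layer(c(3, 4, 5))
  out <- filter_by_detection_rate(t1, 0.40, quiet = TRUE)
  expect_identical(features(out), "F1")
  # a fully observed feature is retained unchanged
  t2 <- censored_layer(c(0, 4))
  out2 <- filter_by_detection_rate(t2, 0.40, quiet = TRUE)
  expect_identical(features(out2), "F1")
  expect_identical(out2$values[, "F1"], t2$values[, "F1"])
  expect_identical(participants(out2), participants(t2))
  expect_error(filter_by_detection_rate(censored_layer(c(5, 6)), 0.4,
                                        quiet = TRUE),
               "all features removed")
  expect_error(filter_by_detection_rate(t1, 0), "max_missing_fraction")
})

test_that("half-LOD imputation fills masked cells with lod/2 per feature", {
  t1 <- censored_layer(c(1, 1), lod = c(F1 = 2, F2 = 8))
  out <- impute_half_min_lod(t1)
  expect_identical(out$values[1, "F1"], 1)
  expect_identical(out$values[1, "F2"], 4)
  expect_false(any(out$missing_mask))
  # untouched elsewhere
  expect_identical(out$values[-1, ], t1$values[-1, ])
  # empty mask: identity
  t2 <- censored_layer(c(0, 0))
  expect_identical(impute_half_min_lod(t2), t2)
  # missing LOD is an error naming the feature
  t3 <- censored_layer(c(1, 0), lod = NULL)
  expect_error(impute_half_min_lod(t3), "F1")
})

test_that("zero-replacement imputation uses half the feature minimum", {
  v <- matrix(c(4, 8, NA, 10, NA, 6), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("m1", "m2")))
  t1 <- omic_layer_table(v, "metabolite")
  out <- impute_zero_replacement(t1)
  expect_identical(out$values["P3", "m1"], 2)
  expect_identical(out$values["P2", "m2"], 3)
  expect_false(any(out$missing_mask))
  # identity with no mask; layer restriction; all-masked error
  t2 <- omic_layer_table(matrix(5, 3, 1, dimnames = list(paste0("P", 1:3),
                                                         "m1")),
                         "metabolite")
  expect_identical(impute_zero_replacement(t2), t2)
  expect_error(impute_zero_replacement(make_layer(matrix(1, 2, 1))),
               "metabolite")
  v3 <- v; v3[, 1] <- NA
  expect_error(impute_zero_replacement(omic_layer_table(v3, "metabolite")),
               "m1")
  # literal-zero strategy
  out0 <- impute_zero_replacement(t1, strategy = "zero")
  expect_identical(out0$values["P3", "m1"], 0)
})

test_that("log2 transform is exact and invertible", {
  t1 <- make_layer(matrix(c(8, 1, 2, 4), 2, 2))
  out <- log2_transform(t1)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(log2_inverse(out)$values, t1$values, tolerance = 1e-12)
  t2 <- make_layer(matrix(c(1, 0, 2, 4), 2, 2))
  expect_error(log2_transform(t2), "P02.*F1")
})

test_that("technical-CV filter applies the strict replicate-CV cutoff", {
  v <- matrix(5, 2, 3, dimnames = list(c("P1", "P2"), c("a", "b", "c")))
  layer <- omic_layer_table(v, "host_protein")
  refs <- reference_replicates(rbind(
    a = c(10, 10),   # CV 0: kept
    b = c(1, 3),     # mean 2, SD sqrt(2): CV ~0.707, removed
    z = c(5, 5)))
  # feature c absent from refs: dropped, not an error
  expect_message(out <- filter_by_technical_cv(layer, refs, 0.25),
                 "absent from reference")
  expect_identical(features(out), "a")
  # sanity: the closed-form CV of {1,3}
  expect_equal(sd(c(1, 3)) / mean(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  # zero replicate mean: warning + drop, not a crash
  layer_ab <- omic_layer_table(v[, c("a", "b")], "host_protein")
  refs0 <- reference_replicates(rbind(a = c(10, 10), b = c(0, 0)))
  expect_warning(out0 <- filter_by_technical_cv(layer_ab, refs0, 0.25,
                                                quiet = TRUE),
                 "zero replicate mean")
  expect_identical(features(out0), "a")
  # max_cv = 1 keeps every feature with positive replicate mean
  refs1 <- reference_replicates(rbind(a = c(1, 9), b = c(2, 3), c = c(4, 4)))
  expect_identical(features(filter_by_technical_cv(layer, refs1, 1,
                                                   quiet = TRUE)),
                   c("a", "b", "c"))
})

test_that("complete-case filter intersects complete participants in order", {
  v1 <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  v2 <- matrix(1, 3, 2, dimnames = list(c("B", "C", "D"), c("u", "v")))
  out <- complete_case_filter(list(make_layer(v1), make_layer(v2)))
  expect_identical(participants(out[[1]]), c("B", "C"))
  expect_identical(participants(out[[2]]), c("B", "C"))
  # identical sets: identity
  out2 <- complete_case_filter(list(make_layer(v1)))
  expect_identical(participants(out2[[1]]), c("A", "B", "C"))
  # 43 participants, one layer missing 4 rows -> 39 retained
  ids <- sprintf("P%02d", 1:43)
  big1 <- matrix(1, 43, 2, dimnames = list(ids, c("x", "y")))
  big2 <- matrix(1, 39, 2, dimnames = list(ids[1:39], c("u", "v")))
  out3 <- complete_case_filter(list(make_layer(big1), make_layer(big2)))
  expect_identical(nrow(out3[[1]]$values), 39L)
  # empty intersection errors with per-table counts
  v3 <- matrix(1, 1, 1, dimnames = list("Z", "w"))
  expect_error(complete_case_filter(list(make_layer(v1), make_layer(v3))),
               "no participant")
})

test_that("imputation is idempotent and filtering precedes it cleanly", {
  set.seed(42)
  for (rep in 1:5) {
    t1 <- censored_layer(sample(0:3, 4, replace = TRUE),
                         lod = c(F1 = 1, F2 = 2, F3 = 3, F4 = 4))
    once <- impute_half_min_lod(t1)
    expect_identical(impute_half_min_lod(once), once)
    # threshold 1.0 keeps any feature with >= 1 observation; imputing then
    # leaves no masked entries
    kept <- filter_by_detection_rate(t1, 1.0, quiet = TRUE)
    expect_false(any(impute_half_min_lod(kept)$missing_mask))
  }
})
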