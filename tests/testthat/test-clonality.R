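test_that("normalized VAFs follow the specimen-maximum definition", {
  # a single mutation always normalizes to 1 and is clonal
  one <- make_calls(vaf = 0.07)
  nv1 <- normalize_vafs(one)
  expect_equal(nv1$normalized_vaf, 1)
  expect_true(nv1$clonal)

  # 0.19 / 0.40 = 0.475 < 0.5: subclonal
  two <- make_calls(vaf = c(0.40, 0.19), pos = c(10L, 20L))
  nv2 <- normalize_vafs(two)
  expect_equal(nv2$normalized_vaf, c(1, 0.475))
  expect_identical(nv2$clonal, c(TRUE, FALSE))

  # the boundary 0.5 is inclusive (clonal)
  tie <- make_calls(vaf = c(0.4, 0.2), pos = c(10L, 20L))
  expect_true(all(normalize_vafs(tie)$clonal))

  expect_equal(nrow(normalize_vafs(make_calls()[0, ])), 0)
})

test_that("normalization is invariant to rescaling all VAFs", {
  set.seed(2)
  vafs <- round(runif(12, 0.02, 0.45), 3)
  base <- normalize_vafs(make_calls(vaf = vafs, pos = 1:12 * 10L))
  for (c_ in c(0.1, 0.5, 0.9)) {
    scaled <- normalize_vafs(make_calls(vaf = vafs * c_, pos = 1:12 * 10L))
    expect_equal(scaled$normalized_vaf, base$normalized_vaf)
    expect_identical(scaled$clonal, base$clonal)
  }
})

test_that("partitioning splits shared and component-specific mutations", {
  s <- make_calls(component = "stroma", pos = c(10L, 20L, 30L))
  n <- make_calls(component = "neoplasm", pos = c(10L, 20L, 40L, 50L))
  part <- partition_mutations(s, n)
  expect_length(part$shared, 2)
  expect_length(part$stroma_specific, 1)
  expect_length(part$neoplasm_specific, 2)
  # conservation
  expect_equal(length(part$shared) + length(part$stroma_specific), 3)
  expect_equal(length(part$shared) + length(part$neoplasm_specific), 4)

  ident <- partition_mutations(n, n)
  expect_length(ident$shared, 4)
  expect_length(ident$stroma_specific, 0)
  expect_length(ident$neoplasm_specific, 0)

  disjoint <- partition_mutations(make_calls(component = "stroma", pos = 99L), n)
  expect_length(disjoint$shared, 0)

  other <- make_calls(patient_id = "P02", component = "stroma", pos = 10L)
  expect_error(partition_mutations(other, n), "different patients")
})

test_that("the landmark cohort partitions into 114 / 13 / 134", {
  fx <- landmark_cohort()
  totals <- c(shared = 0L, s_spec = 0L, n_spec = 0L)
  for (p in unique(fx$neoplasm$patient_id)) {
    part <- partition_mutations(fx$stroma[fx$stroma$patient_id == p, ],
                                fx$neoplasm[fx$neoplasm$patient_id == p, ])
    totals <- totals + c(length(part$shared), length(part$stroma_specific),
                         length(part$neoplasm_specific))
  }
  expect_equal(unname(totals), c(114L, 13L, 134L))
  expect_equal(nrow(fx$stroma), 127)
  expect_equal(nrow(fx$neoplasm), 248)
})

test_that("landmark clonality proportions reproduce the printed fractions", {
  fs <- fixture_summary()
  expect_equal(fs$shared_clonal_stroma, 99)        # 86.8% of 114
  expect_equal(fs$both_clonal, 96)                 # 84.2% of 114
  expect_equal(fs$nspec_clonal, 72)                # 53.7% of 134
  expect_equal(fs$nspec_total, 134)
})

test_that("CCF computation matches the purity/copy-number formula", {
  expect_equal(compute_ccf(0.25, purity = 1), 0.5)
  expect_equal(compute_ccf(0.25, purity = 0.5), 1.0)
  expect_warning(out <- compute_ccf(0.6, purity = 0.5), "clipped")
  expect_equal(out, 1.0)
  expect_error(compute_ccf(0.2, purity = 0), "purity")
  # higher copy number dilutes the per-copy VAF
  expect_equal(compute_ccf(0.25, purity = 1, copy_number = 4), 1.0)
})

test_that("clustering collapses identical CCFs and splits separated ones", {
  set.seed(6)
  # one CCF: K = 1
  same <- make_calls(hq_alt_reads = rbinom(10, 1000, 0.45), depth = 1000L,
                     pos = 1:10 * 10L)
  same$vaf <- same$hq_alt_reads / same$depth
  fit1 <- cluster_clones(same, purity = 1, seed = 1)
  expect_equal(fit1$K, 1)

  # two well-separated groups: K = 2 with correct membership
  truth <- rep(c(0.9, 0.2), each = 10)
  alt <- rbinom(20, 1000, truth / 2)
  sep <- make_calls(hq_alt_reads = alt, depth = 1000L, pos = 1:20 * 10L)
  sep$vaf <- sep$hq_alt_reads / sep$depth
  fit2 <- cluster_clones(sep, purity = 1, seed = 1)
  expect_equal(fit2$K, 2)
  expect_equal(fit2$assignment, rep(c(1L, 2L), each = 10))
  # trunk candidate (rank 1) is the high-CCF cluster
  expect_gt(fit2$clusters$mean_ccf[1], fit2$clusters$mean_ccf[2])

  # single mutation: single cluster, no error
  single <- cluster_clones(make_calls(hq_alt_reads = 300L), seed = 1)
  expect_equal(single$K, 1)
})

test_that("clustering is deterministic given the seed", {
  set.seed(44)
  alt <- rbinom(15, 1000, rep(c(0.45, 0.2, 0.05), each = 5))
  calls <- make_calls(hq_alt_reads = alt, depth = 1000L, pos = 1:15 * 10L)
  calls$vaf <- calls$hq_alt_reads / calls$depth
  f1 <- cluster_clones(calls, seed = 7)
  f2 <- cluster_clones(calls, seed = 7)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$clusters, f2$clusters)
})

test_that("EM attains the exhaustive-enumeration optimum on small instances", {
  set.seed(15)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    K_true <- sample(1:3, 1)
    ccf <- sort(runif(K_true, 0.05, 1), decreasing = TRUE)
    z <- sample(seq_len(K_true), n, replace = TRUE)
    depth <- rnbinom(n, size = 15, mu = 1000) + 1L
    alt <- rbinom(n, depth, ccf[z] / 2)
    calls <- make_calls(hq_alt_reads = alt, depth = depth, pos = seq_len(n) * 10L)
    calls$vaf <- calls$hq_alt_reads / calls$depth
    em <- cluster_clones(calls, purity = 1, max_clusters = 3, seed = i,
                         select = "fixed_k")
    bf <- brute_force_clusters(calls, purity = 1, max_clusters = 3)
    expect_gte(em$loglik, bf$loglik - 1e-6)
  }
})

test_that("truncal mutations are called clonal on deep synthetic cohorts", {
  cal <- truncal_clonality_calibration(n_patients = 30, seed = 5)
  expect_gte(cal$rate, 0.95)
  expect_gt(cal$n_truncal, 50)
})
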