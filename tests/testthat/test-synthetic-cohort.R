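test_that("degenerate configuration yields a single-clone, single-driver tree", {
  cfg <- sim_config(n_patients = 1, clone_count_range = c(1, 1),
                    passengers_per_clone = 0, subclonal_driver_prob = 0,
                    trunk_driver_probs = c(KRAS = 1),
                    germline_rate = 0, stroma_private_rate = 0, seed = 1)
  set.seed(1)
  tree <- simulate_clone_tree(cfg)
  expect_length(tree$parent, 1)
  expect_equal(tree$ccf_neoplasm, 1)
  expect_equal(nrow(tree$mutations), 1)
  expect_equal(tree$mutations$gene, "KRAS")
  expect_true(tree$mutations$is_driver)
})

test_that("seeded tree generation is deterministic", {
  cfg <- sim_config(n_patients = 1, seed = 7)
  set.seed(7); t1 <- simulate_clone_tree(cfg)
  set.seed(7); t2 <- simulate_clone_tree(cfg)
  expect_identical(t1, t2)
})

test_that("passenger counts follow the configured Poisson mean", {
  cfg <- sim_config(n_patients = 1, passengers_per_clone = 3,
                    subclonal_driver_prob = 0, seed = 1)
  set.seed(42)
  per_clone <- unlist(lapply(1:3000, function(i) {
    tree <- simulate_clone_tree(cfg)
    tabulate(tree$mutations$clone[!tree$mutations$is_driver],
             nbins = length(tree$parent))
  }))
  # forced minimum of one mutation per clone biases upward by < P(Pois=0)
  expect_gt(mean(per_clone), 2.9)
  expect_lt(mean(per_clone), 3.1)
})

test_that("clone CCFs respect the tree ordering", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  set.seed(11)
  for (i in 1:50) {
    tree <- simulate_clone_tree(cfg)
    for (k in seq_along(tree$parent)[-1]) {
      expect_lte(tree$ccf_neoplasm[k], tree$ccf_neoplasm[tree$parent[k]])
    }
    expect_equal(tree$ccf_neoplasm[1], 1)
  }
})

test_that("stromal seeding realizes every subtype's defining pattern", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  set.seed(5)
  # single-clone tree, target C: the clone is absent from stroma
  cfg1 <- sim_config(n_patients = 1, clone_count_range = c(1, 1), seed = 1)
  tree1 <- simulate_clone_tree(cfg1)
  sC <- seed_stroma(tree1, "C", cfg1)
  expect_equal(sC$ccf_stroma, 0)
  # B on a multi-clone tree: trunk present, at least one clone absent
  repeat {
    tree <- simulate_clone_tree(cfg)
    if (length(tree$parent) >= 3 && any(tree$mutations$is_driver)) break
  }
  sB <- seed_stroma(tree, "B", cfg)
  expect_gt(sB$ccf_stroma[1], 0)
  expect_true(any(sB$ccf_stroma[-1] == 0))
  # A: every clone present, stromal CCF bounded by neoplastic CCF
  sA <- seed_stroma(tree, "A", cfg)
  expect_true(all(sA$ccf_stroma > 0))
  expect_true(all(sA$ccf_stroma <= tree$ccf_neoplasm + 1e-12))
  # B impossible on a single-clone tree
  expect_error(seed_stroma(tree1, "B", cfg1), "impossible")
})

test_that("subtype realizability holds on noise-free presence", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  set.seed(21)
  for (target in c("A", "B", "C", "D")) {
    for (i in 1:25) {
      tree <- NULL; seeding <- NULL
      for (attempt in 1:50) {
        tree_try <- simulate_clone_tree(cfg)
        seeding_try <- tryCatch(seed_stroma(tree_try, target, cfg),
                                error = function(e) NULL)
        if (!is.null(seeding_try)) { tree <- tree_try; seeding <- seeding_try; break }
      }
      muts <- tree$mutations
      in_stroma <- seeding$mut_ccf_stroma > 0
      trunk_muts <- muts$clone == 1
      if (target == "A") {
        expect_true(all(in_stroma))
      } else if (target == "B") {
        expect_true(all(in_stroma[trunk_muts]))
        absent_clones <- setdiff(seq_along(tree$parent),
                                 unique(muts$clone[in_stroma]))
        expect_gt(length(absent_clones), 0)
      } else if (target == "C") {
        expect_false(any(in_stroma))
      } else {
        # D: trunk absent with a later clone present, or trunk present
        # with every trunk driver suppressed
        mode1 <- !any(in_stroma[trunk_muts]) && any(in_stroma)
        mode2 <- any(in_stroma[trunk_muts]) &&
          !any(in_stroma[trunk_muts & muts$is_driver])
        expect_true(mode1 || mode2)
      }
    }
  }
})

test_that("read sampling matches the binomial observation model", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  set.seed(3)
  # CCF 0: no alt reads ever
  r0 <- sample_reads(rep(0, 100), 1, cfg)
  expect_true(all(r0$alt == 0))
  expect_true(all(r0$vaf == 0))
  # heterozygous limit: CCF 1, full cell fraction, expected VAF 0.5
  r1 <- sample_reads(rep(1, 10000), 1, cfg)
  expect_equal(mean(r1$vaf), 0.5, tolerance = 0.01)
  # CCF 0.8 at cell fraction 0.5: expected VAF 0.2
  r2 <- sample_reads(rep(0.8, 10000), 0.5, cfg)
  expect_lt(abs(mean(r2$vaf) - 0.2), 0.005)
  # depth range loosely reproduces the targeted-panel spread
  expect_gt(min(r2$depth), 200)
  expect_lt(max(r2$depth), 2500)
})

test_that("detection is calibrated: true VAF >= 5% survives the filters", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  set.seed(13)
  # CCF * cf / 2 = 0.05  =>  ccf = 0.2 at cf = 0.5
  r <- sample_reads(rep(0.2, 5000), 0.5, cfg)
  detected <- r$alt >= 5 & r$vaf >= 0.01
  expect_gt(mean(detected), 0.99)
})

test_that("clinical simulation censors and stratifies as configured", {
  tt <- data.frame(patient_id = c("a", "b", "c", "d"),
                   neoplasm_like = c(TRUE, TRUE, FALSE, FALSE),
                   stromal_kras = FALSE, stromal_tp53 = FALSE)
  cfg0 <- sim_config(n_patients = 4, censoring_horizon = 0, seed = 1)
  clin0 <- simulate_clinical(tt, cfg0, seed = 2)
  expect_true(all(clin0$dfs_months == 0))
  expect_true(all(!clin0$event))

  # Cox estimate near truth for one seeded draw at n = 200
  hr <- hr_recovery(true_hr = 3, n = 200, replicates = 1, seed = 10)
  expect_gt(hr$estimates[1], 2.0)
  expect_lt(hr$estimates[1], 4.5)
})

test_that("cohort simulation is bit-reproducible and truth-consistent", {
  cfg <- sim_config(n_patients = 4, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$clinical, s2$clinical)
  # stromal CCF never exceeds neoplastic CCF for neoplasm-derived mutations
  for (tr in s1$truth) {
    expect_true(all(tr$mutations$ccf_stroma <= tr$mutations$ccf_neoplasm + 1e-12))
    expect_identical(tr$neoplasm_like, tr$subtype %in% c("A", "B"))
  }
})
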