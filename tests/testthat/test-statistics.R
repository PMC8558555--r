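test_that("prevalence counts patients, not mutations", {
  one <- make_calls(component = "stroma", gene = "KRAS")
  tab <- prevalence_table(one, denominator = 1)
  expect_equal(tab$n_patients, 1L)
  expect_equal(tab$percent, 100)

  # two KRAS mutations in one patient still count once
  two <- make_calls(component = "stroma", gene = "KRAS", pos = c(10L, 20L))
  expect_equal(prevalence_table(two, denominator = 2)$n_patients, 1L)
  expect_equal(prevalence_table(two, denominator = 2)$percent, 50)
})

test_that("landmark prevalences match the printed percentages", {
  fx <- landmark_cohort()
  st <- prevalence_table(fx$stroma, denominator = 39)
  expect_equal(st$percent[st$gene == "KRAS"], 71.8, tolerance = 0.002)
  expect_equal(st$percent[st$gene == "TP53"], 61.5, tolerance = 0.002)
  expect_equal(st$percent[st$gene == "CDKN2A"], 23.1, tolerance = 0.002)
  ne <- prevalence_table(fx$neoplasm, denominator = 50)
  expect_equal(ne$percent[ne$gene == "KRAS"], 94.0)
  expect_equal(ne$percent[ne$gene == "TP53"], 86.0)
})

test_that("Spearman correlation handles monotone and anti-monotone pairs", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  up <- vaf_correlation(x, x^2)          # monotone increasing
  expect_equal(up$rho_squared, 1)
  expect_equal(up$rho, 1)
  down <- vaf_correlation(x, rev(x))     # anti-monotone
  expect_equal(down$rho_squared, 1)
  expect_equal(down$rho, -1)
  expect_error(vaf_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("co-truncal KRAS/TP53 VAFs correlate strongly under shared noise", {
  set.seed(9)
  n <- 20
  tcf <- runif(n, 0.3, 0.9)          # shared purity drives both VAFs
  kras <- rbinom(n, 1000, tcf / 2) / 1000
  tp53 <- rbinom(n, 1000, tcf / 2) / 1000
  expect_gt(vaf_correlation(kras, tp53)$rho_squared, 0.5)
})

test_that("chi-square on the clonality table matches the textbook formula", {
  counts <- matrix(c(99, 15, 72, 62), nrow = 2)  # clonal/subclonal x set
  res <- group_compare("chi_square", counts = counts)
  # independent hand computation: sum (O - E)^2 / E
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat_hand <- sum((counts - E)^2 / E)
  expect_equal(res$statistic, stat_hand)
  expect_lt(res$p, 1e-4)
})

test_that("Mann-Whitney detects a shifted group and respects ties", {
  set.seed(10)
  x <- c(rnorm(30, 0.7, 0.1), rnorm(30, 0.5, 0.1))
  g <- rep(c("mut", "wt"), each = 30)
  res <- group_compare("mann_whitney", x = x, g = g)
  expect_lt(res$p, 0.01)
  expect_error(group_compare("mann_whitney", x = 1:5,
                             g = rep("a", 5)), "two groups")
})

test_that("KM estimator matches the hand-computed product-limit", {
  rec <- data.frame(dfs_months = c(1, 2, 3, 4, 5),
                    event = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                    grp = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  km <- survival::survfit(survival::Surv(rec$dfs_months, rec$event) ~ 1)
  # S(1) = 4/5; S(3) = 4/5 * 2/3; S(4) = 4/5 * 2/3 * 1/2
  expect_equal(summary(km, times = c(1, 3, 4))$surv,
               c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
})

test_that("forced medians: early events vs fully censored group", {
  rec <- data.frame(
    dfs_months = c(rep(1, 5), rep(10, 5)),
    event = c(rep(TRUE, 5), rep(FALSE, 5)),
    grp = rep(c(TRUE, FALSE), each = 5)
  )
  # group 2 has no events: the Cox coefficient diverges (coxph warns) but
  # the KM medians are still well-defined
  expect_warning(sr <- survival_analysis(rec, grouping = "grp"),
                 "infinite")
  expect_equal(sr$median_dfs[sr$groups == "TRUE"], 1)
  expect_true(is.na(sr$median_dfs[sr$groups == "FALSE"]))  # unreached
})

test_that("identical groups give HR near 1 and a large log-rank p", {
  set.seed(20)
  rec <- data.frame(
    dfs_months = rexp(200, 0.1),
    event = TRUE,
    grp = rep(c(TRUE, FALSE), 100)
  )
  sr <- survival_analysis(rec, grouping = "grp")
  expect_gt(sr$logrank_p, 0.05)
  expect_lt(abs(log(sr$hazard_ratio)), 0.35)
  expect_true(sr$ci_lower <= sr$hazard_ratio && sr$hazard_ratio <= sr$ci_upper)
})

test_that("survival errors on degenerate analysis sets", {
  rec <- data.frame(dfs_months = c(1, 2, 3), event = FALSE,
                    grp = c(TRUE, FALSE, TRUE))
  expect_error(survival_analysis(rec, grouping = "grp"), "no relapse events")
  rec2 <- data.frame(dfs_months = 1:4, event = TRUE, grp = TRUE)
  expect_error(survival_analysis(rec2, grouping = "grp"), "single level")
})

test_that("statistics are invariant to patient row order", {
  sim <- simulate_cohort(sim_config(n_patients = 60, seed = 14))
  res <- analyze_cohort(sim$calls, clinical = sim$clinical, seed = 14)
  tab <- merge(sim$clinical, res$subtypes, by = "patient_id")
  set.seed(1)
  perm <- sample(nrow(tab))
  a <- survival_analysis(tab, grouping = "neoplasm_like")
  b <- survival_analysis(tab[perm, ], grouping = "neoplasm_like")
  expect_equal(a$hazard_ratio, b$hazard_ratio)
  expect_equal(a$logrank_p, b$logrank_p)
  ta <- prevalence_table(fixture_summary()$fx$stroma, 39)
  tb <- prevalence_table(fixture_summary()$fx$stroma[sample(127), ], 39)
  expect_equal(ta, tb)
})

test_that("forward LR selection keeps the real predictor, drops noise", {
  set.seed(30)
  n <- 300
  nl <- runif(n) < 0.5
  rec <- data.frame(
    dfs_months = rexp(n, 0.06 * ifelse(nl, 3, 1)),
    event = TRUE,
    neoplasm_like = nl,
    noise1 = rnorm(n),
    noise2 = runif(n) < 0.5
  )
  sr <- survival_analysis(rec, grouping = "neoplasm_like",
                          covariates = c("noise1", "noise2"))
  expect_true("neoplasm_like" %in% sr$multivariate$selected)
})
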