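test_that("event log2 ratio is correct and antisymmetric under channel swap", {
  expect_equal(event_log2_ratio(200, 100), 1)
  expect_equal(event_log2_ratio(100, 100), 0)
  expect_equal(event_log2_ratio(50, 100), -1)
  set.seed(3)
  h <- rlnorm(50, 10, 1); l <- rlnorm(50, 10, 1)
  expect_equal(event_log2_ratio(h, l), -event_log2_ratio(l, h))
  expect_error(event_log2_ratio(0, 100), "positive")
  expect_error(event_log2_ratio(10, -1), "positive")
})

test_that("t-test p-value matches an independent t-CDF oracle", {
  # closed-form oracle: t = mean / (sd / sqrt(n)); p = 2 * P(T_{n-1} <= -|t|)
  oracle <- function(x) 2 * pt(-abs(mean(x) / (sd(x) / sqrt(length(x)))),
                               df = length(x) - 1)
  x <- c(0.3, 0.4, 0.5)
  expect_equal(mean(x) / (sd(x) / sqrt(3)), 6.928203, tolerance = 1e-6)
  expect_equal(ttest_pvalue(x), 0.0202041, tolerance = 1e-5)
  expect_equal(ttest_pvalue(x), oracle(x), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(sample(2:12, 1), sd = 0.4)
    expect_equal(ttest_pvalue(y), oracle(y), tolerance = 1e-12)
  }
})

test_that("t-test handles degenerate inputs as documented", {
  expect_equal(ttest_pvalue(c(-1, 1)), 1)
  expect_equal(ttest_pvalue(rep(0, 4)), 1)
  expect_warning(p <- ttest_pvalue(c(0.3, 0.3, 0.3)), "zero variance")
  expect_true(p > 0 && p < 1e-300)
  expect_error(ttest_pvalue(0.5), "at least 2")
})

test_that("protein rollup averages event log2 ratios", {
  pq <- rollup_protein(make_events("Hp", c(1.0, 0.6, 0.8)))
  expect_equal(pq$mean_log2_ratio, 0.8)
  expect_equal(pq$n_events, 3)
  expect_equal(pq$n_peptides, 3)

  one <- rollup_protein(make_events("Hp", 0.5))
  expect_equal(one$mean_log2_ratio, 0.5)
  expect_true(is.na(one$p_ttest))

  mixed <- dplyr::bind_rows(make_events("Hp", 0.5), make_events("Ccl8", 0.1))
  expect_error(rollup_protein(mixed), "single gene symbol")
})

test_that("peptide-level rollup averages within peptides first", {
  ev <- make_events("Hp", c(0.2, 0.4, 0.9),
                    peptide = c("AAK", "AAK", "CCK"))
  by_event <- rollup_protein(ev, filter_config(rollup = "event"))
  by_pep <- rollup_protein(ev, filter_config(rollup = "peptide"))
  expect_equal(by_event$mean_log2_ratio, 0.5)
  expect_equal(by_pep$mean_log2_ratio, mean(c(0.3, 0.9)))
  expect_equal(by_pep$n_events, 3)   # counts stay event-level
  expect_equal(length(by_pep$event_ratios), 2)
})

test_that("rollup recovers a known shift from many noisy events", {
  set.seed(42)
  n <- 2000
  ev <- make_events("Hp", rnorm(n, mean = 0.5, sd = 0.3),
                    peptide = paste0("P", rep(1:40, each = 50), "K"))
  pq <- rollup_protein(ev)
  expect_equal(pq$mean_log2_ratio, 0.5, tolerance = 0.03)  # ~4.5 x SE
  expect_equal(pq$n_peptides, 40)
})

test_that("the empirical null stores sorted ratios and validates input", {
  nd <- quiet(build_null(c(1, -0.5, 0, 0.5, -1)))
  expect_equal(nd$ratios, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(nd$n, 5)
  expect_error(build_null(numeric(0)), "zero finite")
  expect_warning(quiet_nd <- suppressMessages(build_null(0.2)), "single")
  expect_equal(quiet_nd$n, 1)
})

test_that("empirical p-values follow the smoothed two-sided rank formula", {
  nd <- quiet(build_null(c(-1, -0.5, 0, 0.5, 1)))
  expect_equal(empirical_pvalue(1.2, nd), 1 / 6)
  expect_equal(empirical_pvalue(0, nd), 1)        # least extreme
  expect_equal(empirical_pvalue(-0.75, nd), 3 / 6) # two-sided, |r| >= 0.75

  # brute-force oracle on random data, including ties
  set.seed(5)
  r <- round(rnorm(200, 0, 0.3), 2)
  obs <- round(rnorm(50, 0, 0.5), 2)
  nd2 <- quiet(build_null(r))
  brute <- vapply(obs, function(o) (1 + sum(abs(r) >= abs(o))) / (length(r) + 1),
                  numeric(1))
  expect_equal(empirical_pvalue(obs, nd2), brute)

  # monotone nonincreasing in |observed|
  grid <- seq(0, 1.5, by = 0.01)
  expect_true(all(diff(empirical_pvalue(grid, nd2)) <= 0))
})

test_that("empirical p-values are uniform under their own null", {
  set.seed(99)
  cc <- generate_control_control(
    synth_config(n_proteins = 200, noise_sd = 0.25), seed = 99)
  nd <- quiet(build_null(quiet(filter_for_quantitation(cc))))
  draws <- rnorm(10000, 0, 0.25)
  p <- empirical_pvalue(draws, nd)
  expect_gt(mean(p <= 0.05), 0.04)
  expect_lt(mean(p <= 0.05), 0.06)
})

test_that("the dual significance rule is a recorded disjunction", {
  nd <- quiet(build_null(rnorm(500, 0, 0.2)))
  cfg <- filter_config()

  # t-test route alone
  pq1 <- rollup_protein(make_events("A", c(0.30, 0.32, 0.34)))
  pq1 <- call_significance(pq1, nd, cfg)
  expect_true(pq1$significant)
  expect_equal(pq1$criterion, "ttest")

  # all-events route is the only one open to single-event proteins
  pq2 <- rollup_protein(make_events("B", 1.5))
  pq2 <- call_significance(pq2, nd, cfg)
  expect_true(pq2$significant)
  expect_equal(pq2$criterion, "all-events")

  # neither route: mixed-sign events, one well inside the null spread
  pq3 <- rollup_protein(make_events("C", c(0.45, -0.05)))
  pq3 <- call_significance(pq3, nd, cfg)
  expect_false(pq3$significant)
  expect_equal(pq3$criterion, "none")

  # no null + single event -> unquantifiable for significance
  pq4 <- call_significance(rollup_protein(make_events("D", 0.9)), NULL, cfg)
  expect_true(is.na(pq4$significant))
  expect_equal(pq4$criterion, "unquantifiable")
})

test_that("differential calls require both significance and 1.25-fold", {
  cfg <- filter_config()
  mk <- function(mean, sig) {
    pq <- rollup_protein(make_events("X", mean))  # single event: mean exact
    pq$significant <- sig
    classify_differential(pq, cfg)$direction
  }
  expect_equal(mk(0.35, TRUE), "increased")   # 0.35 >= log2(1.25)
  expect_equal(mk(0.20, TRUE), "unchanged")   # fails fold despite p
  expect_equal(mk(-0.50, FALSE), "unchanged") # fails significance
  expect_equal(mk(log2(1.25), TRUE), "increased")  # tie counts as changed
  expect_equal(mk(-log2(1.25), TRUE), "decreased")
})

test_that("differential counts are monotone nonincreasing in min_fold", {
  syn <- generate_experiment(synth_config(n_proteins = 80), seed = 17)
  cc <- generate_control_control(synth_config(n_proteins = 80), seed = 18)
  nd <- quiet(build_null(quiet(filter_for_quantitation(cc))))
  folds <- c(1.1, 1.25, 1.5, 2)
  counts <- vapply(folds, function(f) {
    prof <- quiet(quantify_profile(syn$events, nd,
                                   filter_config(min_fold = f)))
    length(altered_genes(prof))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
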