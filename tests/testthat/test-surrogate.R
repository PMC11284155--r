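derive_seed_ <- function(a, b) preictal:::derive_seed(a, b)

test_that("surrogate onsets respect spacing, bounds, and determinism", {
  on1 <- surrogate_onsets(0, 20000, 3, spacing = 1200, seed = 5)
  expect_identical(on1, surrogate_onsets(0, 20000, 3, spacing = 1200, seed = 5))
  expect_true(all(diff(on1) >= 1200))
  expect_true(all(on1 >= 1200 & on1 <= 20000))

  # exclusion zones around real onsets
  for (s in 1:50) {
    so <- surrogate_onsets(0, 20000, 2, spacing = 1200,
                           real_onsets = 10000, seed = s)
    expect_true(all(abs(so - 10000) >= 1200))
  }

  expect_error(surrogate_onsets(0, 1000, 1, spacing = 1200), "too short")
  expect_error(surrogate_onsets(0, 5000, 10, spacing = 1200), "separation")
})

test_that("surrogate onsets are uniform over the admissible interval", {
  draws <- vapply(1:1000, function(s) {
    surrogate_onsets(0, 3600, 1, spacing = 1200, seed = s)
  }, 0)
  # admissible interval is [1200, 3600]; uniform mean at its midpoint
  expect_equal(mean(draws), 2400, tolerance = 0.05)
  expect_gt(min(draws), 1200 - 1e-9)
  expect_lt(max(draws), 3600 + 1e-9)
  ks <- stats::ks.test(draws, "punif", 1200, 3600)$p.value
  expect_gt(ks, 0.001)
})

test_that("the decision rule validates real skill and never zero sensitivity", {
  cfg <- pipeline_config(seed = 2)
  # alarms that predict both real onsets perfectly, on a timeline where
  # random onsets rarely land inside the two alarm windows
  onsets <- c(20000, 40000)
  alarms <- onsets - 1500                       # inside [sph, sph+sop]
  res <- surrogate_test_alarm(alarms, onsets, test_start = 0,
                              test_end = 50000, test_duration = 50000,
                              sop = 30, sph = 10, config = cfg)
  expect_equal(res$observed_statistic, 1)
  expect_true(res$validated)

  # observed sensitivity 0 can never validate
  res0 <- surrogate_test_alarm(numeric(0), onsets, 0, 50000, 50000,
                               30, 10, cfg)
  expect_equal(res0$observed_statistic, 0)
  expect_false(res0$validated)
})

test_that("sample surrogate shifts labels circularly and excludes shift 0", {
  cfg <- pipeline_config(seed = 3, n_surrogates = 30)
  truth <- c(rep(0L, 150), rep(1L, 50))   # one preictal block, aperiodic
  perfect <- truth
  res <- surrogate_test_sample(truth, perfect, cfg)
  expect_equal(res$observed_statistic, 1)
  expect_true(res$validated)
  # shift 0 would reproduce the observed statistic exactly; with unbalanced
  # blocks no surrogate shift can reach sensitivity 1
  expect_true(all(res$surrogate_statistics < 1))

  # degenerate: all surrogates equal the observed value -> not validated
  d <- preictal:::surrogate_decision(0.5, rep(0.5, 30), 0.05, "ttest")
  expect_false(d$validated)
  expect_true(d$degenerate)
})

test_that("the rank rule requires the observed value to beat every surrogate", {
  r1 <- preictal:::surrogate_decision(0.9, seq(0, 0.8, length.out = 30),
                                      0.05, "rank")
  expect_true(r1$validated)
  expect_equal(r1$p_value, 1 / 31)
  r2 <- preictal:::surrogate_decision(0.7, seq(0, 0.8, length.out = 30),
                                      0.05, "rank")
  expect_false(r2$validated)
})

test_that("null predictors validate at close to the nominal rate", {
  # quick version of the type-I simulation: random refractory-respecting
  # alarms, real onsets fixed; 100 replications
  cfg <- pipeline_config(seed = 4)
  sop <- 30; sph <- 10
  spacing <- (sop + sph) * 60
  test_dur <- 12 * 3600
  onsets <- c(2.5, 5, 7.5, 10) * 3600
  hits <- 0
  for (rep in 1:100) {
    at <- surrogate_onsets(0, test_dur, 6, spacing,
                           seed = derive_seed_(9000, rep)) - 600
    cfg_r <- pipeline_config(seed = rep)
    res <- surrogate_test_alarm(at, onsets, 0, test_dur, test_dur,
                                sop, sph, cfg_r)
    if (res$validated) hits <- hits + 1
  }
  expect_lte(hits / 100, 0.10)      # guard against anticonservatism
  expect_gte(hits / 100, 0.0)
})

test_that("observed rank among surrogates is near-uniform under the null", {
  # exchangeability sanity at reduced scale: the observed statistic's rank
  # among its surrogates should not concentrate
  cfg <- pipeline_config(seed = 6, n_surrogates = 10)
  sop <- 30; sph <- 10
  test_dur <- 12 * 3600
  onsets <- c(3, 6, 9) * 3600
  ranks <- vapply(1:60, function(rep) {
    at <- surrogate_onsets(0, test_dur, 5, (sop + sph) * 60,
                           seed = derive_seed_(7000, rep)) - 600
    cfg_r <- pipeline_config(seed = 1000 + rep, n_surrogates = 10)
    res <- surrogate_test_alarm(at, onsets, 0, test_dur, test_dur,
                                sop, sph, cfg_r)
    sum(res$surrogate_statistics < res$observed_statistic) +
      0.5 * sum(res$surrogate_statistics == res$observed_statistic)
  }, 0)
  # mean mid-rank should be near 5 (center of 0..10)
  expect_equal(mean(ranks), 5, tolerance = 1.2)
})
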