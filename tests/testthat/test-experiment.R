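test_that("protocol invariants are enforced", {
  expect_s3_class(dialysis_protocol(), "dialysis_protocol")
  expect_error(dialysis_protocol(injection_time = 50), "must equal")
  expect_error(dialysis_protocol(horizon = 170), "divisible")
  expect_error(dialysis_protocol(dt = 0), "positive multiple")
})

test_that("default sampling hits 20-120 min post-injection at absolute 80-180", {
  st <- necsim:::protocol_sample_times(dialysis_protocol())
  expect_equal(st$pre, c(20, 40, 60))
  expect_equal(st$post, c(80, 100, 120, 140, 160, 180))
  expect_equal(st$post_rel, c(20, 40, 60, 80, 100, 120))
})

test_that("baseline is the arithmetic mean of the three pre-injection samples", {
  m <- fixture_cohort_small()[[1]]
  eq <- equilibrium_state(build_linear_system(m$parameters))
  tr <- simulate_circuit(m$parameters, circuit_condition("sham"),
                         initial = eq, horizon = 180)
  expect_equal(baseline_mean(tr, "NE_mPFC"), unname(eq["NE_mPFC"]))
  # hand check on a manipulated trajectory: samples 0.3, 0.4, 0.5 -> 0.4
  tr2 <- tr
  tr2$NE_NAcc[tr2$time_min %in% c(20, 40, 60)] <- c(0.3, 0.4, 0.5)
  expect_equal(baseline_mean(tr2, "NE_NAcc"), 0.4)
})

test_that("percent-of-baseline is scale invariant", {
  m <- fixture_cohort_small()[[1]]
  tr <- simulate_circuit(m$parameters,
                         circuit_condition("sham", kernel = m$kernel),
                         horizon = 180)
  proto <- dialysis_protocol()
  s1 <- necsim:::sample_series(tr, "NE_NAcc", proto, "m", "sham")
  tr$NE_NAcc <- tr$NE_NAcc * 7.3
  s2 <- necsim:::sample_series(tr, "NE_NAcc", proto, "m", "sham")
  expect_equal(s2$pct_baseline, s1$pct_baseline, tolerance = 1e-12)
  expect_equal(s2$raw_pg, s1$raw_pg * 7.3)
})

test_that("run_condition produces flat 100% prefrontal NE under depletion", {
  proto <- dialysis_protocol(cohort_size = 3L, noise_sd = 0)
  run <- run_condition(fixture_cohort_small(), "depleted", proto)
  expect_length(run$failures, 0L)
  dial <- run$dialysis
  mp <- dial[dial$region == "NE_mPFC", ]
  expect_equal(mp$pct_baseline, rep(100, nrow(mp)), tolerance = 1e-12)
  # accumbal NE still responds (the kernel acts on its own damping)
  na <- dial[dial$region == "NE_NAcc", ]
  expect_gt(max(na$pct_baseline), 110)
})

test_that("with the kernel disabled every sample sits at 100% of baseline", {
  proto <- dialysis_protocol(cohort_size = 3L, noise_sd = 0)
  flat <- kernel_parameters(0, 4000, 300, 60)
  run <- run_condition(fixture_cohort_small(), "sham", proto, kernel = flat)
  expect_equal(run$dialysis$pct_baseline, rep(100, nrow(run$dialysis)),
               tolerance = 1e-9)
})

test_that("sham and depleted arms differ only through the depletion switch", {
  m <- fixture_cohort_small()[[1]]
  eq <- equilibrium_state(build_linear_system(m$parameters))
  # depleted condition forced to l = 1 must reproduce the sham trajectory
  sham <- simulate_circuit(m$parameters,
                           circuit_condition("sham", kernel = m$kernel),
                           initial = eq, horizon = 180)
  dep1 <- simulate_circuit(m$parameters,
                           circuit_condition("depleted", kernel = m$kernel,
                                             l = 1),
                           initial = eq, horizon = 180)
  expect_equal(sham[, -1], dep1[, -1], tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("activity summaries partition the run at the injection time", {
  proto <- dialysis_protocol(cohort_size = 3L, noise_sd = 0)
  run <- run_condition(fixture_cohort_small(), "sham", proto)
  act <- run$activity
  expect_setequal(unique(act$region), c("LC", "mPFC", "NTS", "NAcc"))
  expect_equal(nrow(act), 3L * 4L)
  # noiseless sham: post-injection mean above pre-injection mean in NAcc
  na <- act[act$region == "NAcc", ]
  expect_true(all(na$post_mean > na$pre_mean))
})

test_that("comparing a cohort against itself finds nothing", {
  proto <- dialysis_protocol(cohort_size = 3L, noise_sd = 0.05)
  sham <- run_condition(fixture_cohort_small(), "sham", proto)
  # relabel as depleted so the comparison machinery sees two groups
  fake <- sham
  fake$condition_label <- "depleted"
  fake$dialysis$condition <- "depleted"
  fake$activity$condition <- "depleted"
  rep <- compare_experiment(sham, fake)
  for (region in names(rep$ne_timecourse)) {
    sig <- vapply(rep$ne_timecourse[[region]]$per_timepoint, `[[`,
                  logical(1), "significant")
    expect_false(any(sig))
    expect_false(isTRUE(rep$baseline[[region]]$significant))
  }
})

test_that("mismatched protocols are refused", {
  p1 <- dialysis_protocol(cohort_size = 3L, noise_sd = 0)
  p2 <- dialysis_protocol(cohort_size = 3L, noise_sd = 0.05)
  r1 <- run_condition(fixture_cohort_small(), "sham", p1)
  r2 <- run_condition(fixture_cohort_small(), "depleted", p2)
  expect_error(compare_experiment(r1, r2), "different protocols")
})
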