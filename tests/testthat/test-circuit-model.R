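test_that("vector field reproduces direct substitution", {
  p <- example_circuit_parameters()
  p2 <- unclass(p)
  p2[] <- 0.0
  p2[c("tau_LC", "tau_NE_mPFC", "tau_mPFC", "tau_NTS", "tau_NE_NAcc",
       "tau_NAcc")] <- 1
  p2["alpha_LC_mPFC"] <- 1
  p2 <- circuit_parameters(p2)
  st <- c(LC = 1, NE_mPFC = 0, mPFC = 2, NTS = 0, NE_NAcc = 0, NAcc = 0)
  d <- circuit_derivs(st, p2)
  expect_equal(unname(d["LC"]), -1 + 2)  # -tau*LC + alpha*mPFC
  expect_equal(unname(d["NTS"]), 0)
})

test_that("depletion multiplier freezes the prefrontal NE derivative only", {
  p <- example_circuit_parameters()
  st <- c(2, 0.5, 1.8, 1.6, 0.3, 1.4)
  d0 <- circuit_derivs(st, p, l = 0)
  d1 <- circuit_derivs(st, p, l = 1)
  expect_identical(unname(d0["NE_mPFC"]), 0)
  expect_equal(d0[-2], d1[-2])
})

test_that("the equilibrium zeroes the vector field", {
  p <- example_circuit_parameters()
  eq <- equilibrium_state(build_linear_system(p))
  expect_equal(unname(circuit_derivs(eq, p)), rep(0, 6), tolerance = 1e-12)
})

test_that("vector field rejects invalid numeric input", {
  p <- example_circuit_parameters()
  expect_error(circuit_derivs(c(1, NA, 1, 1, 1, 1), p), "non-finite")
  expect_error(circuit_derivs(rep(1, 6), p, k_t = 0), "k_t")
  expect_error(circuit_derivs(rep(1, 6), p, l = 2), "l must")
})

test_that("vector field is affine: its Jacobian is the linear-system matrix", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_stable_params()
    l <- sample(c(0, 0.5, 1), 1)
    k <- stats::runif(1, 0.3, 1)
    state <- stats::runif(6, 0, 3)
    A <- build_linear_system(p, l = l, k_value = k)$A
    expect_equal(unname(numeric_jacobian(p, l, k, state)), unname(A),
                 tolerance = 1e-6)
  }
})

test_that("a trajectory started at equilibrium stays there without noise", {
  p <- example_circuit_parameters()
  eq <- equilibrium_state(build_linear_system(p))
  tr <- simulate_circuit(p, circuit_condition("sham"), initial = eq,
                         horizon = 180)
  expect_equal(nrow(tr), 181L)
  expect_equal(tr$time_min, 0:180)
  for (v in c("LC", "NE_mPFC", "mPFC", "NTS", "NE_NAcc", "NAcc")) {
    expect_equal(tr[[v]], rep(unname(eq[v]), 181), tolerance = 1e-12)
  }
})

test_that("identical inputs and seed give bit-identical noisy trajectories", {
  p <- example_circuit_parameters()
  cond <- circuit_condition("sham", kernel = kernel_parameters(0.5, 4000, 300, 60))
  t1 <- simulate_circuit(p, cond, horizon = 180, noise_sd = 0.05, seed = 11L)
  t2 <- simulate_circuit(p, cond, horizon = 180, noise_sd = 0.05, seed = 11L)
  t3 <- simulate_circuit(p, cond, horizon = 180, noise_sd = 0.05, seed = 12L)
  expect_identical(t1$NAcc, t2$NAcc)
  expect_false(identical(t1$NAcc, t3$NAcc))
})

test_that("simulation does not perturb the caller's RNG stream", {
  p <- example_circuit_parameters()
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(simulate_circuit(p, circuit_condition("sham"), horizon = 10,
                             noise_sd = 0.05, seed = 5L))
  expect_identical(runif(1), before)
})

test_that("depletion keeps prefrontal NE exactly at its start, even with noise", {
  p <- example_circuit_parameters()
  cond <- circuit_condition("depleted",
                            kernel = kernel_parameters(0.5, 4000, 300, 60))
  tr <- simulate_circuit(p, cond, horizon = 180, noise_sd = 0.05, seed = 3L)
  expect_identical(tr$NE_mPFC, rep(tr$NE_mPFC[1], 181L))
})

test_that("cocaine kernel drives NE above baseline and back toward it", {
  m <- fixture_cohort_small()[[1]]
  eq <- equilibrium_state(build_linear_system(m$parameters))
  tr <- simulate_circuit(m$parameters,
                         circuit_condition("sham", kernel = m$kernel),
                         initial = eq, horizon = 180)
  ne <- tr$NE_NAcc
  expect_equal(ne[1:61], rep(ne[1], 61), tolerance = 1e-12)  # flat pre-injection
  expect_gt(max(ne), ne[1] * 1.2)
  expect_lt(ne[181], max(ne) * 0.9)          # decaying back by the horizon
  expect_gt(ne[181], ne[1])                  # but still above baseline
  expect_gt(tr$NE_mPFC[121], tr$NE_mPFC[1])  # prefrontal NE responds too
})

test_that("divergence raises an instability error naming the first bad step", {
  p <- unclass(example_circuit_parameters())
  p["tau_LC"] <- 9.5  # far outside the Euler stability region at dt = 1
  p <- circuit_parameters(p)
  expect_error(
    simulate_circuit(p, circuit_condition("sham"), initial = rep(1000, 6),
                     horizon = 180),
    "diverged at t = ")
})

test_that("halving the step barely moves the endpoint of a smooth run", {
  m <- fixture_cohort_small()[[1]]
  eq <- equilibrium_state(build_linear_system(m$parameters))
  cond <- circuit_condition("sham", kernel = m$kernel)
  t1 <- simulate_circuit(m$parameters, cond, initial = eq, horizon = 180,
                         dt = 1)
  t2 <- simulate_circuit(m$parameters, cond, initial = eq, horizon = 180,
                         dt = 0.5)
  end1 <- unlist(t1[nrow(t1), -1]); end2 <- unlist(t2[nrow(t2), -1])
  expect_lt(max(abs(end1 - end2) / pmax(abs(end2), 1e-8)), 0.02)
})

test_that("fixed-step integration agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  m <- fixture_cohort_small()[[1]]
  p <- m$parameters; kp <- m$kernel
  eq <- equilibrium_state(build_linear_system(p))
  ours <- simulate_circuit(p, circuit_condition("sham", kernel = kp),
                           initial = eq, horizon = 180, method = "rk4",
                           substeps = 10L)
  rhs <- function(t, y, parms) {
    list(unname(circuit_derivs(y, p, l = 1, k_t = cocaine_kernel(t, kp))))
  }
  ref <- deSolve::lsoda(y = unname(eq), times = c(0, 90, 180), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  end_ref <- as.numeric(ref[nrow(ref), -1])
  end_ours <- as.numeric(ours[nrow(ours), -1])
  expect_equal(end_ours, end_ref, tolerance = 1e-6)
  # the native Euler scheme is first-order consistent with the same solution
  euler <- simulate_circuit(p, circuit_condition("sham", kernel = kp),
                            initial = eq, horizon = 180)
  expect_equal(as.numeric(euler[nrow(euler), -1]), end_ref, tolerance = 0.05)
})

test_that("trajectory CSV export uses the tidy unit-labelled layout", {
  m <- fixture_cohort_small()[[1]]
  tr <- simulate_circuit(m$parameters, circuit_condition("sham"), horizon = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, mouse_id = "fix_01")
  df <- read.csv(path)
  expect_named(df, c("time_min", "LC_Hz", "NE_mPFC_pg", "mPFC_Hz", "NTS_Hz",
                     "NE_NAcc_pg", "NAcc_Hz", "condition", "mouse_id", "seed"))
  expect_equal(nrow(df), 11L)
})
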