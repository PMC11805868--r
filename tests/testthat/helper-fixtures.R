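# Shared fixtures. The GA-fitted default cohort is expensive, so it is
# fitted lazily once per test run and reused by every test that needs it.

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- fit_cohort(steady_state_targets(), ga_config(),
                                      n_mice = 10L, base_seed = 1L)
  }
  .fixture_env$cohort
}

fixture_cohort_small <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- make_fixture_cohort(seed = 7L, n = 3L)
  }
  .fixture_env$small
}

# A random circuit that is stable both in continuous time and for the
# explicit Euler map at dt = 1 (spectral radius of I + A below rho_max).
random_stable_params <- function(rho_max = 0.95) {
  repeat {
    tau <- stats::runif(6, 0.2, 1.6)
    g <- stats::runif(8, 0, 0.4)
    p <- try(circuit_parameters(
      tau_LC = tau[1], alpha_LC_mPFC = g[1], alpha_LC_ext = stats::runif(1, 0.5, 3),
      tau_NE_mPFC = tau[2], alpha_mPFC_LC = g[2],
      tau_mPFC = tau[3], alpha_mPFC_NE = g[3], alpha_mPFC_ext = stats::runif(1, 0.5, 3),
      tau_NTS = tau[4], alpha_NTS_mPFC = g[4], alpha_NTS_ext = stats::runif(1, 0.5, 3),
      tau_NE_NAcc = tau[5], alpha_NAcc_LC = g[5], alpha_NAcc_NTS = g[6],
      tau_NAcc = tau[6], alpha_NAcc_NE = g[7], alpha_NAcc_ext = stats::runif(1, 0.5, 3)
    ), silent = TRUE)
    if (inherits(p, "try-error")) next
    ev <- eigen(build_linear_system(p)$A, only.values = TRUE)$values
    if (max(Re(ev)) < 0 && max(Mod(1 + ev)) < rho_max) return(p)
  }
}

# Central-difference Jacobian of the vector field at a state.
numeric_jacobian <- function(p, l, k_t, state, h = 1e-6) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (circuit_derivs(up, p, l, k_t) - circuit_derivs(dn, p, l, k_t)) / (2 * h)
  }
  J
}
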