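#' Construct a small synthetic cohort without running the GA
#'
#' Builds `n` hand-constructed, diagonally dominant parameter sets whose
#' sham equilibria sit on (seeded jitter: near) the packaged steady-state
#' targets, each paired with a fixed dipping kernel. All systems are
#' certified asymptotically stable before return. Intended for fast tests
#' and examples of the simulate / analyze / stability stages; a GA-fitted
#' cohort is the production path.
#'
#' @param seed RNG seed for the jitter.
#' @param n cohort size.
#' @param targets steady-state vector the construction hits.
#' @param kernel kernel shared by the cohort.
#' @return A `fitted_cohort` of `n` synthetic mice.
#' @export
make_fixture_cohort <- function(seed = 1L, n = 3L,
                                targets = steady_state_targets(),
                                kernel = kernel_parameters(0.6, 4000, 300, 60)) {
  mice <- with_private_seed(seed, {
    lapply(seq_len(n), function(i) {
      tau <- stats::runif(6, 0.7, 1.3)
      gs <- stats::runif(1, 0.8, 1.2)
      p <- example_circuit_parameters(targets, tau = tau, gain_scale = gs)
      sys <- build_linear_system(p, l = 1, k_value = 1)
      rep <- stability_report(sys)
      if (rep$verdict != "asymptotically_stable") {
        stop("fixture construction produced an unstable system")
      }
      structure(list(mouse_id = sprintf("fix_%02d", i), condition = "sham",
                     seed = seed * 1000L + i, parameters = p, kernel = kernel,
                     fitness = NA_real_,
                     achieved_steady_state = rep$equilibrium,
                     steady_state_rel_err = abs(rep$equilibrium - targets) / targets,
                     stability_verdict = rep$verdict, accepted = TRUE,
                     generations_run = 0L, history = NULL, targets = targets),
                class = "fitted_mouse")
    })
  })
  structure(mice, class = "fitted_cohort", targets = targets)
}
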