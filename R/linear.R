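#' Compact linear form of the circuit model
#'
#' For fixed depletion multiplier `l` and kernel value `k`, the circuit ODEs
#' are linear: `dy/dt = A y + b` with a sparse 6x6 matrix `A` (negative
#' diagonal damping entries, excitatory off-diagonals) and a drive vector
#' `b` that is zero on the two NE coordinates. Depletion scales row 2 of
#' `A` by `l`; a cocaine snapshot scales the NE damping entries (2,2) and
#' (5,5) by `k`.
#'
#' @param p [circuit_parameters()].
#' @param l depletion multiplier in `[0, 1]`.
#' @param k_value kernel value in `(0, 1]`.
#' @param label optional label stored on the system (defaults to
#'   `"sham"`/`"depleted"` by `l`, with a kernel-snapshot note when
#'   `k_value < 1`).
#' @return An object of class `linear_system`: list with elements `A`
#'   (6x6), `b` (length 6), `label`, `k_value`, `l_value`.
#' @export
build_linear_system <- function(p, l = 1, k_value = 1, label = NULL) {
  stopifnot(inherits(p, "circuit_parameters"))
  if (!is.finite(l) || l < 0 || l > 1) stop("l must lie in [0, 1]")
  if (!is.finite(k_value) || k_value <= 0 || k_value > 1) {
    stop("k_value must lie in (0, 1]")
  }
  A <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  A[1, 1] <- -p[["tau_LC"]];            A[1, 3] <- p[["alpha_LC_mPFC"]]
  A[2, 1] <- l * p[["alpha_mPFC_LC"]];  A[2, 2] <- -l * k_value * p[["tau_NE_mPFC"]]
  A[3, 2] <- p[["alpha_mPFC_NE"]];      A[3, 3] <- -p[["tau_mPFC"]]
  A[4, 3] <- p[["alpha_NTS_mPFC"]];     A[4, 4] <- -p[["tau_NTS"]]
  A[5, 1] <- p[["alpha_NAcc_LC"]];      A[5, 4] <- p[["alpha_NAcc_NTS"]]
  A[5, 5] <- -k_value * p[["tau_NE_NAcc"]]
  A[6, 5] <- p[["alpha_NAcc_NE"]];      A[6, 6] <- -p[["tau_NAcc"]]
  b <- c(p[["alpha_LC_ext"]], 0, p[["alpha_mPFC_ext"]], p[["alpha_NTS_ext"]],
         0, p[["alpha_NAcc_ext"]])
  names(b) <- STATE_NAMES
  if (is.null(label)) {
    label <- if (l == 0) "depleted" else "sham"
    if (k_value < 1) label <- paste0(label, "-kernel-snapshot")
  }
  structure(list(A = A, b = b, label = label, k_value = k_value, l_value = l),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("<linear_system> %s (l = %g, k = %g)\n", x$label, x$l_value,
              x$k_value))
  print(round(x$A, 4))
  cat("b:", paste(round(x$b, 4), collapse = " "), "\n")
  invisible(x)
}

#' Equilibrium of a linear circuit system
#'
#' Solves `A y + b = 0` by a linear solve (never an explicit inverse). The
#' depleted system (`l = 0`) has a structurally zero row and is singular:
#' the prefrontal NE pool is frozen, not relaxing, so its level must be
#' supplied via `ne_mpfc`, and the remaining five coordinates are solved
#' with that level as a fixed input.
#'
#' @param sys a [build_linear_system()] result.
#' @param ne_mpfc fixed prefrontal NE level (pg), required when the system
#'   is singular (`l = 0`).
#' @param max_kappa condition-number threshold beyond which the full solve
#'   is refused.
#' @return Named length-6 equilibrium vector (Hz and pg, in state order).
#' @export
equilibrium_state <- function(sys, ne_mpfc = NULL, max_kappa = 1e10) {
  stopifnot(inherits(sys, "linear_system"))
  A <- sys$A; b <- sys$b
  if (is.null(ne_mpfc)) {
    kappa <- kappa(A, exact = FALSE)
    if (!is.finite(kappa) || kappa > max_kappa) {
      stop("singular or near-singular system (l = 0?): supply ne_mpfc to ",
           "solve the reduced 5-variable system")
    }
    y <- solve(A, -b)
  } else {
    keep <- setdiff(seq_len(6L), 2L)
    b_red <- b[keep] + A[keep, 2] * ne_mpfc
    y_red <- solve(A[keep, keep], -b_red)
    y <- numeric(6L)
    y[keep] <- y_red
    y[2L] <- ne_mpfc
    names(y) <- STATE_NAMES
  }
  resid <- A %*% y + b
  if (is.null(ne_mpfc) && max(abs(resid)) > 1e-10 * max(1, max(abs(b)))) {
    stop("equilibrium solve failed the residual check")
  }
  y
}

#' Eigenvalue stability report
#'
#' Computes the spectrum of `A`, the maximum real part, and a verdict:
#' asymptotically stable iff every eigenvalue has negative real part;
#' marginally stable when the largest real part is zero (within `tol`) and
#' nothing is positive - the depleted system always lands here through the
#' structural zero eigenvalue of its frozen NE coordinate; unstable
#' otherwise.
#'
#' @param sys a [build_linear_system()] result.
#' @param tol magnitude below which a real part counts as zero.
#' @return An object of class `stability_report`: list with `system`,
#'   `equilibrium` (or `NA` for singular systems), `eigenvalues`,
#'   `max_real_part`, `n_zero` (eigenvalues on the imaginary axis),
#'   `verdict`.
#' @export
stability_report <- function(sys, tol = 1e-9) {
  stopifnot(inherits(sys, "linear_system"))
  ev <- eigen(sys$A, only.values = TRUE)$values
  re <- Re(ev)
  max_re <- max(re)
  n_zero <- sum(abs(re) <= tol)
  verdict <- if (max_re < -tol) {
    "asymptotically_stable"
  } else if (max_re <= tol) {
    "marginally_stable"
  } else {
    "unstable"
  }
  eq <- tryCatch(equilibrium_state(sys), error = function(e) rep(NA_real_, 6L))
  structure(list(system = sys, equilibrium = eq, eigenvalues = ev,
                 max_real_part = max_re, n_zero = n_zero, verdict = verdict),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s (max Re lambda = %.4g, %d on axis)\n",
              x$verdict, x$max_real_part, x$n_zero))
  invisible(x)
}

#' Stability sweep across the kernel transient
#'
#' Builds frozen snapshots `A_c(t)` with `k_value = k(t)` on a time grid and
#' certifies each. The paper-level argument is that the time-varying system
#' inherits stability from the `k -> 1` limit; the sweep verifies the
#' stronger pointwise statement for a fitted mouse.
#'
#' @param p [circuit_parameters()].
#' @param l depletion multiplier.
#' @param kp [kernel_parameters()].
#' @param times grid of snapshot times (minutes).
#' @return List of [stability_report()]s, one per grid time, with attribute
#'   `all_stable` (TRUE iff every snapshot with `l = 1` is asymptotically
#'   stable; for `l = 0`, iff every snapshot is at worst marginal through
#'   the structural zero only).
#' @export
sweep_kernel_stability <- function(p, l = 1, kp, times = 0:180) {
  stopifnot(inherits(kp, "kernel_parameters"))
  ks <- cocaine_kernel(times, kp)
  reports <- lapply(ks, function(k) {
    stability_report(build_linear_system(p, l = l, k_value = k))
  })
  ok <- vapply(reports, function(r) {
    if (l > 0) r$verdict == "asymptotically_stable"
    else r$verdict == "marginally_stable" && r$n_zero == 1L
  }, logical(1))
  structure(reports, all_stable = all(ok), times = times)
}

#' Serialize a stability report to JSON
#'
#' Matrix row-major, eigenvalues as `[re, im]` pairs.
#'
#' @param report a [stability_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_report_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  obj <- list(
    label = report$system$label,
    l_value = report$system$l_value,
    k_value = report$system$k_value,
    A_row_major = as.numeric(t(report$system$A)),
    b = as.numeric(report$system$b),
    equilibrium = as.numeric(report$equilibrium),
    eigenvalues = lapply(seq_along(report$eigenvalues), function(i) {
      c(Re(report$eigenvalues[i]), Im(report$eigenvalues[i]))
    }),
    max_real_part = report$max_real_part,
    verdict = report$verdict
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
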