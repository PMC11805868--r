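#' Circuit coefficients of the four-region noradrenaline model
#'
#' Bundles the 17 free coefficients of the mean-field circuit: per-region
#' decay constants (`tau_*`, per-minute rates), inter-region excitation and
#' NE-release gains (`alpha_<target>_<source>`), and constant external
#' drives (`alpha_*_ext`). Decay constants must be strictly positive; gains
#' and drives non-negative (all modelled connections are excitatory).
#'
#' @param ... the 17 named coefficients (see [circuit_parameter_names()]),
#'   or a single named numeric vector / list containing all of them.
#' @return An object of class `circuit_parameters`: a named numeric vector
#'   of length 17.
#' @examples
#' p <- example_circuit_parameters()
#' p[["tau_LC"]]
#' @export
circuit_parameters <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.numeric(dots[[1L]]) || is.list(dots[[1L]]))) {
    dots <- as.list(dots[[1L]])
  }
  missing <- setdiff(PARAM_NAMES, names(dots))
  if (length(missing)) {
    stop("missing circuit parameters: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(dots), PARAM_NAMES)
  if (length(extra)) {
    stop("unknown circuit parameters: ", paste(extra, collapse = ", "))
  }
  p <- vapply(dots[PARAM_NAMES], function(x) as.numeric(x)[1L], numeric(1))
  validate_circuit_parameters(p)
  structure(p, class = "circuit_parameters")
}

#' @rdname circuit_parameters
#' @export
circuit_parameter_names <- function() PARAM_NAMES

validate_circuit_parameters <- function(p) {
  if (!all(is.finite(p))) stop("circuit parameters must be finite")
  taus <- p[startsWith(names(p), "tau_")]
  if (any(taus <= 0)) stop("decay constants (tau_*) must be strictly positive")
  gains <- p[startsWith(names(p), "alpha_")]
  if (any(gains < 0)) stop("gains and drives (alpha_*) must be non-negative")
  invisible(p)
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("<circuit_parameters> 17 coefficients\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Pharmacodynamic kernel parameters
#'
#' Parameters of the cocaine kernel `k(t)`: amplitude `a` (unitless), slow
#' Gaussian width `b` and fast width `c` (both minutes squared, `b > c`),
#' and injection time `t_c` (minutes). The difference-of-Gaussians dip must
#' keep `k(t)` within (0, 1]; parameter sets whose global minimum of `k`
#' would touch zero are rejected.
#'
#' @param a kernel amplitude, `a >= 0`.
#' @param b slow width, minutes^2.
#' @param c fast width, minutes^2, `0 < c < b`.
#' @param t_c injection time, minutes.
#' @return An object of class `kernel_parameters`.
#' @seealso [cocaine_kernel()], [kernel_minimum()]
#' @export
kernel_parameters <- function(a, b, c, t_c = 60) {
  kp <- structure(list(a = as.numeric(a), b = as.numeric(b),
                       c = as.numeric(c), t_c = as.numeric(t_c)),
                  class = "kernel_parameters")
  validate_kernel_parameters(kp)
  kp
}

validate_kernel_parameters <- function(kp) {
  with(kp, {
    if (!all(is.finite(c(a, b, c, t_c)))) {
      stop("kernel parameters must be finite")
    }
    if (a < 0) stop("rejected kernel parameters: amplitude a must be >= 0")
    if (c <= 0 || b <= c) {
      stop("rejected kernel parameters: widths must satisfy b > c > 0")
    }
  })
  if (kernel_minimum(kp) <= 0) {
    stop("rejected kernel parameters: k(t) would leave (0, 1]")
  }
  invisible(kp)
}

#' @export
print.kernel_parameters <- function(x, ...) {
  cat(sprintf("<kernel_parameters> a = %.4g, b = %.4g, c = %.4g, t_c = %g (k_min = %.4f)\n",
              x$a, x$b, x$c, x$t_c, kernel_minimum(x)))
  invisible(x)
}

#' Experimental condition: sham or NE-depleted
#'
#' A condition couples the depletion multiplier `l` (1 in sham, 0 in
#' prefrontal-NE-depleted virtual mice; intermediate values are allowed but
#' non-default) to the kernel used for the cocaine injection.
#'
#' @param label `"sham"` or `"depleted"`.
#' @param kernel a [kernel_parameters()] object, or `NULL` for no injection
#'   (kernel identically 1).
#' @param l depletion multiplier in `[0, 1]`; defaults to 1 for sham and 0
#'   for depleted.
#' @return An object of class `circuit_condition`.
#' @export
circuit_condition <- function(label = c("sham", "depleted"), kernel = NULL,
                              l = NULL) {
  label <- match.arg(label)
  if (is.null(l)) l <- if (label == "sham") 1 else 0
  l <- as.numeric(l)
  if (!is.finite(l) || l < 0 || l > 1) stop("l must lie in [0, 1]")
  if (!is.null(kernel) && !inherits(kernel, "kernel_parameters")) {
    stop("kernel must be a kernel_parameters object or NULL")
  }
  structure(list(label = label, l = l, kernel = kernel),
            class = "circuit_condition")
}

#' @export
print.circuit_condition <- function(x, ...) {
  cat(sprintf("<circuit_condition> %s (l = %g), kernel: %s\n", x$label, x$l,
              if (is.null(x$kernel)) "none (k = 1)" else
                sprintf("a = %.3g, t_c = %g", x$kernel$a, x$kernel$t_c)))
  invisible(x)
}

#' A hand-constructed stable parameter set
#'
#' Returns a diagonally-dominant circuit whose sham equilibrium equals the
#' packaged steady-state targets exactly (the external drives are solved
#' from the chosen decay constants and gains). Useful for examples and as a
#' fast stand-in for a GA fit.
#'
#' @param targets a named length-6 vector of steady states, default
#'   [steady_state_targets()].
#' @param tau decay constants to use for the six equations (recycled).
#' @param gain_scale multiplier on the cross-region gains; smaller values
#'   give stronger diagonal dominance.
#' @return A `circuit_parameters` object.
#' @export
example_circuit_parameters <- function(targets = steady_state_targets(),
                                       tau = c(1, 0.8, 1, 1, 0.9, 1),
                                       gain_scale = 1) {
  tau <- rep_len(tau, 6L)
  y <- as.numeric(targets[STATE_NAMES])
  g <- 0.3 * gain_scale
  # NE pools have no external drive: their gains are pinned by the targets.
  a_mPFC_LC  <- tau[2] * y[2] / y[1]
  w_LC  <- 0.5
  a_NAcc_LC  <- w_LC * tau[5] * y[5] / y[1]
  a_NAcc_NTS <- (1 - w_LC) * tau[5] * y[5] / y[4]
  p <- c(
    tau_LC = tau[1], alpha_LC_mPFC = g, alpha_LC_ext = tau[1] * y[1] - g * y[3],
    tau_NE_mPFC = tau[2], alpha_mPFC_LC = a_mPFC_LC,
    tau_mPFC = tau[3], alpha_mPFC_NE = g, alpha_mPFC_ext = tau[3] * y[3] - g * y[2],
    tau_NTS = tau[4], alpha_NTS_mPFC = g, alpha_NTS_ext = tau[4] * y[4] - g * y[3],
    tau_NE_NAcc = tau[5], alpha_NAcc_LC = a_NAcc_LC, alpha_NAcc_NTS = a_NAcc_NTS,
    tau_NAcc = tau[6], alpha_NAcc_NE = g, alpha_NAcc_ext = tau[6] * y[6] - g * y[5]
  )
  if (any(p[c("alpha_LC_ext", "alpha_mPFC_ext", "alpha_NTS_ext", "alpha_NAcc_ext")] < 0)) {
    stop("gain_scale too large: implied external drives would be negative")
  }
  circuit_parameters(p)
}

# --- serialization -----------------------------------------------------------

#' Read and write parameter sets as JSON
#'
#' Circuit and kernel parameters round-trip through JSON using the exact
#' field names of their constructors.
#'
#' @param x a `circuit_parameters` or `kernel_parameters` object.
#' @param path file path.
#' @return `write_parameters_json` returns `path` invisibly;
#'   `read_circuit_parameters_json` / `read_kernel_parameters_json` return
#'   the reconstructed object.
#' @export
write_parameters_json <- function(x, path) {
  stopifnot(inherits(x, "circuit_parameters") || inherits(x, "kernel_parameters"))
  jsonlite::write_json(as.list(unclass(x)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_circuit_parameters_json <- function(path) {
  circuit_parameters(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_parameters_json
#' @export
read_kernel_parameters_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernel_parameters(a = v$a, b = v$b, c = v$c, t_c = v$t_c)
}
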