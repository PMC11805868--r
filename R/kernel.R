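#' Cocaine pharmacodynamic kernel k(t)
#'
#' The kernel multiplies the NE damping terms and encodes the reuptake
#' blockade produced by an acute cocaine injection at time `t_c`:
#' \deqn{k(t) = 1 \quad (t \le t_c), \qquad
#'   k(t) = 1 - a\left(e^{-(t-t_c)^2/b} - e^{-(t-t_c)^2/c}\right) \quad (t > t_c).}
#' With `b > c > 0` the difference of Gaussians is positive after `t_c`, so
#' `k` dips below 1 (reduced damping, hence NE accumulation) and returns to
#' 1 as the effect wears off: `k(t) -> 1` as `t -> Inf`.
#'
#' @param t time(s) in minutes; vectorized.
#' @param kp a [kernel_parameters()] object.
#' @return Kernel values in (0, 1], same length as `t`.
#' @export
cocaine_kernel <- function(t, kp) {
  stopifnot(inherits(kp, "kernel_parameters"), all(is.finite(t)))
  s <- (t - kp$t_c)^2
  k <- 1 - kp$a * (exp(-s / kp$b) - exp(-s / kp$c))
  k[t <= kp$t_c] <- 1
  k
}

#' Global minimum of the kernel
#'
#' Closed form: the dip `a (e^{-x/b} - e^{-x/c})` with `x = (t - t_c)^2` is
#' maximal at `x* = bc/(b - c) * log(b/c)`, so
#' `min k = 1 - a (e^{-x*/b} - e^{-x*/c})`. Used to certify `k(t) > 0`
#' without scanning a grid.
#'
#' @inheritParams cocaine_kernel
#' @return The minimum of `k(t)` over all real `t`.
#' @export
kernel_minimum <- function(kp) {
  if (kp$a == 0) return(1)
  xs <- kp$b * kp$c / (kp$b - kp$c) * log(kp$b / kp$c)
  1 - kp$a * (exp(-xs / kp$b) - exp(-xs / kp$c))
}
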