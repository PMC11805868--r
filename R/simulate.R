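# Internal: run code with a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Time derivatives of the six-equation circuit model
#'
#' Evaluates the mean-field vector field for the state
#' `[LC, NE_mPFC, mPFC, NTS, NE_NAcc, NAcc]`:
#' firing activities decay with rate `tau_<region>` and are excited by their
#' inputs plus a constant external drive; the two NE pools are filled by
#' their source nuclei (LC for the mPFC pool; LC and NTS for the NAcc pool)
#' and cleared with rate `tau_NE_*` scaled by the kernel value `k_t`.
#' The depletion multiplier `l` scales both terms of the mPFC NE equation,
#' so `l = 0` freezes prefrontal NE exactly.
#'
#' @param state named (or ordered) numeric vector of length 6.
#' @param p [circuit_parameters()].
#' @param l depletion multiplier in `[0, 1]`.
#' @param k_t kernel value in `(0, 1]`.
#' @return Named numeric vector of the six time derivatives (per minute).
#' @export
circuit_derivs <- function(state, p, l = 1, k_t = 1) {
  if (!all(is.finite(state)) || !all(is.finite(p))) {
    stop("non-finite state or parameters")
  }
  if (k_t <= 0 || k_t > 1) stop("k_t must lie in (0, 1]")
  if (l < 0 || l > 1) stop("l must lie in [0, 1]")
  y <- as.numeric(state)
  d <- c(
    LC      = -p[["tau_LC"]] * y[1] + p[["alpha_LC_mPFC"]] * y[3] + p[["alpha_LC_ext"]],
    NE_mPFC = -l * k_t * p[["tau_NE_mPFC"]] * y[2] + l * p[["alpha_mPFC_LC"]] * y[1],
    mPFC    = -p[["tau_mPFC"]] * y[3] + p[["alpha_mPFC_NE"]] * y[2] + p[["alpha_mPFC_ext"]],
    NTS     = -p[["tau_NTS"]] * y[4] + p[["alpha_NTS_mPFC"]] * y[3] + p[["alpha_NTS_ext"]],
    NE_NAcc = -k_t * p[["tau_NE_NAcc"]] * y[5] + p[["alpha_NAcc_LC"]] * y[1] +
              p[["alpha_NAcc_NTS"]] * y[4],
    NAcc    = -p[["tau_NAcc"]] * y[6] + p[["alpha_NAcc_NE"]] * y[5] + p[["alpha_NAcc_ext"]]
  )
  d
}

#' Fixed-step integration of the circuit model
#'
#' Integrates the circuit ODEs with the model's native discretization:
#' explicit Euler at `dt = 1` min (each step is one minute of experiment
#' time). An optional higher-accuracy mode subdivides each step and applies
#' classical fourth-order Runge-Kutta; it is used by the package's own
#' consistency checks. Process noise, when enabled, perturbs the four
#' external-drive terms with independent zero-mean Gaussians of standard
#' deviation `noise_sd * alpha_*_ext`, redrawn once per `dt` step (held
#' constant across sub-steps) from a private RNG stream seeded by `seed`.
#'
#' @param p [circuit_parameters()].
#' @param condition [circuit_condition()]; its kernel (if any) defines the
#'   injection, its `l` the depletion state.
#' @param initial numeric length-6 initial state; default the condition's
#'   equilibrium (see [equilibrium_state()]).
#' @param horizon total simulated time, minutes; must be a positive
#'   multiple of `dt`.
#' @param dt outer step size, minutes.
#' @param noise_sd relative standard deviation of the drive noise
#'   (fraction of each `alpha_*_ext`); 0 disables noise.
#' @param seed integer seed for the noise stream (required if
#'   `noise_sd > 0`).
#' @param method `"euler"` (native) or `"rk4"`.
#' @param substeps integer number of sub-steps per `dt` (only used by
#'   `"rk4"`; `"euler"` also honours values > 1).
#' @param ceiling divergence guard: any state magnitude above this aborts
#'   with an error naming the first offending time.
#' @return A data frame of class `circuit_trajectory` with columns
#'   `time_min` and the six state variables; attributes `condition`,
#'   `parameters`, `seed`, `dt`, `noise_sd`. Trajectories containing
#'   negative states carry attribute `negative_states = TRUE`.
#' @export
simulate_circuit <- function(p, condition = circuit_condition("sham"),
                             initial = NULL, horizon = 180, dt = 1,
                             noise_sd = 0, seed = NULL,
                             method = c("euler", "rk4"), substeps = 1L,
                             ceiling = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(p, "circuit_parameters"),
            inherits(condition, "circuit_condition"))
  n_steps <- horizon / dt
  if (horizon <= 0 || abs(n_steps - round(n_steps)) > 1e-9) {
    stop("horizon must be a positive multiple of dt")
  }
  n_steps <- as.integer(round(n_steps))
  if (noise_sd > 0 && is.null(seed)) stop("seed is required when noise_sd > 0")

  if (is.null(initial)) {
    initial <- equilibrium_state(
      build_linear_system(p, l = 1, k_value = 1))
  }
  y <- as.numeric(initial)
  if (length(y) != 6L || !all(is.finite(y))) stop("initial state must be 6 finite values")

  l <- condition$l
  kp <- condition$kernel
  times <- seq(0, horizon, by = dt)
  kt <- if (is.null(kp)) rep(1, length(times)) else cocaine_kernel(times, kp)

  drives <- p[c("alpha_LC_ext", "alpha_mPFC_ext", "alpha_NTS_ext", "alpha_NAcc_ext")]
  noise <- matrix(0, nrow = n_steps, ncol = 4L)
  if (noise_sd > 0) {
    noise <- with_private_seed(seed, matrix(stats::rnorm(n_steps * 4L), n_steps, 4L))
    noise <- sweep(noise, 2L, noise_sd * as.numeric(drives), `*`)
  }

  tau_LC <- p[["tau_LC"]]; aLCm <- p[["alpha_LC_mPFC"]]
  tauNEm <- p[["tau_NE_mPFC"]]; amLC <- p[["alpha_mPFC_LC"]]
  tau_m <- p[["tau_mPFC"]]; amNE <- p[["alpha_mPFC_NE"]]
  tau_NTS <- p[["tau_NTS"]]; aNTSm <- p[["alpha_NTS_mPFC"]]
  tauNEn <- p[["tau_NE_NAcc"]]; anLC <- p[["alpha_NAcc_LC"]]; anNTS <- p[["alpha_NAcc_NTS"]]
  tau_n <- p[["tau_NAcc"]]; anNE <- p[["alpha_NAcc_NE"]]

  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 6L,
                dimnames = list(NULL, STATE_NAMES))
  out[1L, ] <- y
  substeps <- max(1L, as.integer(substeps))
  h <- dt / substeps
  kfun <- if (is.null(kp)) function(t) 1 else function(t) cocaine_kernel(t, kp)

  derivs <- function(t, y, dr, k_t) {
    c(-tau_LC * y[1] + aLCm * y[3] + dr[1],
      -l * k_t * tauNEm * y[2] + l * amLC * y[1],
      -tau_m * y[3] + amNE * y[2] + dr[2],
      -tau_NTS * y[4] + aNTSm * y[3] + dr[3],
      -k_t * tauNEn * y[5] + anLC * y[1] + anNTS * y[4],
      -tau_n * y[6] + anNE * y[5] + dr[4])
  }

  for (i in seq_len(n_steps)) {
    t0 <- times[i]
    dr <- as.numeric(drives) + noise[i, ]
    if (method == "euler" && substeps == 1L) {
      y <- y + dt * derivs(t0, y, dr, kt[i])
    } else if (method == "euler") {
      for (s in seq_len(substeps)) {
        ts <- t0 + (s - 1L) * h
        y <- y + h * derivs(ts, y, dr, kfun(ts))
      }
    } else {
      for (s in seq_len(substeps)) {
        ts <- t0 + (s - 1L) * h
        k1 <- derivs(ts, y, dr, kfun(ts))
        k2 <- derivs(ts + h / 2, y + h / 2 * k1, dr, kfun(ts + h / 2))
        k3 <- derivs(ts + h / 2, y + h / 2 * k2, dr, kfun(ts + h / 2))
        k4 <- derivs(ts + h, y + h * k3, dr, kfun(ts + h))
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    if (any(!is.finite(y)) || max(abs(y)) > ceiling) {
      stop(sprintf("integration diverged at t = %g min (|state| > %g)",
                   times[i + 1L], ceiling))
    }
    out[i + 1L, ] <- y
  }

  traj <- as.data.frame(out)
  traj <- cbind(time_min = times, traj)
  attr(traj, "condition") <- condition
  attr(traj, "parameters") <- p
  attr(traj, "seed") <- seed
  attr(traj, "dt") <- dt
  attr(traj, "noise_sd") <- noise_sd
  attr(traj, "negative_states") <- any(out < 0)
  class(traj) <- c("circuit_trajectory", "data.frame")
  traj
}

#' Export a trajectory as tidy CSV
#'
#' Columns: `time_min, LC_Hz, NE_mPFC_pg, mPFC_Hz, NTS_Hz, NE_NAcc_pg,
#' NAcc_Hz, condition, mouse_id, seed`.
#'
#' @param traj a `circuit_trajectory`.
#' @param path output file.
#' @param mouse_id identifier written into the `mouse_id` column.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, mouse_id = NA_character_) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  cond <- attr(traj, "condition")
  df <- data.frame(
    time_min = traj$time_min,
    LC_Hz = traj$LC, NE_mPFC_pg = traj$NE_mPFC, mPFC_Hz = traj$mPFC,
    NTS_Hz = traj$NTS, NE_NAcc_pg = traj$NE_NAcc, NAcc_Hz = traj$NAcc,
    condition = cond$label, mouse_id = mouse_id,
    seed = if (is.null(attr(traj, "seed"))) NA_integer_ else attr(traj, "seed")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
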