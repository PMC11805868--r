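#' Virtual microdialysis protocol
#'
#' The in-silico analogue of an acute-cocaine microdialysis session:
#' 180 min simulated at 1-min steps, injection at 60 min, samples every
#' 20 min. The three samples at 20, 40 and 60 min (the injection instant
#' still has `k = 1`) are averaged into the baseline; the six post-injection
#' samples fall at 20-120 min after injection.
#'
#' @param horizon total simulated time, minutes.
#' @param dt integration step, minutes.
#' @param injection_time cocaine injection time `t_c`, minutes.
#' @param sampling_interval microdialysis sampling interval, minutes.
#' @param n_baseline_samples pre-injection samples averaged into baseline.
#' @param cohort_size mice per condition.
#' @param noise_sd relative drive-noise level passed to
#'   [simulate_circuit()].
#' @param base_seed seed from which per-mouse simulation seeds are derived.
#' @return An object of class `dialysis_protocol`.
#' @export
dialysis_protocol <- function(horizon = 180, dt = 1, injection_time = 60,
                              sampling_interval = 20, n_baseline_samples = 3,
                              cohort_size = 10L, noise_sd = 0.05,
                              base_seed = 1L) {
  if (injection_time != n_baseline_samples * sampling_interval) {
    stop("injection_time must equal n_baseline_samples * sampling_interval")
  }
  if ((horizon - injection_time) %% sampling_interval != 0) {
    stop("horizon - injection_time must be divisible by sampling_interval")
  }
  if (dt <= 0 || sampling_interval %% dt != 0) {
    stop("sampling_interval must be a positive multiple of dt")
  }
  structure(list(horizon = horizon, dt = dt, injection_time = injection_time,
                 sampling_interval = sampling_interval,
                 n_baseline_samples = n_baseline_samples,
                 cohort_size = as.integer(cohort_size), noise_sd = noise_sd,
                 base_seed = as.integer(base_seed)),
            class = "dialysis_protocol")
}

protocol_sample_times <- function(proto) {
  pre <- proto$sampling_interval * seq_len(proto$n_baseline_samples)
  post <- seq(proto$injection_time + proto$sampling_interval, proto$horizon,
              by = proto$sampling_interval)
  list(pre = pre, post = post, post_rel = post - proto$injection_time)
}

# Per-mouse, per-condition simulation seed. Offsetting by a fixed constant
# for the depleted arm keeps the two arms' noise streams independent while
# remaining a pure function of the mouse seed.
condition_seed <- function(mouse_seed, label) {
  offset <- if (label == "depleted") 1000003L else 0L
  (as.integer(mouse_seed) + offset) %% 2147483647L
}

#' Baseline (pre-injection) mean of an NE trajectory
#'
#' Arithmetic mean of the region's values at the pre-injection sampling
#' instants (20, 40, 60 min under the default protocol).
#'
#' @param traj a `circuit_trajectory`.
#' @param region `"NE_mPFC"` or `"NE_NAcc"`.
#' @param proto a [dialysis_protocol()].
#' @return Baseline mean in pg.
#' @export
baseline_mean <- function(traj, region = c("NE_mPFC", "NE_NAcc"),
                          proto = dialysis_protocol()) {
  region <- match.arg(region)
  st <- protocol_sample_times(proto)
  if (max(st$pre) > proto$injection_time) {
    stop("protocol error: pre-injection samples extend past the injection")
  }
  idx <- match(st$pre, traj$time_min)
  if (anyNA(idx)) stop("protocol error: sampling instants missing from trajectory")
  mean(traj[[region]][idx])
}

sample_series <- function(traj, region, proto, mouse_id, condition) {
  st <- protocol_sample_times(proto)
  base <- baseline_mean(traj, region, proto)
  idx <- match(st$post, traj$time_min)
  raw <- traj[[region]][idx]
  data.frame(mouse_id = mouse_id, condition = condition, region = region,
             time_post_min = st$post_rel, raw_pg = raw,
             pct_baseline = 100 * raw / base, baseline_pg = base)
}

activity_rows <- function(traj, proto, mouse_id, condition) {
  pre <- traj$time_min <= proto$injection_time
  do.call(rbind, lapply(c("LC", "mPFC", "NTS", "NAcc"), function(region) {
    v <- traj[[region]]
    pre_mean <- mean(v[pre]); post_mean <- mean(v[!pre])
    data.frame(mouse_id = mouse_id, condition = condition, region = region,
               pre_mean = pre_mean, post_mean = post_mean,
               percent_change = 100 * (post_mean / pre_mean - 1))
  }))
}

#' Run one condition of the virtual experiment over a cohort
#'
#' Simulates every fitted mouse under the given condition (sham `l = 1` or
#' depleted `l = 0`; the mouse's fitted kernel provides the injection at
#' the protocol's `t_c`), starting from the mouse's sham equilibrium (the
#' depleted arm freezes prefrontal NE at that same baseline, matching the
#' equal baselines reported between groups). Microdialysis series are
#' sampled for both NE pools and pre/post firing summaries computed for the
#' four regions.
#'
#' @param cohort a `fitted_cohort`.
#' @param condition_label `"sham"` or `"depleted"`.
#' @param proto a [dialysis_protocol()].
#' @param kernel optional kernel override; by default each mouse's own
#'   fitted kernel is used (re-timed to the protocol's injection time).
#' @return An object of class `condition_run`: list with `trajectories`
#'   (per mouse), `dialysis` (tidy data frame), `activity` (tidy data
#'   frame), `failures` (character vector of mice whose integration
#'   diverged), `condition_label`, `protocol`.
#' @export
run_condition <- function(cohort, condition_label = c("sham", "depleted"),
                          proto = dialysis_protocol(), kernel = NULL) {
  condition_label <- match.arg(condition_label)
  stopifnot(inherits(cohort, "fitted_cohort"), length(cohort) >= 1L)
  trajs <- list(); dial <- list(); act <- list(); failures <- character()
  for (m in cohort) {
    kp <- if (is.null(kernel)) m$kernel else kernel
    kp <- kernel_parameters(kp$a, kp$b, kp$c, t_c = proto$injection_time)
    cond <- circuit_condition(condition_label, kernel = kp)
    eq <- equilibrium_state(build_linear_system(m$parameters, l = 1,
                                                k_value = 1))
    traj <- tryCatch(
      simulate_circuit(m$parameters, cond, initial = eq,
                       horizon = proto$horizon, dt = proto$dt,
                       noise_sd = proto$noise_sd,
                       seed = condition_seed(m$seed, condition_label)),
      error = function(e) e)
    if (inherits(traj, "error")) {
      failures <- c(failures, m$mouse_id)
      next
    }
    trajs[[m$mouse_id]] <- traj
    dial[[m$mouse_id]] <- rbind(
      sample_series(traj, "NE_mPFC", proto, m$mouse_id, condition_label),
      sample_series(traj, "NE_NAcc", proto, m$mouse_id, condition_label))
    act[[m$mouse_id]] <- activity_rows(traj, proto, m$mouse_id,
                                       condition_label)
  }
  structure(list(trajectories = trajs,
                 dialysis = do.call(rbind, c(dial, list(make.row.names = FALSE))),
                 activity = do.call(rbind, c(act, list(make.row.names = FALSE))),
                 failures = failures, condition_label = condition_label,
                 protocol = proto),
            class = "condition_run")
}

#' @export
print.condition_run <- function(x, ...) {
  cat(sprintf("<condition_run> %s: %d mice simulated, %d failures\n",
              x$condition_label, length(x$trajectories), length(x$failures)))
  invisible(x)
}

group_summary <- function(dial) {
  agg <- stats::aggregate(pct_baseline ~ condition + region + time_post_min,
                          data = dial, FUN = function(v) {
                            c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                              n = length(v))
                          })
  cbind(agg[, c("condition", "region", "time_post_min")],
        as.data.frame(agg$pct_baseline))
}

#' Compare sham and depleted virtual experiments
#'
#' Assembles the group tables (NE percent-of-baseline per timepoint,
#' baselines, pre/post firing means) and runs the statistical pipeline:
#' per-timepoint between-group tests with Sidak adjustment (plus
#' repeated-measures ANOVA when every cell is normal), baseline-equivalence
#' tests, and within-condition pre-vs-post firing tests per region.
#'
#' @param sham,depleted [run_condition()] results under the same protocol.
#' @param policy a [selection_policy()].
#' @return An object of class `experiment_report`: list with
#'   `ne_timecourse` (per region), `baseline` (per region),
#'   `firing_pre_post` (per condition x region), and `group_means`
#'   (mean +/- SEM per timepoint).
#' @export
compare_experiment <- function(sham, depleted, policy = selection_policy()) {
  stopifnot(inherits(sham, "condition_run"), inherits(depleted, "condition_run"))
  if (!identical(unclass(sham$protocol), unclass(depleted$protocol))) {
    stop("the two condition runs used different protocols")
  }
  dial <- rbind(sham$dialysis, depleted$dialysis)
  act <- rbind(sham$activity, depleted$activity)

  ne_timecourse <- lapply(stats::setNames(nm = c("NE_mPFC", "NE_NAcc")),
    function(region) {
      timecourse_comparison(dial[dial$region == region, ], policy)
    })

  baseline <- lapply(stats::setNames(nm = c("NE_mPFC", "NE_NAcc")),
    function(region) {
      baseline_equivalence(dial[dial$region == region, ], policy)
    })

  firing <- list()
  for (cond in c("sham", "depleted")) {
    for (region in c("LC", "mPFC", "NTS", "NAcc")) {
      sub <- act[act$condition == cond & act$region == region, ]
      firing[[paste(cond, region, sep = ".")]] <-
        choose_and_run(sub$pre_mean, sub$post_mean, policy,
                       labels = c("pre", "post"))
    }
  }

  structure(list(ne_timecourse = ne_timecourse, baseline = baseline,
                 firing_pre_post = firing, group_means = group_summary(dial),
                 activity = act, dialysis = dial),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  for (region in names(x$ne_timecourse)) {
    tc <- x$ne_timecourse[[region]]
    sig <- sum(vapply(tc$per_timepoint, `[[`, logical(1), "significant"))
    cat(sprintf("  %s: %d/%d post-injection timepoints significant; baseline p = %.3g\n",
                region, sig, length(tc$per_timepoint),
                x$baseline[[region]]$p_value))
  }
  for (nm in names(x$firing_pre_post)) {
    r <- x$firing_pre_post[[nm]]
    cat(sprintf("  firing %s: %s p = %.3g %s\n", nm, r$test_name, r$p_value,
                if (r$significant) "*" else ""))
  }
  invisible(x)
}

#' Export microdialysis series as tidy CSV
#'
#' Columns: `mouse_id, condition, region, time_post_min, raw_pg,
#' pct_baseline, baseline_pg`.
#'
#' @param run a [run_condition()] result (or an `experiment_report`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dialysis_csv <- function(run, path) {
  dial <- if (inherits(run, "condition_run")) run$dialysis else run$dialysis
  utils::write.csv(dial, path, row.names = FALSE)
  invisible(path)
}
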