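#' Harmonic number
#'
#' \eqn{H_N = \sum_{n=1}^{N} 1/n}, the scaling factor of the stochastic
#' unfolding model (expected maximum of N unit-rate exponentials).
#'
#' @param N Positive integer (vectorized).
#' @return Numeric.
#' @export
harmonic_number <- function(N) {
  vapply(as.integer(N), function(n) {
    if (n < 1) stop("N must be >= 1")
    sum(1 / seq_len(n))
  }, numeric(1))
}

#' Total unfolding rate under the stochastic model
#'
#' When all `N` domains of a polyprotein are simultaneously under force,
#' each unfolds independently at rate `rU` (first-order kinetics); the time
#' to unfold them all is the maximum of N exponentials, so the total rate is
#' \eqn{r_N = r_U / H_N}.
#'
#' @param N Domain count (integer >= 1, vectorized).
#' @param rU Per-domain unfolding rate, s^-1 (> 0).
#' @return Total unfolding rate, s^-1.
#' @seealso [sequential_rate()]
#' @export
stochastic_rate <- function(N, rU) {
  if (rU <= 0) stop("rU must be positive")
  rU / harmonic_number(N)
}

#' Total unfolding rate under the sequential model
#'
#' When domain i can only unfold after domain i-1 (one-at-a-time
#' processing, as in a translocation pore), the total time is the sum of N
#' exponential waits: \eqn{r_N = r_U / N}. This declines much more steeply
#' with N than the stochastic model (ratio N vs H_N).
#'
#' @inheritParams stochastic_rate
#' @return Total unfolding rate, s^-1.
#' @export
sequential_rate <- function(N, rU) {
  if (rU <= 0) stop("rU must be positive")
  if (any(as.integer(N) < 1)) stop("N must be >= 1")
  rU / as.integer(N)
}

#' Simulate a force-clamp unfolding trajectory
#'
#' Monte-Carlo staircase of a polyprotein held at constant force. In
#' `"stochastic"` mode the N domain unfolding times are i.i.d.
#' exponential(rU); in `"sequential"` mode N exponential waits are
#' accumulated. The extension is a staircase of `step_size` per event plus
#' additive Gaussian sampling noise; the molecule detaches
#' `detachment_factor` times the last unfolding time after force
#' application.
#'
#' @param N Number of folded domains picked up (integer >= 1).
#' @param rU Per-domain unfolding rate, s^-1.
#' @param step_size Extension gain per unfolding event, nm (default 25, the
#'   Ig27 fingerprint at 150 pN).
#' @param mode `"stochastic"` or `"sequential"`.
#' @param noise_sd Additive Gaussian noise SD, nm (default 2).
#' @param sample_rate Sampling rate, Hz (default 1000, matching a 1-kHz
#'   filtered recording). `sample_rate = 0` skips waveform synthesis and
#'   stores only event times (fast path for rate studies).
#' @param detachment_factor Detachment time as a multiple of the last
#'   unfolding time (default 5).
#' @param force Clamp force, pN (metadata only; default 150).
#' @param seed Integer seed; required for reproducibility.
#' @param trajectory_id Identifier.
#' @return An object of class `unfolding_trajectory`: list with `time`,
#'   `extension` (empty when `sample_rate = 0`), `n_domains`,
#'   `true_step_times`, `detachment_time`, `force`, `step_size` and
#'   simulation metadata.
#' @export
simulate_trajectory <- function(N, rU, step_size = 25,
                                mode = c("stochastic", "sequential"),
                                noise_sd = 2, sample_rate = 1000,
                                detachment_factor = 5, force = 150,
                                seed = NULL, trajectory_id = "traj") {
  mode <- match.arg(mode)
  N <- as.integer(N)
  if (N < 1) stop("N must be >= 1")
  if (rU <= 0 || step_size <= 0 || noise_sd < 0 || detachment_factor <= 0) {
    stop("parameters must be positive (noise_sd may be zero)")
  }
  if (!is.null(seed)) set.seed(seed)
  waits <- stats::rexp(N, rate = rU)
  step_times <- if (mode == "stochastic") sort(waits) else cumsum(waits)
  t_N <- step_times[N]
  detachment <- detachment_factor * t_N
  time <- numeric(0)
  extension <- numeric(0)
  if (sample_rate > 0) {
    time <- seq(0, detachment, by = 1 / sample_rate)
    extension <- step_size * findInterval(time, step_times) +
      if (noise_sd > 0) stats::rnorm(length(time), 0, noise_sd) else 0
  }
  structure(list(trajectory_id = trajectory_id, time = time,
                 extension = extension, n_domains = N,
                 true_step_times = step_times, detachment_time = detachment,
                 force = force, step_size = step_size,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 mode = mode, detected_steps = NULL),
            class = "unfolding_trajectory")
}

#' @export
print.unfolding_trajectory <- function(x, ...) {
  cat(sprintf("<unfolding_trajectory> %s: N = %d (%s), t_N = %.3f s, detach = %.3f s, %d samples\n",
              x$trajectory_id, x$n_domains, x$mode,
              max(x$true_step_times), x$detachment_time, length(x$time)))
  invisible(x)
}

#' Detect unfolding steps in a sampled trajectory
#'
#' Change-point detection on the low-pass-filtered extension: the signal is
#' smoothed with a moving mean, the jump across each sample boundary is
#' estimated as the difference of the trailing and leading window means,
#' and contiguous above-threshold regions are collapsed to the boundary
#' with the largest jump. Jumps smaller than
#' `min_step_fraction * expected_step` are rejected; a single jump close to
#' a multiple of the expected step (sub-resolution coincidence of events)
#' is counted as that many steps at the same time.
#'
#' @param traj An [simulate_trajectory()] result (or any
#'   `unfolding_trajectory` with sampled `time`/`extension`).
#' @param expected_step Nominal step size, nm (default the trajectory's).
#' @param min_step_fraction Smallest accepted jump as a fraction of
#'   `expected_step` (default 0.5).
#' @param window Smoothing / jump-estimation window, seconds (default
#'   0.003).
#' @return Data.frame with columns `time` (s) and `size` (nm), one row per
#'   detected step (coincident events appear as repeated rows with split
#'   sizes). Empty data.frame if no steps.
#' @export
detect_steps <- function(traj, expected_step = NULL, min_step_fraction = 0.5,
                         window = 0.003) {
  stopifnot(inherits(traj, "unfolding_trajectory"))
  if (length(traj$time) == 0) stop("trajectory has no sampled extension")
  if (is.null(expected_step)) expected_step <- traj$step_size
  x <- traj$extension
  t <- traj$time
  n <- length(x)
  w <- max(1L, as.integer(round(window * traj$sample_rate)))
  if (n < 2 * w + 2) return(data.frame(time = numeric(0), size = numeric(0)))
  cs <- cumsum(x)
  # jump across the boundary between samples i and i+1:
  # mean(x[i+1 .. i+w]) - mean(x[i-w+1 .. i])
  i <- w:(n - w)
  lead <- (cs[i + w] - cs[i]) / w
  trail <- (cs[i] - c(0, cs)[i - w + 1]) / w
  jump <- lead - trail
  thr <- min_step_fraction * expected_step
  above <- jump > thr
  if (!any(above)) return(data.frame(time = numeric(0), size = numeric(0)))
  idx <- which(above)
  brk <- c(0, which(diff(idx) > w), length(idx))
  times <- numeric(0)
  sizes <- numeric(0)
  for (b in seq_len(length(brk) - 1)) {
    cl <- idx[(brk[b] + 1):brk[b + 1]]
    best <- cl[which.max(jump[cl])]
    sz <- jump[best]
    k <- max(1L, round(sz / expected_step))
    tt <- t[i[best]] + 0.5 / traj$sample_rate
    times <- c(times, rep(tt, k))
    sizes <- c(sizes, rep(sz / k, k))
  }
  data.frame(time = times, size = sizes)
}

#' Select analysable trajectories
#'
#' Retains only trajectories with a robust molecular fingerprint: at least
#' `min_steps` detected steps, and a detachment time at least
#' `detachment_multiple` times the last unfolding time (so that every
#' domain under force had time to unfold and the rate distribution is not
#' truncated).
#'
#' @param trajs List of `unfolding_trajectory` objects. Trajectories with a
#'   `detected_steps` element use the detected steps; otherwise the
#'   detector is run (sampled trajectories) or the true step times are used
#'   (fast-path trajectories).
#' @param min_steps Minimum step count (default 2).
#' @param detachment_multiple Minimum detachment-to-unfolding time ratio
#'   (default 3).
#' @param ... Passed to [detect_steps()] when detection is needed.
#' @return The retained sublist, each element annotated with
#'   `detected_steps`.
#' @export
select_trajectories <- function(trajs, min_steps = 2, detachment_multiple = 3,
                                ...) {
  out <- list()
  for (traj in trajs) {
    if (is.null(traj$detected_steps)) {
      traj$detected_steps <- if (length(traj$time)) {
        detect_steps(traj, ...)
      } else {
        data.frame(time = traj$true_step_times,
                   size = rep(traj$step_size, traj$n_domains))
      }
    }
    ns <- nrow(traj$detected_steps)
    if (ns < min_steps) next
    t_last <- max(traj$detected_steps$time)
    if (traj$detachment_time < detachment_multiple * t_last) next
    out[[length(out) + 1]] <- traj
  }
  out
}

#' Ensemble total unfolding rates grouped by step count
#'
#' Groups trajectories by their (detected) number of steps N and estimates
#' the total unfolding rate of each group as \eqn{r_N = 1 / \langle t_N
#' \rangle}, the inverse of the mean time of the last unfolding event.
#' (The alternative estimator \eqn{\langle 1/t_N \rangle} is not used: the
#' reciprocal of an exponential-like time has no finite expectation.) The
#' SEM is propagated from the SEM of \eqn{\langle t_N \rangle}.
#'
#' @param trajs List of `unfolding_trajectory` objects, typically from
#'   [select_trajectories()] (elements without `detected_steps` fall back
#'   to true step times).
#' @return Data.frame with columns `N`, `n_traj`, `r_N` (s^-1), `sem`
#'   (`NA` with a single trajectory in the group).
#' @export
ensemble_rates <- function(trajs) {
  if (length(trajs) == 0) stop("no trajectories")
  tN <- vapply(trajs, function(tr) {
    st <- if (!is.null(tr$detected_steps)) tr$detected_steps$time else tr$true_step_times
    max(st)
  }, numeric(1))
  nst <- vapply(trajs, function(tr) {
    as.numeric(if (!is.null(tr$detected_steps)) nrow(tr$detected_steps)
               else tr$n_domains)
  }, numeric(1))
  out <- do.call(rbind, lapply(sort(unique(nst)), function(N) {
    ti <- tN[nst == N]
    m <- mean(ti)
    sem_t <- if (length(ti) > 1) stats::sd(ti) / sqrt(length(ti)) else NA_real_
    data.frame(N = N, n_traj = length(ti), r_N = 1 / m,
               sem = sem_t / m^2)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the one-parameter N-scaling of unfolding rates
#'
#' Weighted least squares of the per-N total rates against
#' `rU / H_N` (stochastic) or `rU / N` (sequential) -- linear in the single
#' free parameter rU, so solved in closed form. Weights are `1/sem^2`
#' (unit weights where the SEM is missing). The residual sum of squares of
#' the competing model is reported alongside for model discrimination.
#'
#' @param rate_table Data.frame with columns `N`, `r_N` and optionally
#'   `sem`, as from [ensemble_rates()].
#' @param model `"stochastic"` or `"sequential"`.
#' @return Object of class `scaling_fit`: list with `model`, `rU_hat`
#'   (s^-1), `per_N_rates` (input table plus fitted values and residuals),
#'   `rss`, and `rss_alt` (competing model).
#' @export
fit_scaling <- function(rate_table, model = c("stochastic", "sequential")) {
  model <- match.arg(model)
  stopifnot(all(c("N", "r_N") %in% names(rate_table)))
  if (length(unique(rate_table$N)) < 2) {
    stop("need rates for at least 2 distinct N")
  }
  w <- if ("sem" %in% names(rate_table)) {
    s <- rate_table$sem
    ifelse(is.na(s) | s <= 0, 1, 1 / s^2)
  } else rep(1, nrow(rate_table))
  basis <- function(kind) {
    if (kind == "stochastic") 1 / harmonic_number(rate_table$N)
    else 1 / rate_table$N
  }
  wls <- function(kind) {
    x <- basis(kind)
    rU <- sum(w * x * rate_table$r_N) / sum(w * x^2)
    list(rU = rU, rss = sum(w * (rate_table$r_N - rU * x)^2))
  }
  this <- wls(model)
  other <- wls(setdiff(c("stochastic", "sequential"), model))
  tab <- rate_table
  tab$fitted <- this$rU * basis(model)
  tab$residual <- tab$r_N - tab$fitted
  structure(list(model = model, rU_hat = this$rU, per_N_rates = tab,
                 rss = this$rss, rss_alt = other$rss),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s model: rU = %.4f s^-1 (rss = %.3g; competing model rss = %.3g)\n",
              x$model, x$rU_hat, x$rss, x$rss_alt))
  invisible(x)
}

#' Read / write unfolding trajectories
#'
#' On-disk dialect: one CSV per trajectory with columns
#' `trajectory_id,time_s,extension_nm`, plus a JSON sidecar
#' (`<path>.json`) carrying N, force, mode, seed metadata and -- for
#' synthetic data -- the true step times.
#'
#' @param traj An `unfolding_trajectory`.
#' @param path CSV path (sidecar written next to it).
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the reconstructed object.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(trajectory_id = traj$trajectory_id,
                              time_s = traj$time,
                              extension_nm = traj$extension),
                   path, row.names = FALSE)
  meta <- traj[c("trajectory_id", "n_domains", "true_step_times",
                 "detachment_time", "force", "step_size", "sample_rate",
                 "noise_sd", "mode")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(trajectory_id = meta$trajectory_id, time = df$time_s,
                 extension = df$extension_nm, n_domains = meta$n_domains,
                 true_step_times = meta$true_step_times,
                 detachment_time = meta$detachment_time, force = meta$force,
                 step_size = meta$step_size, sample_rate = meta$sample_rate,
                 noise_sd = meta$noise_sd, mode = meta$mode,
                 detected_steps = NULL),
            class = "unfolding_trajectory")
}
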