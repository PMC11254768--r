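test_that("scaling laws match their closed forms", {
  expect_equal(stochastic_rate(1, 0.7), 0.7)
  expect_equal(sequential_rate(1, 0.7), 0.7)
  expect_equal(stochastic_rate(2, 1.0), 2 / 3)       # H2 = 1.5
  expect_equal(sequential_rate(8, 1.15), 0.14375)
  # H8 = 761/280
  expect_equal(harmonic_number(8), 761 / 280)
  expect_equal(stochastic_rate(8, 1.15), 1.15 / (761 / 280), tolerance = 1e-12)
  expect_equal(round(stochastic_rate(8, 1.15), 4), 0.4231)
  # stochastic decline is shallow: r1/r8 = H8 vs 8 for sequential
  expect_true(all(stochastic_rate(1:8, 1.15) >= sequential_rate(1:8, 1.15)))
  expect_equal(stochastic_rate(1, 1) / stochastic_rate(8, 1), 761 / 280)
  expect_equal(sequential_rate(1, 1) / sequential_rate(8, 1), 8)
  expect_error(stochastic_rate(0, 1), "N must be")
})

test_that("simulated staircases honour their construction", {
  tr <- simulate_trajectory(5, 1.15, noise_sd = 0, seed = 31)
  expect_length(tr$true_step_times, 5)
  expect_true(all(diff(tr$true_step_times) > 0))
  # noise-free extension is a monotone staircase ending at 5 steps
  expect_true(all(diff(tr$extension) >= 0))
  expect_equal(max(tr$extension), 5 * 25)
  expect_equal(tr$detachment_time, 5 * max(tr$true_step_times))
  expect_error(simulate_trajectory(0, 1), "N must be")
  # same seed -> bit-identical
  tr2 <- simulate_trajectory(5, 1.15, noise_sd = 0, seed = 31)
  expect_identical(tr$extension, tr2$extension)
})

test_that("mean last-unfolding times follow exponential order statistics", {
  # E[max of N exp(rU)] = H_N / rU; E[sum] = N / rU.
  # 1e4 reps per mode via the fast (unsampled) path.
  ens_s <- generate_trajectory_ensemble(1e4, N = 8, rU = 1.15,
                                        mode = "stochastic", seed = 32)
  r_s <- ensemble_rates(ens_s$trajectories)
  expect_equal(r_s$N, 8)
  expect_lt(abs(r_s$r_N / stochastic_rate(8, 1.15) - 1), 0.02)
  ens_q <- generate_trajectory_ensemble(1e4, N = 8, rU = 1.15,
                                        mode = "sequential", seed = 33)
  r_q <- ensemble_rates(ens_q$trajectories)
  expect_lt(abs(r_q$r_N / sequential_rate(8, 1.15) - 1), 0.02)
  # and within 3 MC standard errors using the truth table directly
  se <- sd(ens_s$truth$t_N) / sqrt(nrow(ens_s$truth))
  expect_lt(abs(mean(ens_s$truth$t_N) - harmonic_number(8) / 1.15), 3 * se)
})

test_that("step detection is exact on clean staircases and silent on noise", {
  tr <- simulate_trajectory(5, 1.15, noise_sd = 0, seed = 34)
  st <- detect_steps(tr)
  expect_equal(nrow(st), 5)
  expect_equal(st$time, tr$true_step_times, tolerance = 2e-3)
  expect_equal(st$size, rep(25, 5), tolerance = 0.02)
  # counts recovered exactly for N up to 8 on clean data
  for (N in c(1, 3, 8)) {
    trN <- simulate_trajectory(N, 1.15, noise_sd = 0, seed = 340 + N)
    expect_equal(nrow(detect_steps(trN)), N)
  }
  # pure noise, no steps
  flat <- simulate_trajectory(1, 1.15, noise_sd = 2, seed = 35)
  flat$extension <- rnorm(length(flat$time), 0, 2)
  expect_equal(nrow(detect_steps(flat)), 0)
  expect_error(detect_steps(structure(list(time = numeric(0)),
                                      class = "unfolding_trajectory")),
               "no sampled")
})

test_that("noisy step detection matches truth within +/- 5 ms", {
  set.seed(36)
  matched <- 0; total <- 0
  for (i in 1:500) {
    tr <- simulate_trajectory(8, 1.15, noise_sd = 2, sample_rate = 1000,
                              seed = NULL)
    st <- detect_steps(tr)
    matched <- matched + match_steps(st$time, tr$true_step_times, 0.005)
    total <- total + 8
  }
  expect_gte(matched / total, 0.95)
})

test_that("trajectory selection enforces the fingerprint rules", {
  one_step <- simulate_trajectory(1, 1.15, noise_sd = 0, seed = 37)
  keep <- select_trajectories(list(one_step))
  expect_length(keep, 0)                       # < 2 steps
  close_detach <- simulate_trajectory(4, 1.15, noise_sd = 0, seed = 38,
                                      detachment_factor = 2)
  far_detach <- simulate_trajectory(4, 1.15, noise_sd = 0, seed = 38,
                                    detachment_factor = 4)
  kept <- select_trajectories(list(close_detach, far_detach))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$detachment_time, far_detach$detachment_time)
  expect_length(select_trajectories(list()), 0)
})

test_that("ensemble rates handle degenerate groups", {
  mk <- function(id, times) {
    structure(list(trajectory_id = id, time = numeric(0),
                   extension = numeric(0), n_domains = length(times),
                   true_step_times = times, detachment_time = 5 * max(times),
                   force = 150, step_size = 25, sample_rate = 0,
                   noise_sd = 0, mode = "stochastic", detected_steps = NULL),
              class = "unfolding_trajectory")
  }
  same <- list(mk("a", c(1, 2)), mk("b", c(0.5, 2)), mk("c", c(1.5, 2)))
  r <- ensemble_rates(same)
  expect_equal(r$r_N, 0.5)
  expect_equal(r$sem, 0)
  single <- ensemble_rates(list(mk("solo", c(0.4, 2.5))))
  expect_equal(single$r_N, 0.4)
  expect_true(is.na(single$sem))                # flagged undefined
  expect_error(ensemble_rates(list()), "no trajectories")
})

test_that("scaling fit is exact on exact tables and discriminates models", {
  tab <- data.frame(N = 1:8, r_N = 2.0 / harmonic_number(1:8))
  fit <- fit_scaling(tab, "stochastic")
  expect_equal(fit$rU_hat, 2.0, tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_gt(fit$rss_alt, 0)
  seq_tab <- data.frame(N = 1:8, r_N = 2.0 / (1:8))
  wrong <- fit_scaling(seq_tab, "stochastic")
  expect_gt(wrong$rss, 0)
  # scale equivariance: rates * c -> rU_hat * c
  fit3 <- fit_scaling(transform(tab, r_N = r_N * 3.7), "stochastic")
  expect_equal(fit3$rU_hat, 2.0 * 3.7, tolerance = 1e-12)
  expect_error(fit_scaling(data.frame(N = 2, r_N = 1), "stochastic"),
               "2 distinct N")
})

test_that("scaling fit recovers the generating rate from noisy ensembles", {
  ens <- generate_trajectory_ensemble(4000, N = "uniform", N_max = 8,
                                      rU = 1.15, mode = "stochastic",
                                      seed = 39)
  kept <- select_trajectories(ens$trajectories)
  rates <- ensemble_rates(kept)
  fit <- fit_scaling(rates[rates$N <= 8, ], "stochastic")
  expect_lt(abs(fit$rU_hat / 1.15 - 1), 0.05)
  expect_lt(fit$rss, fit$rss_alt)
  # mixed pickup gives roughly uniform group sizes (chi-square sanity)
  counts <- table(factor(ens$truth$N, levels = 1:8))
  chi <- sum((counts - 500)^2 / 500)
  expect_lt(chi, 30)
})

test_that("trajectory CSV + sidecar round trip preserves the object", {
  tr <- simulate_trajectory(4, 1.15, noise_sd = 1, seed = 40)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory(tr, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$extension, tr$extension)
  expect_equal(back$true_step_times, tr$true_step_times)
  expect_equal(back$n_domains, 4)
  expect_equal(back$mode, "stochastic")
})

test_that("the CLI subcommands run end to end", {
  dir <- file.path(tempdir(), "cli_out")
  res <- suppressMessages(
    unfolding_cli(c("simulate-trajectories", "--n-traj", "5",
                    "--n-domains", "4", "--seed", "99", "--sampled", "true",
                    "--out-dir", dir)))
  expect_length(res$trajectories, 5)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  csv1 <- file.path(dir, "traj_00001.csv")
  out1 <- tempfile(fileext = ".csv")
  unfolding_cli(c("detect-steps", "--trajectory", csv1, "--out", out1))
  expect_true(file.exists(out1))
  rates_csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(N = 1:8, r_N = 1.15 / harmonic_number(1:8)),
            rates_csv, row.names = FALSE)
  outj <- tempfile(fileext = ".json")
  unfolding_cli(c("scaling-fit", "--rates", rates_csv, "--model",
                  "stochastic", "--out", outj))
  got <- jsonlite::read_json(outj, simplifyVector = TRUE)
  expect_equal(got$rU_hat, 1.15, tolerance = 1e-10)
  expect_error(unfolding_cli("nope"), "unknown subcommand")
})
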