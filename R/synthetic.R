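#' Reported per-construct import-rate table
#'
#' Packaged fixture of the population import-rate constants (mean +/- SEM,
#' retained cell count) reported for each optogenetic construct, keyed by
#' construct name and experimental cohort (the same construct was
#' re-measured in several experiment series, with slightly different
#' values; all are kept). Rates are in ks^-1 except the `mrtfa` cohort,
#' whose values are dimensionless normalized rates (GFP/mCherry channel
#' ratio).
#'
#' Masses and unfolding forces are coordinates for the mass-law and
#' free-energy analyses: masses are approximate construct masses (the
#' monomer cargo construct is ~55 kDa; an R16 fusion ~70 kDa) and the
#' unfolding forces are representative single-molecule AFM values for the
#' leading domain (R16 ~40 pN, I27 V13P ~130 pN, I27 WT ~200 pN, I27 Y9P
#' ~250 pN, the inextensible pilin Spy0128 nominally 1000 pN). The forces
#' are synthetic/representative placeholders, not measured values from
#' this dataset; they never enter any fitted quantity.
#'
#' @param name Optional construct name; returns that construct's rows
#'   (error if unknown).
#' @param cohort Optional cohort filter, one of `"monomer"`,
#'   `"heterodimer"`, `"spy"`, `"gs_length"`, `"tag_chemistry"`,
#'   `"gs_by_variant"`, `"nup153_knockdown"`, `"mrtfa"`.
#' @return Data.frame with columns `name`, `cohort`, `condition`,
#'   `n_domains`, `mass_kda`, `unfolding_force_pn`, `ki_mean_ks`,
#'   `ki_sem_ks`, `n_cells`, `leading_domain`. With `name` given and
#'   several cohorts matching, the first (canonical) row is ordered first.
#' @export
construct_table <- function(name = NULL, cohort = NULL) {
  r <- function(name, cohort, condition, N, M, FU, ki, sem, n, lead) {
    data.frame(name = name, cohort = cohort, condition = condition,
               n_domains = N, mass_kda = M, unfolding_force_pn = FU,
               ki_mean_ks = ki, ki_sem_ks = sem, n_cells = n,
               leading_domain = lead, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    # monomers
    r("WT",   "monomer", "none", 1, 55, 200, 1.62, 0.05, 249, "WT"),
    r("V13P", "monomer", "none", 1, 55, 130, 1.80, 0.09, 161, "V13P"),
    r("Y9P",  "monomer", "none", 1, 55, 250, 1.09, 0.03, 279, "Y9P"),
    # soft/stiff heterodimers (directionality series)
    r("R16-V13P", "heterodimer", "none", 2, 70,  40, 1.64, 0.04, 276, "R16"),
    r("V13P-R16", "heterodimer", "none", 2, 70, 130, 1.72, 0.04, 154, "V13P"),
    r("R16-WT",   "heterodimer", "none", 2, 70,  40, 1.42, 0.04, 192, "R16"),
    r("WT-R16",   "heterodimer", "none", 2, 70, 200, 1.29, 0.04, 260, "WT"),
    r("R16-Y9P",  "heterodimer", "none", 2, 70,  40, 1.58, 0.07,  80, "R16"),
    r("Y9P-R16",  "heterodimer", "none", 2, 70, 250, 1.02, 0.08,  55, "Y9P"),
    # ultrastable pilin trimers
    r("(WT)2-Spy0128", "spy", "none", 3, 90,  200, 0.89, 0.07,  70, "WT"),
    r("WT-Spy0128-WT", "spy", "none", 3, 90,  200, 0.99, 0.07, 118, "WT"),
    r("Spy0128-(WT)2", "spy", "none", 3, 90, 1000, 0.56, 0.03, 106, "Spy0128"),
    # GS-tag length series
    r("WT",        "gs_length", "none", 1, 55.0, 200, 1.64, 0.05, 249, "WT"),
    r("(GS)-WT",   "gs_length", "none", 1, 55.2, 200, 1.65, 0.07, 131, "GS-tag"),
    r("(GS)2-WT",  "gs_length", "none", 1, 55.4, 200, 1.88, 0.04, 131, "GS-tag"),
    r("(GS)4-WT",  "gs_length", "none", 1, 55.9, 200, 1.82, 0.03, 357, "GS-tag"),
    r("(GS)8-WT",  "gs_length", "none", 1, 56.8, 200, 1.61, 0.07,  89, "GS-tag"),
    r("(GS)25-WT", "gs_length", "none", 1, 60.5, 200, 1.29, 0.06,  70, "GS-tag"),
    # tag chemistry series (same WT baseline cohort)
    r("WT",       "tag_chemistry", "none", 1, 55.0, 200, 1.60, 0.06,  80, "WT"),
    r("(GS)4-WT", "tag_chemistry", "none", 1, 55.9, 200, 1.82, 0.07, 357, "GS-tag"),
    r("(GI)4-WT", "tag_chemistry", "none", 1, 55.9, 200, 1.97, 0.06,  87, "GI-tag"),
    r("(GD)4-WT", "tag_chemistry", "none", 1, 55.9, 200, 1.45, 0.04,  98, "GD-tag"),
    # (GS)4 across mechanical variants
    r("(GS)4-V13P", "gs_by_variant", "none", 1, 55.9, 130, 1.90, 0.05, 127, "GS-tag"),
    r("V13P",       "gs_by_variant", "none", 1, 55.0, 130, 1.87, 0.08, 170, "V13P"),
    r("(GS)4-Y9P",  "gs_by_variant", "none", 1, 55.9, 250, 1.48, 0.05, 132, "GS-tag"),
    # Nup153 knockdown series
    r("R16-WT",   "nup153_knockdown", "siNT",     2, 70,  40, 1.35, 0.05, 130, "R16"),
    r("R16-WT",   "nup153_knockdown", "siNup153", 2, 70,  40, 1.15, 0.05, 108, "R16"),
    r("WT-R16",   "nup153_knockdown", "siNT",     2, 70, 200, 1.20, 0.05, 179, "WT"),
    r("WT-R16",   "nup153_knockdown", "siNup153", 2, 70, 200, 1.09, 0.05,  98, "WT"),
    r("R16-Y9P",  "nup153_knockdown", "siNT",     2, 70,  40, 1.51, 0.06,  92, "R16"),
    r("R16-Y9P",  "nup153_knockdown", "siNup153", 2, 70,  40, 0.93, 0.06,  57, "R16"),
    r("Y9P-R16",  "nup153_knockdown", "siNT",     2, 70, 250, 1.07, 0.04, 100, "Y9P"),
    r("Y9P-R16",  "nup153_knockdown", "siNup153", 2, 70, 250, 0.83, 0.09,  33, "Y9P"),
    r("WT",       "nup153_knockdown", "siNT",     1, 55, 200, 1.61, 0.05, 147, "WT"),
    r("WT",       "nup153_knockdown", "siNup153", 1, 55, 200, 1.22, 0.05, 118, "WT"),
    r("(GS)4-WT", "nup153_knockdown", "siNT",     1, 55.9, 200, 2.02, 0.05, 169, "GS-tag"),
    r("(GS)4-WT", "nup153_knockdown", "siNup153", 1, 55.9, 200, 1.28, 0.04, 122, "GS-tag"),
    # MRTFA (normalized, dimensionless GFP/mCherry rates)
    r("MRTFA",       "mrtfa", "none", 1, NA, NA, 0.68, 0.03, 21, "MRTFA"),
    r("(GS)4-MRTFA", "mrtfa", "none", 1, NA, NA, 0.87, 0.03, 34, "GS-tag")
  )
  if (!is.null(cohort)) {
    if (!all(cohort %in% tab$cohort)) stop("unknown cohort: ", cohort)
    tab <- tab[tab$cohort %in% cohort, , drop = FALSE]
  }
  if (!is.null(name)) {
    if (!all(name %in% tab$name)) {
      stop("unknown construct: ", paste(setdiff(name, tab$name), collapse = ", "))
    }
    tab <- tab[tab$name %in% name, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Configuration for the synthetic single-cell generators
#'
#' Collects every generation parameter with the acquisition defaults of the
#' emulated experiments: blue-light activation for 10 min with one frame
#' per minute, then a 45-min dark recovery at the same frame rate.
#'
#' @param seed Integer seed (mandatory: every generator is a deterministic
#'   function of its parameters and the seed).
#' @param n_cells Number of cells for [generate_population()].
#' @param frame_interval Frame spacing, s (default 60).
#' @param activation_duration Light phase length, s (default 600).
#' @param recovery_duration Dark recovery length, s (default 2700).
#' @param noise_cv Per-frame multiplicative Gaussian noise CV on each
#'   compartment signal (default 0.05, shot-noise-like).
#' @param intercell_sigma Log-scale SD of kI and Ke across cells (default
#'   0.3; rates are positive and right-skewed, so lognormal with the
#'   construct value as median).
#' @param v_mean,v_sd Truncated-normal distribution of the per-cell volume
#'   ratio (defaults 0.25, 0.05).
#' @param Ke_mean Median steady-state accumulation (default 2).
#' @param n0_mean,n0_sd Residual-activation amplitude distribution
#'   (truncated normal at zero; defaults 0.05, 0.02 signal units).
#' @param k_act_mean,k_act_sd Activation-phase export rate distribution for
#'   well-activated cells, ks^-1 (truncated normal, defaults 6, 1.5,
#'   floored at 1.5 -- safely above the 1.4 ks^-1 QC threshold).
#' @param poor_activation_frac Fraction of cells whose activation rate is
#'   drawn uniformly in (0.5, 1.1) ks^-1, i.e. constructed QC failures
#'   (default 0).
#' @param construct Name keying [construct_table()] for the generating kI.
#' @param direction `"import"`, `"export"` or `"coupled"`.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, n_cells = 100, frame_interval = 60,
                             activation_duration = 600,
                             recovery_duration = 2700, noise_cv = 0.05,
                             intercell_sigma = 0.3, v_mean = 0.25,
                             v_sd = 0.05, Ke_mean = 2, n0_mean = 0.05,
                             n0_sd = 0.02, k_act_mean = 6, k_act_sd = 1.5,
                             poor_activation_frac = 0, construct = "WT",
                             direction = c("import", "export", "coupled")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory (reproducibility contract)")
  }
  direction <- match.arg(direction)
  stopifnot(frame_interval > 0, activation_duration > 0,
            recovery_duration > 0, noise_cv >= 0, intercell_sigma >= 0,
            v_mean > 0, n_cells >= 1)
  structure(list(seed = as.integer(seed), n_cells = n_cells,
                 frame_interval = frame_interval,
                 activation_duration = activation_duration,
                 recovery_duration = recovery_duration, noise_cv = noise_cv,
                 intercell_sigma = intercell_sigma, v_mean = v_mean,
                 v_sd = v_sd, Ke_mean = Ke_mean, n0_mean = n0_mean,
                 n0_sd = n0_sd, k_act_mean = k_act_mean,
                 k_act_sd = k_act_sd,
                 poor_activation_frac = poor_activation_frac,
                 construct = construct, direction = direction),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param config A `synthetic_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname synthetic_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_config, x)
}

# truncated-normal draw (simple rejection-free clamp-resample)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0
  while (length(bad) && guard < 100) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    guard <- guard + 1
  }
  pmin(pmax(x, lower), upper)
}

# Forward model of one cell's signals. The recovery nuclear signal is
# n0 e^{-kI t} + Ke g0 (1 - e^{-kI t}) (shared-rate form, so the
# initial-condition correction model is exact) and the cytoplasmic signal
# g0 (1 + v Ke e^{-kI t}), which makes the corrected nucleus/cytoplasm
# ratio exactly the compartmental model; with n0 = 0 the raw ratio is.
.import_signals <- function(t_act, t_rec, Ke, kI, v, n0, k_act) {
  g0 <- 1
  Ea <- exp(-(k_act / .KS) * t_act)
  nuc_a <- n0 + (Ke * g0 - n0) * Ea
  cyt_a <- g0 * (1 + v * Ke * (1 - Ea))
  Er <- exp(-(kI / .KS) * t_rec)
  nuc_r <- n0 * Er + Ke * g0 * (1 - Er)
  cyt_r <- g0 * (1 + v * Ke * Er)
  list(nuc = c(nuc_a, nuc_r), cyt = c(cyt_a, cyt_r))
}

#' Generate one synthetic single-cell trace
#'
#' Forward model of an optogenetic shuttling experiment: during the light
#' phase the nuclear signal decays exponentially at the activation export
#' rate toward a residual; during dark recovery the signals follow the
#' compartmental model with the cell's (Ke, kI, v) plus a residual
#' amplitude `n0` decaying at the recovery rate (the form removed exactly
#' by [correct_initial_conditions()]). Multiplicative Gaussian noise of CV
#' `noise_cv` is applied per frame to each compartment signal. With
#' `noise_cv = 0` and `n0 = 0` the recovery nucleus-to-cytoplasm ratio
#' equals the compartmental model to machine precision.
#'
#' Export-direction traces are generated as the exact mirror (compartments
#' swapped, volume ratio inverted), with the rate interpreted as kE.
#'
#' @param params List with `Ke`, `kI` (ks^-1; interpreted as kE for export
#'   traces), `v`, and optionally `n0` (default 0) and `k_act` (ks^-1,
#'   default 6).
#' @param config A [synthetic_config()] (its `seed` is consumed here; pass
#'   `seed = NULL` inside [generate_population()]-style loops that manage
#'   the RNG stream themselves).
#' @param cell_id Identifier.
#' @param use_seed Set the RNG from `config$seed` (default `TRUE`).
#' @return A [cell_trace()].
#' @export
generate_cell_trace <- function(params, config, cell_id = "cell_1",
                                use_seed = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (use_seed) set.seed(config$seed)
  Ke <- params$Ke
  rate <- params$kI
  v <- params$v
  n0 <- if (is.null(params$n0)) 0 else params$n0
  k_act <- if (is.null(params$k_act)) 6 else params$k_act
  stopifnot(Ke > 0, rate > 0, v > 0, n0 >= 0)
  dt <- config$frame_interval
  t_act <- seq(0, config$activation_duration, by = dt)
  t_rec <- seq(0, config$recovery_duration, by = dt)
  vv <- if (config$direction == "export") 1 / v else v
  sig <- .import_signals(t_act, t_rec, Ke, rate, vv, n0, k_act)
  nuc <- sig$nuc
  cyt <- sig$cyt
  if (config$direction == "export") {  # mirror: swap compartments
    tmp <- nuc; nuc <- cyt; cyt <- tmp
  }
  if (config$noise_cv > 0) {
    nuc <- nuc * (1 + stats::rnorm(length(nuc), 0, config$noise_cv))
    cyt <- cyt * (1 + stats::rnorm(length(cyt), 0, config$noise_cv))
    nuc <- pmax(nuc, 1e-9)
    cyt <- pmax(cyt, 1e-9)
  }
  time <- c(t_act, config$activation_duration + dt + t_rec)
  phase <- c(rep("activation", length(t_act)), rep("recovery", length(t_rec)))
  cell_trace(cell_id, time, nuc, nuc + cyt, phase,
             direction = config$direction, v = v)
}

#' Generate a synthetic cell population with ground truth
#'
#' Draws per-cell kinetic parameters around the construct's fixture values
#' -- kI lognormal with the [construct_table()] rate as median and log-SD
#' `intercell_sigma`, Ke lognormal around `Ke_mean`, v truncated normal --
#' generates each cell's trace, and returns the traces together with a
#' truth table for recovery tests. A configured fraction of cells is
#' generated "poorly activated" (activation rate drawn below the QC
#' threshold) to exercise the filters.
#'
#' @param config A [synthetic_config()].
#' @return List with `traces` (named list of [cell_trace()]) and `truth`
#'   (data.frame: `cell_id`, `kI`, `Ke`, `v`, `n0`, `k_act`,
#'   `poorly_activated`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  base <- construct_table(config$construct)
  kI0 <- base$ki_mean_ks[1]
  n <- config$n_cells
  kI <- stats::rlnorm(n, meanlog = log(kI0), sdlog = config$intercell_sigma)
  Ke <- stats::rlnorm(n, meanlog = log(config$Ke_mean),
                      sdlog = config$intercell_sigma)
  v <- .rtnorm(n, config$v_mean, config$v_sd, lower = 0.05)
  n0 <- .rtnorm(n, config$n0_mean, config$n0_sd, lower = 0)
  poor <- stats::runif(n) < config$poor_activation_frac
  k_act <- ifelse(poor,
                  stats::runif(n, 0.5, 1.1),
                  .rtnorm(n, config$k_act_mean, config$k_act_sd, lower = 1.5))
  ids <- sprintf("cell_%04d", seq_len(n))
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    traces[[i]] <- generate_cell_trace(
      list(Ke = Ke[i], kI = kI[i], v = v[i], n0 = n0[i], k_act = k_act[i]),
      config, cell_id = ids[i], use_seed = FALSE)
  }
  names(traces) <- ids
  list(traces = traces,
       truth = data.frame(cell_id = ids, kI = kI, Ke = Ke, v = v, n0 = n0,
                          k_act = k_act, poorly_activated = poor,
                          stringsAsFactors = FALSE))
}

#' Generate a coupled import/export trace (optionally two channels)
#'
#' Serum-stimulation-style forward model of a cargo with simultaneous
#' active import and export: the nucleus-to-cytoplasm ratio follows the
#' coupled compartmental model with aggregates Ke = kI/kE and
#' k = kE + v kI. There is no light phase; all frames are labelled
#' recovery and start from a depleted nucleus. When reference rates are
#' supplied a second channel sharing the cell's volume ratio is generated
#' (internal-normalization experiments).
#'
#' @param kI,kE Generating rates, ks^-1.
#' @param v Volume ratio.
#' @param config A [synthetic_config()] (`direction` is ignored; frames and
#'   noise settings are used; the seed is consumed here).
#' @param kI_ref,kE_ref Optional second-channel rates.
#' @param cell_id Identifier.
#' @return A single [cell_trace()] (direction `"coupled"`), or a list with
#'   elements `gfp` and `mcherry` when reference rates are given.
#' @export
generate_coupled_trace <- function(kI, kE, v, config, kI_ref = NULL,
                                   kE_ref = NULL, cell_id = "cell_1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  one <- function(ki, ke, id) {
    Ke_hat <- ki / ke
    k_hat <- ke + v * ki
    t <- seq(0, config$recovery_duration, by = config$frame_interval)
    E <- exp(-(k_hat / .KS) * t)
    nuc <- Ke_hat * (1 - E)
    cyt <- 1 + v * Ke_hat * E
    if (config$noise_cv > 0) {
      nuc <- pmax(nuc * (1 + stats::rnorm(length(nuc), 0, config$noise_cv)), 0)
      cyt <- pmax(cyt * (1 + stats::rnorm(length(cyt), 0, config$noise_cv)), 1e-9)
    }
    cell_trace(id, t, nuc, nuc + cyt, rep("recovery", length(t)),
               direction = "coupled", v = v)
  }
  if (is.null(kI_ref)) return(one(kI, kE, cell_id))
  list(gfp = one(kI, kE, paste0(cell_id, "_gfp")),
       mcherry = one(kI_ref, kE_ref, paste0(cell_id, "_mcherry")))
}

#' Generate an ensemble of force-clamp trajectories with ground truth
#'
#' Delegates to [simulate_trajectory()] across a configured distribution of
#' pickup lengths N (the AFM tip picks the chain up at a random position,
#' so trajectories show up to the full number of domains). Returns the
#' trajectories plus a truth table for detector and rate-estimator tests.
#'
#' @param n_traj Number of trajectories.
#' @param N Either a single domain count, a vector sampled from uniformly
#'   (mixed pickup), or `"uniform"` for uniform pickup over 1..N_max.
#' @param N_max Maximum domain count for `"uniform"` pickup (default 8).
#' @param rU Per-domain unfolding rate, s^-1.
#' @param mode `"stochastic"` or `"sequential"`.
#' @param seed Integer seed (mandatory).
#' @param sampled Synthesize the noisy extension waveform (default
#'   `FALSE`: event times only, the fast path for rate studies).
#' @param ... Further arguments to [simulate_trajectory()].
#' @return List with `trajectories` and `truth` (data.frame:
#'   `trajectory_id`, `N`, `t_N`, `detachment_time`).
#' @export
generate_trajectory_ensemble <- function(n_traj, N = 8, N_max = 8, rU = 1.15,
                                         mode = c("stochastic", "sequential"),
                                         seed, sampled = FALSE, ...) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  Ns <- if (identical(N, "uniform")) {
    sample.int(N_max, n_traj, replace = TRUE)
  } else if (length(N) == 1) {
    rep(as.integer(N), n_traj)
  } else {
    sample(as.integer(N), n_traj, replace = TRUE)
  }
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    trajs[[i]] <- simulate_trajectory(
      Ns[i], rU, mode = mode, seed = NULL,
      sample_rate = if (sampled) 1000 else 0,
      trajectory_id = sprintf("traj_%05d", i), ...)
  }
  truth <- data.frame(
    trajectory_id = vapply(trajs, `[[`, character(1), "trajectory_id"),
    N = Ns,
    t_N = vapply(trajs, function(tr) max(tr$true_step_times), numeric(1)),
    detachment_time = vapply(trajs, `[[`, numeric(1), "detachment_time"),
    stringsAsFactors = FALSE)
  list(trajectories = trajs, truth = truth)
}
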