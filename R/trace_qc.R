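#' Flag unphysical fits
#'
#' Step 1a of the three-step filtering protocol: marks fits that did not
#' converge, have non-positive parameters, or sit at the optimizer bounds
#' (a parameter pinned at a bound is a failed fit in disguise).
#'
#' @param fits List of [recovery_fit()] objects.
#' @param rel_tol Relative closeness to a bound that counts as "at bound".
#' @return The list with `"unphysical"` added to `qc_flags` where needed.
#'   Parameter values are never mutated, only flags.
#' @export
flag_unphysical <- function(fits, rel_tol = 1e-3) {
  lapply(fits, function(f) {
    bad <- !f$converged
    rate <- if (!is.na(f$kI)) f$kI else f$kE
    if (!bad) {
      bad <- is.na(rate) || rate <= 0 || is.na(f$Ke) || f$Ke <= 0 ||
        rate >= .KI_MAX * (1 - rel_tol) || f$Ke >= .KE_ACC_MAX * (1 - rel_tol)
    }
    if (bad) f$qc_flags <- unique(c(f$qc_flags, "unphysical"))
    f
  })
}

#' Iterative extreme studentized deviate outlier filter
#'
#' Step 1b of the filtering protocol. Iteratively removes the single most
#' extreme value while its studentized deviation |x - mean| / sd exceeds
#' `tolerance_sd`, recomputing mean and sd after every removal. This is the
#' generalized-extreme-studentized-deviate style sweep with the literal
#' "tolerance of two standard deviations" as the critical value (not the
#' alpha-based GESD critical value). Deterministic and idempotent.
#'
#' @param values Numeric vector of fitted rates (or accumulations).
#' @param tolerance_sd Critical studentized deviation (default 2).
#' @param max_iter Maximum removals; default 20% of the sample size
#'   (at least 1), standard bounded-runtime practice.
#' @return List with integer index vectors `kept` and `rejected` (indices
#'   into `values`).
#' @export
gesd_filter <- function(values, tolerance_sd = 2,
                        max_iter = max(1L, ceiling(0.2 * length(values)))) {
  n <- length(values)
  if (n < 3) {
    warning("gesd_filter needs >= 3 values; returning all as kept")
    return(list(kept = seq_len(n), rejected = integer()))
  }
  kept <- seq_len(n)
  rejected <- integer()
  for (i in seq_len(max_iter)) {
    if (length(kept) <= 2) break
    x <- values[kept]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    z <- abs(x - mean(x)) / s
    worst <- which.max(z)
    if (z[worst] <= tolerance_sd) break
    rejected <- c(rejected, kept[worst])
    kept <- kept[-worst]
  }
  list(kept = kept, rejected = sort(rejected))
}

#' Apply the outlier filter to a fit collection
#'
#' Runs [gesd_filter()] independently on the kI (or kE for export fits) and
#' Ke distributions of the converged, physically sensible fits; a cell
#' rejected by either sweep gets the `"gesd_outlier"` flag.
#'
#' @param fits List of [recovery_fit()] objects (typically after
#'   [flag_unphysical()]).
#' @inheritParams gesd_filter
#' @return The list with flags added.
#' @export
flag_outliers <- function(fits, tolerance_sd = 2) {
  eligible <- which(vapply(fits, function(f) {
    f$converged && !("unphysical" %in% f$qc_flags)
  }, logical(1)))
  if (length(eligible) < 3) return(fits)
  rate <- vapply(fits[eligible],
                 function(f) if (!is.na(f$kI)) f$kI else f$kE, numeric(1))
  acc <- vapply(fits[eligible], function(f) f$Ke, numeric(1))
  rej <- union(gesd_filter(rate, tolerance_sd)$rejected,
               gesd_filter(acc, tolerance_sd)$rejected)
  for (i in rej) {
    j <- eligible[i]
    fits[[j]]$qc_flags <- unique(c(fits[[j]]$qc_flags, "gesd_outlier"))
  }
  fits
}

#' Activation-phase quality control
#'
#' Step 2 of the filtering protocol. The compartmental model assumes the
#' activation phase fully depleted the nucleus ([N]0 -> 0), which holds
#' only if export during activation was fast. The activation-phase nuclear
#' signal (cytoplasmic signal for export-direction traces) is fitted to a
#' single exponential decay `a * exp(-k t) + c`; the cell fails QC iff the
#' fitted rate is below `threshold`.
#'
#' @param trace A [cell_trace()] with activation frames.
#' @param threshold Minimum acceptable activation rate, ks^-1 (default 1.4).
#' @return List with `pass` (logical), `k_act` (fitted rate, ks^-1; `NA` if
#'   the fit failed, which also fails QC).
#' @export
activation_qc <- function(trace, threshold = 1.4) {
  stopifnot(inherits(trace, "cell_trace"))
  act <- trace[trace$phase == "activation", , drop = FALSE]
  if (nrow(act) < 3) stop("activation-phase frames are required")
  t <- act$time - act$time[1]
  y <- if (attr(trace, "direction") == "export") act$cell - act$nuc else act$nuc
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-k * t) + c0,
               start = list(a = max(y[1] - y[length(y)], 1e-8),
                            c0 = max(min(y), 0), k = 2e-3),
               algorithm = "port",
               lower = c(a = 1e-12, c0 = 0, k = 1e-8),
               upper = c(a = Inf, c0 = Inf, k = 1),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(pass = FALSE, k_act = NA_real_))
  # a flat trace can "converge" with a vanishing amplitude and an arbitrary
  # rate; demand that the decay actually explains the signal
  var0 <- sum((y - mean(y))^2)
  r2 <- if (var0 > 0) 1 - sum(resid(fit)^2) / var0 else 0
  if (r2 < 0.2 || unname(coef(fit)["a"]) <= 1e-6 * max(abs(y), 1)) {
    return(list(pass = FALSE, k_act = NA_real_))
  }
  k_act <- unname(coef(fit)["k"]) * .KS
  list(pass = k_act >= threshold, k_act = k_act)
}

#' Run activation QC over matched traces and fits
#'
#' Convenience wrapper: evaluates [activation_qc()] per trace, stores the
#' fitted `k_act` in the matching fit and flags `"poor_activation"` on
#' failure.
#'
#' @param fits List of [recovery_fit()] objects.
#' @param traces Named list of [cell_trace()] objects (names or `cell_id`
#'   attributes matching the fits).
#' @inheritParams activation_qc
#' @return The annotated fit list.
#' @export
flag_poor_activation <- function(fits, traces, threshold = 1.4) {
  ids <- vapply(traces, function(tr) attr(tr, "cell_id"), character(1))
  lapply(fits, function(f) {
    i <- match(f$cell_id, ids)
    if (is.na(i)) return(f)
    qc <- activation_qc(traces[[i]], threshold)
    f$k_act <- qc$k_act
    if (!qc$pass) f$qc_flags <- unique(c(f$qc_flags, "poor_activation"))
    f
  })
}

#' Apply a manual rejection list
#'
#' Step 3 of the filtering protocol: human inspection is represented by an
#' explicit exclusion list of cell identifiers. Listed cells are flagged
#' `"manual_reject"`; the flag (audit trail) is retained in all outputs.
#'
#' @param fits List of [recovery_fit()] objects.
#' @param reject_list Character vector of cell identifiers.
#' @return The annotated fit list. Unknown identifiers trigger a warning
#'   and are ignored.
#' @export
apply_manual_rejections <- function(fits, reject_list) {
  if (length(reject_list) == 0) return(fits)
  ids <- vapply(fits, function(f) f$cell_id, character(1))
  unknown <- setdiff(reject_list, ids)
  if (length(unknown)) {
    warning("unknown cell ids in reject list: ", paste(unknown, collapse = ", "))
  }
  lapply(fits, function(f) {
    if (f$cell_id %in% reject_list) {
      f$qc_flags <- unique(c(f$qc_flags, "manual_reject"))
    }
    f
  })
}

#' Population summary of retained cells
#'
#' Mean and SEM of the fitted rate and accumulation over retained cells
#' (converged, no QC flags), plus the point-by-point average recovery ratio
#' curve on the common recovery time grid.
#'
#' @param fits List of [recovery_fit()] objects.
#' @param traces Optional named list of matching [cell_trace()] objects;
#'   when supplied, the mean time course is computed.
#' @param construct Label carried through to the summary.
#' @return An object of class `population_summary`: list with `construct`,
#'   `n`, `kI_mean`, `kI_sem`, `Ke_mean`, `Ke_sem` and (if traces given)
#'   `mean_timecourse` (data.frame `time`, `mean`, `sem`, `n`). SEM is 0 by
#'   convention when `n = 1`.
#' @export
summarize_population <- function(fits, traces = NULL, construct = NA_character_) {
  keep <- vapply(fits, is_retained, logical(1))
  if (!any(keep)) stop("no retained cells")
  kept <- fits[keep]
  rate <- vapply(kept, function(f) if (!is.na(f$kI)) f$kI else f$kE, numeric(1))
  acc <- vapply(kept, function(f) f$Ke, numeric(1))
  n <- length(kept)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- list(construct = construct, n = n,
              kI_mean = mean(rate), kI_sem = sem(rate),
              Ke_mean = mean(acc), Ke_sem = sem(acc),
              mean_timecourse = NULL)
  if (!is.null(traces)) {
    ids <- vapply(traces, function(tr) attr(tr, "cell_id"), character(1))
    kept_ids <- vapply(kept, function(f) f$cell_id, character(1))
    curves <- lapply(traces[match(intersect(kept_ids, ids), ids)], function(tr) {
      rec <- recovery_frames(tr)
      cyt <- rec$cell - rec$nuc
      data.frame(time = rec$time, ratio = ifelse(cyt > 0, rec$nuc / cyt, NA_real_))
    })
    if (length(curves)) {
      grid <- sort(unique(unlist(lapply(curves, `[[`, "time"))))
      mat <- vapply(curves, function(cu) {
        cu$ratio[match(grid, cu$time)]
      }, numeric(length(grid)))
      mat <- matrix(mat, nrow = length(grid))
      m <- rowMeans(mat, na.rm = TRUE)
      npt <- rowSums(!is.na(mat))
      s <- apply(mat, 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
      })
      out$mean_timecourse <- data.frame(time = grid, mean = m, sem = s, n = npt)
    }
  }
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s: n = %d, kI = %.3f +/- %.3f ks^-1, Ke = %.3f +/- %.3f\n",
              x$construct, x$n, x$kI_mean, x$kI_sem, x$Ke_mean, x$Ke_sem))
  invisible(x)
}

#' Compare two import-rate distributions
#'
#' Thin wrapper over the two-sided Wilcoxon rank-sum (Mann-Whitney) test,
#' the appropriate comparison for the markedly non-Gaussian import-rate
#' distributions.
#'
#' @param a,b Numeric vectors of per-cell rates.
#' @return List with `p_value`, group sizes, and `low_power` (`TRUE` with a
#'   warning when either group has fewer than 3 observations).
#' @export
compare_groups <- function(a, b) {
  low <- length(a) < 3 || length(b) < 3
  if (low) warning("fewer than 3 observations in a group; low-power comparison")
  p <- stats::wilcox.test(a, b, exact = (length(a) < 50 && length(b) < 50))$p.value
  list(p_value = p, n_a = length(a), n_b = length(b), low_power = low)
}

#' QC report for a filtered fit collection
#'
#' One row per cell with each flag as a boolean column, the activation rate
#' and the final decision.
#'
#' @param fits List of [recovery_fit()] objects after filtering.
#' @param path Optional CSV path; when given the report is written there.
#' @return Data.frame (invisibly returns `path` when writing).
#' @export
qc_report <- function(fits, path = NULL) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id,
               unphysical = "unphysical" %in% f$qc_flags,
               gesd_outlier = "gesd_outlier" %in% f$qc_flags,
               poor_activation = "poor_activation" %in% f$qc_flags,
               manual_reject = "manual_reject" %in% f$qc_flags,
               k_act = f$k_act,
               decision = if (is_retained(f)) "retained" else "rejected",
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df
}
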