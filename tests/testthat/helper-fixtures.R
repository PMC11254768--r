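# shared fixture builders for the suite

# 45-frame noise-free import config (one frame a minute, 10 min light,
# 44 min dark so the recovery grid has exactly 45 frames)
clean_import_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, noise_cv = 0, recovery_duration = 2640,
                   frame_interval = 60, ...)
}

# quick list of converged recovery_fit objects from bare numbers
fits_from_values <- function(kI, Ke = rep(2, length(kI)),
                             ids = sprintf("c%03d", seq_along(kI))) {
  mapply(function(id, ki, ke) {
    recovery_fit(id, Ke = ke, kI = ki, v = 0.25, n0 = 0, rss = 0,
                 converged = TRUE)
  }, ids, kI, Ke, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# greedy matching of detected to true step times within a tolerance;
# returns the number of true steps matched
match_steps <- function(detected, truth, tol = 0.005) {
  used <- rep(FALSE, length(detected))
  matched <- 0
  for (tt in truth) {
    d <- abs(detected - tt)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      matched <- matched + 1
      used[which.min(d)] <- TRUE
    }
  }
  matched
}
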