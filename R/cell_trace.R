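#' Construct a single-cell fluorescence time course
#'
#' A `cell_trace` holds one cell's time-stamped nuclear and whole-cell
#' fluorescence signals across the light-activation and dark-recovery phases
#' of an optogenetic shuttling experiment, plus the experiment direction.
#' The cytoplasmic signal is not stored: by convention it is
#' `cell - nuc` (integrated signals), so total signal is conserved by
#' construction and the nucleus-to-cytoplasm ratio is `nuc / (cell - nuc)`.
#'
#' @param cell_id Identifier (scalar character).
#' @param time Strictly increasing time stamps, seconds.
#' @param nuc Nuclear signal, arbitrary units, `0 <= nuc <= cell`.
#' @param cell Whole-cell signal, arbitrary units, >= 0.
#' @param phase Per-frame label, `"activation"` or `"recovery"`.
#' @param direction Experiment type: `"import"` (NLS-driven recovery),
#'   `"export"` (NES-driven recovery) or `"coupled"` (simultaneous
#'   import/export, e.g. serum-stimulated MRTFA).
#' @param v Nucleus-to-cytoplasm volume ratio for this cell (from
#'   segmentation areas when available); `NA` means "use the analysis-time
#'   default".
#' @return A data.frame of class `cell_trace` with columns
#'   `time`, `nuc`, `cell`, `phase` and attributes `cell_id`, `direction`,
#'   `v`.
#' @export
cell_trace <- function(cell_id, time, nuc, cell, phase,
                       direction = c("import", "export", "coupled"),
                       v = NA_real_) {
  direction <- match.arg(direction)
  n <- length(time)
  if (length(nuc) != n || length(cell) != n || length(phase) != n) {
    stop("time, nuc, cell and phase must have equal length")
  }
  if (n >= 2 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(nuc < 0) || any(cell < 0)) stop("signals must be non-negative")
  if (any(nuc > cell + 1e-9 * pmax(cell, 1))) {
    stop("nuclear signal cannot exceed whole-cell signal")
  }
  phase <- as.character(phase)
  if (!all(phase %in% c("activation", "recovery"))) {
    stop("phase labels must be 'activation' or 'recovery'")
  }
  for (ph in unique(phase)) {
    if (sum(phase == ph) < 3) stop("need at least 3 frames per phase")
  }
  out <- data.frame(time = as.numeric(time), nuc = as.numeric(nuc),
                    cell = as.numeric(cell), phase = phase,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cell_trace", "data.frame"),
            cell_id = as.character(cell_id), direction = direction,
            v = as.numeric(v))
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %s (%s), %d frames (%d activation / %d recovery), v = %s\n",
              attr(x, "cell_id"), attr(x, "direction"), nrow(x),
              sum(x$phase == "activation"), sum(x$phase == "recovery"),
              format(attr(x, "v"))))
  invisible(x)
}

#' Recovery-phase frames of a trace with the clock re-zeroed
#'
#' Extracts the recovery-phase frames and re-zeroes time at the first
#' post-activation frame (the model clock starts when the light goes off).
#'
#' @param trace A [cell_trace()].
#' @return A data.frame with columns `time` (seconds from recovery start),
#'   `nuc`, `cell`.
#' @export
recovery_frames <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  rec <- trace[trace$phase == "recovery", , drop = FALSE]
  if (nrow(rec) < 3) stop("need at least 3 recovery frames")
  data.frame(time = rec$time - rec$time[1], nuc = rec$nuc, cell = rec$cell)
}

#' Read / write single-cell traces in the long CSV dialect
#'
#' The on-disk format is long CSV with header
#' `cell_id,time_s,nuc,cell,phase,direction` (UTF-8) and an optional `v`
#' column; one file can hold many cells.
#'
#' @param path CSV file path.
#' @return `read_traces()` returns a named list of [cell_trace()] objects;
#'   `write_traces()` returns `path` invisibly.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "nuc", "cell", "phase", "direction")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  traces <- lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    cell_trace(d$cell_id[1], d$time_s, d$nuc, d$cell, d$phase,
               direction = d$direction[1],
               v = if ("v" %in% names(d)) d$v[1] else NA_real_)
  })
  traces[order(names(traces))]
}

#' @param traces List of [cell_trace()] objects.
#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = attr(tr, "cell_id"), time_s = tr$time,
               nuc = tr$nuc, cell = tr$cell, phase = tr$phase,
               direction = attr(tr, "direction"), v = attr(tr, "v"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
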