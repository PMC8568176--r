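# Parcel time-series containers, task regressors (FIR x HRF), task
# regression, run concatenation, and amplitude / global-signal / motion
# metrics.

#' Construct a parcel time-series object
#'
#' @param data T x N numeric matrix: one row per volume, one column per
#'   parcel, arbitrary BOLD units. No missing values allowed.
#' @param tr Repetition time in seconds.
#' @param parcel_ids Unique parcel labels (default: column names or
#'   `p1, p2, ...`).
#' @param subject,condition,run Optional labels.
#' @return A `parcel_ts` object.
#' @export
parcel_ts <- function(data, tr, parcel_ids = NULL, subject = NA_character_,
                      condition = NA_character_, run = NA_character_) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("parcel time series must not contain missing values")
  if (ncol(data) < 2) stop("at least 2 parcels required")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  if (is.null(parcel_ids)) parcel_ids <- colnames(data)
  if (is.null(parcel_ids)) parcel_ids <- paste0("p", seq_len(ncol(data)))
  parcel_ids <- as.character(parcel_ids)
  if (anyDuplicated(parcel_ids)) stop("parcel_ids must be unique")
  if (length(parcel_ids) != ncol(data)) stop("parcel_ids must match columns")
  colnames(data) <- parcel_ids
  structure(list(data = data, tr = tr, parcel_ids = parcel_ids,
                 subject = subject, condition = condition, run = run),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("parcel_ts: %d volumes x %d parcels, TR = %gs%s\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (is.na(x$subject)) "" else
                sprintf(" [%s/%s]", x$subject, x$condition)))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The difference of two gamma densities: a response component peaking at
#' `peak` seconds and an undershoot peaking at `undershoot` seconds with
#' relative amplitude `1/ratio`. Gamma shapes are `peak + 1` and
#' `undershoot + 1` with unit rate, so the modes fall exactly at the stated
#' times. The curve is normalized to unit peak amplitude.
#'
#' @param t Time in seconds (vector).
#' @param peak Time-to-peak of the response, seconds (default 6).
#' @param undershoot Time-to-peak of the undershoot, seconds (default 16).
#' @param ratio Response/undershoot amplitude ratio (default 6).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(h)
}

#' Validate a task events table
#'
#' @param events Data frame with columns `onset` (s), `duration` (s),
#'   `trial_type`.
#' @param run_duration Optional run length in seconds; events starting beyond
#'   it are dropped with a warning.
#' @return The validated (possibly truncated) events data frame.
#' @export
events_table <- function(events, run_duration = NULL) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("events table must have columns: ", paste(need, collapse = ", "))
  if (nrow(events) == 0) stop("events table is empty")
  if (any(events$onset < 0)) stop("event onsets must be non-negative")
  if (any(events$duration < 0)) stop("event durations must be non-negative")
  if (!is.null(run_duration) && any(events$onset >= run_duration)) {
    warning("events extending beyond the run were truncated")
    events <- events[events$onset < run_duration, , drop = FALSE]
    if (nrow(events) == 0) stop("no events remain within the run")
  }
  events
}

#' Build FIR-by-HRF task regressors
#'
#' For each trial type, a finite-impulse-response basis spans `fir_span`
#' seconds after onset in bins of one TR; each bin's stimulus train
#' (impulses for zero-duration events, `dt`-weighted boxcars otherwise,
#' shifted by the bin offset) is convolved with the canonical double-gamma
#' HRF on an oversampled grid and sampled at volume acquisition times
#' `0, TR, 2 TR, ...`. Columns are labelled `<trial_type>.b<bin>`.
#'
#' @param events An [events_table()] data frame.
#' @param n_timepoints Number of volumes.
#' @param tr Repetition time, seconds.
#' @param fir_span FIR window length in seconds (default 16).
#' @param hrf_params List with `peak`, `undershoot`, `ratio` passed to
#'   [canonical_hrf()].
#' @param oversample Samples per TR on the convolution grid (default 16).
#' @return T x P design matrix with labelled columns; attribute `"basis"`
#'   describes the construction.
#' @export
build_task_regressors <- function(events, n_timepoints, tr, fir_span = 16,
                                  hrf_params = list(peak = 6, undershoot = 16,
                                                    ratio = 6),
                                  oversample = 16L) {
  stopifnot(tr > 0, fir_span > 0, n_timepoints >= 2)
  run_duration <- n_timepoints * tr
  events <- events_table(events, run_duration)
  dt <- tr / oversample
  n_grid <- n_timepoints * oversample
  grid_t <- (seq_len(n_grid) - 1) * dt
  hrf_t <- seq(0, 32, by = dt)
  h <- do.call(canonical_hrf, c(list(t = hrf_t), hrf_params))
  n_bins <- max(1L, as.integer(round(fir_span / tr)))
  types <- unique(as.character(events$trial_type))
  cols <- matrix(0, n_timepoints, length(types) * n_bins)
  labels <- character(ncol(cols))
  vol_idx <- (seq_len(n_timepoints) - 1L) * oversample + 1L
  j <- 0L
  for (tt in types) {
    ev <- events[events$trial_type == tt, , drop = FALSE]
    for (b in seq_len(n_bins)) {
      stim <- numeric(n_grid)
      for (e in seq_len(nrow(ev))) {
        t0 <- ev$onset[e] + (b - 1L) * tr
        if (ev$duration[e] <= dt / 2) {           # impulse event
          i0 <- round(t0 / dt) + 1L
          if (i0 >= 1L && i0 <= n_grid) stim[i0] <- stim[i0] + 1
        } else {                                   # boxcar, dt-weighted
          ii <- which(grid_t >= t0 & grid_t < t0 + ev$duration[e])
          stim[ii] <- stim[ii] + dt
        }
      }
      conv <- .causal_convolve(stim, h)
      j <- j + 1L
      cols[, j] <- conv[vol_idx]
      labels[j] <- sprintf("%s.b%d", tt, b)
    }
  }
  colnames(cols) <- labels
  attr(cols, "basis") <- sprintf(
    "FIR (%d bins of %gs) x double-gamma HRF (peak %gs, undershoot %gs, ratio %g)",
    n_bins, tr, hrf_params$peak, hrf_params$undershoot, hrf_params$ratio)
  cols
}

#' @keywords internal
#' @noRd
.causal_convolve <- function(x, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_len(n)]
}

#' Regress task-evoked activity out of parcel time series
#'
#' Ordinary least squares per parcel on an intercept, a linear trend, and the
#' supplied design matrix; returns the residual series. Residuals are
#' orthogonal to every regressor by construction. A rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param ts A [parcel_ts()].
#' @param design T x P design matrix (e.g. from [build_task_regressors()]),
#'   or `NULL` for intercept + trend only (detrending/demeaning).
#' @return A `parcel_ts` of residuals.
#' @export
regress_task <- function(ts, design = NULL) {
  stopifnot(inherits(ts, "parcel_ts"))
  T <- nrow(ts$data)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != T) stop("design rows must equal time-series rows")
  }
  trend <- seq_len(T) - (T + 1) / 2
  X <- cbind(intercept = 1, trend = trend / max(abs(trend)), design)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  resid <- ts$data - X %*% qr.coef(q, ts$data)
  parcel_ts(resid, ts$tr, ts$parcel_ids, ts$subject, ts$condition, ts$run)
}

#' Concatenate runs of one subject and condition
#'
#' Each run is demeaned per parcel (optionally variance-normalized) before
#' rows are stacked in the given order, preventing run-level mean offsets
#' from inducing spurious covariance.
#'
#' @param runs List of [parcel_ts()] with identical `parcel_ids` and `tr`.
#' @param normalize_variance If `TRUE`, each run is also scaled to unit
#'   per-parcel variance before stacking (default `FALSE`).
#' @return A single concatenated `parcel_ts`.
#' @export
concatenate_runs <- function(runs, normalize_variance = FALSE) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "parcel_ts")))
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$parcel_ids, ref$parcel_ids)) {
      diff <- union(setdiff(r$parcel_ids, ref$parcel_ids),
                    setdiff(ref$parcel_ids, r$parcel_ids))
      stop("parcel sets differ across runs: ", paste(diff, collapse = ", "))
    }
    if (!isTRUE(all.equal(r$tr, ref$tr))) stop("TR differs across runs")
  }
  blocks <- lapply(runs, function(r)
    scale(r$data, center = TRUE, scale = normalize_variance))
  parcel_ts(do.call(rbind, blocks), ref$tr, ref$parcel_ids,
            ref$subject, ref$condition, run = "concatenated")
}

#' Amplitude and global-signal metrics
#'
#' The global signal is the unweighted row-wise mean across parcels.
#' Standard deviations use the T-1 denominator. A constant parcel yields a
#' missing correlation with a warning.
#'
#' @param ts A [parcel_ts()] with at least 3 volumes.
#' @return List with `parcel_sd` (named vector), `global_signal` (length-T
#'   series), `global_signal_sd`, and `parcel_gs_cor` (named vector of
#'   parcel-to-global-signal Pearson correlations).
#' @export
amplitude_metrics <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (nrow(ts$data) < 3) stop("at least 3 volumes required")
  gs <- rowMeans(ts$data)
  parcel_sd <- apply(ts$data, 2, stats::sd)
  cors <- rep(NA_real_, ncol(ts$data))
  ok <- parcel_sd > 0 & stats::sd(gs) > 0
  if (any(ok)) cors[ok] <- as.vector(stats::cor(ts$data[, ok, drop = FALSE], gs))
  if (any(!ok)) warning("constant series: correlation undefined for ",
                        sum(!ok), " parcel(s)")
  names(cors) <- names(parcel_sd) <- ts$parcel_ids
  list(parcel_sd = parcel_sd, global_signal = gs,
       global_signal_sd = stats::sd(gs), parcel_gs_cor = cors)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |delta translation| + head_radius * sum |delta rotation|`,
#' with FD fixed at 0 for the first volume.
#'
#' @param motion T x 6 matrix: three translations (mm) then three rotations
#'   (radians).
#' @param head_radius Radius (mm) converting rotations to arc displacement;
#'   default 50.
#' @return List with `fd` (per-volume series, mm) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns (3 translations mm, 3 rotations rad)")
  if (nrow(motion) < 2) stop("at least 2 volumes required")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}
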