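# Synthetic multi-subject, multi-condition cohort with known ground truth:
# block-structured correlation (within-network > between-network), an
# additive global-signal component with condition-dependent amplitude,
# HRF-convolved task-evoked responses, and behavioral change scores coupled
# to each subject's true change in FCR.

#' Block-structured unit-variance covariance matrix
#'
#' Builds the correlation matrix implied by a partition into systems:
#' `within_r[k]` for parcel pairs inside system k, `between_r` for pairs in
#' different systems, unit diagonal. Positive definiteness is verified by
#' factorization; a failing parameter combination is rejected with a message
#' naming the offending block (an equicorrelated block of size m requires
#' `within_r > -1/(m-1)`).
#'
#' @param n_parcels Number of parcels.
#' @param part A [partition()] (or label vector) covering all parcels.
#' @param within_r Within-system correlation: scalar or named vector per
#'   system, each in (-1, 1).
#' @param between_r Between-system correlation in (-1, 1) (default 0).
#' @return Positive-definite correlation matrix with parcel dimnames.
#' @export
make_block_covariance <- function(n_parcels, part, within_r, between_r = 0) {
  part <- .as_partition(part, n_parcels)
  if (any(abs(c(within_r, between_r)) >= 1))
    stop("all correlations must lie in (-1, 1)")
  if (length(within_r) == 1L) within_r <- stats::setNames(
    rep(within_r, part$K), names(part$systems))
  if (is.null(names(within_r))) names(within_r) <- names(part$systems)
  if (!all(names(part$systems) %in% names(within_r)))
    stop("within_r must name every system")
  R <- matrix(between_r, n_parcels, n_parcels)
  for (k in names(part$systems)) {
    idx <- part$systems[[k]]
    m <- length(idx)
    if (m > 1 && within_r[k] <= -1 / (m - 1))
      stop(sprintf("block '%s' (size %d) is not positive definite: within_r = %g <= -1/(m-1)",
                   k, m, within_r[k]))
    R[idx, idx] <- within_r[k]
  }
  diag(R) <- 1
  dimnames(R) <- list(part$parcel_ids, part$parcel_ids)
  ok <- tryCatch({chol(R); TRUE}, error = function(e) FALSE)
  if (!ok) {
    # identify the offending structure for the error message
    for (k in names(part$systems)) {
      idx <- part$systems[[k]]
      sub_ok <- tryCatch({chol(R[idx, idx, drop = FALSE]); TRUE},
                         error = function(e) FALSE)
      if (!sub_ok) stop("block '", k, "' makes the covariance non-positive-definite")
    }
    stop("between-system correlation ", between_r,
         " makes the covariance non-positive-definite")
  }
  R
}

#' Simulate one session of parcel time series
#'
#' Rows are i.i.d. multivariate normal draws with the given covariance
#' (matching the i.i.d.-sample Gaussian model behind the integration
#' measures); an optional AR(1) switch induces temporal autocorrelation to
#' probe the overestimation that sample dependence causes. A shared scalar
#' Gaussian global-signal component scaled by `gs_amplitude` is added
#' equally to all parcels, and, when events are given, HRF-convolved task
#' regressors scaled by `task_amplitude` are added to `task_parcels`.
#' The generating components are stored in the `"truth"` attribute.
#'
#' @param cov Positive-definite covariance matrix (N x N).
#' @param n_timepoints Number of volumes (>= 2).
#' @param gs_amplitude Standard-deviation multiplier of the shared global
#'   component (0 disables it).
#' @param events Optional [events_table()] data frame.
#' @param tr Repetition time, seconds.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param ar1 AR(1) coefficient in [0, 1) for innovations (default 0:
#'   i.i.d. rows); the stationary marginal variance stays at 1.
#' @param task_amplitude Amplitude of the added task response (default 1).
#' @param task_parcels Indices of parcels receiving the task response
#'   (default: all).
#' @return A [parcel_ts()] with attribute `"truth"` (list: `cov`,
#'   `global_signal`, `task_component`).
#' @export
simulate_session <- function(cov, n_timepoints, gs_amplitude = 0,
                             events = NULL, tr = 2, seed = 1, ar1 = 0,
                             task_amplitude = 1, task_parcels = NULL) {
  if (n_timepoints < 2) stop("n_timepoints must be at least 2")
  .check_symmetric(cov)
  R <- .chol_or_stop(cov)
  n <- nrow(cov)
  if (n_timepoints < 2 * n)
    warning("n_timepoints < 2 x n_parcels: sample covariances may be ill-conditioned")
  set.seed(seed)
  E <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  g <- stats::rnorm(n_timepoints)
  if (ar1 > 0) {
    E <- apply(E, 2, function(e) as.vector(
      stats::filter(e * sqrt(1 - ar1^2), ar1, method = "recursive")))
    g <- as.vector(stats::filter(g * sqrt(1 - ar1^2), ar1, method = "recursive"))
  }
  Y <- E %*% R
  gs_series <- gs_amplitude * g
  Y <- Y + gs_series
  task_component <- NULL
  if (!is.null(events)) {
    X <- build_task_regressors(events, n_timepoints, tr)
    if (is.null(task_parcels)) task_parcels <- seq_len(n)
    task_component <- task_amplitude * rowSums(X)
    Y[, task_parcels] <- Y[, task_parcels] + task_component
  }
  out <- parcel_ts(Y, tr, parcel_ids = rownames(cov))
  attr(out, "truth") <- list(cov = cov, global_signal = gs_series,
                             task_component = task_component)
  out
}

#' Ground-truth specification for a synthetic cohort
#'
#' Bundles the generating parameters of [simulate_cohort()] and validates
#' that every condition's implied covariance factorizes.
#'
#' @param n_parcels Number of parcels.
#' @param hp A [hierarchical_partition()]; level-7 systems define the
#'   covariance blocks.
#' @param within_r Named list: per condition, a scalar or per-system vector
#'   of within-block correlations.
#' @param between_r Named list or vector: per-condition between-block
#'   correlation.
#' @param gs_amplitude Named vector: per-condition global-signal sd
#'   multiplier (default 0).
#' @param n_timepoints Volumes per session.
#' @param tr Repetition time, seconds.
#' @param subject_jitter SD of the subject-level trait deviation added to
#'   correlations (shared across conditions; default 0.02).
#' @param condition_jitter SD of the independent per-condition state
#'   deviation added on top of the trait (default 0.02); this component
#'   gives subjects a distribution of true FCR change between conditions.
#' @param behavior_coupling Slope linking each subject's true change in FCR
#'   (second condition minus first) to the behavioral change score.
#' @param behavior_noise_sd SD of additive Gaussian behavioral noise.
#' @param seed Integer seed.
#' @return A `ground_truth_spec` object.
#' @export
ground_truth_spec <- function(n_parcels, hp, within_r, between_r,
                              gs_amplitude = NULL, n_timepoints = 400,
                              tr = 2, subject_jitter = 0.02,
                              condition_jitter = 0.02,
                              behavior_coupling = 0, behavior_noise_sd = 1,
                              seed = 1) {
  stopifnot(inherits(hp, "hierarchical_partition"),
            length(hp$parcel_ids) == n_parcels)
  conds <- names(within_r)
  if (is.null(conds) || length(conds) < 1) stop("within_r must be a named list per condition")
  between_r <- unlist(between_r)[conds]
  if (anyNA(between_r)) stop("between_r must name every condition in within_r")
  if (is.null(gs_amplitude)) gs_amplitude <- stats::setNames(rep(0, length(conds)), conds)
  gs_amplitude <- unlist(gs_amplitude)[conds]
  part7 <- partition(hp$level7, hp$parcel_ids)
  cond_cov <- lapply(conds, function(cn)
    make_block_covariance(n_parcels, part7, within_r[[cn]], between_r[[cn]]))
  names(cond_cov) <- conds
  if (n_timepoints < 2 * n_parcels)
    warning("n_timepoints < 2 x n_parcels: sample covariances will be noisy")
  structure(list(n_parcels = n_parcels, hp = hp, within_r = within_r,
                 between_r = between_r, gs_amplitude = gs_amplitude,
                 n_timepoints = n_timepoints, tr = tr,
                 subject_jitter = subject_jitter,
                 condition_jitter = condition_jitter,
                 behavior_coupling = behavior_coupling,
                 behavior_noise_sd = behavior_noise_sd, seed = seed,
                 conditions = conds, condition_cov = cond_cov),
            class = "ground_truth_spec")
}

#' Simulate a multi-subject, multi-condition cohort
#'
#' Each subject's covariance is jittered around the condition covariance on
#' the correlation scale and projected to the nearest positive-definite
#' correlation matrix. The jitter has two components: a trait deviation
#' shared across conditions (connectivity idiosyncrasies behave as stable
#' traits in a within-subject design) and an independent per-condition state
#' deviation, which is what spreads the true FCR change across subjects.
#' Sessions are then simulated per condition from the subject's jittered
#' condition covariance. Behavioral change scores couple linearly to the
#' subject's true FCR change between the first two conditions:
#' `accuracy change = behavior_coupling * dFCR + noise` (per task), and
#' reaction-time change with the opposite sign scaled to milliseconds.
#'
#' @param spec A [ground_truth_spec()].
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Condition labels to simulate (default: all in `spec`;
#'   at least 2). The first is the baseline, the second the contrast used
#'   for behavioral coupling.
#' @param tasks Task labels for the behavior table (default three tasks).
#' @param max_retries Resampling attempts when jitter breaks positive
#'   definiteness (default 20).
#' @return A `cohort` object: `sessions[[subject]][[condition]]`
#'   ([parcel_ts()]), `behavior` (long data frame: subject, task, condition,
#'   accuracy, reaction_time), `truth` (per-subject covariances, FCR per
#'   condition, `delta_fcr`, behavioral change scores), and `spec`.
#' @export
simulate_cohort <- function(spec, n_subjects, conditions = NULL,
                            tasks = c("taskA", "taskB", "taskC"),
                            max_retries = 20) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (n_subjects < 2) stop("at least 2 subjects required")
  if (is.null(conditions)) conditions <- spec$conditions
  if (length(conditions) < 2) stop("at least 2 conditions required")
  if (!all(conditions %in% spec$conditions))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, spec$conditions), collapse = ", "))
  part7 <- partition(spec$hp$level7, spec$hp$parcel_ids)
  n <- spec$n_parcels
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  sessions <- list(); subj_cov <- list()
  fcr_true <- matrix(NA_real_, n_subjects, length(conditions),
                     dimnames = list(subjects, conditions))
  set.seed(spec$seed)
  for (i in seq_len(n_subjects)) {
    # subject trait deviation, shared across conditions
    attempt <- 0; covs <- NULL
    repeat {
      attempt <- attempt + 1
      D <- matrix(stats::rnorm(n * n, sd = spec$subject_jitter), n, n)
      D <- .symmetrize(D); diag(D) <- 0
      Dc <- lapply(conditions, function(cn) {
        E <- matrix(stats::rnorm(n * n, sd = spec$condition_jitter), n, n)
        E <- .symmetrize(E); diag(E) <- 0
        E
      })
      names(Dc) <- conditions
      covs <- tryCatch(
        lapply(conditions, function(cn)
          .nearest_pd_corr(spec$condition_cov[[cn]] + D + Dc[[cn]])),
        error = function(e) NULL)
      if (!is.null(covs)) break
      if (attempt >= max_retries)
        stop("subject jitter broke positive definiteness after ",
             max_retries, " retries")
    }
    names(covs) <- conditions
    subj_cov[[subjects[i]]] <- covs
    sessions[[subjects[i]]] <- list()
    for (ci in seq_along(conditions)) {
      cn <- conditions[ci]
      ts <- simulate_session(covs[[cn]], spec$n_timepoints,
                             gs_amplitude = spec$gs_amplitude[[cn]],
                             tr = spec$tr,
                             seed = .child_seed(spec$seed, i * 100 + ci))
      ts$subject <- subjects[i]; ts$condition <- cn
      sessions[[subjects[i]]][[cn]] <- ts
      fcr_true[i, ci] <- fcr(covs[[cn]], part7)
    }
  }
  delta_fcr <- fcr_true[, 2] - fcr_true[, 1]
  # behavioral table: baseline levels plus coupled change in the contrast
  set.seed(.child_seed(spec$seed, 999983))
  behavior <- expand.grid(subject = subjects, task = tasks,
                          condition = conditions[1:2],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  behavior <- behavior[order(behavior$subject, behavior$task), ]
  acc_change <- rt_change <- matrix(NA_real_, n_subjects, length(tasks),
                                    dimnames = list(subjects, tasks))
  for (tk in tasks) {
    acc_change[, tk] <- spec$behavior_coupling * delta_fcr +
      stats::rnorm(n_subjects, sd = spec$behavior_noise_sd)
    rt_change[, tk] <- -10 * spec$behavior_coupling * delta_fcr +
      stats::rnorm(n_subjects, sd = 10 * spec$behavior_noise_sd)
  }
  base_acc <- 85; base_rt <- 600
  behavior$accuracy <- ifelse(
    behavior$condition == conditions[1], base_acc,
    base_acc + acc_change[cbind(behavior$subject, behavior$task)])
  behavior$reaction_time <- ifelse(
    behavior$condition == conditions[1], base_rt,
    base_rt + rt_change[cbind(behavior$subject, behavior$task)])
  behavior$accuracy <- pmin(pmax(behavior$accuracy, 0), 100)
  structure(list(sessions = sessions, behavior = behavior,
                 truth = list(subject_cov = subj_cov, fcr = fcr_true,
                              delta_fcr = delta_fcr,
                              accuracy_change = acc_change,
                              reaction_time_change = rt_change),
                 spec = spec, conditions = conditions, subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects x %d conditions (%s), %d parcels, T = %d\n",
              length(x$subjects), length(x$conditions),
              paste(x$conditions, collapse = ", "),
              x$spec$n_parcels, x$spec$n_timepoints))
  invisible(x)
}

#' Write a cohort to disk as delimited text plus a JSON manifest
#'
#' One tab-separated file per subject and condition (columns = parcels), a
#' behavior table, the partition table, and `manifest.json` recording the
#' generating parameters and per-subject true FCR values.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) for (cn in cohort$conditions) {
    f <- file.path(dir, sprintf("%s_%s_bold.tsv", s, cn))
    utils::write.table(cohort$sessions[[s]][[cn]]$data, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_partition_table(cohort$spec$hp, file.path(dir, "partition.tsv"))
  spec <- cohort$spec
  manifest <- list(
    n_parcels = spec$n_parcels, n_timepoints = spec$n_timepoints,
    tr = spec$tr, conditions = cohort$conditions,
    subjects = cohort$subjects, within_r = spec$within_r,
    between_r = as.list(spec$between_r),
    gs_amplitude = as.list(spec$gs_amplitude),
    subject_jitter = spec$subject_jitter,
    condition_jitter = spec$condition_jitter,
    behavior_coupling = spec$behavior_coupling,
    behavior_noise_sd = spec$behavior_noise_sd, seed = spec$seed,
    true_fcr = as.data.frame(cohort$truth$fcr),
    true_delta_fcr = as.list(cohort$truth$delta_fcr))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
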