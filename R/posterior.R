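# Gibbs sampler for the posterior of group and subject covariance matrices,
# posterior distributions of integration measures, and probability-of-
# difference inference between conditions.
#
# Hierarchical model (two-level conjugate family):
#   y_{i,t} | Sigma_i  ~  N(0, Sigma_i)          t = 1..T_i, subject i
#   Sigma_i | Psi      ~  InvWishart(nu, Psi)    nu = shrinkage df
#   Psi                ~  Wishart(nu0, S0)       weakly informative hyperprior
# Both full conditionals are closed-form:
#   Sigma_i | y_i, Psi ~ InvWishart(nu + T_i, Psi + Y_i'Y_i)
#   Psi | Sigma_{1..n} ~ Wishart(nu0 + n*nu, (S0^-1 + sum_i Sigma_i^-1)^-1)
# The stored group covariance draw is Psi / (nu - N - 1), the expectation
# scale of a subject covariance given Psi. Larger shrinkage df pulls subject
# posteriors toward the group matrix and keeps the posterior proper even
# when T is small relative to N.

#' Gibbs sampler for the group covariance posterior
#'
#' Alternates closed-form conditional draws of each subject's covariance
#' (inverse-Wishart, combining the group scale with the subject scatter
#' matrix) and of the group-level scale (Wishart, combining the hyperprior
#' with the summed subject precisions). After `burn_in` sweeps, every sweep
#' stores the group covariance on expectation scale; subject draws are
#' accumulated into posterior means. The chain is reproducible from `seed`.
#'
#' @param subject_data List of [parcel_ts()] (or T x N matrices), one per
#'   subject, single condition, identical parcel sets. Series are demeaned
#'   per parcel before the scatter matrices are formed.
#' @param S Number of retained draws (default 1000).
#' @param burn_in Discarded initial sweeps (default 500).
#' @param seed Integer seed.
#' @param shrinkage_df Subject-level inverse-Wishart degrees of freedom
#'   `nu`; default `N + 32`. Larger values shrink subjects harder toward the
#'   group matrix.
#' @param hyper_df,hyper_scale Hyperprior `Wishart(nu0, S0)` on the group
#'   scale; `hyper_scale` is interpreted as the prior expectation of the
#'   group covariance (internally `S0 = hyper_scale * (nu - N - 1) / nu0`).
#'   Defaults: `nu0 = N + 2` and an empirical-Bayes centering on the pooled
#'   sample covariance across subjects (ridge-stabilized), which leaves
#'   posterior correlations unbiased; pass e.g. `diag(N)` for an
#'   identity-centered prior.
#' @param min_timepoints Minimum volumes required per subject (default 10).
#' @param store_subject_draws Keep full per-subject draw arrays (memory
#'   heavy; default `FALSE`, posterior means are always accumulated).
#' @param clamp_group Fix the group scale `Psi` at this matrix instead of
#'   sampling it (validation aid: with the group level clamped the subject
#'   conditional is the closed-form conjugate posterior). Permits a single
#'   subject.
#' @param condition Optional condition label carried in the result.
#' @return A `posterior_samples` object: `draws` (N x N x S array of group
#'   covariance draws), `subject_means` (list of posterior-mean matrices),
#'   `settings`, `condition`, `parcel_ids`.
#' @export
gibbs_sample_group_covariance <- function(subject_data, S = 1000,
                                          burn_in = 500, seed = 1,
                                          shrinkage_df = NULL,
                                          hyper_df = NULL, hyper_scale = NULL,
                                          min_timepoints = 10,
                                          store_subject_draws = FALSE,
                                          clamp_group = NULL,
                                          condition = NA_character_) {
  mats <- lapply(subject_data, function(x) {
    if (inherits(x, "parcel_ts")) x$data else as.matrix(x)
  })
  if (length(mats) < 2 && is.null(clamp_group))
    stop("at least 2 subjects required")
  N <- ncol(mats[[1]])
  ids <- if (inherits(subject_data[[1]], "parcel_ts"))
    subject_data[[1]]$parcel_ids else colnames(mats[[1]])
  for (i in seq_along(mats)) {
    if (ncol(mats[[i]]) != N)
      stop("subject ", i, " has a mismatched parcel set")
    if (inherits(subject_data[[i]], "parcel_ts") &&
        !identical(subject_data[[i]]$parcel_ids, ids))
      stop("subject ", i, " has a mismatched parcel set")
    if (nrow(mats[[i]]) < min_timepoints)
      stop("subject ", i, " has fewer than ", min_timepoints, " volumes")
  }
  n_sub <- length(mats)
  mats <- lapply(mats, scale, center = TRUE, scale = FALSE)
  scatter <- lapply(mats, crossprod)
  Tn <- vapply(mats, nrow, integer(1))
  nu <- if (is.null(shrinkage_df)) N + 32 else shrinkage_df
  if (nu <= N + 1) stop("shrinkage_df must exceed N + 1")
  nu0 <- if (is.null(hyper_df)) N + 2 else hyper_df
  if (is.null(hyper_scale)) {
    # empirical-Bayes centering: pooled sample covariance, ridge-stabilized
    pooled <- Reduce(`+`, scatter) / sum(Tn - 1)
    hyper_scale <- pooled + diag(1e-4 * mean(diag(pooled)), N)
  }
  S0 <- as.matrix(hyper_scale) * (nu - N - 1) / nu0
  S0inv <- chol2inv(chol(S0))

  set.seed(seed)
  # initialize subject covariances at (ridge-stabilized) sample covariances
  Sigma <- lapply(seq_len(n_sub), function(i) {
    C <- scatter[[i]] / (Tn[i] - 1)
    C + diag(1e-6 * mean(diag(C)) + 1e-12, N)
  })
  draws <- array(NA_real_, c(N, N, S))
  subj_sum <- lapply(seq_len(n_sub), function(i) matrix(0, N, N))
  subj_draws <- if (store_subject_draws)
    lapply(seq_len(n_sub), function(i) array(NA_real_, c(N, N, S))) else NULL
  total <- burn_in + S
  for (sweep in seq_len(total)) {
    # group scale conditional (skipped when clamped)
    if (is.null(clamp_group)) {
      prec_sum <- S0inv
      for (i in seq_len(n_sub)) prec_sum <- prec_sum + chol2inv(chol(Sigma[[i]]))
      Psi <- stats::rWishart(1, nu0 + n_sub * nu, chol2inv(chol(prec_sum)))[, , 1]
    } else {
      Psi <- as.matrix(clamp_group)
    }
    # subject conditionals
    for (i in seq_len(n_sub)) {
      Wi <- stats::rWishart(1, nu + Tn[i],
                            chol2inv(chol(Psi + scatter[[i]])))[, , 1]
      Sigma[[i]] <- chol2inv(chol(Wi))
    }
    if (sweep > burn_in) {
      s_idx <- sweep - burn_in
      G <- Psi / (nu - N - 1)
      if (any(!is.finite(G)))
        stop("non-finite group draw at sweep ", sweep)
      draws[, , s_idx] <- G
      for (i in seq_len(n_sub)) {
        subj_sum[[i]] <- subj_sum[[i]] + Sigma[[i]]
        if (store_subject_draws) subj_draws[[i]][, , s_idx] <- Sigma[[i]]
      }
    }
  }
  subject_means <- lapply(subj_sum, function(m) .symmetrize(m / S))
  names(subject_means) <- names(subject_data)
  if (!is.null(ids)) dimnames(draws)[1:2] <- list(ids, ids)
  structure(list(draws = draws, subject_means = subject_means,
                 subject_draws = subj_draws,
                 settings = list(S = S, burn_in = burn_in, seed = seed,
                                 shrinkage_df = nu, hyper_df = nu0,
                                 hyper_scale_mean_diag = mean(diag(S0)) * nu0 / (nu - N - 1),
                                 n_subjects = n_sub, n_timepoints = Tn),
                 condition = condition, parcel_ids = ids),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior samples: %d group covariance draws (%d x %d), %d subjects%s\n",
              dim(x$draws)[3], dim(x$draws)[1], dim(x$draws)[2],
              x$settings$n_subjects,
              if (is.na(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Posterior distributions of integration measures
#'
#' Applies the integration decomposition to every retained group covariance
#' draw at the given partition (one hierarchy node), yielding the posterior
#' distribution of I_tot, I_ws, I_bs and FCR as frequency histograms over
#' draws. A draw failing the positive-definiteness check is rejected and
#' counted, never silently skipped; FCR draws with between-system
#' integration at tolerance are recorded as missing.
#'
#' @param samples A [gibbs_sample_group_covariance()] result.
#' @param part A [partition()] (or a [hierarchical_partition()], in which
#'   case `level` selects the node: `"cortex"` uses the level-7 systems).
#' @param level Node selector when `part` is hierarchical (default
#'   `"cortex"`).
#' @return Named list of `measure_distribution` objects (`I_tot`, `I_ws`,
#'   `I_bs`, `FCR`): numeric vectors of per-draw values with attributes
#'   `mean`, `sd`, `n_missing`, `measure`.
#' @export
posterior_measures <- function(samples, part, level = "cortex") {
  stopifnot(inherits(samples, "posterior_samples"))
  if (inherits(part, "hierarchical_partition")) {
    if (level != "cortex")
      stop("only the cortex node is selectable directly; subset draws for deeper nodes")
    part <- partition(part$level7, part$parcel_ids)
  }
  S <- dim(samples$draws)[3]
  vals <- matrix(NA_real_, S, 4,
                 dimnames = list(NULL, c("I_tot", "I_ws", "I_bs", "FCR")))
  n_rejected <- 0
  for (s in seq_len(S)) {
    G <- .symmetrize(samples$draws[, , s])
    res <- tryCatch(decompose_integration(G, part),
                    error = function(e) NULL)
    if (is.null(res)) {
      n_rejected <- n_rejected + 1
      next
    }
    vals[s, ] <- c(res$I_tot, res$I_ws, res$I_bs, res$FCR)
  }
  if (n_rejected > 0)
    message(n_rejected, " draw(s) rejected (failed positive-definiteness check)")
  out <- lapply(colnames(vals), function(m) {
    v <- vals[, m]
    structure(v, mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
              n_missing = sum(is.na(v)), measure = m,
              class = "measure_distribution")
  })
  names(out) <- colnames(vals)
  out
}

#' @export
print.measure_distribution <- function(x, ...) {
  cat(sprintf("%s posterior: %d draws, mean = %.4f, sd = %.4f (%d missing)\n",
              attr(x, "measure"), length(x), attr(x, "mean"), attr(x, "sd"),
              attr(x, "n_missing")))
  invisible(x)
}

#' Posterior probability of a difference between conditions
#'
#' The fraction of paired draws in which `a` strictly exceeds `b`:
#' `P(A > B | y) ~= (1/S) #\{a_s > b_s\}`. Draws are paired by index;
#' missing draws are pairwise-deleted with the count reported. A probability
#' above 0.95 is flagged significant.
#'
#' @param a,b `measure_distribution` vectors of equal length.
#' @return Probability in `[0, 1]` with attributes `n_used` and
#'   `significant`.
#' @export
probability_of_difference <- function(a, b) {
  if (length(a) != length(b)) stop("draw counts differ: ",
                                   length(a), " vs ", length(b))
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) == 0) stop("no complete draw pairs")
  p <- mean(as.numeric(a[keep]) > as.numeric(b[keep]))
  structure(p, n_used = sum(keep), n_dropped = sum(!keep),
            significant = p > 0.95)
}

#' Per-subject posterior-mean covariance matrices
#'
#' Returns each subject's posterior mean covariance, symmetrized and
#' verified positive definite (nearest-PD repair is applied and logged if
#' averaging broke tolerance). These individual estimates feed subject-level
#' FCR and brain-behavior correlations.
#'
#' @param samples A [gibbs_sample_group_covariance()] result.
#' @return Named list of covariance matrices.
#' @export
subject_covariance_estimates <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  lapply(samples$subject_means, function(m) {
    ok <- tryCatch({chol(m); TRUE}, error = function(e) FALSE)
    if (!ok) {
      message("posterior-mean covariance repaired to nearest positive-definite matrix")
      m <- as.matrix(Matrix::nearPD(m)$mat)
    }
    if (!is.null(samples$parcel_ids))
      dimnames(m) <- list(samples$parcel_ids, samples$parcel_ids)
    m
  })
}
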