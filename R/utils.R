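# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
.symmetrize <- function(m) (m + t(m)) / 2

# Cholesky with informative failure: reports the smallest eigenvalue so the
# caller can distinguish "mildly indefinite" from "garbage input".
#' @keywords internal
#' @noRd
.chol_or_stop <- function(cov, context = "covariance matrix") {
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) {
    ev <- min(eigen(.symmetrize(cov), symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3e)",
                 context, ev), call. = FALSE)
  }
  R
}

#' @keywords internal
#' @noRd
.check_symmetric <- function(cov, tol = 1e-8, context = "covariance matrix") {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop(context, " must be a square matrix", call. = FALSE)
  if (max(abs(cov - t(cov))) > tol * max(1, max(abs(cov))))
    stop(context, " is not symmetric to tolerance", call. = FALSE)
  invisible(TRUE)
}

# Relative positive-definiteness check: smallest eigenvalue must exceed
# rel_tol * largest. Optional ridge repair adds eps * mean(diag) * I.
#' @keywords internal
#' @noRd
.ensure_pd <- function(cov, ridge = FALSE, rel_tol = 1e-10, ridge_eps = 1e-6,
                       context = "covariance matrix") {
  cov <- .symmetrize(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > rel_tol * max(ev)) return(cov)
  if (!ridge)
    stop(sprintf(
      "%s fails positive-definiteness tolerance (min eig %.3e, max eig %.3e); enable ridge repair to proceed",
      context, min(ev), max(ev)), call. = FALSE)
  repaired <- cov + diag(ridge_eps * mean(diag(cov)), nrow(cov))
  message(sprintf("ridge repair applied to %s (epsilon = %.1e x mean variance)",
                  context, ridge_eps))
  repaired
}

# Project a near-correlation matrix to the nearest PD correlation matrix.
#' @keywords internal
#' @noRd
.nearest_pd_corr <- function(m) {
  m <- .symmetrize(m)
  diag(m) <- 1
  ok <- tryCatch({chol(m); TRUE}, error = function(e) FALSE)
  if (ok) return(m)
  as.matrix(Matrix::nearPD(m, corr = TRUE, keepDiag = TRUE)$mat)
}

# Seed handling: derive reproducible child seeds below 2^31 from a parent.
#' @keywords internal
#' @noRd
.child_seed <- function(seed, index) {
  (seed * 48271 + index * 2654435) %% 2147483587L
}
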