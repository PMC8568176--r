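# Gaussian functional integration and its within/between-system
# decomposition, computed from covariance log-determinants.
#
# For a zero-mean multivariate Gaussian with covariance Sigma, the entropy is
# H = 1/2 ln|Sigma| (the additive (N/2)(1 + ln 2pi) constant cancels in every
# integration quantity, so it is omitted throughout). Integration over a
# partition of the variables into K blocks is the KL divergence between the
# joint and the product of block marginals,
#   I[y_1, ..., y_K] = sum_k H(y_k) - H(y),
# which is non-negative, zero iff the blocks are independent, and invariant
# to marginal rescaling. Over K systems the total integration decomposes as
#   I_tot = I_ws + I_bs,
# I_ws summing each system's internal integration (over its parcels) and
# I_bs the integration among the K system-level blocks. The functional
# clustering ratio FCR = I_ws / I_bs indexes segregation: higher values mean
# systems generate proportionally more information internally than jointly.

#' Gaussian entropy from a covariance matrix
#'
#' Computes `0.5 * log(det(cov))` in nats via the Cholesky factor
#' (`sum(log(diag(chol(cov))))`), never through a raw determinant, so it is
#' stable for the few-hundred-parcel matrices typical of cortical
#' parcellations. The additive entropy constant is omitted; it cancels in all
#' integration quantities.
#'
#' @param cov Symmetric positive-definite covariance matrix.
#' @param ridge If `TRUE`, a failing matrix is repaired by adding
#'   `1e-6 * mean(diag(cov))` to the diagonal (logged via `message`);
#'   default `FALSE`, in which case non-PD input is an error reporting the
#'   smallest eigenvalue.
#' @return Entropy in nats (up to the omitted constant).
#' @examples
#' gaussian_entropy(diag(3))          # 0
#' gaussian_entropy(matrix(4, 1, 1))  # log(2)
#' @export
gaussian_entropy <- function(cov, ridge = FALSE) {
  .check_symmetric(cov)
  if (ridge) cov <- .ensure_pd(cov, ridge = TRUE)
  R <- .chol_or_stop(cov)
  sum(log(diag(R)))
}

#' Construct a partition of parcels into systems
#'
#' @param labels Vector (coercible to character) of system labels, one per
#'   parcel, in parcel order.
#' @param parcel_ids Optional parcel identifiers; defaults to `names(labels)`
#'   or `p1, p2, ...`.
#' @return A `partition` object: list with `labels`, `parcel_ids`, `K` and
#'   `systems` (list of index vectors per system, in order of first
#'   appearance).
#' @export
partition <- function(labels, parcel_ids = NULL) {
  labels <- as.character(labels)
  if (is.null(parcel_ids)) parcel_ids <- names(labels)
  if (is.null(parcel_ids)) parcel_ids <- paste0("p", seq_along(labels))
  if (anyNA(labels)) stop("partition labels must not be missing")
  if (length(parcel_ids) != length(labels))
    stop("parcel_ids and labels differ in length")
  sys_order <- unique(labels)
  systems <- lapply(sys_order, function(s) which(labels == s))
  names(systems) <- sys_order
  structure(list(labels = labels, parcel_ids = parcel_ids,
                 K = length(systems), systems = systems),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d parcels in %d systems (%s)\n",
              length(x$labels), x$K,
              paste(sprintf("%s:%d", names(x$systems),
                            lengths(x$systems)), collapse = ", ")))
  invisible(x)
}

#' @keywords internal
#' @noRd
.as_partition <- function(x, n) {
  if (inherits(x, "partition")) {
    if (length(x$labels) != n)
      stop("partition covers ", length(x$labels), " parcels but covariance has ", n)
    return(x)
  }
  if (length(x) != n) stop("partition labels must cover all ", n, " parcels")
  partition(x)
}

#' Total integration of a Gaussian system over a partition
#'
#' The mutual information among the blocks of `units`: the KL divergence
#' between the joint Gaussian and the product of block marginals, computed as
#' `sum_k H(block k) - H(full)` in nats. With singleton units this is the
#' total integration I_tot of the system.
#'
#' @param cov Positive-definite covariance matrix.
#' @param units A [partition()] (or label vector), or `NULL` for singleton
#'   units (one block per parcel, the default).
#' @return Integration in nats (non-negative up to numerical tolerance).
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' total_integration(S)  # -0.5 * log(0.75)
#' @export
total_integration <- function(cov, units = NULL) {
  .check_symmetric(cov)
  n <- nrow(cov)
  h_full <- gaussian_entropy(cov)
  if (is.null(units)) return(0.5 * sum(log(diag(cov))) - h_full)
  units <- .as_partition(units, n)
  h_blocks <- vapply(units$systems, function(idx) {
    if (length(idx) == 1L) return(0.5 * log(cov[idx, idx]))
    tryCatch(gaussian_entropy(cov[idx, idx, drop = FALSE]),
             error = function(e) stop("singular principal submatrix for block '",
                                      names(which(vapply(units$systems, identical, TRUE, idx))),
                                      "': ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
  sum(h_blocks) - h_full
}

#' Decompose total integration into within- and between-system terms
#'
#' Splits `I_tot` (singleton-unit integration of the whole system) exactly
#' into `I_ws`, the summed internal integration of each system over its own
#' parcels, and `I_bs`, the integration among the K system-level blocks.
#' Singleton systems contribute zero to `I_ws`. The identity
#' `I_tot = I_ws + I_bs` holds to machine precision because the block
#' entropies cancel telescopically.
#'
#' @param cov Positive-definite covariance matrix.
#' @param partition A [partition()] with at least 2 systems.
#' @param level Optional label describing the hierarchy level.
#' @return An `integration_result`: list with `I_tot`, `I_ws`, `I_bs`, `FCR`
#'   (`NA` when `I_bs` is at tolerance), `per_system` (named vector of
#'   within-system integrations, nats) and `level`.
#' @export
decompose_integration <- function(cov, partition, level = NA_character_) {
  .check_symmetric(cov)
  part <- .as_partition(partition, nrow(cov))
  if (part$K < 2) stop("integration decomposition requires at least 2 systems")
  h_full <- gaussian_entropy(cov)
  h_diag <- 0.5 * sum(log(diag(cov)))
  h_blocks <- vapply(seq_along(part$systems), function(k) {
    idx <- part$systems[[k]]
    if (length(idx) == 1L) 0.5 * log(cov[idx, idx])
    else gaussian_entropy(cov[idx, idx, drop = FALSE])
  }, numeric(1))
  per_system <- vapply(seq_along(part$systems), function(k) {
    idx <- part$systems[[k]]
    if (length(idx) == 1L) return(0)       # singleton: zero within-integration
    0.5 * sum(log(diag(cov)[idx])) - h_blocks[k]
  }, numeric(1))
  names(per_system) <- names(part$systems)
  i_ws <- sum(per_system)
  i_bs <- sum(h_blocks) - h_full
  i_tot <- h_diag - h_full
  fcr_val <- if (i_bs > 1e-12) i_ws / i_bs else NA_real_
  structure(list(I_tot = i_tot, I_ws = i_ws, I_bs = i_bs, FCR = fcr_val,
                 per_system = per_system, level = level),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration%s: I_tot = %.4f, I_ws = %.4f, I_bs = %.4f, FCR = %.4f (nats)\n",
              if (is.na(x$level)) "" else paste0(" [", x$level, "]"),
              x$I_tot, x$I_ws, x$I_bs, x$FCR))
  invisible(x)
}

#' Functional clustering ratio
#'
#' `FCR = I_ws / I_bs`: the ratio of within-system to between-system
#' integration. Values above 1 mean systems generate more information
#' internally than jointly; an increase indicates functional segregation of
#' the system into its subsystems.
#'
#' @param x Either an `integration_result` from [decompose_integration()] or
#'   a covariance matrix.
#' @param partition Required when `x` is a covariance matrix.
#' @param tol Systems are declared effectively independent when
#'   `I_bs <= tol`; this raises an error (the ratio is undefined, not
#'   infinite).
#' @return The FCR (unitless, non-negative).
#' @export
fcr <- function(x, partition = NULL, tol = 1e-12) {
  res <- if (inherits(x, "integration_result")) x
         else decompose_integration(x, partition)
  if (!(res$I_bs > tol))
    stop(sprintf("FCR undefined: between-system integration (%.3e) is at tolerance; systems are effectively independent",
                 res$I_bs))
  res$I_ws / res$I_bs
}

#' Integration decomposition at every node of a parcel hierarchy
#'
#' Walks a nested cortex / level-7 / level-17 / assembly hierarchy: the
#' cortex node is decomposed over level-7 systems, each level-7 node over its
#' level-17 systems (on the principal submatrix of its parcels), and each
#' level-17 node over its assemblies. At every node `I_tot = I_ws + I_bs`,
#' and the cortex-level singleton integration equals the telescoped sum of
#' `I_bs` terms down the tree plus the leaf within-assembly integrations.
#'
#' @param cov Positive-definite covariance matrix over all parcels.
#' @param hp A [hierarchical_partition()]; the assembly level may be absent,
#'   in which case the walk stops at level 17.
#' @return Nested list: `cortex` (an `integration_result`), `level7` (list of
#'   results per level-7 system, each with a `level17` sublist when
#'   assemblies are present).
#' @export
hierarchical_integration <- function(cov, hp) {
  stopifnot(inherits(hp, "hierarchical_partition"))
  if (nrow(cov) != length(hp$parcel_ids))
    stop("covariance dimension does not match hierarchy parcel count")
  out <- list()
  out$cortex <- decompose_integration(cov, partition(hp$level7, hp$parcel_ids),
                                      level = "cortex")
  out$level7 <- list()
  for (net in unique(hp$level7)) {
    idx <- which(hp$level7 == net)
    sub17 <- hp$level17[idx]
    if (length(unique(sub17)) < 2) {
      warning("level-7 system '", net,
              "' has fewer than 2 level-17 subsystems; node skipped")
      next
    }
    node <- decompose_integration(cov[idx, idx, drop = FALSE],
                                  partition(sub17, hp$parcel_ids[idx]),
                                  level = paste0("level7:", net))
    if (!is.null(hp$assembly)) {
      node$level17 <- list()
      for (s17 in unique(sub17)) {
        jdx <- idx[sub17 == s17]
        asm <- hp$assembly[jdx]
        if (length(unique(asm)) < 2) {
          warning("level-17 system '", s17,
                  "' has fewer than 2 assemblies; node skipped")
          next
        }
        node$level17[[s17]] <- decompose_integration(
          cov[jdx, jdx, drop = FALSE], partition(asm, hp$parcel_ids[jdx]),
          level = paste0("level17:", s17))
      }
    }
    out$level7[[net]] <- node
  }
  out
}
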