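# Edge-wise connectivity change statistics, subcortical-cortical
# connectivity, behavioral PCA, brain-behavior correlation with covariate
# control, and spin-permutation spatial tests.

#' Pearson connectivity matrix with Fisher-z transform
#'
#' @param ts A [parcel_ts()] with at least 3 volumes.
#' @return List with `r` (correlation matrix, diagonal `NA`) and `z`
#'   (`atanh(r)`); entries from constant or perfectly correlated parcel
#'   pairs are missing with a warning.
#' @export
connectivity_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (nrow(ts$data) < 3) stop("at least 3 volumes required")
  sds <- apply(ts$data, 2, stats::sd)
  r <- suppressWarnings(stats::cor(ts$data))
  if (any(sds == 0)) {
    warning("constant parcel series: affected correlations set to missing")
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  }
  diag(r) <- NA
  degenerate <- !is.na(r) & abs(r) >= 1 - 1e-12
  if (any(degenerate)) {
    warning("perfectly correlated parcel pair(s): Fisher z undefined, set to missing")
    r[degenerate] <- NA
  }
  z <- atanh(r)
  dimnames(r) <- dimnames(z) <- list(ts$parcel_ids, ts$parcel_ids)
  list(r = r, z = z)
}

#' Edge-wise paired test of connectivity change between conditions
#'
#' A paired two-sided t test per upper-triangle edge on the Fisher-z scale,
#' Benjamini-Hochberg corrected over all edges. Reports the percentage of
#' all edges that significantly increased / decreased, and the directional
#' split among significant edges. Edges missing in some subjects are tested
#' on the complete pairs, with the per-edge n reported.
#'
#' @param zA,zB Lists of per-subject Fisher-z matrices (same subjects, same
#'   order; condition B minus condition A is the tested change).
#' @param q FDR level (default 0.05).
#' @return Data frame with one row per edge (`i`, `j`, `t`, `p`, `p_fdr`,
#'   `significant`, `mean_change`, `n`), plus attributes `pct_increased`,
#'   `pct_decreased` (percent of all edges significantly changed in each
#'   direction).
#' @export
edge_change_test <- function(zA, zB, q = 0.05) {
  if (length(zA) != length(zB)) stop("conditions have different subject counts")
  n_sub <- length(zA)
  if (n_sub < 3) stop("at least 3 subjects required")
  N <- nrow(zA[[1]])
  ut <- which(upper.tri(zA[[1]]))
  dmat <- vapply(seq_len(n_sub),
                 function(i) (zB[[i]] - zA[[i]])[ut], numeric(length(ut)))
  n_edge <- rowSums(!is.na(dmat))
  mean_d <- rowMeans(dmat, na.rm = TRUE)
  sd_d <- apply(dmat, 1, stats::sd, na.rm = TRUE)
  tstat <- mean_d / (sd_d / sqrt(n_edge))
  pval <- 2 * stats::pt(-abs(tstat), df = n_edge - 1)
  pval[n_edge < 3 | sd_d == 0] <- NA
  p_fdr <- stats::p.adjust(pval, method = "BH")
  sig <- !is.na(p_fdr) & p_fdr < q
  idx <- arrayInd(ut, c(N, N))
  out <- data.frame(i = idx[, 1], j = idx[, 2], t = tstat, p = pval,
                    p_fdr = p_fdr, significant = sig,
                    mean_change = mean_d, n = n_edge)
  attr(out, "pct_increased") <- 100 * mean(sig & mean_d > 0)
  attr(out, "pct_decreased") <- 100 * mean(sig & mean_d < 0)
  out
}

#' Subcortical-to-cortical connectivity
#'
#' Pearson correlation between each subcortical region's series and every
#' cortical parcel. Given per-subject session lists, the mean connectivity
#' (per network and whole cortex) is tested against zero with a two-sided
#' one-sample t test across subjects on the Fisher-z scale.
#'
#' @param cortex_ts A [parcel_ts()] or list of them (one per subject).
#' @param subcortical_ts A [parcel_ts()] of subcortical region series (or
#'   matching list).
#' @param hp Optional [hierarchical_partition()] for per-network means.
#' @return For single sessions: list with `r` (region x parcel matrix) and
#'   `network_means`. For subject lists: additionally `tests`, a data frame
#'   of per-region one-sample t tests of the whole-cortex mean (z scale).
#' @export
subcortical_connectivity <- function(cortex_ts, subcortical_ts, hp = NULL) {
  single <- inherits(cortex_ts, "parcel_ts")
  if (single) { cortex_ts <- list(cortex_ts); subcortical_ts <- list(subcortical_ts) }
  if (length(cortex_ts) != length(subcortical_ts))
    stop("cortical and subcortical session lists differ in length")
  per_subj <- lapply(seq_along(cortex_ts), function(i) {
    ct <- cortex_ts[[i]]; st <- subcortical_ts[[i]]
    if (nrow(ct$data) != nrow(st$data))
      stop("subject ", i, ": cortical and subcortical series differ in length")
    t(stats::cor(st$data, ct$data))   # parcel x region -> transpose below
  })
  rmats <- lapply(per_subj, t)        # region x parcel
  rbar <- Reduce(`+`, rmats) / length(rmats)
  net_means <- NULL
  if (!is.null(hp)) {
    nets <- unique(hp$level7)
    net_means <- vapply(nets, function(nw)
      rowMeans(rbar[, hp$level7 == nw, drop = FALSE]), numeric(nrow(rbar)))
    colnames(net_means) <- nets
  }
  out <- list(r = rbar, network_means = net_means)
  if (!single) {
    zbar <- vapply(rmats, function(m) rowMeans(atanh(pmin(pmax(m, -1 + 1e-12),
                                                          1 - 1e-12))),
                   numeric(nrow(rbar)))  # region x subject
    tests <- do.call(rbind, lapply(seq_len(nrow(rbar)), function(k) {
      tt <- stats::t.test(zbar[k, ])
      data.frame(region = rownames(rbar)[k] %||% paste0("region", k),
                 mean_z = mean(zbar[k, ]), t = unname(tt$statistic),
                 p = tt$p.value)
    }))
    out$tests <- tests
  }
  out
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' First principal component of behavioral change scores
#'
#' Columns (tasks) are standardized, the first principal component is
#' extracted, and its sign is fixed so scores correlate positively with the
#' subject-mean standardized change across tasks. Constant columns are
#' dropped with a warning.
#'
#' @param changes Subject x task matrix of change scores.
#' @return List with `scores` (per subject), `variance_explained` (fraction
#'   for component 1), `loadings`.
#' @export
performance_pca <- function(changes) {
  changes <- as.matrix(changes)
  if (nrow(changes) < 3) stop("at least 3 subjects required")
  if (ncol(changes) < 2) stop("at least 2 tasks required")
  sds <- apply(changes, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant task column(s) dropped: ",
            paste(colnames(changes)[sds == 0], collapse = ", "))
    changes <- changes[, sds > 0, drop = FALSE]
    if (ncol(changes) < 2) stop("fewer than 2 non-constant tasks remain")
  }
  Z <- scale(changes)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (stats::cor(scores, rowMeans(Z)) < 0) {
    scores <- -scores
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  list(scores = scores,
       variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = pc$rotation[, 1])
}

#' Brain-behavior correlation with optional covariate control
#'
#' Product-moment correlation between a per-subject brain measure change and
#' a behavioral score. With covariates, both variables are residualized on
#' an intercept plus the covariates and the partial correlation is tested on
#' `n - 2 - k` degrees of freedom.
#'
#' @param x,y Numeric vectors (per subject).
#' @param covariates Optional vector or matrix of per-subject covariates
#'   (e.g. mean framewise displacement).
#' @return List with `r`, `p`, `n`, `df`, and `partial` flag.
#' @export
brain_behavior_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  if (is.null(covariates)) {
    if (n < 4) stop("at least 4 subjects required")
    ct <- stats::cor.test(x, y)
    return(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                df = n - 2, partial = FALSE))
  }
  C <- as.matrix(covariates)
  k <- ncol(C)
  if (n < 5 || n <= 2 + k) stop("too few subjects for ", k, " covariate(s)")
  X <- cbind(1, C)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) < 1e-10 * stats::sd(x) || stats::sd(ry) < 1e-10 * stats::sd(y))
    stop("degenerate covariate: a variable is collinear with the covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df,
       partial = TRUE)
}

#' Spin permutation test for cortical map correspondence
#'
#' Tests the spatial correlation of two per-parcel maps against a null that
#' preserves spatial autocorrelation: each permutation applies one uniform
#' random 3D rotation to the spherical parcel centroids of one hemisphere
#' and its mirror image to the other, then reassigns parcel values within
#' each hemisphere by matching rotated to original centroids. The default
#' `"bijective"` method matches one-to-one greedily by descending cosine
#' similarity, so every permuted map preserves the multiset of map values
#' exactly; `"replacement"` uses plain nearest-neighbor lookup, in which
#' case a parcel value may be duplicated (duplication rate logged).
#'
#' @param map1,map2 Per-parcel numeric maps (equal length, no constants).
#' @param coords Parcel centroid coordinates on the unit sphere: matrix with
#'   columns x, y, z (normalized if slightly off-unit, with a warning).
#' @param hemisphere Character/factor of `"L"`/`"R"` per parcel.
#' @param n_perm Number of angular permutations (default 100).
#' @param seed Integer seed.
#' @param method `"bijective"` (default) or `"replacement"`.
#' @return A `spin_result`: list with `r_obs`, `r_perm` (length `n_perm`),
#'   `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)`, and
#'   `duplication_rate` (mean fraction of parcels duplicated per rotation;
#'   0 for the bijective method).
#' @export
spin_permutation_test <- function(map1, map2, coords, hemisphere,
                                  n_perm = 100, seed = 1,
                                  method = c("bijective", "replacement")) {
  method <- match.arg(method)
  n <- length(map1)
  if (length(map2) != n) stop("maps have mismatched parcel counts")
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching the maps")
  if (length(hemisphere) != n) stop("hemisphere labels must cover all parcels")
  if (stats::sd(map1) == 0 || stats::sd(map2) == 0)
    stop("constant map: correlation undefined")
  norms <- sqrt(rowSums(coords^2))
  if (any(norms == 0)) stop("zero-length centroid coordinate")
  if (any(abs(norms - 1) > 1e-6)) {
    warning("coordinates normalized to the unit sphere")
    coords <- coords / norms
  }
  hemis <- as.character(hemisphere)
  r_obs <- stats::cor(map1, map2)
  set.seed(seed)
  mirror <- diag(c(-1, 1, 1))
  r_perm <- numeric(n_perm)
  dup <- numeric(n_perm)
  perm_indices <- matrix(NA_integer_, n_perm, n)
  for (p in seq_len(n_perm)) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    perm_idx <- integer(n)
    for (h in unique(hemis)) {
      idx <- which(hemis == h)
      Rh <- if (h == unique(hemis)[1]) Q else mirror %*% Q %*% mirror
      rotated <- coords[idx, , drop = FALSE] %*% t(Rh)
      sim <- rotated %*% t(coords[idx, , drop = FALSE])
      if (method == "replacement") {
        nn <- max.col(sim, ties.method = "first")
      } else {
        nn <- .greedy_match(sim)
      }
      perm_idx[idx] <- idx[nn]
    }
    dup[p] <- 1 - length(unique(perm_idx)) / n
    perm_indices[p, ] <- perm_idx
    r_perm[p] <- stats::cor(map1, map2[perm_idx])
  }
  structure(list(r_obs = r_obs, r_perm = r_perm,
                 p = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm),
                 duplication_rate = mean(dup), perm_indices = perm_indices,
                 n_perm = n_perm, seed = seed, method = method),
            class = "spin_result")
}

# greedy one-to-one matching: repeatedly take the best remaining
# (rotated, original) pair by similarity; returns, per rotated row, the
# matched original column. O(n^2 log n), ample for parcel-level maps.
#' @keywords internal
#' @noRd
.greedy_match <- function(sim) {
  n <- nrow(sim)
  ord <- order(sim, decreasing = TRUE)
  rows <- ((ord - 1) %% n) + 1
  cols <- ((ord - 1) %/% n) + 1
  match_of <- integer(n)
  row_done <- col_done <- logical(n)
  filled <- 0L
  for (k in seq_along(ord)) {
    i <- rows[k]; j <- cols[k]
    if (row_done[i] || col_done[j]) next
    match_of[i] <- j
    row_done[i] <- col_done[j] <- TRUE
    filled <- filled + 1L
    if (filled == n) break
  }
  match_of
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("spin test: r_obs = %.3f, p = %.4f (%d rotations, %.1f%% mean duplication)\n",
              x$r_obs, x$p, x$n_perm, 100 * x$duplication_rate))
  invisible(x)
}
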