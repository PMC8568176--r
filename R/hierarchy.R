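# Nested cortical hierarchy: cortex -> 7 networks -> 17 subnetworks ->
# data-driven assemblies, and the clustering that derives the assembly level
# from baseline connectivity.

#' Construct a hierarchical partition of parcels
#'
#' Represents the nested assignment of parcels to systems at up to four
#' levels: the whole cortex, a coarse network template (level 7), a finer
#' subnetwork template (level 17) nested inside it, and data-driven
#' assemblies nested inside level 17. Nesting is strict: a level-17 label
#' occurring under two different level-7 labels is an error, as is an
#' assembly spanning two level-17 systems.
#'
#' @param parcel_ids Unique parcel identifiers, in matrix order.
#' @param level7,level17 System labels per parcel.
#' @param assembly Optional assembly labels per parcel (usually filled by
#'   [cluster_assemblies()]).
#' @return A `hierarchical_partition` object.
#' @export
hierarchical_partition <- function(parcel_ids, level7, level17, assembly = NULL) {
  parcel_ids <- as.character(parcel_ids)
  level7 <- as.character(level7); level17 <- as.character(level17)
  n <- length(parcel_ids)
  if (anyDuplicated(parcel_ids)) stop("duplicated parcel_id: ",
                                      parcel_ids[anyDuplicated(parcel_ids)])
  if (length(level7) != n || length(level17) != n)
    stop("level7/level17 labels must cover every parcel exactly once")
  .check_nesting(level17, level7, "level-17", "level-7")
  if (!is.null(assembly)) {
    assembly <- as.character(assembly)
    if (length(assembly) != n) stop("assembly labels must cover every parcel")
    .check_nesting(assembly, level17, "assembly", "level-17")
  }
  sizes17 <- table(level17)
  if (any(sizes17 == 1L))
    warning("level-17 system(s) with a single parcel (cannot be decomposed further): ",
            paste(names(sizes17)[sizes17 == 1L], collapse = ", "))
  structure(list(parcel_ids = parcel_ids, level7 = level7,
                 level17 = level17, assembly = assembly),
            class = "hierarchical_partition")
}

#' @keywords internal
#' @noRd
.check_nesting <- function(child, parent, child_name, parent_name) {
  tab <- unique(data.frame(child = child, parent = parent))
  dup <- tab$child[duplicated(tab$child)]
  if (length(dup))
    stop(child_name, " label(s) spanning multiple ", parent_name,
         " systems (nesting violated): ", paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  cat(sprintf("hierarchical partition: %d parcels, %d level-7 systems, %d level-17 systems, %s\n",
              length(x$parcel_ids), length(unique(x$level7)),
              length(unique(x$level17)),
              if (is.null(x$assembly)) "assembly level empty"
              else sprintf("%d assemblies", length(unique(x$assembly)))))
  invisible(x)
}

#' Read a parcel-to-network lookup table
#'
#' Expects delimited text with a header containing at least `parcel_id`,
#' `level7` and `level17` columns (an `assembly` column is honored when
#' present). Nesting of level 17 inside level 7 is inferred from
#' co-occurrence and validated.
#'
#' @param path Path to a whitespace- or tab-delimited table.
#' @return A [hierarchical_partition()].
#' @export
load_partition_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("parcel_id", "level7", "level17")
  if (!all(need %in% names(tab)))
    stop("partition table must have columns: ", paste(need, collapse = ", "))
  hierarchical_partition(tab$parcel_id, tab$level7, tab$level17,
                         assembly = if ("assembly" %in% names(tab)) tab$assembly)
}

#' Write a hierarchical partition as delimited text
#'
#' @param hp A [hierarchical_partition()].
#' @param path Output path.
#' @export
write_partition_table <- function(hp, path) {
  tab <- data.frame(parcel_id = hp$parcel_ids, level7 = hp$level7,
                    level17 = hp$level17)
  if (!is.null(hp$assembly)) tab$assembly <- hp$assembly
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive the assembly level by clustering baseline connectivity
#'
#' Within each level-17 system, parcel-pair correlations from the designated
#' baseline condition are thresholded at significance (two-sided t test for
#' a Pearson correlation with `n_obs` samples; non-significant entries set
#' to 0), converted to the dissimilarity `d = 1 - r^2`, and clustered
#' agglomeratively. The tree is cut at the merge showing the largest
#' increase in merge height (the elbow of intracluster distance), subject to
#' a minimum of two clusters per system so the downstream integration
#' decomposition is defined.
#'
#' Assembly labels are canonical -- `<system>.<k>` numbered by order of first
#' parcel appearance -- so the result is invariant to parcel input order up
#' to this renaming.
#'
#' @param baseline_corr Correlation matrix over all parcels, computed from
#'   the baseline (rested) condition.
#' @param hp A [hierarchical_partition()] with the assembly level empty.
#' @param n_obs Number of time samples behind `baseline_corr` (needed for
#'   the significance threshold).
#' @param sig_threshold Two-sided p-value threshold below which a
#'   correlation is retained; default 0.05, uncorrected.
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   default `"average"`.
#' @return The hierarchy with the assembly level filled.
#' @export
cluster_assemblies <- function(baseline_corr, hp, n_obs,
                               sig_threshold = 0.05, linkage = "average") {
  stopifnot(inherits(hp, "hierarchical_partition"))
  n <- length(hp$parcel_ids)
  if (nrow(baseline_corr) != n)
    stop("baseline correlation dimension does not match hierarchy")
  if (n_obs < 4) stop("n_obs too small for a correlation significance test")
  assembly <- character(n)
  for (s17 in unique(hp$level17)) {
    idx <- which(hp$level17 == s17)
    m <- length(idx)
    if (m < 2L) {
      warning("system '", s17, "' has a single parcel; one singleton assembly")
      assembly[idx] <- paste0(s17, ".1")
      next
    }
    if (m < 4L) {
      warning("system '", s17, "' has fewer than 4 parcels; deterministic split into 2 clusters")
      if (m == 2L) cl <- c(1L, 2L)
      else cl <- stats::cutree(stats::hclust(stats::as.dist(
        .assembly_dissimilarity(baseline_corr[idx, idx], n_obs, sig_threshold)),
        method = linkage), k = 2L)
    } else {
      d <- .assembly_dissimilarity(baseline_corr[idx, idx], n_obs, sig_threshold)
      hc <- stats::hclust(stats::as.dist(d), method = linkage)
      k <- .elbow_k(hc$height, m)
      if (is.na(k)) {
        warning("system '", s17,
                "' has degenerate (all-equal) dissimilarities; deterministic split into 2 clusters by parcel order")
        cl <- rep(c(1L, 2L), c(ceiling(m / 2), floor(m / 2)))
      } else cl <- stats::cutree(hc, k = k)
    }
    # canonical labels by order of first appearance
    first <- match(unique(cl), cl)
    relab <- match(cl, cl[sort(first)])
    assembly[idx] <- paste0(s17, ".", relab)
  }
  hierarchical_partition(hp$parcel_ids, hp$level7, hp$level17, assembly)
}

# dissimilarity d = 1 - r^2 after zeroing non-significant correlations
#' @keywords internal
#' @noRd
.assembly_dissimilarity <- function(r, n_obs, sig_threshold) {
  r <- .symmetrize(as.matrix(r)); diag(r) <- 1
  r[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * (1 - 1e-12)
  tval <- r * sqrt((n_obs - 2) / (1 - r^2))
  pval <- 2 * stats::pt(-abs(tval), df = n_obs - 2)
  r[pval >= sig_threshold] <- 0
  d <- 1 - r^2
  diag(d) <- 0
  d
}

# Cut at the merge with the largest increase in merge height, scanning the
# successive-height differences; k clusters remain when the cut falls just
# after merge i* = which.max(diff(heights)). NA signals a degenerate tree.
#' @keywords internal
#' @noRd
.elbow_k <- function(heights, m) {
  if (length(heights) < 2) return(2L)
  gaps <- diff(heights)
  if (max(gaps) <= 1e-12 && stats::sd(heights) <= 1e-12) return(NA_integer_)
  istar <- which.max(gaps)            # first index on ties: cut lower -> more clusters
  max(2L, m - istar)
}
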