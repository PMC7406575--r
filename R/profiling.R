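# Product-profile fingerprinting: per-sample max-normalization, aggregation
# by degree of polymerization, and complete-linkage hierarchical clustering
# of samples within a (substrate, time) stratum.
#
# Normalizing each sample to its most abundant compound turns raw
# intensities into a fingerprint of *what* the enzyme makes rather than how
# much: the clustering is then invariant to per-sample global intensity
# scale (dosage, injection volume, overall activity).

#' Max-normalize a sample profile
#'
#' Divides every compound intensity by the sample maximum so the most
#' abundant compound is exactly 1. An all-zero profile is returned
#' unchanged with attribute `all_zero = TRUE` (division skipped).
#'
#' @param profile A `sample_profile` from [build_profile()], or a bare
#'   named numeric vector of intensities.
#' @return Same shape as the input with values in `[0, 1]`.
#' @export
normalize_profile <- function(profile) {
  vec <- if (inherits(profile, "sample_profile")) profile$intensities
         else profile
  if (any(vec < 0)) stop("negative intensity", call. = FALSE)
  mx <- max(vec)
  if (mx == 0) {
    out <- vec
    attr(out, "all_zero") <- TRUE
  } else {
    out <- vec / mx
  }
  if (inherits(profile, "sample_profile")) {
    profile$intensities <- out
    attr(profile, "all_zero") <- isTRUE(attr(out, "all_zero"))
    profile
  } else out
}

#' Aggregate a normalized profile by DP
#'
#' Sums normalized intensities per degree of polymerization, optionally
#' split into non-acetylated ("DP*n*") and acetylated ("DP*n* ace") bins;
#' retention-time isomers of one composition are summed into the same bin.
#' Aggregation conserves the profile total.
#'
#' @param profile Named numeric vector (names parseable compound names) or
#'   a `sample_profile`.
#' @param split_acetyl Split bins by presence of acetyl substitution.
#' @return Named numeric vector of bin totals, ordered by DP (acetylated
#'   bin after the plain bin of the same DP).
#' @export
aggregate_by_dp <- function(profile, split_acetyl = TRUE) {
  vec <- if (inherits(profile, "sample_profile")) profile$intensities
         else profile
  if (length(vec) == 0L) return(stats::setNames(numeric(0), character(0)))
  parsed <- lapply(names(vec), function(nm) {
    p <- tryCatch(parse_oligo_name(nm), error = function(e)
      stop("unparseable profile key: '", nm, "'", call. = FALSE))
    p$composition
  })
  dp <- vapply(parsed, `[[`, integer(1), "dp")
  ace <- vapply(parsed, function(p) p$n_acetyl > 0L, logical(1))
  bin <- if (split_acetyl) paste0("DP", dp, ifelse(ace, " ace", ""))
         else paste0("DP", dp)
  tot <- tapply(vec, bin, sum)
  ord <- order(as.integer(sub("^DP([0-9]+).*$", "\\1",  names(tot))),
               grepl(" ace$", names(tot)))
  stats::setNames(as.numeric(tot)[ord], names(tot)[ord])
}

#' Assemble a profile matrix
#'
#' Stacks normalized profiles of one (substrate, time) stratum into a
#' rectangular samples x compounds matrix (missing compounds are zero),
#' rows named by the enzyme label and sorted lexicographically so
#' downstream clustering is reproducible.
#'
#' @param profiles List of `sample_profile` objects sharing a compound set.
#' @return Numeric matrix, rows = samples, columns = compounds.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  cols <- names(profiles[[1]]$intensities)
  rows <- t(vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(cols)), cols)
    v[intersect(names(p$intensities), cols)] <-
      p$intensities[intersect(names(p$intensities), cols)]
    v
  }, numeric(length(cols))))
  rownames(rows) <- vapply(profiles, `[[`, character(1), "enzyme")
  rows[order(rownames(rows)), , drop = FALSE]
}

#' Cluster samples by product profile
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' Euclidean distance matrix of profile rows. Rows are sorted
#' lexicographically by name before clustering so ties resolve
#' reproducibly; leaf order follows the dendrogram.
#'
#' @param mat Numeric matrix, rows = samples (>= 2), columns = compounds or
#'   DP bins.
#' @return List with `hclust` (the [stats::hclust] object), `order`
#'   (leaf order as row names) and `heights` (merge heights).
#' @export
cluster_samples <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples to cluster",
                           call. = FALSE)
  if (anyNA(mat)) stop("profile matrix contains NA", call. = FALSE)
  if (!is.null(rownames(mat)))
    mat <- mat[order(rownames(mat)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  list(hclust = hc,
       order = if (is.null(rownames(mat))) hc$order
               else rownames(mat)[hc$order],
       heights = hc$height)
}

#' Heatmap-ready table in dendrogram order
#'
#' Reorders the profile matrix rows by the clustering leaf order; values
#' are left untransformed (already in `[0, 1]` after normalization).
#' Optionally renders a heatmap via the pheatmap package when available.
#'
#' @param mat Profile matrix used for `clustering`.
#' @param clustering Result of [cluster_samples()] on `mat` (NULL for a
#'   single-row matrix, which is returned as is).
#' @param draw Render a pheatmap figure (requires the pheatmap package).
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The reordered matrix (invisibly when `draw = TRUE`).
#' @export
export_heatmap_table <- function(mat, clustering = NULL, draw = FALSE, ...) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  out <- if (is.null(clustering)) mat
         else mat[clustering$order, , drop = FALSE]
  if (draw) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop("pheatmap not installed", call. = FALSE)
    pheatmap::pheatmap(out, cluster_rows = FALSE, cluster_cols = FALSE, ...)
    return(invisible(out))
  }
  out
}
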