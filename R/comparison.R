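#' Assemble a condition-by-feature profile matrix
#'
#' Pivots a tidy table into the matrix that is hierarchically clustered:
#' rows are condition descriptors (e.g. model x duration), columns are
#' features (e.g. compound x concentration), cells are the mean `value`
#' over replicates. Assembly fails if any row/column combination is
#' missing, so the matrix is always complete.
#'
#' @param df tidy data.frame.
#' @param rows character vector of column names forming the row descriptor.
#' @param cols character vector of column names forming the features.
#' @param value name of the value column (default `"value"`).
#' @return numeric matrix with informative dimnames.
#' @export
profile_matrix <- function(df, rows, cols, value = "value") {
  stopifnot(all(c(rows, cols, value) %in% names(df)))
  rkey <- interaction(df[rows], sep = "|", drop = TRUE)
  ckey <- interaction(df[cols], sep = "|", drop = TRUE)
  m <- tapply(df[[value]], list(rkey, ckey), mean)
  if (anyNA(m)) {
    stop("profile matrix has missing condition/feature combinations", call. = FALSE)
  }
  m
}

#' Encode PoD values as clustering features
#'
#' log10-transforms PoD values; an undefined PoD (no departure within the
#' tested range) is encoded as one dilution step (a factor 10^(1/3)) above
#' the highest tested concentration, so insensitive conditions cluster
#' together rather than being dropped. Sentinel positions are flagged.
#'
#' @param pod numeric PoD values in uM (`NA` = undefined).
#' @param highest_tested highest tested concentration in uM (scalar or per
#'   value).
#' @return numeric vector of log10 PoDs with attribute `sentinel`
#'   (logical).
#' @export
pod_features <- function(pod, highest_tested) {
  stopifnot(all(highest_tested > 0))
  sentinel <- !is.finite(pod)
  filled <- ifelse(sentinel, rep_len(highest_tested, length(pod)) * 10^(1 / 3), pod)
  structure(log10(filled), sentinel = sentinel)
}

#' Euclidean distances between profile rows
#'
#' @param matrix numeric matrix with >= 2 rows (a [profile_matrix()]).
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(matrix) {
  if (nrow(matrix) < 2L) {
    stop("need at least 2 profiles to compare", call. = FALSE)
  }
  as.matrix(stats::dist(matrix, method = "euclidean"))
}

#' Average distance matrices over reporters
#'
#' The three reporters yield one distance matrix each; their element-wise
#' mean is the consensus distance used for clustering culture models and
#' exposure durations.
#'
#' @param distances list of distance matrices with identical dimnames.
#' @return the element-wise mean matrix.
#' @export
mean_over_reporters <- function(distances) {
  stopifnot(is.list(distances), length(distances) >= 1L)
  ref <- dimnames(distances[[1]])
  for (d in distances) {
    if (!identical(dim(d), dim(distances[[1]])) ||
      !identical(dimnames(d), ref)) {
      stop("distance matrices must share the same row/column sets", call. = FALSE)
    }
  }
  Reduce(`+`, distances) / length(distances)
}

#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical clustering under complete linkage (maximum inter-cluster
#' pairwise distance) or Ward's criterion (minimum within-cluster variance
#' increase, on squared Euclidean distances). Both are supported because
#' screening studies report either; the default is complete linkage.
#'
#' @param distmat symmetric distance matrix with zero diagonal, or a
#'   `dist` object.
#' @param linkage `"complete"` (default) or `"ward"`.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(distmat, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  if (!inherits(distmat, "dist")) {
    distmat <- as.matrix(distmat)
    if (!isSymmetric(unname(distmat)) || any(diag(distmat) != 0)) {
      stop("distance matrix must be symmetric with a zero diagonal", call. = FALSE)
    }
    distmat <- stats::as.dist(distmat)
  }
  stats::hclust(distmat, method = if (linkage == "ward") "ward.D2" else "complete")
}

#' Export a cluster tree as a newick string
#'
#' @param tree an `hclust` from [hierarchical_cluster()].
#' @param file optional path; when given the newick string is written there.
#' @return the newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(tree, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("package 'ape' is required for newick export", call. = FALSE)
  }
  phy <- ape::as.phylo(tree)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Merge table of a cluster tree
#'
#' @param tree an `hclust`.
#' @return data.frame with one row per merge: `step`, `left`, `right`
#'   (negative = leaf index, positive = earlier merge) and `height`.
#' @export
cluster_merges <- function(tree) {
  data.frame(
    step = seq_len(nrow(tree$merge)),
    left = tree$merge[, 1],
    right = tree$merge[, 2],
    height = tree$height
  )
}
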