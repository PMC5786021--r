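# Chemical shift covariance analysis (CHESCA): correlation distances between
# per-methyl shift trajectories and complete-linkage clustering.

#' Correlation distance between two shift vectors
#'
#' `d_ij = 1 - (centered dot product) / (product of centered norms)`, i.e.
#' `1 - Pearson correlation` of the two methyls' combined-shift vectors
#' across the variant panel. 0 means identical response, 2 opposite
#' response.
#'
#' @param v_i,v_j Numeric vectors of combined shifts over the same variants
#'   (length >= 3, neither constant).
#' @return The unit-less distance in \[0, 2\].
#' @export
correlation_distance <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) stop("shift vectors differ in length")
  if (length(v_i) < 3) stop("need at least 3 variants for a correlation distance")
  ci <- v_i - mean(v_i)
  cj <- v_j - mean(v_j)
  ni <- sqrt(sum(ci^2))
  nj <- sqrt(sum(cj^2))
  if (ni == 0 || nj == 0)
    stop("zero-variance shift vector (filter by MAD significance first)")
  1 - sum(ci * cj) / (ni * nj)
}

#' Pairwise correlation-distance matrix
#'
#' @param st A `shift_table`.
#' @param methyls Optional subset of methyl labels (typically the
#'   MAD-significant set). Default: all rows.
#' @return Symmetric matrix of distances with zero diagonal, dimnames =
#'   methyl labels.
#' @export
shift_distance_matrix <- function(st, methyls = NULL) {
  m <- shift_matrix(st)
  if (!is.null(methyls)) {
    missing <- setdiff(methyls, rownames(m))
    if (length(missing))
      stop("methyls absent from shift table: ", paste(missing, collapse = ", "))
    m <- m[methyls, , drop = FALSE]
  }
  mc <- m - rowMeans(m)
  norms <- sqrt(rowSums(mc^2))
  if (any(norms == 0))
    stop("zero-variance shift vector(s): ",
         paste(rownames(m)[norms == 0], collapse = ", "))
  d <- 1 - (mc %*% t(mc)) / outer(norms, norms)
  diag(d) <- 0
  # numerical guard: clamp tiny excursions outside [0, 2]
  d[d < 0] <- 0
  d[d > 2] <- 2
  (d + t(d)) / 2
}

#' CHESCA clustering by complete linkage
#'
#' Agglomerative complete-linkage clustering of the correlation-distance
#' matrix, cut at a fixed unit-less height (default 1.5). Under complete
#' linkage every pair of methyls inside a flat cluster is within the cutoff.
#' Distances are not filtered before clustering. Clusters smaller than
#' `min_size` are reported as unclustered (`NA`). Anti-correlated responders
#' (d near 2) land in different clusters by construction.
#'
#' @param d Distance matrix from [shift_distance_matrix()] (or any symmetric
#'   matrix with zero diagonal and values in \[0, 2\]).
#' @param cutoff Dendrogram cut height, default 1.5.
#' @param min_size Minimum cluster size to report, default 3.
#' @return An object of class `chesca_clustering`: list with `assignment`
#'   (data.frame `methyl`, `cluster`; `NA` = unclustered), `tree` (an
#'   `hclust` object, `NULL` for a single methyl), `cutoff`, `min_size`.
#'   Cluster ids are 1, 2, ... in decreasing order of size.
#' @export
chesca_cluster <- function(d, cutoff = 1.5, min_size = 3) {
  if (is.null(dim(d)) || nrow(d) == 0) stop("empty distance matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(d)))
  if (nrow(d) == 1) {
    cl <- if (min_size <= 1) 1L else NA_integer_
    return(structure(list(
      assignment = data.frame(methyl = labels, cluster = cl),
      tree = NULL, cutoff = cutoff, min_size = min_size),
      class = "chesca_clustering"))
  }
  tree <- hclust(as.dist(d), method = "complete")
  raw <- cutree(tree, h = cutoff)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  cl <- ifelse(raw %in% keep, raw, NA_integer_)
  # relabel surviving clusters 1..K by decreasing size (ties: first methyl)
  if (any(!is.na(cl))) {
    surv <- sort(table(cl), decreasing = TRUE)
    first_at <- vapply(names(surv), function(k) min(which(cl == as.integer(k))),
                       integer(1))
    ord <- names(surv)[order(-as.vector(surv), first_at)]
    cl <- match(as.character(cl), ord)
  }
  structure(list(
    assignment = data.frame(methyl = labels, cluster = as.integer(cl)),
    tree = tree, cutoff = cutoff, min_size = min_size),
    class = "chesca_clustering")
}

#' @export
print.chesca_clustering <- function(x, ...) {
  k <- x$assignment$cluster
  cat("CHESCA clustering: ", length(k), " methyls, cutoff ", x$cutoff,
      "; ", length(unique(k[!is.na(k)])), " cluster(s) of size >= ",
      x$min_size, ", ", sum(is.na(k)), " unclustered\n", sep = "")
  invisible(x)
}

#' Export the dendrogram merge tree
#'
#' Flattens the complete-linkage tree into a table suitable for plotting or
#' archiving: one row per merge with its two children and the merge height
#' (heights are non-decreasing for complete linkage). Children are leaf
#' methyl labels or `"node<k>"` references to earlier merges.
#'
#' @param clustering A `chesca_clustering` from [chesca_cluster()].
#' @return Data.frame with columns `step`, `child1`, `child2`, `height`;
#'   zero rows when the tree has a single leaf.
#' @export
dendrogram_export <- function(clustering) {
  stopifnot(inherits(clustering, "chesca_clustering"))
  tree <- clustering$tree
  if (is.null(tree))
    return(data.frame(step = integer(), child1 = character(),
                      child2 = character(), height = numeric()))
  child_name <- function(i) {
    if (i < 0) tree$labels[-i] else paste0("node", i)
  }
  data.frame(
    step = seq_len(nrow(tree$merge)),
    child1 = vapply(tree$merge[, 1], child_name, character(1)),
    child2 = vapply(tree$merge[, 2], child_name, character(1)),
    height = tree$height
  )
}
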