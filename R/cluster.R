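# Sample-level hierarchical clustering under the centroid-correlation
# distance 2*(1-cc) on cube-root transformed profiles.

.clampedCor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance profile: correlation treated as 0 (distance 2)")
    return(0)
  }
  max(0, cor(a, b))
}

#' Distance between a sample and a cluster
#'
#' Computes 2 * (1 - cc), where cc is the Pearson correlation between a
#' cube-root expression profile and the entrywise average of the
#' profiles already in the cluster, clamped below at zero so the
#' distance lies on the dendrogram scale [0, 2]. A zero-variance profile
#' yields cc = 0 (distance 2) with a warning.
#'
#' @param sampleProfile numeric vector (cube-root expression of one
#'   sample over the selected miRNAs).
#' @param clusterProfiles numeric matrix with one column per cluster
#'   member (same miRNAs as rows), or a single vector.
#' @return distance in [0, 2].
#' @examples
#' p <- c(1, 2, 3, 4)
#' sampleClusterDistance(p, cbind(p, p))   # identical: 0
#' @export
sampleClusterDistance <- function(sampleProfile, clusterProfiles) {
  cp <- as.matrix(clusterProfiles)
  if (ncol(cp) == 0L) stop("cluster must be nonempty")
  if (length(sampleProfile) != nrow(cp))
    stop("profiles must have the same length")
  if (length(sampleProfile) < 3L)
    stop("profiles must have length at least 3")
  2 * (1 - .clampedCor(sampleProfile, rowMeans(cp)))
}

#' Greedy centroid-correlation agglomeration of samples
#'
#' Builds a binary merge tree over samples: at each step the pair of
#' clusters with the smallest distance 2 * (1 - cc) between their
#' average cube-root profiles (cc clamped at 0) is merged, and distances
#' are recomputed against the new cluster average. Ties are broken by
#' the lexicographically smallest pair of leading member ids, making the
#' procedure deterministic. Because average-profile linkage can invert,
#' merge heights are made monotone by a running maximum.
#'
#' @param x numeric matrix of cube-root expression, miRNAs x samples,
#'   usually restricted to a discriminating miRNA subset (e.g. the
#'   q-value-zero set), or a [MirExperiment-class] (cube-rooted
#'   internally).
#' @param mirnas optional character vector restricting the rows used.
#' @return a [MirDendrogram-class].
#' @examples
#' sim <- simulateStudy(simConfig(nMirnas = 30L, seed = 2))
#' d <- agglomerativeCluster(sim$experiment)
#' d
#' @export
agglomerativeCluster <- function(x, mirnas = NULL) {
  if (is(x, "MirExperiment")) x <- cubeRoot(mirExprs(x))
  if (!is.null(mirnas)) {
    missing <- setdiff(mirnas, rownames(x))
    if (length(missing))
      stop("miRNA(s) not present: ", paste(missing, collapse = ", "))
    x <- x[mirnas, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("the miRNA subset must be nonempty")
  n <- ncol(x)
  if (n < 2L) stop("at least two samples are required")
  labels <- colnames(x)

  members <- as.list(seq_len(n))        # column indices per active cluster
  nodeId <- as.integer(-seq_len(n))     # hclust convention
  profiles <- lapply(seq_len(n), function(j) x[, j])
  keyOf <- function(mem) min(labels[mem])

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      d <- 2 * (1 - .clampedCor(profiles[[a]], profiles[[b]]))
      key <- sort(c(keyOf(members[[a]]), keyOf(members[[b]])))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(a = a, b = b, d = d, key = key)
      }
    }
    ab <- if (keyOf(members[[best$a]]) <= keyOf(members[[best$b]]))
      c(best$a, best$b) else c(best$b, best$a)
    merge[step, ] <- nodeId[ab]
    height[step] <- if (step == 1L) best$d else max(best$d, height[step - 1L])
    newMem <- c(members[[best$a]], members[[best$b]])
    keep <- setdiff(seq_len(k), c(best$a, best$b))
    members <- c(members[keep], list(newMem))
    profiles <- c(profiles[keep],
                  list(rowMeans(x[, newMem, drop = FALSE])))
    nodeId <- c(nodeId[keep], as.integer(step))
  }

  # leaf order by tree traversal
  ordOf <- function(node) {
    if (node < 0L) return(-node)
    c(ordOf(merge[node, 1L]), ordOf(merge[node, 2L]))
  }
  new("MirDendrogram", merge = merge, height = pmin(height, 2),
      labels = labels, order = as.integer(ordOf(n - 1L)))
}

#' Convert a MirDendrogram to an hclust object
#'
#' @param x a [MirDendrogram-class].
#' @return an object of class \code{hclust} (plottable with
#'   \code{plot()}).
#' @export
asHclust <- function(x) {
  stopifnot(is(x, "MirDendrogram"))
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "centroid-correlation",
                 call = match.call(), dist.method = "2*(1-cc)"),
            class = "hclust")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths follow the usual half-height convention for converting
#' a merge tree to an ultrametric phylogram.
#'
#' @param x a [MirDendrogram-class].
#' @param path output file path.
#' @return invisibly, the \code{ape} phylo object written.
#' @export
writeNewick <- function(x, path) {
  phy <- ape::as.phylo(asHclust(x))
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' Merge table of a dendrogram
#'
#' @param x a [MirDendrogram-class].
#' @return data.frame with columns \code{step}, \code{memberA},
#'   \code{memberB} (member sample ids joined by \code{"+"}) and
#'   \code{height}.
#' @export
mergeTable <- function(x) {
  stopifnot(is(x, "MirDendrogram"))
  desc <- function(node) {
    if (node < 0L) return(x@labels[-node])
    c(desc(x@merge[node, 1L]), desc(x@merge[node, 2L]))
  }
  n1 <- nrow(x@merge)
  data.frame(
    step = seq_len(n1),
    memberA = vapply(seq_len(n1), function(s)
      paste(sort(desc(x@merge[s, 1L])), collapse = "+"), character(1L)),
    memberB = vapply(seq_len(n1), function(s)
      paste(sort(desc(x@merge[s, 2L])), collapse = "+"), character(1L)),
    height = x@height, stringsAsFactors = FALSE)
}

#' Leaves of the clade containing a set of samples
#'
#' Utility for testing clade composition: returns the members of the
#' smallest clade (merge subtree) containing all requested samples.
#'
#' @param x a [MirDendrogram-class].
#' @param samples character vector of sample ids.
#' @return character vector of the clade's leaves.
#' @export
cladeMembers <- function(x, samples) {
  stopifnot(is(x, "MirDendrogram"))
  desc <- function(node) {
    if (node < 0L) return(x@labels[-node])
    c(desc(x@merge[node, 1L]), desc(x@merge[node, 2L]))
  }
  for (s in seq_len(nrow(x@merge))) {
    mem <- desc(s)
    if (all(samples %in% mem)) return(mem)
  }
  x@labels
}
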