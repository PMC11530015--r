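# Majority-class undersampling by cluster centroids.
#
# The majority category's feature vectors are replaced by k prototype points:
# the centroids of a mini-batch k-means clustering. Mini-batch k-means trades
# a marginal amount of distortion for speed and memory: per iteration a random
# batch is assigned to the nearest centroids and each touched centroid moves
# to the mean of its batch members.

# Squared Euclidean distances between rows of x (n x d) and rows of c (k x d).
.sqdist <- function(x, centers) {
  xn <- rowSums(x^2)
  cn <- rowSums(centers^2)
  d2 <- outer(xn, cn, `+`) - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

#' Mini-batch k-means clustering
#'
#' Initial centers are k distinct data points drawn at random. Each iteration
#' samples a mini-batch of `batch_size` points, assigns each to its nearest
#' center (Euclidean distance), then replaces every center that received
#' points by the mean of its batch members. Centers receiving no batch points
#' in an iteration are re-seeded to a random data point. After the final
#' iteration all points are assigned to their nearest center.
#'
#' @param points n x d numeric matrix.
#' @param k Number of clusters, 1..n. `k == n` degenerates to every point
#'   being its own centroid.
#' @param batch_size Mini-batch size b (capped at n).
#' @param max_iter Iteration count T.
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @return Object of class `minibatch_kmeans`: list with `centroids` (k x d),
#'   `assignments` (length n), `iterations_run` and `distortion` (total
#'   within-cluster sum of squares of the final full assignment).
#' @export
minibatch_kmeans <- function(points, k, batch_size = 1024L, max_iter = 100L,
                             seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k >= 1L, batch_size >= 1L, max_iter >= 1L)
  if (k > n) stop("k = ", k, " exceeds the number of points (", n, ")")
  rng <- .local_rng(seed)
  on.exit(rng())
  if (k == n) {
    return(structure(list(centroids = points, assignments = seq_len(n),
                          iterations_run = 0L, distortion = 0),
                     class = "minibatch_kmeans"))
  }
  b <- min(as.integer(batch_size), n)
  centers <- points[sample.int(n, k), , drop = FALSE]
  for (t in seq_len(max_iter)) {
    batch <- points[sample.int(n, b), , drop = FALSE]
    nearest <- max.col(-.sqdist(batch, centers), ties.method = "first")
    touched <- unique(nearest)
    for (j in touched) {
      centers[j, ] <- colMeans(batch[nearest == j, , drop = FALSE])
    }
    empty <- setdiff(seq_len(k), touched)
    if (length(empty) > 0L) {
      centers[empty, ] <- points[sample.int(n, length(empty)), , drop = FALSE]
    }
  }
  assignments <- max.col(-.sqdist(points, centers), ties.method = "first")
  distortion <- sum((points - centers[assignments, , drop = FALSE])^2)
  structure(list(centroids = centers, assignments = assignments,
                 iterations_run = as.integer(max_iter),
                 distortion = distortion),
            class = "minibatch_kmeans")
}

#' Assemble a sample set
#'
#' @param features n x 46 feature matrix.
#' @param labels n x 4 binary label matrix (columns A, C, M, S).
#' @param categories Integer vector of n category ids.
#' @return Object of class `sample_set`.
#' @export
sample_set <- function(features, labels, categories) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  stopifnot(nrow(features) == nrow(labels),
            nrow(features) == length(categories),
            ncol(labels) == 4L)
  structure(list(features = features, labels = labels,
                 categories = as.integer(categories)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:", nrow(x$features), "samples x", ncol(x$features),
      "features\n")
  print(table(factor(x$categories, levels = 1:11,
                     labels = category_names())))
  invisible(x)
}

#' Undersample the majority category with cluster centroids
#'
#' The majority category's N feature vectors are replaced by
#' `k = max(1, round(ratio * N))` mini-batch k-means centroids, each labeled
#' with the majority category's label vector; all other categories pass
#' through untouched. `ratio` is the post-sampling count of the majority
#' class divided by its original count; `ratio = 1` is the identity.
#'
#' @param data `sample_set`.
#' @param majority_category Category id to undersample (default 1, the
#'   acetyl-only class, which dominates real training sets).
#' @param ratio Undersampling ratio in (0, 1].
#' @param batch_size,max_iter Mini-batch k-means parameters.
#' @param seed Integer RNG seed.
#' @return A new `sample_set`: non-majority samples in their original order,
#'   followed by the centroid prototypes. Attribute `sampler_log` records k,
#'   iterations and distortion.
#' @export
cluster_centroids_undersample <- function(data, majority_category = 1L,
                                          ratio = 0.1, batch_size = 1024L,
                                          max_iter = 100L, seed = 1L) {
  stopifnot(inherits(data, "sample_set"))
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1], got ", ratio)
  is_maj <- data$categories == majority_category
  if (!any(is_maj)) {
    stop("majority category ", majority_category, " not present")
  }
  if (ratio == 1) return(data)
  maj_feat <- data$features[is_maj, , drop = FALSE]
  N <- nrow(maj_feat)
  k <- max(1L, .round_half_up(ratio * N))
  km <- minibatch_kmeans(maj_feat, k, batch_size = batch_size,
                         max_iter = max_iter, seed = seed)
  maj_label <- onehot_label(majority_category)
  out <- sample_set(
    rbind(data$features[!is_maj, , drop = FALSE], km$centroids),
    rbind(data$labels[!is_maj, , drop = FALSE],
          matrix(maj_label, nrow = k, ncol = 4L, byrow = TRUE,
                 dimnames = list(NULL, MOD_LETTERS))),
    c(data$categories[!is_maj], rep(majority_category, k))
  )
  attr(out, "sampler_log") <- list(majority_category = majority_category,
                                   original_n = N, k = k,
                                   iterations = km$iterations_run,
                                   distortion = km$distortion)
  out
}
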