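#' Describe one entangled Gaussian-mixture classification task
#'
#' A task is a two-class mixture of `2K` isotropic Gaussian clusters whose
#' centers sit in a bounded region of a two-dimensional "relevant" subspace.
#' Each center is randomly assigned a class in \{-1, +1\}, and a sample's
#' label is the class of its *nearest* center, not of the cluster that
#' generated it -- with overlapping clusters this entangles the two classes,
#' and the entanglement grows with `K`.  Additional task-irrelevant input
#' dimensions, uniform over the same range as the relevant values, can be
#' appended after sampling.
#'
#' The cluster spread defaults to `0.5 * width / sqrt(2K)` where `width` is
#' the extent of the center region, i.e. roughly half the typical spacing
#' between neighbouring cluster centers, so that adjacent clusters overlap
#' moderately at every `K`.  The declared `relevant_range` is the extent
#' widened by `range_margin` cluster standard deviations on each side; it
#' bounds essentially all generated relevant values and is the range the
#' uniform irrelevant dimensions span.
#'
#' @param K Clusters per class (total `2K` clusters); must be >= 1.
#' @param n_irrelevant Number of task-irrelevant dimensions that will be
#'   appended to sampled datasets (stored on the spec for bookkeeping).
#' @param seed Integer seed controlling center positions and class
#'   assignment.
#' @param extent Numeric length-2 interval: the square region the cluster
#'   centers are drawn from, per relevant dimension.
#' @param cluster_sigma Isotropic within-cluster standard deviation shared
#'   by all clusters; `NULL` (default) uses the spacing-based formula above.
#' @param label_noise_rate Probability in `[0, 1)` that a label is flipped;
#'   applied by [corrupt_labels()], stored here as task metadata.
#' @param range_margin Half-width of the declared relevant range beyond the
#'   center extent, in units of `cluster_sigma`.
#' @return An object of class `mixture_task_spec`: a list with fields `K`,
#'   `center_positions` (`2K x 2` matrix), `center_classes` (`2K` values in
#'   \{-1, +1\}, both classes present), `cluster_sigma`, `label_noise_rate`,
#'   `n_irrelevant`, `relevant_range` (`2 x 2` matrix, rows `lo`/`hi`,
#'   columns the relevant dimensions), `extent` and `seed`.
#' @seealso [sample_dataset()], [append_irrelevant_dims()]
#' @examples
#' spec <- build_task_spec(K = 2, n_irrelevant = 0, seed = 1)
#' nrow(spec$center_positions) # 4 centers
#' table(spec$center_classes)  # both classes present
#' @export
build_task_spec <- function(K, n_irrelevant = 0L, seed,
                            extent = c(0, 3), cluster_sigma = NULL,
                            label_noise_rate = 0.05, range_margin = 2) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1 || K != floor(K))
    kr_stop("invalid_spec", "`K` must be a positive integer (clusters per class)")
  if (n_irrelevant < 0 || n_irrelevant != floor(n_irrelevant))
    kr_stop("invalid_spec", "`n_irrelevant` must be a non-negative integer")
  if (label_noise_rate < 0 || label_noise_rate >= 1)
    kr_stop("invalid_spec", "`label_noise_rate` must lie in [0, 1)")
  if (length(extent) != 2L || extent[2] <= extent[1])
    kr_stop("invalid_spec", "`extent` must be an increasing length-2 interval")
  K <- as.integer(K)
  width <- extent[2] - extent[1]
  if (is.null(cluster_sigma)) cluster_sigma <- 0.5 * width / sqrt(2 * K)
  if (cluster_sigma <= 0)
    kr_stop("invalid_spec", "`cluster_sigma` must be positive")

  set.seed(seed)
  centers <- matrix(runif(4L * K, extent[1], extent[2]), ncol = 2L,
                    dimnames = list(NULL, c("x1", "x2")))
  classes <- sample(c(-1, 1), 2L * K, replace = TRUE)
  while (length(unique(classes)) < 2L)
    classes <- sample(c(-1, 1), 2L * K, replace = TRUE)

  rr <- rbind(lo = rep(extent[1] - range_margin * cluster_sigma, 2L),
              hi = rep(extent[2] + range_margin * cluster_sigma, 2L))
  colnames(rr) <- c("x1", "x2")

  structure(list(K = K,
                 center_positions = centers,
                 center_classes = classes,
                 cluster_sigma = cluster_sigma,
                 label_noise_rate = label_noise_rate,
                 n_irrelevant = as.integer(n_irrelevant),
                 relevant_range = rr,
                 extent = as.numeric(extent),
                 seed = as.integer(seed)),
            class = "mixture_task_spec")
}

#' @export
print.mixture_task_spec <- function(x, ...) {
  cat("Mixture task spec:", 2L * x$K, "clusters (K =", x$K, "per class),",
      "sigma =", signif(x$cluster_sigma, 4), "\n")
  cat("  label noise", x$label_noise_rate, "|", x$n_irrelevant,
      "irrelevant dim(s) | seed", x$seed, "\n")
  invisible(x)
}

#' Construct a labeled dataset container
#'
#' Thin validated container used throughout the package: a numeric feature
#' matrix with one row per sample, labels in \{-1, +1\}, the index set of
#' task-relevant columns, a split role, and (optionally) the declared range
#' of the relevant dimensions used by lattice-based center selection and by
#' [append_irrelevant_dims()].
#'
#' @param features Numeric matrix `n x p`.
#' @param labels Numeric vector of `n` values in \{-1, +1\}.
#' @param relevant_dims Integer indices of the task-relevant columns.
#' @param role One of `"full"`, `"train"`, `"test"`.
#' @param relevant_range Optional `2 x length(relevant_dims)` matrix with
#'   rows `lo`/`hi`.
#' @param cluster_id Optional integer vector recording which mixture cluster
#'   generated each sample (diagnostic metadata, never used by models).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels,
                            relevant_dims = seq_len(min(2L, ncol(features))),
                            role = c("full", "train", "test"),
                            relevant_range = NULL, cluster_id = NULL) {
  role <- match.arg(role)
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    kr_stop("invalid_spec", "feature rows and labels must have equal length")
  if (!all(labels %in% c(-1, 1)))
    kr_stop("invalid_spec", "labels must take values in {-1, +1}")
  if (length(relevant_dims) == 0L || any(relevant_dims < 1) ||
      any(relevant_dims > ncol(features)))
    kr_stop("invalid_spec", "`relevant_dims` must index feature columns")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  structure(list(features = features,
                 labels = as.numeric(labels),
                 relevant_dims = as.integer(relevant_dims),
                 role = role,
                 relevant_range = relevant_range,
                 cluster_id = cluster_id),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset (", x$role, "): ", nrow(x$features), " x ",
      ncol(x$features), " features, ", sum(x$labels > 0), " positive / ",
      sum(x$labels < 0), " negative labels\n", sep = "")
  invisible(x)
}

#' Label points by the class of the nearest cluster center
#'
#' The generative label rule: a point's class is the class of the Euclidean
#' nearest center in the relevant subspace, regardless of which cluster
#' generated it.  Deterministic, so relabeling an already-labeled dataset
#' with the same spec is a no-op.  Distance ties go to the lowest center
#' index.
#'
#' @param features Numeric matrix whose columns `relevant_dims` are compared
#'   against the spec's center positions.
#' @param spec A [build_task_spec()] object.
#' @param relevant_dims Columns of `features` holding the relevant subspace.
#' @return Numeric vector of labels in \{-1, +1\}.
#' @export
nearest_center_labels <- function(features, spec, relevant_dims = 1:2) {
  X <- as.matrix(features)[, relevant_dims, drop = FALSE]
  C <- spec$center_positions
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  spec$center_classes[max.col(-d2, ties.method = "first")]
}

#' Sample points from a mixture task
#'
#' Each point picks one of the `2K` clusters uniformly at random and adds
#' isotropic Gaussian noise with sd `cluster_sigma` to that cluster's
#' center; its label is then the class of the *nearest* center (see
#' [nearest_center_labels()]).  Labels are noise free at this stage; apply
#' [corrupt_labels()] afterwards.  Bit-identical output for equal seeds.
#'
#' @param spec A [build_task_spec()] object.
#' @param n Number of points to draw (>= 1).
#' @param seed Integer seed for cluster choice and Gaussian noise.
#' @return A [labeled_dataset()] with `p = 2` relevant features, role
#'   `"full"`, carrying the spec's `relevant_range` and the generating
#'   cluster ids as metadata.
#' @export
sample_dataset <- function(spec, n, seed) {
  stopifnot(inherits(spec, "mixture_task_spec"))
  if (n < 1) kr_stop("invalid_parameter", "`n` must be >= 1")
  set.seed(seed)
  ids <- sample.int(2L * spec$K, n, replace = TRUE)
  X <- spec$center_positions[ids, , drop = FALSE] +
    matrix(rnorm(2L * n, sd = spec$cluster_sigma), ncol = 2L)
  colnames(X) <- c("x1", "x2")
  labeled_dataset(X, nearest_center_labels(X, spec),
                  relevant_dims = 1:2, role = "full",
                  relevant_range = spec$relevant_range, cluster_id = ids)
}

#' Flip labels independently with a fixed probability
#'
#' @param labels Numeric vector of values in \{-1, +1\}.
#' @param rate Flip probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Label vector of the same length.
#' @examples
#' corrupt_labels(c(1, 1, -1), rate = 0, seed = 1) # identity at rate 0
#' @export
corrupt_labels <- function(labels, rate, seed) {
  if (rate < 0 || rate >= 1)
    kr_stop("invalid_parameter", "`rate` must lie in [0, 1)")
  if (rate == 0) return(labels)
  set.seed(seed)
  flip <- runif(length(labels)) < rate
  labels[flip] <- -labels[flip]
  labels
}

#' Append task-irrelevant input dimensions
#'
#' Adds `n_irrelevant` columns drawn i.i.d. uniform over the dataset's
#' declared relevant range (the distributional reading of "spanning the same
#' range as the relevant values": a fixed range keeps train and test
#' exchangeable, unlike a per-sample empirical min/max).  Labels and
#' `relevant_dims` are unchanged.  Falls back to the empirical range of the
#' relevant columns when no declared range is attached.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_irrelevant Number of columns to append (>= 0).
#' @param seed Integer seed.
#' @return The augmented [labeled_dataset()].
#' @export
append_irrelevant_dims <- function(dataset, n_irrelevant, seed) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (n_irrelevant < 0 || n_irrelevant != floor(n_irrelevant))
    kr_stop("invalid_parameter", "`n_irrelevant` must be a non-negative integer")
  if (n_irrelevant == 0L) return(dataset)
  rr <- dataset$relevant_range
  if (is.null(rr)) {
    rel <- dataset$features[, dataset$relevant_dims, drop = FALSE]
    rr <- rbind(lo = apply(rel, 2, min), hi = apply(rel, 2, max))
  }
  lo <- min(rr[1, ]); hi <- max(rr[2, ])
  n <- nrow(dataset$features)
  set.seed(seed)
  extra <- matrix(runif(n * n_irrelevant, lo, hi), nrow = n)
  feats <- cbind(dataset$features, extra)
  colnames(feats) <- paste0("x", seq_len(ncol(feats)))
  dataset$features <- feats
  dataset
}

#' Randomly partition a dataset into training and test sets
#'
#' Draws a disjoint random partition covering every row; `round(n *
#' train_fraction)` rows go to training.  Identical seeds give identical
#' partitions.
#'
#' @param dataset A [labeled_dataset()].
#' @param train_fraction Proportion in `(0, 1)` assigned to training.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both [labeled_dataset()]
#'   objects with roles set.
#' @export
split_train_test <- function(dataset, train_fraction = 0.7, seed) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    kr_stop("invalid_parameter", "`train_fraction` must lie in (0, 1)")
  n <- nrow(dataset$features)
  set.seed(seed)
  tr <- sort(sample.int(n, round(n * train_fraction)))
  take <- function(idx, role) {
    labeled_dataset(dataset$features[idx, , drop = FALSE],
                    dataset$labels[idx],
                    relevant_dims = dataset$relevant_dims, role = role,
                    relevant_range = dataset$relevant_range,
                    cluster_id = dataset$cluster_id[idx])
  }
  list(train = take(tr, "train"), test = take(setdiff(seq_len(n), tr), "test"))
}
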