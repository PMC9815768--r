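#' Gaussian kernel evaluation
#'
#' The similarity a single granule-cell-like unit assigns to an input:
#' \deqn{\kappa(x, c) = \frac{1}{\sqrt{2\pi}\,\sigma}
#'   \exp\!\left(-\frac{\lVert x - c\rVert^2}{2\sigma^2}\right)}
#' where the squared term is the squared Euclidean distance between the
#' input and the stored center, giving an isotropic bump with the
#' one-dimensional normaliser (the normaliser is a constant absorbed by the
#' linear readout, so classification results do not depend on it).  The
#' peak value, attained at `x == center`, is `1 / (sqrt(2 * pi) * width)`.
#'
#' @param x Numeric input vector.
#' @param center Numeric stored pattern of the same length.
#' @param width Kernel width `sigma > 0`; the model fixes it to 1.
#' @return Kernel value in `(0, 1 / (sqrt(2 * pi) * width)]`.
#' @examples
#' gaussian_kernel(c(0, 0), c(0, 0), 1) # 1 / sqrt(2 * pi)
#' @export
gaussian_kernel <- function(x, center, width = 1) {
  if (length(x) != length(center))
    kr_stop("shape", "`x` and `center` must have equal dimension")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    kr_stop("invalid_parameter", "`width` must be a positive scalar")
  exp(-sum((x - center)^2) / (2 * width^2)) / (sqrt(2 * pi) * width)
}

#' Construct a Gaussian kernel expansion layer
#'
#' A bank of `m` Gaussian kernels, each centered on a stored training
#' sample.  Every center-selection regime produces such a layer; the rows of
#' `centers` are always exact copies of training rows.
#'
#' @param centers Numeric `m x p` matrix of stored samples (one kernel per
#'   row).
#' @param widths Positive kernel widths, recycled to length `m`; the model
#'   fixes all widths to 1.
#' @param provenance Optional list recording which regime and seed selected
#'   the centers (kept for serialization, see [write_kernel_layer()]).
#' @return An object of class `kernel_layer`.
#' @export
kernel_layer <- function(centers, widths = 1, provenance = NULL) {
  centers <- as.matrix(centers)
  widths <- rep_len(as.numeric(widths), nrow(centers))
  if (any(widths <= 0))
    kr_stop("invalid_parameter", "all kernel widths must be positive")
  structure(list(centers = centers, widths = widths, provenance = provenance),
            class = "kernel_layer")
}

#' @export
print.kernel_layer <- function(x, ...) {
  cat("Gaussian kernel layer:", nrow(x$centers), "centers in",
      ncol(x$centers), "dimensions\n")
  invisible(x)
}

#' Construct a random projection expansion layer
#'
#' The "lazy" control: a fixed `p x m` projection with weights and hidden
#' biases drawn i.i.d. from a zero-mean Gaussian with standard deviation 3,
#' followed by an elementwise activation.  With `activation = "identity"`
#' the layer is affine, the linear control; `"relu"` (default) and
#' `"tanh"` give the nonlinear variants.  Bias diversity matters: without
#' it every ReLU unit would hinge on the same hyperplane through the
#' origin.
#'
#' @param p Input dimension (>= 1).
#' @param m Hidden dimension (>= 1).
#' @param seed Integer seed; equal seeds give identical layers.
#' @param activation One of `"relu"`, `"tanh"`, `"identity"`.
#' @param weight_sd,bias_sd Standard deviations of the weight and bias
#'   distributions (default 3, the model's value, for both).
#' @return An object of class `random_projection_layer` with fields
#'   `weights` (`p x m`), `hidden_bias` (length `m`) and `activation`.
#' @export
sample_projection_layer <- function(p, m, seed,
                                    activation = c("relu", "tanh", "identity"),
                                    weight_sd = 3, bias_sd = 3) {
  activation <- match.arg(activation)
  if (p < 1 || m < 1)
    kr_stop("invalid_parameter", "`p` and `m` must be >= 1")
  set.seed(seed)
  structure(list(weights = matrix(rnorm(p * m, sd = weight_sd), p, m),
                 hidden_bias = rnorm(m, sd = bias_sd),
                 activation = activation),
            class = "random_projection_layer")
}

#' @export
print.random_projection_layer <- function(x, ...) {
  cat("Random projection layer:", nrow(x$weights), "->", ncol(x$weights),
      "units,", x$activation, "activation\n")
  invisible(x)
}

apply_activation <- function(A, name) {
  switch(name,
         relu = pmax(A, 0),
         tanh = tanh(A),
         identity = A,
         kr_stop("invalid_parameter", paste("unknown activation:", name)))
}

#' Evaluate a kernel layer on a matrix of inputs
#'
#' Entry `(i, j)` is [gaussian_kernel()] of input row `i` against center row
#' `j`; all entries are strictly positive and bounded by the per-kernel
#' peak `1 / (sqrt(2 * pi) * width_j)`.
#'
#' @param X Numeric `n x p` input matrix.
#' @param layer A [kernel_layer()] with `p`-dimensional centers.
#' @return Numeric `n x m` feature matrix.
#' @export
kernel_features <- function(X, layer) {
  stopifnot(inherits(layer, "kernel_layer"))
  X <- as.matrix(X)
  C <- layer$centers
  if (ncol(X) != ncol(C))
    kr_stop("shape", "input and center dimensions differ")
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0 # numerical negatives from the expansion identity
  w <- layer$widths
  K <- exp(sweep(d2, 2L, 2 * w^2, "/") * -1)
  sweep(K, 2L, sqrt(2 * pi) * w, "/")
}

#' Evaluate a random projection layer on a matrix of inputs
#'
#' Entry `(i, j)` is `activation(<x_i, w_j> + b_j)`.  With identity
#' activation the map is affine, so the composed classifier's decision
#' boundary is a hyperplane in input space.
#'
#' @param X Numeric `n x p` input matrix.
#' @param layer A [sample_projection_layer()] object.
#' @return Numeric `n x m` feature matrix.
#' @export
random_projection_features <- function(X, layer) {
  stopifnot(inherits(layer, "random_projection_layer"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(layer$weights))
    kr_stop("shape", "input dimension does not match projection weights")
  A <- sweep(X %*% layer$weights, 2L, layer$hidden_bias, "+")
  apply_activation(A, layer$activation)
}

#' Map inputs to the hidden representation of any expansion layer
#'
#' Generic dispatcher used by the prediction pipeline so that kernel and
#' random-projection layers are interchangeable behind the readout.
#'
#' @param X Numeric `n x p` input matrix.
#' @param layer A [kernel_layer()] or [sample_projection_layer()] object.
#' @return Numeric `n x m` feature matrix.
#' @export
expansion_features <- function(X, layer) UseMethod("expansion_features", layer)

#' @export
expansion_features.kernel_layer <- function(X, layer) kernel_features(X, layer)

#' @export
expansion_features.random_projection_layer <- function(X, layer)
  random_projection_features(X, layer)
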