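#' Fit the linear readout in closed form
#'
#' The Purkinje-like readout is the least-squares solution over hidden
#' features.  Columns of `H` are mean-centered with the training means
#' `mu`, and the weights solve the (ridge-stabilised) normal equations
#' \deqn{\alpha = (H_c^\top H_c + \lambda I)^{-1} H_c^\top y,}
#' computed via a Cholesky factorisation rather than explicit inversion.
#' The intercept is the centered-regression one, `bias = mean(y)`, so that
#' predictions are `(h(x) - mu) . alpha + mean(y)`.  A small default ridge
#' keeps the system well posed when overlapping Gaussian kernels make
#' `H^T H` rank deficient; with `ridge = 0` a singular system raises a
#' classed `kernelregimes_rank_deficiency` error instead of returning a
#' spurious solution.
#'
#' @param H Numeric `n x m` hidden feature matrix (training rows).
#' @param y Numeric label vector of length `n` (values in \{-1, +1\} in
#'   this package, though any numeric target is accepted).
#' @param ridge Non-negative regularisation strength added to the diagonal
#'   of the normal equations.
#' @return An object of class `readout_solution`: list with `alpha`
#'   (length `m`), `bias`, `feature_means` (length `m`), `ridge`.
#' @examples
#' H <- matrix(c(1, -1), ncol = 1)
#' solve_readout(H, c(1, -1), ridge = 0) # alpha = 1, bias = 0
#' @export
solve_readout <- function(H, y, ridge = 1e-8) {
  H <- as.matrix(H)
  y <- as.numeric(y)
  if (nrow(H) != length(y))
    kr_stop("shape", "rows of `H` must correspond to entries of `y`")
  if (ridge < 0)
    kr_stop("invalid_parameter", "`ridge` must be non-negative")
  m <- ncol(H)
  mu <- colMeans(H)
  Hc <- sweep(H, 2L, mu, "-")
  A <- crossprod(Hc)
  if (ridge > 0) diag(A) <- diag(A) + ridge
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    if (ridge == 0)
      kr_stop("rank_deficiency",
              "H^T H is singular with ridge = 0; supply ridge > 0")
    kr_stop("numerical",
            "normal equations not positive definite even with the supplied ridge")
  }
  alpha <- backsolve(R, backsolve(R, crossprod(Hc, y), transpose = TRUE))
  structure(list(alpha = as.numeric(alpha),
                 bias = mean(y),
                 feature_means = as.numeric(mu),
                 ridge = ridge),
            class = "readout_solution")
}

#' @export
print.readout_solution <- function(x, ...) {
  cat("Readout solution:", length(x$alpha), "weights, bias",
      signif(x$bias, 4), ", ridge", format(x$ridge), "\n")
  invisible(x)
}

# Scores from an already-computed feature matrix; shared by predict_readout
# and the batched experiment evaluators.
readout_scores <- function(H, solution) {
  if (ncol(H) != length(solution$alpha))
    kr_stop("shape", "feature dimension does not match readout weights")
  drop(H %*% solution$alpha) -
    sum(solution$feature_means * solution$alpha) + solution$bias
}

#' Predict scores and class labels for new inputs
#'
#' Runs inputs through the expansion layer the readout was fit on, centers
#' the features with the stored training means, and applies the readout.
#' The decision rule is `sign(score)` with the tie `score == 0` mapped to
#' `+1` (relevant only in degenerate cases such as an all-zero readout).
#'
#' @param X Numeric `n x p` input matrix.
#' @param layer The expansion layer (kernel or random projection) whose
#'   features the readout was trained on.
#' @param solution A [solve_readout()] result fit on `layer`'s features.
#' @return List with numeric `scores` and `labels` in \{-1, +1\}.
#' @export
predict_readout <- function(X, layer, solution) {
  stopifnot(inherits(solution, "readout_solution"))
  scores <- readout_scores(expansion_features(X, layer), solution)
  list(scores = scores, labels = ifelse(scores >= 0, 1, -1))
}

#' Proportion of matching labels
#'
#' @param predicted,actual Label vectors of equal length.
#' @return Fraction of positions where the labels agree, in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    kr_stop("shape", "label vectors must have equal length")
  mean(predicted == actual)
}
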