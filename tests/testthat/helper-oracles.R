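# Independent iterative least-squares minimizer used as the oracle against
# the closed-form readout: BFGS with the analytic gradient of
# 0.5 * ||Hc a - y||^2 + 0.5 * ridge * ||a||^2 (the 0.5 factors do not move
# the minimiser).  Deliberately shares no code with solve_readout().
iterative_readout_alpha <- function(H, y, ridge = 0) {
  Hc <- sweep(H, 2L, colMeans(H), "-")
  obj <- function(a) 0.5 * sum((Hc %*% a - y)^2) + 0.5 * ridge * sum(a^2)
  grad <- function(a) drop(crossprod(Hc, Hc %*% a - y)) + ridge * a
  fit <- stats::optim(rep(0, ncol(H)), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  fit$par
}

# Two well-separated Gaussian blobs with opposite labels; the workhorse
# constructed instance for regime geometry tests.
make_blobs <- function(n_per = c(50, 50), centers = rbind(c(0, 0), c(4, 0)),
                       sigma = 0.2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(n_per), function(i)
    sweep(matrix(rnorm(2 * n_per[i], sd = sigma), ncol = 2), 2,
          centers[i, ], "+")))
  labeled_dataset(X, rep(rep_len(c(-1, 1), length(n_per)), times = n_per),
                  role = "train")
}

# Standard small task used across regime contract tests.
make_task <- function(n = 2000, K = 5, n_irrelevant = 2, seed = 7) {
  make_condition_dataset(condition(K = K, m = 1, n_irrelevant = n_irrelevant,
                                   n_samples = n), seed)
}
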