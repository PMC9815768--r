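#' Specify a center-selection regime
#'
#' Bundles the name of a selection strategy with its budget and
#' hyperparameters.  `m` is the kernel budget (hidden-layer size), the
#' experiment's stand-in for how many granule cells a task may recruit.
#' `v` is the frequency regime's lattice resolution (bins per dimension),
#' `delta` the novelty regime's admission threshold, `n_subsets` the number
#' of random coordinate subsets the regular regime averages over.
#'
#' @param name One of `"random"`, `"regular"`, `"frequency"`, `"kmeans"`,
#'   `"support_vector"`, `"novelty"`.
#' @param m Kernel budget (>= 1).
#' @param v Frequency-regime bins per dimension (>= 1).
#' @param delta Novelty-regime admission threshold (> 0).
#' @param n_subsets Regular-regime subset count (>= 1); 1,000 at full
#'   scale, smaller values are cheaper.
#' @param seed Integer seed controlling all randomness inside selection.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(name = c("random", "regular", "frequency", "kmeans",
                                 "support_vector", "novelty"),
                        m, v = 16L, delta = 0.25, n_subsets = 1000L,
                        seed = 1L) {
  name <- match.arg(name)
  if (m < 1 || m != floor(m)) kr_stop("invalid_spec", "`m` must be a positive integer")
  if (v < 1 || v != floor(v)) kr_stop("invalid_spec", "`v` must be a positive integer")
  if (delta <= 0) kr_stop("invalid_spec", "`delta` must be positive")
  if (n_subsets < 1) kr_stop("invalid_spec", "`n_subsets` must be >= 1")
  structure(list(name = name, m = as.integer(m), v = as.integer(v),
                 delta = delta, n_subsets = as.integer(n_subsets),
                 seed = as.integer(seed)),
            class = "regime_spec")
}

center_selection <- function(indices, regime, diagnostics = list()) {
  structure(list(center_indices = indices, regime = regime,
                 diagnostics = diagnostics),
            class = "center_selection")
}

#' @export
print.center_selection <- function(x, ...) {
  k <- if (is.list(x$center_indices)) {
    paste(length(x$center_indices), "sets of",
          length(x$center_indices[[1]]), "centers")
  } else paste(length(x$center_indices), "centers")
  cat("Center selection (", x$regime$name, "): ", k, "\n", sep = "")
  invisible(x)
}

#' Select kernel centers under a named regime
#'
#' Dispatches to the regime named in `spec`.  Every regime returns row
#' indices into the training set, so selected centers are always
#' bit-identical copies of training samples.  The random, regular,
#' frequency and k-means regimes ignore the labels entirely
#' (task-independent); the support-vector and novelty regimes use them
#' (task-dependent).  Distances are always Euclidean over *all* input
#' dimensions -- the regimes receive no oracle knowledge of which
#' dimensions are task relevant.
#'
#' @param train A [labeled_dataset()] with role `"train"`.
#' @param spec A [regime_spec()].
#' @param ... Passed to the regime-specific function (e.g. `ridge` and
#'   `rule` for [select_novelty()], `max_n` for
#'   [select_support_vector()]).
#' @return A `center_selection` object: `center_indices` (an integer vector
#'   of `m` distinct training-row indices, or for the regular regime a list
#'   of `n_subsets` such vectors), the `regime` spec used, and a
#'   regime-specific `diagnostics` list.
#' @export
select_centers <- function(train, spec, ...) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(spec, "regime_spec"))
  switch(spec$name,
         random = select_random(train, spec),
         regular = select_regular(train, spec),
         frequency = select_frequency(train, spec),
         kmeans = select_kmeans(train, spec),
         support_vector = select_support_vector(train, spec, ...),
         novelty = select_novelty(train, spec, ...))
}

# ---------------------------------------------------------------------------
# shared helpers

# Per-dimension lattice bounds: the declared relevant range extended to all
# dimensions (irrelevant dimensions are drawn from the same range), falling
# back to the empirical per-column range when no range is declared.
lattice_ranges <- function(dataset) {
  p <- ncol(dataset$features)
  rr <- dataset$relevant_range
  if (is.null(rr)) {
    lims <- apply(dataset$features, 2, range)
    return(rbind(lo = lims[1, ], hi = lims[2, ]))
  }
  lo <- rep(min(rr[1, ]), p)
  hi <- rep(max(rr[2, ]), p)
  lo[dataset$relevant_dims] <- rr[1, ]
  hi[dataset$relevant_dims] <- rr[2, ]
  rbind(lo = lo, hi = hi)
}

rowdist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Snap each query row to the nearest training row, keeping chosen indices
# distinct (each later query takes its nearest not-yet-used sample).
snap_distinct <- function(queries, X) {
  d2 <- rowdist2(queries, X)
  used <- logical(nrow(X))
  out <- integer(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    ord <- order(d2[i, ])
    j <- ord[!used[ord]][1L]
    used[j] <- TRUE
    out[i] <- j
  }
  out
}

# ---------------------------------------------------------------------------

#' Random regime: uniform sampling without replacement
#'
#' @param train A [labeled_dataset()].
#' @param spec A [regime_spec()] with `name = "random"` (only `m` and
#'   `seed` are used).
#' @return A `center_selection`; see [select_centers()].
#' @export
select_random <- function(train, spec) {
  n <- nrow(train$features)
  if (spec$m > n) kr_stop("insufficient_data", "`m` exceeds the training size")
  set.seed(derive_seed(spec$seed, "random_regime"))
  center_selection(sort(sample.int(n, spec$m)), spec)
}

#' Regular regime: even coverage of the input lattice
#'
#' Bins every input dimension linearly into `ceiling(m^(1/p))` bins over
#' the lattice bounds, forms the Cartesian product of the bin midpoints
#' ("regular coordinates"), draws `n_subsets` random `m`-subsets of those
#' coordinates, and replaces each coordinate by its nearest training sample
#' (next nearest when a sample is already used within the subset, so each
#' subset holds `m` distinct rows).  Downstream evaluation averages
#' accuracy over the subsets.  The bins-per-dimension reading of the bin
#' formula is the only one that guarantees at least `m` coordinates
#' (`ceiling(m^(1/p))^p >= m`).
#'
#' @inheritParams select_random
#' @return A `center_selection` whose `center_indices` is a list of
#'   `n_subsets` index vectors.
#' @export
select_regular <- function(train, spec) {
  X <- train$features
  n <- nrow(X); p <- ncol(X); m <- spec$m
  if (m > n) kr_stop("insufficient_data", "`m` exceeds the training size")
  bins <- ceiling(m^(1 / p))
  if (bins^p > 2e5)
    kr_stop("invalid_parameter", "regular-coordinate pool would be too large")
  rng <- lattice_ranges(train)
  mids <- lapply(seq_len(p), function(j) {
    w <- (rng["hi", j] - rng["lo", j]) / bins
    rng["lo", j] + (seq_len(bins) - 0.5) * w
  })
  coords <- as.matrix(expand.grid(mids, KEEP.OUT.ATTRS = FALSE))
  P <- nrow(coords)

  # Nearest-sample candidates per coordinate, deep enough to resolve
  # within-subset collisions (fallback below covers exhaustion).
  d2 <- rowdist2(coords, X)
  depth <- min(n, m + 64L)
  cand <- t(apply(d2, 1L, function(r) order(r)[seq_len(depth)]))

  set.seed(derive_seed(spec$seed, "regular_regime"))
  sets <- vector("list", spec$n_subsets)
  for (s in seq_len(spec$n_subsets)) {
    pick <- if (P == m) seq_len(P) else sample.int(P, m)
    used <- integer(0)
    idx <- integer(m)
    for (i in seq_len(m)) {
      row <- cand[pick[i], ]
      j <- row[!(row %in% used)][1L]
      if (is.na(j)) { # candidate list exhausted; fall back to full order
        ord <- order(d2[pick[i], ])
        j <- ord[!(ord %in% used)][1L]
      }
      used <- c(used, j)
      idx[i] <- j
    }
    sets[[s]] <- idx
  }
  center_selection(sets, spec,
                   diagnostics = list(bins_per_dim = bins, pool_size = P))
}

#' Frequency regime: centers in the most populated lattice cells
#'
#' Partitions the input space into an axis-aligned lattice of `v` bins per
#' dimension (half-open cells, the last cell closed; values outside the
#' declared range are clamped into the boundary cells), counts training
#' samples per cell, keeps the `m` most populous cells (ties broken by
#' lexicographic cell index for determinism) and, within each chosen cell,
#' takes the sample nearest the cell centroid.
#'
#' @inheritParams select_random
#' @return A `center_selection`; diagnostics carry the occupancy table of
#'   the chosen cells.
#' @export
select_frequency <- function(train, spec) {
  X <- train$features
  n <- nrow(X); p <- ncol(X); m <- spec$m; v <- spec$v
  rng <- lattice_ranges(train)
  widths <- (rng["hi", ] - rng["lo", ]) / v
  widths[widths <= 0] <- 1 # constant dimension: everything in one bin
  bin <- sapply(seq_len(p), function(j) {
    b <- floor((X[, j] - rng["lo", j]) / widths[j]) + 1L
    pmin(pmax(b, 1L), v)
  })
  bin <- matrix(bin, nrow = n)
  keys <- apply(matrix(sprintf("%04d", bin), nrow = n), 1L, paste, collapse = ",")
  counts <- table(keys)
  if (length(counts) < m)
    kr_stop("degenerate_lattice",
            sprintf("only %d occupied cells for m = %d; lower `v`",
                    length(counts), m))
  ord <- order(-as.integer(counts), names(counts))
  chosen <- names(counts)[ord[seq_len(m)]]

  idx <- integer(m)
  for (i in seq_len(m)) {
    cell <- as.integer(strsplit(chosen[i], ",", fixed = TRUE)[[1]])
    centroid <- rng["lo", ] + (cell - 0.5) * widths
    members <- which(keys == chosen[i])
    d2 <- colSums((t(X[members, , drop = FALSE]) - centroid)^2)
    idx[i] <- members[which.min(d2)]
  }
  center_selection(idx, spec,
                   diagnostics = list(
                     occupied_cells = length(counts),
                     cell_counts = as.integer(counts)[ord[seq_len(m)]]))
}

# k-means++ seeding (D^2 weighting); stats::kmeans has no built-in version.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1], ], "-")^2)
    for (i in 2:k) {
      tot <- sum(d2)
      idx[i] <- if (tot <= 0) sample.int(n, 1L) else
        sample.int(n, 1L, prob = d2 / tot)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[i], ], "-")^2))
    }
  }
  X[idx, , drop = FALSE]
}

#' K-means regime: centers near cluster centroids
#'
#' Runs k-means with `m` clusters on the training features (labels unused),
#' using k-means++ initialisation and an iteration cap of 300, then snaps
#' each centroid to its nearest training sample (next nearest on
#' collision, keeping the `m` indices distinct).
#'
#' @inheritParams select_random
#' @return A `center_selection`; diagnostics carry the k-means iteration
#'   count and cluster sizes.
#' @export
select_kmeans <- function(train, spec) {
  X <- train$features
  n <- nrow(X); m <- spec$m
  if (m > n) kr_stop("insufficient_data", "`m` exceeds the training size")
  set.seed(derive_seed(spec$seed, "kmeans_regime"))
  init <- kmeanspp_init(X, m)
  km <- suppressWarnings(tryCatch(
    kmeans(X, centers = init, iter.max = 300L),
    error = function(e)
      kmeans(X, centers = init, iter.max = 300L, algorithm = "MacQueen")))
  idx <- snap_distinct(km$centers, X)
  center_selection(idx, spec,
                   diagnostics = list(iterations = km$iter,
                                      cluster_sizes = km$size))
}

#' Support-vector regime: centers that define the class margin
#'
#' Fits a soft-margin SVM with a Gaussian kernel (cost `cost`, kernel width
#' matched to the regime kernels) on the training set, ranks its support
#' vectors by absolute dual coefficient (largest first -- the samples most
#' responsible for the margin) and keeps the top `m`.  When fewer than `m`
#' support vectors exist, the remainder is filled with the training samples
#' nearest the decision surface (smallest absolute decision value) that are
#' not already chosen.  For very large training sets the SVM may be fit on
#' a seed-controlled subsample of `max_n` rows as a cost cap; ranking and
#' filling still index the full training set.
#'
#' @inheritParams select_random
#' @param cost Soft-margin cost `C` of the selector SVM.
#' @param kernel_width Gaussian width of the selector SVM (the libsvm
#'   `gamma` is `1 / (2 * kernel_width^2)`), matching the regime kernels.
#' @param max_n Optional cap on the number of training rows the SVM is fit
#'   on; `NULL` fits on all rows.
#' @return A `center_selection`; diagnostics carry the support-vector count
#'   and how many slots were filled from the decision surface.
#' @export
select_support_vector <- function(train, spec, cost = 1, kernel_width = 1,
                                  max_n = NULL) {
  X <- train$features
  y <- train$labels
  n <- nrow(X); m <- spec$m
  if (m > n) kr_stop("insufficient_data", "`m` exceeds the training size")
  if (length(unique(y)) < 2L)
    kr_stop("invalid_task", "support-vector regime needs both classes present")

  sub <- seq_len(n)
  if (!is.null(max_n) && n > max_n) {
    set.seed(derive_seed(spec$seed, "svm_subsample"))
    sub <- sort(sample.int(n, max_n))
    if (length(unique(y[sub])) < 2L) sub <- seq_len(n)
  }
  fit <- e1071::svm(x = X[sub, , drop = FALSE],
                    y = factor(y[sub], levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * kernel_width^2), cost = cost,
                    scale = FALSE)
  ab <- abs(fit$coefs[, 1])
  sv_global <- sub[fit$index]
  ranked <- sv_global[order(-ab, fit$index)]
  idx <- head(ranked, m)

  filled <- 0L
  if (length(idx) < m) {
    dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
    fill <- setdiff(order(abs(dv)), idx)
    filled <- m - length(idx)
    idx <- c(idx, fill[seq_len(filled)])
  }
  center_selection(as.integer(idx), spec,
                   diagnostics = list(n_support_vectors = length(sv_global),
                                      n_filled = filled,
                                      svm_subsample = length(sub)))
}

# Kernel column of width 1: kernel values of all rows of X against one
# stored center (the novelty stream's incremental building block).
kernel_column <- function(X, center) {
  d2 <- rowSums(X^2) - 2 * drop(X %*% center) + sum(center^2)
  d2[d2 < 0] <- 0
  exp(-d2 / 2) / sqrt(2 * pi)
}

#' Novelty regime: online admission with pruning
#'
#' Streams the training samples in random order through a growing kernel
#' dictionary.  The dictionary starts with a single random sample; for each
#' incoming sample the current model (kernel layer on the dictionary plus a
#' readout refit on all samples seen so far) makes a prediction, and the
#' sample is admitted as a new center when its error is novel.  Under the
#' default rule `"error_threshold"` a sample is novel when its absolute
#' prediction error exceeds `delta` (the classical, stateless novelty
#' criterion); under `"error_increase"` it is novel when its error exceeds
#' the previous sample's error by more than `delta`.  Whenever the
#' dictionary would exceed `m`, the center with the smallest absolute
#' readout weight is pruned.  The readout is refit (closed form, on all
#' samples seen so far) each time the dictionary changes; between changes
#' the model is fixed, which the implementation exploits by scoring the
#' stream in blocks.
#'
#' The final dictionary has exactly `m` centers for any `delta` small
#' enough that admissions continue; for extreme `delta` the stream may end
#' with fewer centers, and the selection is returned at its actual size.
#'
#' @inheritParams select_random
#' @param ridge Ridge used in the streaming readout refits.
#' @param rule Admission rule, see above.
#' @param chunk_size Cap on the internal block size used to score the
#'   stream between dictionary changes (performance only; no effect on
#'   results).
#' @return A `center_selection`; diagnostics carry the admission/pruning
#'   log (`position`, `event`, `train_index`, `dict_size_after`), on which
#'   the dictionary-size invariant can be replayed.
#' @export
select_novelty <- function(train, spec, ridge = 1e-8,
                           rule = c("error_threshold", "error_increase"),
                           chunk_size = 256L) {
  rule <- match.arg(rule)
  X <- train$features
  y <- train$labels
  n <- nrow(X); m <- spec$m; delta <- spec$delta
  set.seed(derive_seed(spec$seed, "novelty_stream"))
  ord <- sample.int(n)
  Xs <- X[ord, , drop = FALSE]
  ys <- y[ord]

  mb <- m + 1L # one spare slot for the add-then-prune transient
  Phi <- matrix(0, n, mb)   # features of seen rows vs slot centers
  G <- matrix(0, mb, mb)    # crossprod of Phi over seen rows
  py <- numeric(mb)         # t(Phi) %*% y over seen rows
  cs <- numeric(mb)         # column sums of Phi over seen rows
  slot_row <- integer(mb)   # training-row index stored in each slot
  active <- integer(0)

  nseen <- 0L; ysum <- 0
  alpha <- numeric(0); offset <- 0

  cap <- 2L * n + 2L # admissions and prunes can never exceed this
  log_pos <- integer(cap); log_event <- character(cap)
  log_idx <- integer(cap); log_size <- integer(cap)
  nlog <- 0L
  note <- function(pos, event, idx, size) {
    nlog <<- nlog + 1L
    log_pos[nlog] <<- pos; log_event[nlog] <<- event
    log_idx[nlog] <<- idx; log_size[nlog] <<- size
  }

  refit <- function() {
    a <- active
    mu <- cs[a] / nseen
    A <- G[a, a, drop = FALSE] - nseen * tcrossprod(mu)
    diag(A) <- diag(A) + ridge
    b <- py[a] - mu * ysum
    R <- chol(A)
    w <- backsolve(R, backsolve(R, b, transpose = TRUE))
    alpha <<- as.numeric(w)
    offset <<- ysum / nseen - sum(mu * w)
  }

  # seed the dictionary with the first streamed sample
  peak <- 1 / sqrt(2 * pi)
  slot_row[1L] <- ord[1L]; active <- 1L
  Phi[1L, 1L] <- peak
  G[1L, 1L] <- peak^2; py[1L] <- peak * ys[1L]; cs[1L] <- peak
  nseen <- 1L; ysum <- ys[1L]
  refit()
  note(1L, "admit", ord[1L], 1L)

  # cached dictionary coordinates for the chunk scorer (refreshed on change)
  Ca <- X[slot_row[active], , drop = FALSE]
  ca2 <- rowSums(Ca^2)
  xs2 <- rowSums(Xs^2)

  pos <- 2L
  prev_err <- 0
  chunk <- 8L # grows while the stream is quiet, shrinks after admissions
  while (pos <= n) {
    hi <- min(n, pos + chunk - 1L)
    rows <- pos:hi
    B <- Xs[rows, , drop = FALSE]
    d2 <- outer(xs2[rows], ca2, "+") - 2 * tcrossprod(B, Ca)
    d2[d2 < 0] <- 0
    FF <- exp(d2 * -0.5) * peak
    errs <- abs(drop(FF %*% alpha) + offset - ys[rows])
    hit <- if (rule == "error_threshold") {
      which(errs > delta)[1L]
    } else {
      which(errs - c(prev_err, errs[-length(errs)]) > delta)[1L]
    }
    upto <- if (is.na(hit)) length(rows) else hit
    absorbed <- rows[seq_len(upto)]
    FA <- FF[seq_len(upto), , drop = FALSE]
    Phi[absorbed, active] <- FA
    G[active, active] <- G[active, active, drop = FALSE] + crossprod(FA)
    py[active] <- py[active] + drop(crossprod(FA, ys[absorbed]))
    cs[active] <- cs[active] + colSums(FA)
    nseen <- nseen + upto
    ysum <- ysum + sum(ys[absorbed])
    prev_err <- errs[upto]

    if (is.na(hit)) {
      pos <- hi + 1L
      chunk <- min(chunk * 2L, as.integer(chunk_size))
      next
    }
    chunk <- 8L
    q <- rows[hit]
    # admit the novel sample as a center
    slot <- setdiff(seq_len(mb), active)[1L]
    colfull <- numeric(n)
    colfull[seq_len(nseen)] <- kernel_column(Xs[seq_len(nseen), , drop = FALSE],
                                             X[ord[q], ])
    Phi[seq_len(nseen), slot] <- colfull[seq_len(nseen)]
    # full-buffer product: rows past nseen are zero in colfull and entries
    # at inactive slots are discarded, so no submatrix copy is needed
    cross <- drop(crossprod(Phi, colfull))
    G[slot, active] <- cross[active]
    G[active, slot] <- cross[active]
    G[slot, slot] <- cross[slot]
    py[slot] <- sum(colfull[seq_len(nseen)] * ys[seq_len(nseen)])
    cs[slot] <- sum(colfull)
    slot_row[slot] <- ord[q]
    active <- c(active, slot)
    refit()
    if (length(active) > m) {
      j <- which.min(abs(alpha))
      note(q, "prune", slot_row[active[j]], m)
      active <- active[-j]
      refit()
    }
    note(q, "admit", ord[q], length(active))
    Ca <- X[slot_row[active], , drop = FALSE]
    ca2 <- rowSums(Ca^2)
    pos <- q + 1L
  }

  keep <- seq_len(nlog)
  center_selection(slot_row[active], spec,
                   diagnostics = list(
                     rule = rule,
                     log = data.frame(position = log_pos[keep],
                                      event = log_event[keep],
                                      train_index = log_idx[keep],
                                      dict_size_after = log_size[keep])))
}

#' Grid search for regime hyperparameters on a validation split
#'
#' Evaluates candidate values of the frequency regime's lattice resolution
#' `v` or the novelty regime's threshold `delta` by selecting centers on
#' `train`, fitting the closed-form readout on the training features, and
#' scoring accuracy on `validation`.  Candidates that raise degenerate
#' errors (e.g. too few occupied lattice cells) are skipped.  The best
#' validation accuracy wins; exact ties go to the smaller hyperparameter
#' value.  Regimes without a searched hyperparameter return the template
#' unchanged.
#'
#' @param train,validation [labeled_dataset()] objects; `validation` must
#'   never be the test set.
#' @param spec_template A [regime_spec()] providing everything except the
#'   searched value.
#' @param v_grid,delta_grid Candidate values (ascending order recommended;
#'   they are sorted internally so the tie rule holds).
#' @param ridge Ridge for the readout fits during the search.
#' @return A [regime_spec()] with the winning hyperparameter filled in; the
#'   validation accuracies are attached as attribute `"search"`.
#' @export
grid_search_hyperparams <- function(train, validation, spec_template,
                                    v_grid = c(4L, 8L, 16L, 32L),
                                    delta_grid = c(0.1, 0.25, 0.5, 1.0),
                                    ridge = 1e-8) {
  stopifnot(inherits(spec_template, "regime_spec"))
  grid <- switch(spec_template$name,
                 frequency = sort(v_grid),
                 novelty = sort(delta_grid),
                 NULL)
  if (is.null(grid)) return(spec_template)
  if (length(grid) == 0L)
    kr_stop("invalid_parameter", "hyperparameter grid must be non-empty")

  accs <- rep(NA_real_, length(grid))
  specs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cand <- spec_template
    if (spec_template$name == "frequency") cand$v <- as.integer(grid[i])
    else cand$delta <- grid[i]
    sel <- tryCatch(select_centers(train, cand, ridge = ridge),
                    kernelregimes_error = function(e) NULL)
    if (is.null(sel)) next
    layer <- kernel_layer(train$features[sel$center_indices, , drop = FALSE])
    sol <- solve_readout(kernel_features(train$features, layer),
                         train$labels, ridge = ridge)
    pred <- predict_readout(validation$features, layer, sol)
    accs[i] <- classification_accuracy(pred$labels, validation$labels)
    specs[[i]] <- cand
  }
  if (all(is.na(accs)))
    kr_stop("invalid_parameter",
            "no hyperparameter candidate produced a valid selection")
  best <- specs[[which.max(accs)]] # first max: smaller value wins ties
  attr(best, "search") <- data.frame(value = grid, accuracy = accs)
  best
}
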