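# Shared 2,000-point task (K = 5, two irrelevant dimensions) for the
# cross-regime contract checks.
task <- make_task(n = 2000, K = 5, n_irrelevant = 2, seed = 7)
train <- task$train

spec_for <- function(name, m = 20, ...) regime_spec(name, m = m, seed = 42, ...)

test_that("every regime returns m distinct training rows, deterministically", {
  for (name in c("random", "regular", "frequency", "kmeans",
                 "support_vector", "novelty")) {
    spec <- spec_for(name, v = 8)
    sel <- select_centers(train, spec)
    sets <- if (is.list(sel$center_indices)) sel$center_indices else
      list(sel$center_indices)
    row_keys <- apply(train$features, 1, paste, collapse = "\r")
    for (s in sets) {
      expect_length(s, 20L)
      expect_false(anyDuplicated(s) > 0)
      expect_true(all(s >= 1 & s <= nrow(train$features)))
      # the layer a selection induces holds bit-identical training rows
      layer <- kernel_layer(train$features[s, , drop = FALSE])
      expect_true(all(apply(layer$centers, 1, paste, collapse = "\r")
                      %in% row_keys))
    }
    expect_identical(sel$center_indices,
                     select_centers(train, spec)$center_indices)
  }
})

test_that("random selection is uniform and covers the exhaustive case", {
  tiny <- labeled_dataset(matrix(rnorm(20), 10, 2),
                          rep(c(-1, 1), 5), role = "train")
  all10 <- select_random(tiny, regime_spec("random", m = 10, seed = 1))
  expect_setequal(all10$center_indices, 1:10)
  expect_error(select_random(tiny, regime_spec("random", m = 11, seed = 1)),
               class = "kernelregimes_insufficient_data")

  counts <- tabulate(vapply(1:2000, function(s)
    select_random(tiny, regime_spec("random", m = 1, seed = s))$center_indices,
    1L), nbins = 10)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("regular regime builds the ceiling(m^(1/p)) lattice and snaps to samples", {
  sp5 <- regime_spec("regular", m = 5, n_subsets = 50, seed = 1)
  sel5 <- select_regular(train, sp5)
  expect_equal(sel5$diagnostics$bins_per_dim, ceiling(5^(1 / 4))) # p = 4
  expect_length(sel5$center_indices, 50L)

  # p = 2: m = 5 gives a 3 x 3 = 9 coordinate pool
  flat <- labeled_dataset(train$features[, 1:2], train$labels, role = "train",
                          relevant_range = train$relevant_range)
  self <- select_regular(flat, sp5)
  expect_equal(self$diagnostics$pool_size, 9L)

  # m = 100, p = 2: pool of exactly 100, so every subset coincides
  sp100 <- regime_spec("regular", m = 100, n_subsets = 20, seed = 1)
  sel100 <- select_regular(flat, sp100)
  expect_equal(sel100$diagnostics$pool_size, 100L)
  keys <- vapply(sel100$center_indices,
                 function(s) paste(sort(s), collapse = ","), "")
  expect_length(unique(keys), 1L)
})

test_that("frequency regime ranks cells by occupancy and handles degeneracy", {
  dense <- make_blobs(n_per = c(900, 100), centers = rbind(c(0, 0), c(4, 4)),
                      sigma = 0.15, seed = 3)
  sel <- select_frequency(dense, regime_spec("frequency", m = 2, v = 2, seed = 1))
  picked <- dense$features[sel$center_indices, ]
  # one center per blob, denser blob's cell ranked first
  expect_lt(sum((picked[1, ] - c(0, 0))^2), 1)
  expect_lt(sum((picked[2, ] - c(4, 4))^2), 1)
  expect_true(sel$diagnostics$cell_counts[1] >= sel$diagnostics$cell_counts[2])

  # all samples identical: one occupied cell serves m = 1, errors at m = 2
  flat <- labeled_dataset(matrix(1, 10, 2), rep(c(-1, 1), 5), role = "train")
  one <- select_frequency(flat, regime_spec("frequency", m = 1, v = 4, seed = 1))
  expect_length(one$center_indices, 1L)
  expect_error(
    select_frequency(flat, regime_spec("frequency", m = 2, v = 4, seed = 1)),
    class = "kernelregimes_degenerate_lattice")
})

test_that("kmeans regime recovers separated blobs and the global mean at m = 1", {
  set.seed(9)
  cents <- cbind(c(0, 5, 10, 0, 10), c(0, 5, 0, 10, 10))
  blobs <- make_blobs(n_per = rep(40, 5), centers = cents, sigma = 0.15,
                      seed = 9)
  blobs$labels <- rep(c(-1, 1), length.out = 200)
  sel <- select_kmeans(blobs, regime_spec("kmeans", m = 5, seed = 2))
  picked <- blobs$features[sel$center_indices, ]
  d2 <- outer(rowSums(picked^2), rowSums(cents^2), "+") -
    2 * tcrossprod(picked, cents)
  expect_setequal(apply(d2, 1, which.min), 1:5) # one center inside each blob
  expect_true(all(apply(d2, 1, min) < 1))

  one <- select_kmeans(train, regime_spec("kmeans", m = 1, seed = 2))
  gm <- colMeans(train$features)
  d2all <- colSums((t(train$features) - gm)^2)
  expect_equal(one$center_indices, which.min(d2all))
})

test_that("support-vector regime picks the margin-defining samples", {
  blobs <- make_blobs(n_per = c(60, 60), centers = rbind(c(0, 0), c(4, 0)),
                      sigma = 0.25, seed = 5)
  sel <- select_support_vector(blobs, regime_spec("support_vector", m = 2,
                                                  seed = 1))
  picked <- blobs$features[sel$center_indices, ]
  lab <- blobs$labels[sel$center_indices]
  expect_setequal(lab, c(-1, 1)) # one per class
  # both chosen samples hug the inter-blob midplane x = 2
  margin_all <- abs(blobs$features[, 1] - 2)
  expect_lt(mean(abs(picked[, 1] - 2)), mean(margin_all))
  for (cls in c(-1, 1)) {
    side <- blobs$labels == cls
    expect_lt(abs(picked[lab == cls, 1] - 2), median(margin_all[side]))
  }

  expect_error(
    select_support_vector(labeled_dataset(matrix(rnorm(8), 4, 2),
                                          rep(1, 4), role = "train"),
                          regime_spec("support_vector", m = 2, seed = 1)),
    class = "kernelregimes_invalid_task")

  # boundary concentration on the entangled task
  selT <- select_support_vector(train, spec_for("support_vector", m = 50))
  expect_length(selT$center_indices, 50L)
})

test_that("novelty admission respects delta limits and the budget at every step", {
  small <- make_task(n = 200, K = 2, n_irrelevant = 0, seed = 3)$train

  # threshold never crossed: the dictionary stays at its single seed sample
  frozen <- select_novelty(small, regime_spec("novelty", m = 20, delta = 1e9,
                                              seed = 1))
  expect_length(frozen$center_indices, 1L)

  # threshold always crossed with room for everyone: every sample admitted
  n_small <- nrow(small$features)
  greedy <- select_novelty(small, regime_spec("novelty", m = n_small,
                                              delta = 1e-9, seed = 1))
  expect_setequal(greedy$center_indices, seq_len(n_small))

  # budget invariant replayed from the admission/pruning log
  sel <- select_novelty(train, spec_for("novelty", m = 20, delta = 0.25))
  expect_length(sel$center_indices, 20L)
  lg <- sel$diagnostics$log
  expect_true(all(lg$dict_size_after <= 20L))
  expect_identical(sel$center_indices,
                   select_novelty(train,
                                  spec_for("novelty", m = 20,
                                           delta = 0.25))$center_indices)

  # the stateless and error-increase rules are both available and differ here
  alt <- select_novelty(train, spec_for("novelty", m = 20, delta = 0.25),
                        rule = "error_increase")
  expect_false(identical(sort(alt$center_indices),
                         sort(sel$center_indices)))
})

test_that("task-independent regimes ignore labels; task-dependent ones use them", {
  shuffled <- train
  set.seed(99)
  shuffled$labels <- sample(train$labels)

  for (name in c("random", "regular", "frequency", "kmeans")) {
    spec <- spec_for(name, v = 8)
    expect_identical(select_centers(train, spec)$center_indices,
                     select_centers(shuffled, spec)$center_indices,
                     label = paste(name, "label-shuffle invariance"))
  }
  for (name in c("support_vector", "novelty")) {
    spec <- spec_for(name)
    expect_false(identical(
      sort(unlist(select_centers(train, spec)$center_indices)),
      sort(unlist(select_centers(shuffled, spec)$center_indices))),
      label = paste(name, "label-shuffle sensitivity"))
  }
})

test_that("hyperparameter search honours ties, skips degenerate values", {
  parts <- split_train_test(train, 0.8, seed = 1)
  tr <- parts$train; val <- parts$test

  # single-element grid is returned as-is
  single <- grid_search_hyperparams(tr, val,
                                    regime_spec("frequency", m = 10, seed = 1),
                                    v_grid = 8L)
  expect_equal(single$v, 8L)

  # v = 1 cannot host m = 10 centers (one cell only): skipped, not fatal
  mixed <- grid_search_hyperparams(tr, val,
                                   regime_spec("frequency", m = 10, seed = 1),
                                   v_grid = c(1L, 8L))
  expect_equal(mixed$v, 8L)
  expect_true(is.na(attr(mixed, "search")$accuracy[1]))

  # regimes without a searched hyperparameter pass through unchanged
  passthrough <- grid_search_hyperparams(tr, val,
                                         regime_spec("kmeans", m = 5, seed = 1))
  expect_identical(passthrough, regime_spec("kmeans", m = 5, seed = 1))
})
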