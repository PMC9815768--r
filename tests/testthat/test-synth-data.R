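test_that("task specs have 2K centers, both classes, and are seed-deterministic", {
  spec <- build_task_spec(K = 2, n_irrelevant = 0, seed = 11)
  expect_equal(nrow(spec$center_positions), 4L)
  expect_setequal(unique(spec$center_classes), c(-1, 1))

  big <- build_task_spec(K = 25, n_irrelevant = 2, seed = 11)
  expect_equal(nrow(big$center_positions), 50L)
  expect_length(big$center_classes, 50L)

  expect_identical(build_task_spec(K = 5, seed = 3),
                   build_task_spec(K = 5, seed = 3))
  expect_error(build_task_spec(K = 0, seed = 1),
               class = "kernelregimes_invalid_spec")
})

test_that("samples are labeled by the nearest center, idempotently", {
  spec <- build_task_spec(K = 5, seed = 2)
  ds <- sample_dataset(spec, 500, seed = 9)

  # relabeling with the same spec changes nothing
  expect_identical(nearest_center_labels(ds$features, spec), ds$labels)
  # a point exactly at center j carries center j's class
  expect_identical(nearest_center_labels(spec$center_positions, spec),
                   spec$center_classes)

  # in the sigma -> 0 limit every sample sits on its generating center,
  # so the generating cluster's class equals the nearest-center label
  tight <- build_task_spec(K = 5, seed = 2, cluster_sigma = 1e-9)
  dst <- sample_dataset(tight, 300, seed = 9)
  expect_identical(dst$labels, tight$center_classes[dst$cluster_id])

  expect_identical(sample_dataset(spec, 200, seed = 5),
                   sample_dataset(spec, 200, seed = 5))
})

test_that("class balance follows the mixture weights on a symmetric layout", {
  # four tight clusters at square corners, alternating classes: analytic
  # P(+1) = 1/2, so the empirical fraction must sit within binomial error
  spec <- build_task_spec(K = 2, seed = 1, cluster_sigma = 0.05)
  spec$center_positions <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  spec$center_classes <- c(1, -1, 1, -1)
  ds <- sample_dataset(spec, 1000, seed = 4)
  p_hat <- mean(ds$labels == 1)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / 1000))
})

test_that("label corruption flips at the binomial rate and rejects bad rates", {
  y <- rep(1, 1e5)
  expect_identical(corrupt_labels(y, 0, seed = 1), y)
  flipped <- sum(corrupt_labels(y, 0.05, seed = 1) != y)
  expect_lt(abs(flipped - 5000), 3 * sqrt(1e5 * 0.05 * 0.95))
  expect_error(corrupt_labels(y, 1, seed = 1),
               class = "kernelregimes_invalid_parameter")
})

test_that("irrelevant dimensions span the declared range and carry no signal", {
  spec <- build_task_spec(K = 2, n_irrelevant = 2, seed = 6)
  ds <- sample_dataset(spec, 4000, seed = 6)
  aug <- append_irrelevant_dims(ds, 2, seed = 8)
  expect_equal(ncol(aug$features), 4L)
  expect_identical(aug$labels, ds$labels)
  expect_identical(aug$relevant_dims, ds$relevant_dims)
  lo <- min(spec$relevant_range[1, ]); hi <- max(spec$relevant_range[2, ])
  expect_true(all(aug$features[, 3:4] >= lo & aug$features[, 3:4] <= hi))
  # point-biserial correlation of an independent uniform column with labels
  for (j in 3:4)
    expect_lt(abs(cor(aug$features[, j], aug$labels)), 4 / sqrt(4000))
  expect_identical(append_irrelevant_dims(ds, 0, seed = 8), ds)
})

test_that("train/test split is an exact seeded partition", {
  spec <- build_task_spec(K = 2, seed = 1)
  ds <- sample_dataset(spec, 1000, seed = 2)
  parts <- split_train_test(ds, 0.7, seed = 3)
  expect_equal(nrow(parts$train$features), 700L)
  expect_equal(nrow(parts$test$features), 300L)
  expect_identical(parts, split_train_test(ds, 0.7, seed = 3))

  # true partition across several seeds: no overlap, full coverage
  key <- function(d) apply(d$features, 1, paste, collapse = ",")
  for (s in 1:5) {
    p <- split_train_test(ds, 0.5, seed = s)
    expect_equal(nrow(p$train$features), 500L)
    expect_length(intersect(key(p$train), key(p$test)), 0L)
    expect_setequal(c(key(p$train), key(p$test)), key(ds))
  }
  expect_error(split_train_test(ds, 1, seed = 1),
               class = "kernelregimes_invalid_parameter")
})

test_that("datasets round-trip through CSV with a regenerating spec sidecar", {
  spec <- build_task_spec(K = 2, n_irrelevant = 1, seed = 5)
  ds <- append_irrelevant_dims(sample_dataset(spec, 50, seed = 5), 1, seed = 6)
  prefix <- file.path(withr::local_tempdir(), "task")
  write_dataset(ds, prefix, spec = spec)
  back <- read_dataset(prefix)
  expect_equal(back$dataset$features, ds$features, ignore_attr = TRUE)
  expect_equal(back$dataset$labels, ds$labels)
  expect_equal(back$spec$center_positions, spec$center_positions,
               ignore_attr = TRUE)
  # the sidecar regenerates the original samples exactly
  regen <- sample_dataset(back$spec, 50, seed = 5)
  expect_equal(regen$features, ds$features[, 1:2], ignore_attr = TRUE)
})
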