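#' Define one experimental condition
#'
#' A condition fixes the data-generating parameters of a cell of the
#' experiment grid: task complexity `K` (clusters per class), kernel
#' budget `m`, the number of appended task-irrelevant dimensions, the
#' dataset size and the train/test split.  The full-scale study conditions
#' are `n_samples = 100000` with a 70/30 split and 5% label noise; the
#' desk default of 5,000 samples preserves every qualitative contrast at a
#' fraction of the cost.
#'
#' @param K Clusters per class; study values 2, 5, 25.
#' @param m Kernel budget / hidden units; study values 5, 20, 100.
#' @param n_irrelevant Appended irrelevant dimensions (0 gives 2/2
#'   relevant, 2 gives 2/4, 6 gives 2/8).
#' @param n_samples Total dataset size before splitting.
#' @param train_fraction Training proportion in `(0, 1)`.
#' @param label_noise_rate Label flip probability in `[0, 1)`.
#' @return An object of class `condition`.
#' @export
condition <- function(K, m, n_irrelevant = 0L, n_samples = 5000L,
                      train_fraction = 0.7, label_noise_rate = 0.05) {
  if (K < 1 || m < 1 || n_samples < 1)
    kr_stop("invalid_spec", "`K`, `m` and `n_samples` must be positive")
  if (train_fraction <= 0 || train_fraction >= 1)
    kr_stop("invalid_spec", "`train_fraction` must lie in (0, 1)")
  structure(list(K = as.integer(K), m = as.integer(m),
                 n_irrelevant = as.integer(n_irrelevant),
                 n_samples = as.integer(n_samples),
                 train_fraction = train_fraction,
                 label_noise_rate = label_noise_rate),
            class = "condition")
}

#' Build the cross-product of condition parameters
#'
#' @param K,m,n_irrelevant Vectors of grid values.
#' @param n_samples,train_fraction,label_noise_rate Shared scalars.
#' @return A list of [condition()] objects covering the cross-product.
#' @export
condition_grid <- function(K = c(2L, 5L, 25L), m = c(5L, 20L, 100L),
                           n_irrelevant = c(0L, 2L, 6L), n_samples = 5000L,
                           train_fraction = 0.7, label_noise_rate = 0.05) {
  g <- expand.grid(K = K, m = m, n_irrelevant = n_irrelevant,
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    condition(g$K[i], g$m[i], g$n_irrelevant[i], n_samples,
              train_fraction, label_noise_rate))
}

# The regime names run_condition understands: the six kernel regimes plus
# the two random-projection controls.
KERNEL_REGIMES <- c("random", "regular", "frequency", "kmeans",
                    "support_vector", "novelty")
ALL_REGIMES <- c(KERNEL_REGIMES, "rp_linear", "rp_nonlinear")

#' Generate the dataset of one (condition, seed) cell
#'
#' Runs the full generative pipeline -- task spec, mixture sampling with
#' nearest-center labels, label corruption, irrelevant-dimension
#' augmentation, train/test split -- with every stage on its own named
#' substream of `seed` (see [derive_seed()]), so all regimes see the same
#' data for the same master seed.
#'
#' @param condition A [condition()].
#' @param seed Master seed of the replicate.
#' @return List with elements `train`, `test` ([labeled_dataset()]) and
#'   `spec` (the [build_task_spec()] used).
#' @export
make_condition_dataset <- function(condition, seed) {
  ds <- derive_seed(seed, "data")
  spec <- build_task_spec(condition$K, condition$n_irrelevant,
                          seed = derive_seed(ds, "spec"),
                          label_noise_rate = condition$label_noise_rate)
  full <- sample_dataset(spec, condition$n_samples, derive_seed(ds, "sample"))
  full$labels <- corrupt_labels(full$labels, condition$label_noise_rate,
                                derive_seed(ds, "noise"))
  full <- append_irrelevant_dims(full, condition$n_irrelevant,
                                 derive_seed(ds, "irrelevant"))
  parts <- split_train_test(full, condition$train_fraction,
                            derive_seed(ds, "split"))
  c(parts, list(spec = spec))
}

# Evaluate many center index sets sharing one training/test pair, reusing
# the pooled feature matrices: the per-set work is only an m x m solve.
# Identical sets are solved once.  Returns one test accuracy per set.
evaluate_center_sets <- function(train, test, sets, ridge = 1e-8) {
  if (!is.list(sets)) sets <- list(sets)
  pool <- sort(unique(unlist(sets)))
  layer <- kernel_layer(train$features[pool, , drop = FALSE])
  Htr <- kernel_features(train$features, layer)
  Hte <- kernel_features(test$features, layer)
  y <- train$labels
  n <- nrow(Htr)
  G <- crossprod(Htr)
  py <- drop(crossprod(Htr, y))
  cs <- colSums(Htr)
  ybar <- mean(y)

  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), "")
  uk <- !duplicated(keys)
  acc_map <- setNames(rep(NA_real_, sum(uk)), keys[uk])
  for (key in names(acc_map)) {
    s <- sets[[match(key, keys)]]
    pos <- match(s, pool)
    mu <- cs[pos] / n
    A <- G[pos, pos, drop = FALSE] - n * tcrossprod(mu)
    diag(A) <- diag(A) + ridge
    b <- py[pos] - mu * (ybar * n)
    R <- chol(A)
    a <- backsolve(R, backsolve(R, b, transpose = TRUE))
    scores <- drop(Hte[, pos, drop = FALSE] %*% a) - sum(mu * a) + ybar
    acc_map[key] <- classification_accuracy(ifelse(scores >= 0, 1, -1),
                                            test$labels)
  }
  unname(acc_map[keys])
}

#' Run one (condition, regime, seed) cell of the experiment
#'
#' Executes the full pipeline: generate the dataset
#' ([make_condition_dataset()]), build the expansion layer (select centers
#' for a kernel regime, or draw a projection for the `rp_linear` /
#' `rp_nonlinear` controls), fit the closed-form readout on the training
#' features, and measure test accuracy.  For the regular regime the
#' reported accuracy is the mean over its `n_subsets` center sets.  All
#' randomness derives from `seed` via named substreams, so repeated calls
#' are bit-identical and the dataset does not depend on the regime.
#'
#' @param condition A [condition()].
#' @param regime One of `"random"`, `"regular"`, `"frequency"`,
#'   `"kmeans"`, `"support_vector"`, `"novelty"`, `"rp_linear"`,
#'   `"rp_nonlinear"`.
#' @param seed Master seed of the replicate.
#' @param v,delta,n_subsets Regime hyperparameters (see [regime_spec()]).
#' @param ridge Readout regularisation.
#' @param activation Nonlinearity of the `rp_nonlinear` control.
#' @param svm_max_n Training-subsample cap for the support-vector
#'   selector (`NULL` disables it).
#' @param novelty_rule Admission rule of the novelty regime.
#' @param data Optional precomputed result of
#'   [make_condition_dataset()] for this `(condition, seed)`, so grid
#'   runners can share one dataset across regimes.
#' @param return_details If `TRUE`, also return the dataset, selection,
#'   layer and readout (used by center dumps and diagnostics).
#' @return A one-row `data.frame` (the result record) with columns `K`,
#'   `m`, `n_irrelevant`, `n_samples`, `regime`, `seed`, `test_accuracy`,
#'   `v`, `delta`, `n_subsets`, `ridge`, `status`; or, with
#'   `return_details = TRUE`, a list with that record plus the pipeline
#'   objects.
#' @export
run_condition <- function(condition, regime, seed, v = 16L, delta = 0.25,
                          n_subsets = 1000L, ridge = 1e-8,
                          activation = "relu", svm_max_n = 2000L,
                          novelty_rule = "error_threshold",
                          data = NULL, return_details = FALSE) {
  stopifnot(inherits(condition, "condition"))
  if (!regime %in% ALL_REGIMES)
    kr_stop("invalid_parameter", paste("unknown regime:", regime))
  if (is.null(data)) data <- make_condition_dataset(condition, seed)
  train <- data$train; test <- data$test
  m <- condition$m
  selection <- NULL; layer <- NULL; solution <- NULL

  if (regime %in% c("rp_linear", "rp_nonlinear")) {
    layer <- sample_projection_layer(
      ncol(train$features), m, derive_seed(seed, "layer"),
      activation = if (regime == "rp_linear") "identity" else activation)
    solution <- solve_readout(expansion_features(train$features, layer),
                              train$labels, ridge = ridge)
    pred <- predict_readout(test$features, layer, solution)
    acc <- classification_accuracy(pred$labels, test$labels)
  } else {
    spec <- regime_spec(regime, m = m, v = v, delta = delta,
                        n_subsets = n_subsets,
                        seed = derive_seed(seed, "regime"))
    selection <- switch(regime,
      support_vector = select_support_vector(train, spec, max_n = svm_max_n),
      novelty = select_novelty(train, spec, ridge = ridge,
                               rule = novelty_rule),
      select_centers(train, spec))
    if (regime == "regular") {
      acc <- mean(evaluate_center_sets(train, test,
                                       selection$center_indices, ridge))
    } else {
      layer <- kernel_layer(
        train$features[selection$center_indices, , drop = FALSE],
        provenance = list(regime = regime, seed = seed))
      solution <- solve_readout(kernel_features(train$features, layer),
                                train$labels, ridge = ridge)
      pred <- predict_readout(test$features, layer, solution)
      acc <- classification_accuracy(pred$labels, test$labels)
    }
  }

  record <- data.frame(K = condition$K, m = m,
                       n_irrelevant = condition$n_irrelevant,
                       n_samples = condition$n_samples,
                       regime = regime, seed = seed, test_accuracy = acc,
                       v = if (regime == "frequency") v else NA_integer_,
                       delta = if (regime == "novelty") delta else NA_real_,
                       n_subsets = if (regime == "regular") n_subsets
                                   else NA_integer_,
                       ridge = ridge, status = "ok",
                       stringsAsFactors = FALSE)
  if (!return_details) return(record)
  list(record = record, data = data, selection = selection, layer = layer,
       solution = solution)
}

failed_record <- function(condition, regime, seed, msg) {
  data.frame(K = condition$K, m = condition$m,
             n_irrelevant = condition$n_irrelevant,
             n_samples = condition$n_samples, regime = regime, seed = seed,
             test_accuracy = NA_real_, v = NA_integer_, delta = NA_real_,
             n_subsets = NA_integer_, ridge = NA_real_,
             status = paste("error:", msg), stringsAsFactors = FALSE)
}

#' Run the full experiment grid
#'
#' Executes every (condition, regime, seed) cell, optionally tuning the
#' frequency regime's `v` and the novelty regime's `delta` per condition
#' beforehand.  Tuning uses only the first seed's data: an 80/20
#' validation split is carved out of that seed's *training* set (the test
#' set is never touched), and the tuned values are reused for all seeds of
#' the condition.  Failures in one cell are recorded in the `status`
#' column and do not abort the grid.  When `out_dir` is given, the tidy
#' result table is written to `results.csv` there together with a
#' `run-manifest.json` of all resolved parameters; records already present
#' in an existing `results.csv` are skipped, making re-runs resumable.
#'
#' @param conditions List of [condition()] objects (see
#'   [condition_grid()]).
#' @param regimes Character vector of regime names (default: all six
#'   kernel regimes plus both random-projection controls).
#' @param seeds Integer vector of replicate master seeds.
#' @param n_subsets Regular-regime subset count used for every cell.
#' @param tune Logical: grid-search `v` and `delta` per condition.
#' @param v_grid,delta_grid Candidate grids for tuning.
#' @param tune_max_n Cap on the tuning training-set size (the search runs
#'   on a seed-controlled subsample of the carved-out training split when
#'   it exceeds this; validation scoring always uses the full split).
#' @param ridge,activation,svm_max_n,novelty_rule Passed to
#'   [run_condition()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress per-condition progress messages.
#' @return A tidy `data.frame` of result records, one row per
#'   (condition, regime, seed).
#' @export
run_grid <- function(conditions, regimes = ALL_REGIMES, seeds = 1:10,
                     n_subsets = 200L, tune = TRUE,
                     v_grid = c(4L, 8L, 16L, 32L),
                     delta_grid = c(0.1, 0.25, 0.5, 1.0), tune_max_n = 1500L,
                     ridge = 1e-8, activation = "relu", svm_max_n = 2000L,
                     novelty_rule = "error_threshold",
                     out_dir = NULL, quiet = FALSE) {
  if (length(conditions) == 0L || length(regimes) == 0L)
    kr_stop("invalid_parameter", "conditions and regimes must be non-empty")
  if (inherits(conditions, "condition")) conditions <- list(conditions)

  done <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "results.csv")
    if (file.exists(csv)) done <- read.csv(csv, stringsAsFactors = FALSE)
  }
  is_done <- function(cond, regime, seed) {
    !is.null(done) && any(done$K == cond$K & done$m == cond$m &
                            done$n_irrelevant == cond$n_irrelevant &
                            done$regime == regime & done$seed == seed)
  }

  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    todo <- expand.grid(regime = regimes, seed = seeds,
                        stringsAsFactors = FALSE)
    todo <- todo[!mapply(is_done, list(cond), todo$regime, todo$seed), ,
                 drop = FALSE]
    if (nrow(todo) == 0L) next

    hyper <- list(v = 16L, delta = 0.25) # fallbacks when not tuned
    if (tune && any(c("frequency", "novelty") %in% todo$regime)) {
      tdata <- make_condition_dataset(cond, seeds[1])
      val <- split_train_test(tdata$train, 0.8,
                              derive_seed(seeds[1], "validation"))
      if (nrow(val$train$features) > tune_max_n) {
        set.seed(derive_seed(seeds[1], "tuning_subsample"))
        keep <- sort(sample.int(nrow(val$train$features), tune_max_n))
        val$train$features <- val$train$features[keep, , drop = FALSE]
        val$train$labels <- val$train$labels[keep]
      }
      for (rg in intersect(c("frequency", "novelty"), todo$regime)) {
        template <- regime_spec(rg, m = cond$m,
                                seed = derive_seed(seeds[1], "tuning"))
        tuned <- tryCatch(
          grid_search_hyperparams(val$train, val$test, template,
                                  v_grid = v_grid, delta_grid = delta_grid,
                                  ridge = ridge),
          kernelregimes_error = function(e) NULL)
        if (!is.null(tuned)) {
          if (rg == "frequency") hyper$v <- tuned$v else
            hyper$delta <- tuned$delta
        }
      }
    }

    # one dataset per (condition, seed), shared across regimes
    recs <- lapply(seeds, function(sd) {
      rg_todo <- todo$regime[todo$seed == sd]
      if (length(rg_todo) == 0L) return(NULL)
      data <- make_condition_dataset(cond, sd)
      do.call(rbind, lapply(rg_todo, function(rg) {
        tryCatch(
          run_condition(cond, rg, sd, v = hyper$v, delta = hyper$delta,
                        n_subsets = n_subsets, ridge = ridge,
                        activation = activation, svm_max_n = svm_max_n,
                        novelty_rule = novelty_rule, data = data),
          error = function(e) failed_record(cond, rg, sd, conditionMessage(e)))
      }))
    })
    out[[ci]] <- do.call(rbind, recs)
    if (!quiet)
      message(sprintf("condition K=%d m=%d n_irrelevant=%d done (%d records)",
                      cond$K, cond$m, cond$n_irrelevant, nrow(out[[ci]])))
  }
  results <- rbind(done, do.call(rbind, out))
  rownames(results) <- NULL

  if (!is.null(out_dir)) {
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    manifest <- list(regimes = regimes, seeds = seeds,
                     n_subsets = n_subsets, tune = tune, v_grid = v_grid,
                     delta_grid = delta_grid, ridge = ridge,
                     activation = activation, svm_max_n = svm_max_n,
                     novelty_rule = novelty_rule,
                     conditions = lapply(conditions, unclass),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "run-manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}

#' Rank regimes within and across grid cells
#'
#' Within each group (by default one grid cell: `K`, `m`,
#' `n_irrelevant`), regimes are ranked by mean test accuracy across seeds,
#' with exact ties broken by the lower accuracy variance (and, as a last
#' resort, regime name, for determinism).  The grand table averages each
#' regime's rank over all groups.  Rows with failed runs (`NA` accuracy)
#' are dropped; groups with fewer than two regimes are excluded with a
#' warning.
#'
#' @param results Result table from [run_grid()] /
#'   [run_condition()].
#' @param group_keys Columns defining a group.
#' @return List with `by_group` (one row per group x regime: mean, sd,
#'   n_seeds, rank) and `overall` (one row per regime: grand mean rank,
#'   grand mean accuracy).
#' @export
rank_regimes <- function(results, group_keys = c("K", "m", "n_irrelevant")) {
  results <- results[!is.na(results$test_accuracy), , drop = FALSE]
  if (nrow(results) == 0L)
    kr_stop("invalid_parameter", "no successful records to rank")
  gid <- interaction(results[group_keys], drop = TRUE)

  rows <- lapply(split(results, gid), function(g) {
    agg <- do.call(rbind, lapply(split(g, g$regime), function(r)
      data.frame(r[1, group_keys, drop = FALSE], regime = r$regime[1],
                 mean_accuracy = mean(r$test_accuracy),
                 sd_accuracy = if (nrow(r) > 1) stats::sd(r$test_accuracy) else 0,
                 n_seeds = nrow(r), stringsAsFactors = FALSE)))
    if (nrow(agg) < 2L) {
      warning("group with fewer than two regimes excluded from ranking")
      return(NULL)
    }
    ord <- order(-agg$mean_accuracy, agg$sd_accuracy, agg$regime)
    agg$rank <- integer(nrow(agg))
    agg$rank[ord] <- seq_len(nrow(agg))
    agg
  })
  by_group <- do.call(rbind, rows)
  rownames(by_group) <- NULL

  overall <- do.call(rbind, lapply(split(by_group, by_group$regime), function(r)
    data.frame(regime = r$regime[1], grand_mean_rank = mean(r$rank),
               grand_mean_accuracy = mean(r$mean_accuracy),
               n_groups = nrow(r), stringsAsFactors = FALSE)))
  overall <- overall[order(overall$grand_mean_rank), ]
  rownames(overall) <- NULL
  list(by_group = by_group, overall = overall)
}

#' Upper bound on attainable test accuracy under label noise
#'
#' With flip rate `r` on the test labels, no model can expect accuracy
#' above `1 - r`; this returns that ceiling plus a 4-standard-deviation
#' sampling allowance, `1 - r + 4 * sqrt(r * (1 - r) / n_test)`.
#'
#' @param label_noise_rate Flip rate `r`.
#' @param n_test Test-set size.
#' @return The ceiling value.
#' @export
noise_ceiling <- function(label_noise_rate, n_test) {
  r <- label_noise_rate
  1 - r + 4 * sqrt(r * (1 - r) / n_test)
}
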