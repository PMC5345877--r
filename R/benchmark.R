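#' Select held-out combinations for the imputation benchmark
#'
#' Picks `n_test + n_valid` active combinations such that (i) every TF and
#' cell line still occurs among the remaining training combinations, (ii)
#' the test combinations use distinct TFs and distinct cell lines, and
#' (iii) at most one TF of any shared-PWM pair is held out — two TFs with
#' identical PWMs are sequence-indistinguishable, so swapping one for the
#' other is not a valid wrong-TF control.
#'
#' @param world a `tfgate_world`.
#' @param n_test held-out test combinations (default 4).
#' @param n_valid extra held-out combinations used as the
#'   held-out-combination validation set (default 2).
#' @return list: `test`, `valid2`, `train` (data.frames `tf`, `cell`).
#' @export
select_holdout_combos <- function(world, n_test = 4L, n_valid = 2L) {
  grid <- expand.grid(tf = rownames(world$activity),
                      cell = colnames(world$activity),
                      stringsAsFactors = FALSE)
  active <- world$activity[cbind(grid$tf, grid$cell)] == 1L
  hold <- integer(0)
  for (i in which(active)) {
    if (length(hold) >= n_test + n_valid) break
    rest_active <- setdiff(which(active), c(hold, i))
    shared_with <- names(world$pwms)[vapply(world$pwms, identical, TRUE,
                                            world$pwms[[grid$tf[i]]])]
    ok <- if (length(hold) < n_test) {
      !any(shared_with %in% grid$tf[hold]) &&
        !(grid$cell[i] %in% grid$cell[hold[seq_len(min(n_test, length(hold)))]])
    } else {
      !any(shared_with %in% grid$tf[hold])
    }
    if (ok &&
        all(grid$tf[active] %in% grid$tf[rest_active]) &&
        all(grid$cell[active] %in% grid$cell[rest_active]))
      hold <- c(hold, i)
  }
  if (length(hold) < n_test + n_valid)
    stop("could not find a coverage-preserving holdout of the requested size")
  # training keeps every other combination, active or not: inactive
  # combinations carry uninformative labels (binding absent) and are what
  # teaches the model that activity is combination-specific
  train_idx <- setdiff(seq_len(nrow(grid)), hold)
  list(test = grid[hold[seq_len(n_test)], , drop = FALSE],
       valid2 = grid[hold[n_test + seq_len(n_valid)], , drop = FALSE],
       train = grid[train_idx, , drop = FALSE])
}

#' Run the scaled-down imputation benchmark
#'
#' The package's core end-to-end experiment: build a synthetic world, hold
#' out active (TF, cell line) combinations whose TF and cell line each
#' appear elsewhere, train the gated convolutional model on the remaining
#' active combinations, and measure binding prediction on the held-out
#' combinations together with the shuffled-TF and shuffled-cell-line
#' negative controls and the PWM log-odds oracle ceiling.
#'
#' Only active combinations contribute instances, mirroring real ChIP-seq
#' compendia where unprofiled combinations have no data.
#'
#' @param seed integer seed controlling the world, data, initialization and
#'   training order.
#' @param num_tfs,num_cells,motif_length,activity_density world parameters.
#' @param n_per_combo instances per active combination.
#' @param seq_length instance length (bp).
#' @param num_filters,filter_length,pool_window,fc_size model size.
#' @param epochs,eval_interval,batch_size training protocol.
#' @param n_valid1_per_combo fresh validation instances per training
#'   combination (within-combination checkpoint).
#' @param verbose print training progress.
#' @return list with `auc` (mean held-out per-combination AUC),
#'   `auc_per_combo`, `auc_shuf_tf`, `auc_shuf_cell`, `oracle_auc`
#'   (per-combination PWM-scan ceiling), `fit` (the `tfgate_fit`),
#'   `holdout`, `world`, `config`.
#' @export
run_imputation_benchmark <- function(seed,
                                     num_tfs = 8L, num_cells = 5L,
                                     motif_length = 8L,
                                     activity_density = 0.7,
                                     n_per_combo = 2000L,
                                     seq_length = 100L,
                                     num_filters = 64L, filter_length = 12L,
                                     pool_window = 100L, fc_size = 50L,
                                     epochs = 5L, eval_interval = 50000L,
                                     batch_size = 64L,
                                     n_valid1_per_combo = 100L,
                                     verbose = FALSE) {
  set.seed(seed)
  world <- make_world(num_tfs, num_cells, motif_length, activity_density,
                      seed = seed)
  hold <- select_holdout_combos(world, n_test = 4L, n_valid = 2L)
  train <- generate_instances(world, hold$train, n_per_combo, seq_length)
  valid1 <- generate_instances(world, hold$train, n_valid1_per_combo,
                               seq_length)
  valid2 <- generate_instances(world, hold$valid2, n_per_combo %/% 5L,
                               seq_length)
  test <- generate_instances(world, hold$test, n_per_combo, seq_length)

  config <- model_config(rownames(world$activity), colnames(world$activity),
                         seq_length = seq_length,
                         filter_length = filter_length,
                         num_filters = num_filters,
                         pool_window = pool_window, fc_size = fc_size)
  tc <- training_config(epochs = epochs, eval_interval = eval_interval,
                        batch_size = batch_size, verbose = verbose)
  fit <- train_model(train, valid1, valid2, config, tc)
  params <- fit$best_valid2$params

  combo <- paste(test$tf, test$cell)
  combo_auc <- function(scores)
    vapply(split(seq_len(nrow(test)), combo), function(ix)
      roc_auc(data.frame(score = scores[ix], label = test$label[ix])), 0.0)

  sc <- predict_batch(test$seq, test$tf, test$cell, params, config,
                      type = "score")
  auc_per_combo <- combo_auc(sc)

  sh_tf <- shuffle_field(test, "tf")
  sc_tf <- predict_batch(sh_tf$seq, sh_tf$tf, sh_tf$cell, params, config,
                         type = "score")
  sh_cell <- shuffle_field(test, "cell")
  sc_cell <- predict_batch(sh_cell$seq, sh_cell$tf, sh_cell$cell, params,
                           config, type = "score")

  oracle <- vapply(split(seq_len(nrow(test)), combo), function(ix) {
    tf <- test$tf[ix[1L]]
    s <- vapply(test$seq[ix], pwm_scan_score, 0.0, pwm = world$pwms[[tf]],
                base_probs = world$base_probs)
    roc_auc(data.frame(score = s, label = test$label[ix]))
  }, 0.0)

  list(auc = mean(auc_per_combo), auc_per_combo = auc_per_combo,
       auc_shuf_tf = mean(combo_auc(sc_tf)),
       auc_shuf_cell = mean(combo_auc(sc_cell)),
       oracle_auc = oracle, fit = fit, holdout = hold,
       world = world, config = config)
}
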