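#' Training configuration
#'
#' @param epochs passes over the training set (default 10; the
#'   random-background protocol uses 50).
#' @param eval_interval validation cadence, in instances seen (default
#'   50,000).
#' @param lr_decay multiplicative step-size decay applied once per
#'   `eval_interval` instances: the update scale is
#'   `(1 - lr_decay)^floor(seen / eval_interval)` (default 0.03).
#' @param adadelta_rho,adadelta_eps AdaDelta accumulator decay and
#'   conditioning constant (defaults 0.95 and 1e-6).
#' @param batch_size mini-batch size (default 64).
#' @param verbose print progress lines to standard error.
#' @param log_file optional TSV path receiving
#'   (instances_seen, loss, auc_valid1, auc_valid2) rows.
#' @return list of class `tfgate_train_config`.
#' @export
training_config <- function(epochs = 10L, eval_interval = 50000L,
                            lr_decay = 0.03, adadelta_rho = 0.95,
                            adadelta_eps = 1e-6, batch_size = 64L,
                            verbose = FALSE, log_file = NULL) {
  stopifnot(lr_decay >= 0, lr_decay < 1, eval_interval >= batch_size,
            epochs >= 1L, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs),
                 eval_interval = as.integer(eval_interval),
                 lr_decay = lr_decay, adadelta_rho = adadelta_rho,
                 adadelta_eps = adadelta_eps,
                 batch_size = as.integer(batch_size),
                 verbose = verbose, log_file = log_file),
            class = "tfgate_train_config")
}

#' Step-size schedule
#'
#' `scale = (1 - decay)^floor(instances_seen / interval)`.  AdaDelta has no
#' base learning rate, so the scale multiplies the computed update.  With
#' `decay = 0` the schedule is identically 1.
#'
#' @param instances_seen non-negative instance counter.
#' @param decay per-interval decay fraction in [0,1).
#' @param interval instances per decay step.
#' @return numeric scale in (0,1].
#' @export
lr_schedule <- function(instances_seen, decay = 0.03, interval = 50000L) {
  (1 - decay)^floor(instances_seen / interval)
}

# fresh AdaDelta state matching a parameter list
adadelta_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(Eg = zero, Ex = zero)
}

#' One AdaDelta update
#'
#' Standard AdaDelta: accumulate squared gradients, compute
#' `delta = -sqrt((Ex + eps)/(Eg + eps)) * g`, accumulate squared (unscaled)
#' deltas, and apply `scale * delta` to the parameters.  `scale` carries the
#' external step-size schedule.
#'
#' @param params named list of numeric arrays.
#' @param grads matching named list of gradients.
#' @param state list with accumulators `Eg`, `Ex` (see `adadelta_init`).
#' @param rho,eps AdaDelta constants.
#' @param scale external step-size multiplier.
#' @return list `(params, state)` after the update.
#' @export
adadelta_step <- function(params, grads, state, rho = 0.95, eps = 1e-6,
                          scale = 1) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (any(!is.finite(g)))
      stop("non-finite gradient in parameter group '", nm, "'")
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g * g
    delta <- -sqrt((state$Ex[[nm]] + eps) / (state$Eg[[nm]] + eps)) * g
    state$Ex[[nm]] <- rho * state$Ex[[nm]] + (1 - rho) * delta * delta
    params[[nm]] <- params[[nm]] + scale * delta
  }
  list(params = params, state = state)
}

# resolve instance table names -> integer id vectors against the vocab
.instance_ids <- function(instances, config) {
  list(tf = vapply(as.character(instances$tf), .entity_index, 0L,
                   vocab = config$tf_vocab, what = "TF", USE.NAMES = FALSE),
       cell = vapply(as.character(instances$cell), .entity_index, 0L,
                     vocab = config$cell_vocab, what = "cell line",
                     USE.NAMES = FALSE))
}

# AUC of the current parameters on an instance table (pooled over instances)
.eval_auc <- function(instances, params, config) {
  if (is.null(instances) || nrow(instances) == 0L) return(NA_real_)
  sc <- predict_batch(instances$seq, instances$tf, instances$cell,
                      params, config, type = "score")
  roc_auc(data.frame(score = sc, label = instances$label))
}

#' Train the gated convolutional binding model
#'
#' Mini-batch AdaDelta training with the dual-validation checkpoint
#' protocol: every `eval_interval` instances the pooled AUC on both
#' validation sets is computed and two running-best parameter snapshots are
#' maintained.  The checkpoint best on `validset1` (instances from
#' combinations present in training) is intended for within-combination test
#' sets; the checkpoint best on `validset2` (held-out combinations) for the
#' imputation test set.
#'
#' @param instances training instance table with columns
#'   `label` (0/1), `tf`, `cell`, `seq`.
#' @param validset1,validset2 instance tables of the same shape (either may
#'   be NULL, in which case its checkpoint tracks the other/last state).
#' @param config a `tfgate_config`.
#' @param train_config a `tfgate_train_config`.
#' @param params optional warm-start parameters (default: fresh
#'   [init_parameters()]).
#' @param max_instances optional hard cap on instances processed (used by
#'   [merge_and_retrain()] to honor an early-stop point).
#' @return list of class `tfgate_fit`:
#'   `best_valid1`/`best_valid2` (checkpoints: `params`, `metric`,
#'   `instances_seen`), `final_params`, `log` (data.frame), `config`.
#' @export
train_model <- function(instances, validset1 = NULL, validset2 = NULL,
                        config, train_config = training_config(),
                        params = NULL, max_instances = Inf) {
  if (is.null(instances) || nrow(instances) == 0L)
    stop("empty training set")
  tc <- train_config
  if (is.null(params)) params <- init_parameters(config)
  state <- adadelta_init(params)
  ids <- .instance_ids(instances, config)
  codes_all <- .codes_matrix(instances$seq, config$seq_length)
  labels <- as.numeric(instances$label)
  n <- nrow(instances)

  best1 <- list(params = params, metric = -Inf, instances_seen = 0L)
  best2 <- list(params = params, metric = -Inf, instances_seen = 0L)
  seen <- 0
  next_eval <- tc$eval_interval
  log <- list()
  run_loss <- 0; run_n <- 0

  evaluate <- function() {
    a1 <- .eval_auc(validset1, params, config)
    a2 <- .eval_auc(validset2, params, config)
    if (!is.na(a1) && a1 > best1$metric)
      best1 <<- list(params = params, metric = a1, instances_seen = seen)
    if (!is.na(a2) && a2 > best2$metric)
      best2 <<- list(params = params, metric = a2, instances_seen = seen)
    mloss <- if (run_n > 0) run_loss / run_n else NA_real_
    log[[length(log) + 1L]] <<- data.frame(
      instances_seen = seen, loss = mloss, auc_valid1 = a1, auc_valid2 = a2)
    if (tc$verbose)
      message(sprintf("seen=%d loss=%.4f auc1=%.4f auc2=%.4f",
                      seen, mloss, a1, a2))
    run_loss <<- 0; run_n <<- 0
  }

  done <- FALSE
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = tc$batch_size)) {
      sel <- ord[s:min(s + tc$batch_size - 1L, n)]
      fw <- forward_batch(codes_all[sel, , drop = FALSE],
                          ids$tf[sel], ids$cell[sel], params, config)
      l <- bce_loss(fw$score, labels[sel])
      grads <- backward_batch(l$dscore, fw, params, config)
      scale <- lr_schedule(seen, tc$lr_decay, tc$eval_interval)
      upd <- adadelta_step(params, grads, state,
                           rho = tc$adadelta_rho, eps = tc$adadelta_eps,
                           scale = scale)
      params <- upd$params; state <- upd$state
      seen <- seen + length(sel)
      run_loss <- run_loss + l$loss * length(sel); run_n <- run_n + length(sel)
      if (seen >= next_eval) {
        evaluate()
        next_eval <- next_eval + tc$eval_interval
      }
      if (seen >= max_instances) { done <- TRUE; break }
    }
    if (done) break
  }
  evaluate()  # final state is always a checkpoint candidate
  if (!is.finite(best1$metric)) best1 <- list(params = params, metric = NA_real_,
                                              instances_seen = seen)
  if (!is.finite(best2$metric)) best2 <- list(params = params, metric = NA_real_,
                                              instances_seen = seen)
  log <- do.call(rbind, log)
  if (!is.null(tc$log_file))
    utils::write.table(log, tc$log_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  structure(list(best_valid1 = best1, best_valid2 = best2,
                 final_params = params, log = log, config = config),
            class = "tfgate_fit")
}

#' Merge all partitions and retrain to a validated stop point
#'
#' Phase 1 trains on the merged non-validation data while monitoring the
#' held-out-combination validation set to find the early-stop point (the
#' instance count of the best checkpoint).  Phase 2 restarts from a fresh
#' initialization under the same seed discipline and trains on everything —
#' including the validation instances — for exactly that many instances.
#'
#' @param all_sets list of instance tables to merge (e.g. train, test1,
#'   valid1, test2, test3).
#' @param validset2 held-out-combination validation instances.
#' @param config,train_config model / training configuration.
#' @return list: `params` (final model), `stop_point` (instances), and the
#'   phase-1 `tfgate_fit`.
#' @export
merge_and_retrain <- function(all_sets, validset2, config,
                              train_config = training_config()) {
  merged <- do.call(rbind, all_sets)
  fit1 <- train_model(merged, validset1 = NULL, validset2 = validset2,
                      config = config, train_config = train_config)
  stop_point <- fit1$best_valid2$instances_seen
  if (stop_point <= 0) stop_point <- train_config$batch_size
  everything <- rbind(merged, validset2)
  fit2 <- train_model(everything, validset1 = NULL, validset2 = NULL,
                      config = config, train_config = train_config,
                      max_instances = stop_point)
  list(params = fit2$final_params, stop_point = stop_point,
       phase1 = fit1, phase2 = fit2)
}
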