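#' Configuration for the multi-TF CNN-RNN variant
#'
#' The long-sequence variant predicts all TFs at once for one cell line:
#' the cell-line embedding has length equal to the number of filters and is
#' passed through a sigmoid to give the gates directly; the gated pooled
#' signal (non-overlapping windows of 50 convolution positions) is fed as a
#' sequence into a GRU, and the last hidden state maps linearly to one
#' output per TF.  Production scale (1,000 bp input, 2,000 filters, hidden
#' size 1,000) is supported by configuration; tests run it scaled down.
#'
#' @param tf_vocab,cell_vocab entity names.
#' @param seq_length input length in bp (default 1000).
#' @param filter_length filter length in bp.
#' @param num_filters number of filters K (= cell embedding length).
#' @param pool_window pooling window in convolution positions (default 50).
#' @param gru_hidden GRU hidden size (default 1000).
#' @param relu_mode rectifier mode as in [model_config()].
#' @return object of class `tfgate_mt_config`.
#' @export
multi_tf_config <- function(tf_vocab, cell_vocab, seq_length = 1000L,
                            filter_length = 20L, num_filters = 2000L,
                            pool_window = 50L, gru_hidden = 1000L,
                            relu_mode = c("literal", "shifted")) {
  relu_mode <- match.arg(relu_mode)
  stopifnot(filter_length <= seq_length, gru_hidden >= 1L)
  structure(list(tf_vocab = as.character(tf_vocab),
                 cell_vocab = as.character(cell_vocab),
                 seq_length = as.integer(seq_length),
                 filter_length = as.integer(filter_length),
                 num_filters = as.integer(num_filters),
                 pool_window = as.integer(pool_window),
                 gru_hidden = as.integer(gru_hidden),
                 relu_mode = relu_mode),
            class = "tfgate_mt_config")
}

#' Initialize multi-TF variant parameters
#'
#' Same initialization discipline as the main model: weights
#' Normal(0, 0.01^2), rectifier thresholds -4, other biases 0.
#'
#' @param config a `tfgate_mt_config`.
#' @return list of parameter arrays (class `tfgate_mt_params`).
#' @export
init_multi_tf_parameters <- function(config) {
  K <- config$num_filters; h <- config$gru_hidden
  Tn <- length(config$tf_vocab)
  sd0 <- 0.01
  mk <- function(nr, nc) matrix(rnorm(nr * nc, 0, sd0), nr, nc)
  params <- list(
    E_cell = matrix(rnorm(length(config$cell_vocab) * K, 0, sd0),
                    nrow = length(config$cell_vocab),
                    dimnames = list(config$cell_vocab, NULL)),
    W = array(rnorm(config$filter_length * 4L * K, 0, sd0),
              dim = c(config$filter_length, 4L, K),
              dimnames = list(NULL, DNA_BASES, NULL)),
    b = rep(-4, K),
    Wz = mk(h, K), Uz = mk(h, h), bz = rep(0, h),
    Wr = mk(h, K), Ur = mk(h, h), br = rep(0, h),
    Wh = mk(h, K), Uh = mk(h, h), bh = rep(0, h),
    Wo = mk(Tn, h), bo = rep(0, Tn)
  )
  class(params) <- "tfgate_mt_params"
  params
}

# adapter so .strand_forward can be reused for the variant
.mt_as_config <- function(config) {
  list(filter_length = config$filter_length,
       num_filters = config$num_filters,
       pool_window = config$pool_window,
       relu_mode = config$relu_mode)
}

# GRU over time-major list of B x K inputs; returns last hidden + caches
.gru_forward <- function(xs, params, want_cache = TRUE) {
  B <- nrow(xs[[1L]])
  h <- length(params$bz)
  hprev <- matrix(0, B, h)
  cache <- list()
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    az <- x %*% t(params$Wz) + hprev %*% t(params$Uz) +
      matrix(params$bz, B, h, byrow = TRUE)
    ar <- x %*% t(params$Wr) + hprev %*% t(params$Ur) +
      matrix(params$br, B, h, byrow = TRUE)
    z <- plogis(az); r <- plogis(ar)
    ac <- x %*% t(params$Wh) + (r * hprev) %*% t(params$Uh) +
      matrix(params$bh, B, h, byrow = TRUE)
    cc <- tanh(ac)
    hnew <- (1 - z) * hprev + z * cc
    if (want_cache)
      cache[[t]] <- list(x = x, hprev = hprev, z = z, r = r, cc = cc)
    hprev <- hnew
  }
  list(h = hprev, cache = cache)
}

# BPTT; returns gradients for GRU params and the per-step input grads
.gru_backward <- function(dh, cache, params) {
  h <- length(params$bz)
  zeros <- function(m) { m[] <- 0; m }
  g <- list(Wz = zeros(params$Wz), Uz = zeros(params$Uz), bz = rep(0, h),
            Wr = zeros(params$Wr), Ur = zeros(params$Ur), br = rep(0, h),
            Wh = zeros(params$Wh), Uh = zeros(params$Uh), bh = rep(0, h))
  dxs <- vector("list", length(cache))
  for (t in rev(seq_along(cache))) {
    st <- cache[[t]]
    dz <- dh * (st$cc - st$hprev)
    dcc <- dh * st$z
    dhprev <- dh * (1 - st$z)
    dac <- dcc * (1 - st$cc^2)
    drh <- dac %*% params$Uh
    dr <- drh * st$hprev
    dhprev <- dhprev + drh * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    dx <- dac %*% params$Wh + daz %*% params$Wz + dar %*% params$Wr
    dhprev <- dhprev + daz %*% params$Uz + dar %*% params$Ur
    g$Wh <- g$Wh + t(dac) %*% st$x
    g$Uh <- g$Uh + t(dac) %*% (st$r * st$hprev)
    g$bh <- g$bh + colSums(dac)
    g$Wz <- g$Wz + t(daz) %*% st$x
    g$Uz <- g$Uz + t(daz) %*% st$hprev
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + t(dar) %*% st$x
    g$Ur <- g$Ur + t(dar) %*% st$hprev
    g$br <- g$br + colSums(dar)
    dxs[[t]] <- dx
    dh <- dhprev
  }
  list(grads = g, dxs = dxs)
}

# full forward for one strand; returns per-TF scores and caches
.mt_strand_forward <- function(codes, cell_ids, params, config, want_cache) {
  st <- .strand_forward(codes, params, .mt_as_config(config), want_cache)
  B <- nrow(codes); K <- config$num_filters; nw <- st$nw
  G <- plogis(params$E_cell[cell_ids, , drop = FALSE])   # B x K gates
  xs <- lapply(seq_len(nw), function(w)
    st$P[, (w - 1L) * K + seq_len(K), drop = FALSE] * G)
  gr <- .gru_forward(xs, params, want_cache)
  O <- gr$h %*% t(params$Wo) +
    matrix(params$bo, B, length(config$tf_vocab), byrow = TRUE)
  list(O = O, st = st, G = G, xs = xs, gru = gr)
}

#' Multi-TF forward pass
#'
#' Scores one batch of sequences in given cell lines for every TF in the
#' vocabulary simultaneously; strand-symmetric via the elementwise maximum
#' of the forward- and reverse-strand outputs.
#'
#' @param seqs character vector of sequences.
#' @param cells cell-line names (recycled).
#' @param params,config variant parameters / configuration.
#' @return list: `score` (matrix, sequences x TFs), `gates` (matrix in
#'   (0,1)).
#' @export
multi_tf_forward <- function(seqs, cells, params, config) {
  B <- length(seqs)
  cells <- rep_len(cells, B)
  ci <- vapply(cells, .entity_index, 0L, vocab = config$cell_vocab,
               what = "cell line")
  codes <- .codes_matrix(seqs, config$seq_length)
  rc <- t(apply(codes, 1L, revcomp_codes))
  if (B == 1L) rc <- matrix(rc, 1L)
  f <- .mt_strand_forward(codes, ci, params, config, want_cache = FALSE)
  r <- .mt_strand_forward(rc, ci, params, config, want_cache = FALSE)
  score <- pmax(f$O, r$O)
  colnames(score) <- config$tf_vocab
  list(score = score, gates = f$G)
}

# internal: forward with caches + backward for training
.mt_train_step <- function(codes, rc, ci, labels, params, config) {
  B <- nrow(codes)
  f <- .mt_strand_forward(codes, ci, params, config, want_cache = TRUE)
  r <- .mt_strand_forward(rc, ci, params, config, want_cache = TRUE)
  use_f <- f$O >= r$O
  score <- ifelse(use_f, f$O, r$O)
  p <- plogis(score)
  eps <- 1e-12
  loss <- -mean(labels * log(p + eps) + (1 - labels) * log(1 - p + eps))
  dscore <- (p - labels) / length(score)

  zero_like <- function(x) { x[] <- 0; x }
  grads <- lapply(params, zero_like)
  dG <- matrix(0, B, config$num_filters)
  for (side in list(list(s = f, d = dscore * use_f),
                    list(s = r, d = dscore * (!use_f)))) {
    s <- side$s; dO <- side$d
    grads$Wo <- grads$Wo + t(dO) %*% s$gru$h
    grads$bo <- grads$bo + colSums(dO)
    dh <- dO %*% params$Wo
    bp <- .gru_backward(dh, s$gru$cache, params)
    for (nm in names(bp$grads)) grads[[nm]] <- grads[[nm]] + bp$grads[[nm]]
    # through the gates and pooled conv signal
    K <- config$num_filters
    st <- s$st
    dP <- matrix(0, B, st$nw * K)
    for (w in seq_len(st$nw)) {
      dx <- bp$dxs[[w]]
      cols <- (w - 1L) * K + seq_len(K)
      dP[, cols] <- dx * s$G                       # x_w = P_w * G
      dG <- dG + dx * st$P[, cols, drop = FALSE]
    }
    bpc <- conv_pool_backward_cpp(st$codes, st$argmax, st$mask, dP,
                                  config$filter_length, K,
                                  config$relu_mode == "literal")
    grads$W <- grads$W + array(bpc$dW, dim = dim(params$W))
    grads$b <- grads$b + bpc$db
  }
  dGpre <- dG * f$G * (1 - f$G)        # gates = sigmoid(E_cell row)
  gec <- rowsum(dGpre, group = ci)
  grads$E_cell <- zero_like(params$E_cell)
  grads$E_cell[as.integer(rownames(gec)), ] <- gec
  list(loss = loss, grads = grads)
}

#' Train the multi-TF variant
#'
#' Plain mini-batch AdaDelta over multi-label instances; no dual-checkpoint
#' protocol (the variant selects its best state on a single validation set
#' when one is supplied).
#'
#' @param seqs,cells,labels training data: sequences, their cell lines, and
#'   a sequences x TFs 0/1 label matrix.
#' @param config a `tfgate_mt_config`.
#' @param epochs,batch_size,lr_decay,eval_interval training knobs (same
#'   semantics as [training_config()]).
#' @param valid optional list(seqs, cells, labels) monitored each epoch.
#' @param verbose print per-epoch loss.
#' @return list: `params`, `log` (data.frame epoch/loss/valid_auc).
#' @export
train_multi_tf <- function(seqs, cells, labels, config, epochs = 5L,
                           batch_size = 32L, lr_decay = 0.01,
                           eval_interval = 200000L, valid = NULL,
                           verbose = FALSE) {
  stopifnot(nrow(labels) == length(seqs),
            ncol(labels) == length(config$tf_vocab))
  params <- init_multi_tf_parameters(config)
  state <- adadelta_init(params)
  ci <- vapply(rep_len(cells, length(seqs)), .entity_index, 0L,
               vocab = config$cell_vocab, what = "cell line")
  codes_all <- .codes_matrix(seqs, config$seq_length)
  n <- length(seqs)
  seen <- 0
  log <- list()
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (s in seq(1L, n, by = batch_size)) {
      sel <- ord[s:min(s + batch_size - 1L, n)]
      codes <- codes_all[sel, , drop = FALSE]
      rc <- t(apply(codes, 1L, revcomp_codes))
      if (length(sel) == 1L) rc <- matrix(rc, 1L)
      stp <- .mt_train_step(codes, rc, ci[sel],
                            labels[sel, , drop = FALSE], params, config)
      scale <- lr_schedule(seen, lr_decay, eval_interval)
      upd <- adadelta_step(params, stp$grads, state, scale = scale)
      params <- upd$params; state <- upd$state
      seen <- seen + length(sel)
      ep_loss <- ep_loss + stp$loss * length(sel); ep_n <- ep_n + length(sel)
    }
    vauc <- NA_real_
    if (!is.null(valid)) {
      sc <- multi_tf_forward(valid$seqs, valid$cells, params, config)$score
      aucs <- vapply(seq_len(ncol(sc)), function(j) {
        rec <- data.frame(score = sc[, j], label = valid$labels[, j])
        if (length(unique(rec$label)) < 2L) return(NA_real_)
        roc_auc(rec)
      }, 0.0)
      vauc <- mean(aucs, na.rm = TRUE)
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / ep_n,
                               valid_auc = vauc)
    if (verbose)
      message(sprintf("epoch %d loss=%.4f valid_auc=%.4f",
                      epoch, ep_loss / ep_n, vauc))
  }
  list(params = params, log = do.call(rbind, log))
}
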