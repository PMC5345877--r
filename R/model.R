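#' Model configuration
#'
#' Collects the architecture hyperparameters of the gated convolutional
#' binding model.  Defaults follow the open-chromatin-background
#' configuration: 300 bp input, filter (motif) length 20, 2,000 filters,
#' max-pooling window of 100 convolution positions (hence three pooled
#' values per filter), 50-unit fully connected output layer, and
#' 50-dimensional embeddings per entity.  The random-background variant uses
#' `seq_length = 100`, `num_filters = 600` (one pooled value per filter).
#'
#' @param tf_vocab,cell_vocab character vectors naming the transcription
#'   factors and cell lines the model can be asked about (order defines the
#'   embedding row index).
#' @param seq_length model input length N in bp.
#' @param filter_length filter (motif detector) length F in bp; must be <= N.
#' @param num_filters number of convolution filters K.
#' @param pool_window max-pooling window, in convolution output positions.
#' @param fc_size size of the fully connected output layer; the model score
#'   is the maximum over its outputs.
#' @param embed_dim embedding dimension per entity (TF or cell line); the
#'   concatenated embedding has length `2 * embed_dim`.
#' @param relu_mode `"literal"` applies the thresholded rectifier exactly as
#'   printed (passes x itself whenever x > b, even when negative);
#'   `"shifted"` applies `max(0, x - b)`.  See [thresholded_relu()].
#' @return an object of class `tfgate_config`.
#' @export
model_config <- function(tf_vocab, cell_vocab,
                         seq_length = 300L, filter_length = 20L,
                         num_filters = 2000L, pool_window = 100L,
                         fc_size = 50L, embed_dim = 50L,
                         relu_mode = c("literal", "shifted")) {
  relu_mode <- match.arg(relu_mode)
  tf_vocab <- as.character(tf_vocab)
  cell_vocab <- as.character(cell_vocab)
  stopifnot(length(tf_vocab) >= 1L, length(cell_vocab) >= 1L,
            !anyDuplicated(tf_vocab), !anyDuplicated(cell_vocab),
            filter_length >= 1L, filter_length <= seq_length,
            num_filters >= 1L, pool_window >= 1L, fc_size >= 1L,
            embed_dim >= 1L)
  cfg <- list(seq_length = as.integer(seq_length),
              filter_length = as.integer(filter_length),
              num_filters = as.integer(num_filters),
              pool_window = as.integer(pool_window),
              fc_size = as.integer(fc_size),
              embed_dim = as.integer(embed_dim),
              tf_vocab = tf_vocab, cell_vocab = cell_vocab,
              relu_mode = relu_mode)
  class(cfg) <- "tfgate_config"
  cfg
}

#' Number of convolution output positions and pooled windows
#'
#' For input length N and filter length F the convolution emits N-F+1
#' positions; non-overlapping pooling windows of `pool_window` positions
#' give `ceiling((N-F+1)/pool_window)` pooled values per filter (the last
#' window may be shorter).
#'
#' @param config a `tfgate_config`.
#' @return list with elements `conv_positions` and `num_windows`.
#' @export
model_geometry <- function(config) {
  r <- config$seq_length - config$filter_length + 1L
  list(conv_positions = r,
       num_windows = as.integer(ceiling(r / config$pool_window)))
}

#' Initialize model parameters
#'
#' All weight matrices are drawn i.i.d. Normal(0, 0.01^2); the per-filter
#' rectifier thresholds `b` start at -4 and all other biases at 0.
#'
#' @param config a `tfgate_config`.
#' @return an object of class `tfgate_params`: list with entries
#'   `E_tf` (|TF| x d), `E_cell` (|cell| x d), `W` (array F x 4 x K, column
#'   order A,C,G,T), `b` (K rectifier thresholds), `W1` (K x 2d), `b1` (K),
#'   `W2` (fc_size x K*num_windows), `b2` (fc_size).
#' @export
init_parameters <- function(config) {
  g <- model_geometry(config)
  d <- config$embed_dim
  K <- config$num_filters
  sd0 <- 0.01
  params <- list(
    E_tf = matrix(rnorm(length(config$tf_vocab) * d, 0, sd0),
                  nrow = length(config$tf_vocab),
                  dimnames = list(config$tf_vocab, NULL)),
    E_cell = matrix(rnorm(length(config$cell_vocab) * d, 0, sd0),
                    nrow = length(config$cell_vocab),
                    dimnames = list(config$cell_vocab, NULL)),
    W = array(rnorm(config$filter_length * 4L * K, 0, sd0),
              dim = c(config$filter_length, 4L, K),
              dimnames = list(NULL, DNA_BASES, NULL)),
    b = rep(-4, K),
    W1 = matrix(rnorm(K * 2L * d, 0, sd0), nrow = K),
    b1 = rep(0, K),
    W2 = matrix(rnorm(config$fc_size * K * g$num_windows, 0, sd0),
                nrow = config$fc_size),
    b2 = rep(0, config$fc_size)
  )
  class(params) <- "tfgate_params"
  params
}

#' Valid convolution of a one-hot sequence with a filter bank
#'
#' `Y[r, k] = sum_{i=1..F} sum_{j=1..4} W[i, j, k] * X[r+i-1, j]` for
#' r = 1 .. N-F+1 (no padding).
#'
#' @param X one-hot matrix, N x 4 (column order A,C,G,T).
#' @param W filter bank, array F x 4 x K.
#' @return feature map, (N-F+1) x K numeric matrix.
#' @export
convolve_onehot <- function(X, W) {
  stopifnot(is.matrix(X), ncol(X) == 4L, is.array(W), length(dim(W)) == 3L,
            dim(W)[2] == 4L)
  n <- nrow(X)
  f <- dim(W)[1]
  k <- dim(W)[3]
  if (n < f) stop(sprintf("sequence length %d shorter than filter length %d", n, f))
  r <- n - f + 1L
  Y <- matrix(0, r, k)
  Wm <- matrix(W, nrow = f * 4L, ncol = k)   # rows ordered i-major then j
  Xs <- matrix(X, nrow = n)                  # ensure numeric matrix
  for (i in seq_len(f)) {
    # rows i..i+r-1 of X against the 4 x K slice for offset i
    Wi <- Wm[i + f * (0:3), , drop = FALSE]
    Y <- Y + Xs[i:(i + r - 1L), , drop = FALSE] %*% Wi
  }
  Y
}

#' Thresholded rectifier
#'
#' The literal form returns `x` whenever `x > b` and 0 otherwise — note that
#' with a negative threshold (it is initialized at -4) this passes negative
#' values.  The shifted form returns `max(0, x - b)`.  Per-filter thresholds
#' reflect that different motifs have different binding affinities.
#'
#' @param x numeric vector/matrix of convolution outputs.
#' @param b threshold(s); recycled against `x` (for a matrix with filters in
#'   columns pass a length-`ncol` vector to `sweep` yourself, or use the
#'   internal batched path).
#' @param mode `"literal"` or `"shifted"`.
#' @return numeric of the same shape as `x`.
#' @export
thresholded_relu <- function(x, b, mode = c("literal", "shifted")) {
  mode <- match.arg(mode)
  if (mode == "literal") ifelse(x > b, x, 0) else pmax(x - b, 0)
}

# Apply the rectifier column-wise (filters in columns, per-filter threshold).
.relu_cols <- function(Y, b, mode) {
  thr <- matrix(b, nrow = nrow(Y), ncol = length(b), byrow = TRUE)
  if (mode == "literal") Y * (Y > thr) else (Y - thr) * (Y > thr)
}

#' Max-pooling over non-overlapping windows
#'
#' Partitions the convolution output rows into consecutive windows of
#' `pool_window` rows (the last window may be shorter) and takes, per
#' filter, the maximum in each window.
#'
#' @param Z feature map, (N-F+1) x K.
#' @param pool_window window size in rows, >= 1.
#' @return num_windows x K matrix of pooled maxima.
#' @export
max_pool <- function(Z, pool_window) {
  stopifnot(pool_window >= 1L)
  r <- nrow(Z)
  nw <- ceiling(r / pool_window)
  out <- matrix(-Inf, nw, ncol(Z))
  for (w in seq_len(nw)) {
    rows <- (((w - 1L) * pool_window + 1L):min(w * pool_window, r))
    sub <- Z[rows, , drop = FALSE]
    out[w, ] <- apply(sub, 2L, max)
  }
  out
}

#' Concatenated TF / cell-line embedding
#'
#' Looks up the embedding row of the TF and of the cell line and
#' concatenates them, TF half first; length `2 * embed_dim`.
#'
#' @param tf,cell entity names (or 1-based integer indices).
#' @param params a `tfgate_params`.
#' @return numeric vector of length `2 * embed_dim`.
#' @export
embed_pair <- function(tf, cell, params) {
  ti <- .entity_index(tf, rownames(params$E_tf), "TF")
  ci <- .entity_index(cell, rownames(params$E_cell), "cell line")
  c(params$E_tf[ti, ], params$E_cell[ci, ])
}

.entity_index <- function(x, vocab, what) {
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (i < 1L || i > length(vocab))
      stop(sprintf("%s index %d outside vocabulary of size %d", what, i, length(vocab)))
    return(i)
  }
  i <- match(x, vocab)
  if (is.na(i))
    stop(sprintf("unknown %s '%s': the model cannot be applied to entities absent from training", what, x))
  i
}

#' Per-filter gates from the concatenated embedding
#'
#' `G = sigmoid(W1 e + b1)`; every gate lies strictly in (0, 1).
#'
#' @param e concatenated embedding vector (length 2*embed_dim).
#' @param W1 K x 2*embed_dim gate weights.
#' @param b1 K gate biases.
#' @return numeric vector of K gates in (0,1).
#' @export
compute_gates <- function(e, W1, b1) {
  plogis(drop(W1 %*% e) + b1)
}

#' Single-strand score of a sequence for a (TF, cell line) pair
#'
#' Reference (single-instance) forward pass: one-hot encode, convolve,
#' rectify, max-pool, multiply each filter's pooled values by its gate (the
#' same gate operates on all pooled windows of a filter), then take the
#' maximum output of the fully connected layer `W2 vec(M) + b2`.
#'
#' @param seq character sequence of exactly the configured model length.
#' @param tf,cell entity names or indices.
#' @param params a `tfgate_params`.
#' @param config a `tfgate_config`.
#' @return a single numeric score.
#' @export
strand_score <- function(seq, tf, cell, params, config) {
  if (nchar(seq) != config$seq_length)
    stop(sprintf("sequence length %d does not match model input length %d",
                 nchar(seq), config$seq_length))
  X <- one_hot_encode(seq)
  Y <- convolve_onehot(X, params$W)
  Z <- .relu_cols(Y, params$b, config$relu_mode)
  P <- max_pool(Z, config$pool_window)            # nw x K
  e <- embed_pair(tf, cell, params)
  G <- compute_gates(e, params$W1, params$b1)     # K
  M <- sweep(P, 2L, G, `*`)                       # gate broadcast over windows
  # vec(M) with window-major blocks: (w1 filters 1..K, w2 filters 1..K, ...)
  v <- as.vector(t(M))
  dim(v) <- NULL
  max(drop(params$W2 %*% v) + params$b2)
}

#' Strand-symmetric binding score and probability
#'
#' The model score is the maximum of the single-strand score on the sequence
#' and on its reverse complement, so predictions are exactly invariant under
#' reverse complementation.  `predict_prob()` maps the score through the
#' logistic function.
#'
#' @inheritParams strand_score
#' @return `predict_score()`: a numeric score; `predict_prob()`: a binding
#'   probability in (0,1).
#' @export
predict_score <- function(seq, tf, cell, params, config) {
  max(strand_score(seq, tf, cell, params, config),
      strand_score(reverse_complement(seq), tf, cell, params, config))
}

#' @rdname predict_score
#' @export
predict_prob <- function(seq, tf, cell, params, config) {
  plogis(predict_score(seq, tf, cell, params, config))
}

#' Batched binding predictions
#'
#' Vectorized forward pass over many (sequence, TF, cell) triples; exactly
#' equivalent to calling [predict_score()] per instance but far faster.
#'
#' @param seqs character vector of sequences of the model length.
#' @param tfs,cells entity names or indices, recycled to `length(seqs)`.
#' @param params,config model parameters and configuration.
#' @param type `"score"` or `"prob"`.
#' @param batch_size internal mini-batch size.
#' @return numeric vector of scores or probabilities.
#' @export
predict_batch <- function(seqs, tfs, cells, params, config,
                          type = c("prob", "score"), batch_size = 256L) {
  type <- match.arg(type)
  n <- length(seqs)
  tfs <- rep_len(tfs, n); cells <- rep_len(cells, n)
  ti <- vapply(tfs, .entity_index, 0L, vocab = rownames(params$E_tf), what = "TF")
  ci <- vapply(cells, .entity_index, 0L, vocab = rownames(params$E_cell), what = "cell line")
  codes <- .codes_matrix(seqs, config$seq_length)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fw <- forward_batch(codes[s:e, , drop = FALSE], ti[s:e], ci[s:e],
                        params, config, want_cache = FALSE)
    out[s:e] <- fw$score
  }
  if (type == "prob") plogis(out) else out
}

# character sequences -> B x N integer code matrix (with validation)
.codes_matrix <- function(seqs, seq_length) {
  B <- length(seqs)
  m <- matrix(0L, B, seq_length)
  for (i in seq_len(B)) {
    codes <- seq_to_codes(seqs[[i]])
    if (length(codes) != seq_length)
      stop(sprintf("sequence %d has length %d; model input length is %d",
                   i, length(codes), seq_length))
    m[i, ] <- codes
  }
  m
}

# ---------------------------------------------------------------------------
# Batched forward / backward pass (the training hot path).  Layout notes:
#  * codes: B x N integer matrix (0 = N base).
#  * conv feature maps are stored as (B*R) x K matrices with row index
#    (b-1)*R + r, i.e. position r varies fastest within an instance.
#  * pooled maps are B x (nw*K) with column index (w-1)*K + k.
# ---------------------------------------------------------------------------

# one strand's conv+relu+pool (compiled kernel) with caches for backprop
.strand_forward <- function(codes, params, config, want_cache) {
  cp <- conv_pool_forward_cpp(codes, as.vector(params$W), params$b,
                              config$filter_length, config$num_filters,
                              config$pool_window,
                              config$relu_mode == "literal")
  res <- list(P = cp$P, B = nrow(codes), R = cp$R, nw = cp$nw,
              K = config$num_filters)
  if (want_cache) {
    res$argmax <- cp$argmax; res$mask <- cp$mask; res$codes <- codes
  }
  res
}

# forward through gates + fc for both strands; returns per-instance score
forward_batch <- function(codes, tf_ids, cell_ids, params, config,
                          want_cache = TRUE) {
  B <- nrow(codes)
  K <- config$num_filters
  rc <- t(apply(codes, 1L, revcomp_codes))
  if (B == 1L) rc <- matrix(rc, 1L)
  fwd <- .strand_forward(codes, params, config, want_cache)
  rev <- .strand_forward(rc, params, config, want_cache)
  nw <- fwd$nw

  E2 <- cbind(params$E_tf[tf_ids, , drop = FALSE],
              params$E_cell[cell_ids, , drop = FALSE])     # B x 2d
  Gpre <- E2 %*% t(params$W1) + matrix(params$b1, B, K, byrow = TRUE)
  G <- plogis(Gpre)
  Gfull <- G[, rep(seq_len(K), nw), drop = FALSE]          # broadcast windows

  strand_out <- function(st) {
    M <- st$P * Gfull
    O <- M %*% t(params$W2) + matrix(params$b2, B, config$fc_size, byrow = TRUE)
    jm <- max.col(O, ties.method = "first")
    list(M = M, jmax = jm, f = O[cbind(seq_len(B), jm)])
  }
  of <- strand_out(fwd)
  orv <- strand_out(rev)
  win_fwd <- of$f >= orv$f
  score <- ifelse(win_fwd, of$f, orv$f)
  out <- list(score = score, G = G)
  if (want_cache) {
    out$cache <- list(fwd = fwd, rev = rev, of = of, orv = orv,
                      win_fwd = win_fwd, E2 = E2, G = G, Gfull = Gfull,
                      Gpre = Gpre, tf_ids = tf_ids, cell_ids = cell_ids,
                      codes = codes, rc = rc)
  }
  out
}

# backward pass: dscore (length B) -> gradients for all parameter groups
backward_batch <- function(dscore, fw, params, config) {
  ch <- fw$cache
  B <- length(dscore)
  K <- config$num_filters
  f <- config$filter_length
  nw <- ch$fwd$nw
  d <- config$embed_dim

  grads <- list(
    E_tf = matrix(0, nrow(params$E_tf), d),
    E_cell = matrix(0, nrow(params$E_cell), d),
    W = array(0, dim = dim(params$W)),
    b = rep(0, K),
    W1 = matrix(0, nrow(params$W1), ncol(params$W1)),
    b1 = rep(0, K),
    W2 = matrix(0, nrow(params$W2), ncol(params$W2)),
    b2 = rep(0, config$fc_size)
  )
  dG <- matrix(0, B, K)

  for (strand in c("fwd", "rev")) {
    st <- ch[[strand]]
    o <- if (strand == "fwd") ch$of else ch$orv
    act <- if (strand == "fwd") dscore * ch$win_fwd else dscore * (!ch$win_fwd)
    live <- which(act != 0)
    if (!length(live)) next
    dO <- matrix(0, B, config$fc_size)
    dO[cbind(live, o$jmax[live])] <- act[live]
    grads$W2 <- grads$W2 + t(dO) %*% o$M
    grads$b2 <- grads$b2 + colSums(dO)
    dM <- dO %*% params$W2                      # B x (nw*K)
    dP <- dM * ch$Gfull
    dGf <- dM * st$P
    for (w in seq_len(nw))
      dG <- dG + dGf[, (w - 1L) * K + seq_len(K), drop = FALSE]
    bp <- conv_pool_backward_cpp(st$codes, st$argmax, st$mask, dP, f, K,
                                 config$relu_mode == "literal")
    grads$W <- grads$W + array(bp$dW, dim = dim(params$W))
    grads$b <- grads$b + bp$db
  }

  dGpre <- dG * ch$G * (1 - ch$G)
  grads$W1 <- t(dGpre) %*% ch$E2
  grads$b1 <- colSums(dGpre)
  dE2 <- dGpre %*% params$W1                    # B x 2d
  gtf <- rowsum(dE2[, seq_len(d), drop = FALSE], group = ch$tf_ids)
  grads$E_tf[as.integer(rownames(gtf)), ] <- gtf
  gcl <- rowsum(dE2[, d + seq_len(d), drop = FALSE], group = ch$cell_ids)
  grads$E_cell[as.integer(rownames(gcl)), ] <- gcl
  grads
}

# Binary cross-entropy loss and its score-gradient for a batch.
bce_loss <- function(score, label) {
  p <- plogis(score)
  eps <- 1e-12
  loss <- -mean(label * log(p + eps) + (1 - label) * log(1 - p + eps))
  dscore <- (p - label) / length(score)
  list(loss = loss, dscore = dscore)
}

# ---------------------------------------------------------------------------
# Serialization: JSON container with config, vocabularies, fixed column
# order, and full-precision parameter arrays.
# ---------------------------------------------------------------------------

#' Save / load a trained model
#'
#' The model is stored as a single versioned JSON file holding the
#' configuration (including vocabularies and the fixed one-hot column order
#' A,C,G,T) and every parameter group at full precision.
#'
#' @param params a `tfgate_params`.
#' @param config a `tfgate_config`.
#' @param path output file.
#' @return `load_model()` returns `list(params=, config=)`.
#' @export
save_model <- function(params, config, path) {
  obj <- list(
    format = "tfgate-model",
    version = 1L,
    column_order = DNA_BASES,
    config = unclass(config),
    params = list(
      E_tf = params$E_tf, E_cell = params$E_cell,
      W = list(dim = dim(params$W), values = as.vector(params$W)),
      b = params$b, W1 = params$W1, b1 = params$b1,
      W2 = params$W2, b2 = params$b2
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tfgate-model"))
    stop("not a tfgate model file: ", path)
  cfgl <- obj$config
  config <- model_config(cfgl$tf_vocab, cfgl$cell_vocab,
                         seq_length = cfgl$seq_length,
                         filter_length = cfgl$filter_length,
                         num_filters = cfgl$num_filters,
                         pool_window = cfgl$pool_window,
                         fc_size = cfgl$fc_size,
                         embed_dim = cfgl$embed_dim,
                         relu_mode = cfgl$relu_mode)
  p <- obj$params
  params <- list(
    E_tf = matrix(p$E_tf, nrow = length(cfgl$tf_vocab),
                  dimnames = list(cfgl$tf_vocab, NULL)),
    E_cell = matrix(p$E_cell, nrow = length(cfgl$cell_vocab),
                    dimnames = list(cfgl$cell_vocab, NULL)),
    W = array(p$W$values, dim = p$W$dim,
              dimnames = list(NULL, DNA_BASES, NULL)),
    b = as.numeric(p$b),
    W1 = matrix(p$W1, nrow = cfgl$num_filters),
    b1 = as.numeric(p$b1),
    W2 = matrix(p$W2, nrow = cfgl$fc_size),
    b2 = as.numeric(p$b2)
  )
  class(params) <- "tfgate_params"
  list(params = params, config = config)
}
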